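#' @importFrom MASS mvrnorm
NULL

#' Simulate a guide library with a skewed abundance distribution
#'
#' Abundances are drawn log-normal(0, \code{skew_sd}); real plasmid pools
#' routinely span several orders of magnitude, and \code{skew_sd = 2.8}
#' reproduces a max/min ratio of 1e4-1e5 at g = 1000. When
#' \code{landscape_length} is given, targeting guides are tiled evenly
#' across the residues (each guide annotated with its primary
#' \code{residue}; the residue pair is \code{(residue, residue + 1)}
#' clipped at the terminus) and \code{n_controls} non-targeting control
#' guides (gene \code{"control"}, residue NA) are appended.
#'
#' @param g number of targeting guides (>= 1).
#' @param skew_sd log-normal sigma of abundances (0 = uniform pool).
#' @param seed integer seed; the generator is deterministic per seed.
#' @param landscape_length optional protein length for residue tiling.
#' @param n_controls number of non-targeting controls to append.
#' @param gene gene label for targeting guides.
#' @return A \linkS4class{GuideLibrary}.
#' @examples
#' simulateLibrary(10, skew_sd = 1, seed = 42)
#' @export
simulateLibrary <- function(g, skew_sd = 2.8, seed = 1L,
                            landscape_length = NULL, n_controls = 0L,
                            gene = "target") {
  if (g < 1) stop("g must be >= 1")
  if (skew_sd < 0) stop("skew_sd must be non-negative")
  set.seed(seed)
  n <- g + n_controls
  ab <- exp(rnorm(n, 0, skew_sd))
  genes <- c(rep(gene, g), rep("control", n_controls))
  res <- rep(NA_integer_, n)
  if (!is.null(landscape_length)) {
    ## even tiling: guide i targets the pair (res_i, res_i + 1)
    res[seq_len(g)] <- as.integer(round(seq(1, landscape_length - 1,
                                            length.out = g)))
  }
  GuideLibrary(guide_id = sprintf("sg%05d", seq_len(n)), abundance = ab,
               gene = genes, residue = res)
}

#' Effect landscape for a synthetic screen
#'
#' Smooth ground-truth per-residue effects built as sums of Gaussian
#' bumps: \code{function_effect} shifts the activation probability of
#' cells carrying an edit at that residue (negative = loss of activation)
#' and \code{dropout_effect} is a log2 fitness cost between the early and
#' late timepoint (negative = toxic).
#'
#' @param length protein length in residues.
#' @param function_bumps,dropout_bumps data.frames with columns
#'   \code{center, depth, sd} (depth is the signed effect at the peak).
#' @return data.frame(position, function_effect, dropout_effect).
#' @export
effectLandscape <- function(length,
                            function_bumps = data.frame(center = length / 2,
                                                        depth = -3,
                                                        sd = length / 12),
                            dropout_bumps = NULL) {
  pos <- seq_len(length)
  bump_sum <- function(bumps) {
    eff <- rep(0, length)
    if (is.null(bumps) || !nrow(bumps)) return(eff)
    for (i in seq_len(nrow(bumps)))
      eff <- eff + bumps$depth[i] *
        exp(-(pos - bumps$center[i])^2 / (2 * bumps$sd[i]^2))
    eff
  }
  data.frame(position = pos,
             function_effect = bump_sum(function_bumps),
             dropout_effect = bump_sum(dropout_bumps))
}

#' Per-guide editing-efficiency model
#'
#' Draws a true editing efficiency per guide (Beta distributed) together
#' with an observable, noisy "guide-dependent score" correlated with it
#' -- the synthetic analogue of sequence-based efficiency predictions.
#'
#' @param n_guides number of guides.
#' @param mean_eff mean editing efficiency in (0, 1).
#' @param concentration Beta concentration (larger = tighter).
#' @param score_noise_sd sd of the noise on the observable score.
#' @param seed integer seed.
#' @return data.frame(efficiency, efficiency_score) with one row per guide.
#' @export
guideEfficiencyModel <- function(n_guides, mean_eff = 0.7,
                                 concentration = 8, score_noise_sd = 0.05,
                                 seed = 1L) {
  stopifnot(mean_eff > 0, mean_eff < 1)
  set.seed(seed)
  eff <- stats::rbeta(n_guides, mean_eff * concentration,
                      (1 - mean_eff) * concentration)
  data.frame(efficiency = eff,
             efficiency_score = eff + rnorm(n_guides, 0, score_noise_sd))
}

#' Simulate a pooled tiling screen
#'
#' Cell-level generative model per replicate: guides per cell are
#' Poisson(\code{moi}); each integrated guide edits its locus with the
#' guide's efficiency; an edited locus contributes the residue's
#' \code{dropout_effect} to the cell's log2 survival weight between day 6
#' and day 14, and its \code{function_effect} to the logit of the cell's
#' activation probability (baseline \code{p_act}). Cells are sorted into
#' activated / unactivated pools by a Bernoulli draw and reads per sample
#' are multinomial over cell-weighted guide frequencies at the requested
#' depth. Non-targeting controls (residue NA) carry no effect.
#'
#' @param library a \linkS4class{GuideLibrary} with a \code{residue}
#'   column (NA for controls).
#' @param landscape data.frame from \code{\link{effectLandscape}}.
#' @param efficiency data.frame from \code{\link{guideEfficiencyModel}}
#'   (or NULL for efficiency 1).
#' @param cells cells transduced per replicate.
#' @param moi multiplicity of infection.
#' @param depth reads per sample.
#' @param replicates biological replicates.
#' @param p_act baseline activation probability.
#' @param seed integer; replicate j uses stream \code{seed + j}.
#' @return A \linkS4class{ScreenCounts} with samples day6/day14/
#'   activated/unactivated per replicate and the ground truth in
#'   \code{metadata()}.
#' @export
simulateScreen <- function(library, landscape, efficiency = NULL,
                           cells = 50000L, moi = 0.3, depth = 500000L,
                           replicates = 3L, p_act = 0.5, seed = 1L) {
  tab <- guideTable(library)
  if (!"residue" %in% names(tab))
    stop("library needs a 'residue' column (NA for non-targeting controls)")
  res <- tab$residue
  ok <- is.na(res) | (res >= 1 & res <= nrow(landscape))
  if (!all(ok))
    stop("guide residues must lie in [1, landscape length] or be NA")
  g <- nrow(tab)
  eff <- if (is.null(efficiency)) rep(1, g) else efficiency$efficiency
  stopifnot(length(eff) == g)
  fx_fun <- ifelse(is.na(res), 0, landscape$function_effect[res])
  fx_dro <- ifelse(is.na(res), 0, landscape$dropout_effect[res])
  prob <- tab$abundance / sum(tab$abundance)

  n_samp <- 4L * replicates
  counts <- matrix(0L, nrow = g, ncol = n_samp)
  cond <- rep(c("day6", "day14", "activated", "unactivated"), replicates)
  repl <- rep(seq_len(replicates), each = 4L)

  for (j in seq_len(replicates)) {
    set.seed(seed + j)
    k_per_cell <- rpois(cells, moi)
    total <- sum(k_per_cell)
    if (total == 0L) next
    gi <- sample.int(g, total, replace = TRUE, prob = prob)
    cell <- rep.int(seq_len(cells), k_per_cell)
    edited <- rbinom(total, 1L, eff[gi]) == 1L
    ## per-cell log2 survival and activation logit shift from edited loci
    drop_c <- rowsum(ifelse(edited, fx_dro[gi], 0), cell)[, 1]
    fun_c <- rowsum(ifelse(edited, fx_fun[gi], 0), cell)[, 1]
    cid <- sort(unique(cell))  # cells carrying at least one guide
    idx <- match(cell, cid)
    w14_c <- 2^drop_c
    act_c <- rbinom(length(cid), 1L, stats::plogis(stats::qlogis(p_act) +
                                                   fun_c)) == 1L
    w6 <- rowsum(rep(1, total), gi)
    w14 <- rowsum(w14_c[idx], gi)
    wact <- rowsum(w14_c[idx] * act_c[idx], gi)
    wun <- rowsum(w14_c[idx] * (!act_c[idx]), gi)
    expand <- function(w) {
      out <- numeric(g)
      out[as.integer(rownames(w))] <- w[, 1]
      out
    }
    draw <- function(w) {
      if (sum(w) <= 0) return(integer(g))
      as.integer(stats::rmultinom(1, depth, w))
    }
    base <- (j - 1L) * 4L
    counts[, base + 1L] <- draw(expand(w6))
    counts[, base + 2L] <- draw(expand(w14))
    counts[, base + 3L] <- draw(expand(wact))
    counts[, base + 4L] <- draw(expand(wun))
  }
  sc <- ScreenCounts(counts, guide_id = tab$guide_id,
                     gene = if ("gene" %in% names(tab)) tab$gene
                            else rep("target", g),
                     condition = cond, replicate = repl)
  metadata(sc) <- list(landscape = landscape, efficiency = eff,
                       residue = res, moi = moi, depth = depth,
                       p_act = p_act, seed = seed)
  sc
}

#' Simulate flow-cytometry events from a Gaussian mixture
#'
#' @param n_events number of events.
#' @param populations list of populations, each a list with \code{mean}
#'   (channel vector), \code{cov} (covariance matrix), \code{weight}, and
#'   \code{label}; weights must sum to 1.
#' @param seed integer seed.
#' @return data.frame with \code{event_id}, one column per channel
#'   (named from the mean vector, else \code{ch1..}), and the ground-truth
#'   \code{label}.
#' @export
simulateFacsEvents <- function(n_events, populations, seed = 1L) {
  w <- vapply(populations, function(p) p$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("population weights must sum to 1")
  for (p in populations) {
    ev <- eigen(as.matrix(p$cov), symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8)) stop("covariance must be positive semi-definite")
  }
  d <- length(populations[[1]]$mean)
  ch <- names(populations[[1]]$mean)
  if (is.null(ch)) ch <- paste0("ch", seq_len(d))
  set.seed(seed)
  if (n_events == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, d, dimnames = list(NULL, ch)))
    return(cbind(data.frame(event_id = character(0)), out,
                 data.frame(label = character(0))))
  }
  comp <- sample.int(length(populations), n_events, replace = TRUE, prob = w)
  X <- matrix(0, n_events, d, dimnames = list(NULL, ch))
  for (i in seq_along(populations)) {
    idx <- which(comp == i)
    if (!length(idx)) next
    X[idx, ] <- mvrnorm(length(idx), populations[[i]]$mean,
                        as.matrix(populations[[i]]$cov))
  }
  lab <- vapply(populations, function(p) p$label, character(1))[comp]
  data.frame(event_id = sprintf("ev%06d", seq_len(n_events)), X,
             label = lab, check.names = FALSE)
}

#' Simulate a molecular-descriptor dataset with linear logBB
#'
#' Descriptors are standard normal; logBB is their linear combination
#' plus Gaussian noise; the binary penetrance class is
#' \code{logBB >= class_threshold}.
#'
#' @param n compounds (>= 2).
#' @param n_descriptors descriptor count.
#' @param coef length-\code{n_descriptors} coefficient vector.
#' @param noise_sd sd of the additive noise on logBB.
#' @param class_threshold class boundary on logBB.
#' @param seed integer seed.
#' @return list(descriptors = data.frame, logbb = numeric,
#'   bbb_class = integer 0/1, compound_key = character).
#' @export
simulateBBBDataset <- function(n, n_descriptors = 10L,
                               coef = rep(1, n_descriptors),
                               noise_sd = 0.1, class_threshold = 0,
                               seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  if (length(coef) != n_descriptors)
    stop("length(coef) must equal n_descriptors")
  set.seed(seed)
  X <- matrix(rnorm(n * n_descriptors), n, n_descriptors,
              dimnames = list(NULL, paste0("d", seq_len(n_descriptors))))
  logbb <- drop(X %*% coef) + rnorm(n, 0, noise_sd)
  list(descriptors = as.data.frame(X), logbb = logbb,
       bbb_class = as.integer(logbb >= class_threshold),
       compound_key = sprintf("cmpd%05d", seq_len(n)))
}

#' Analytic expected scores under the generative screen model
#'
#' Expected per-guide function and dropout scores implied by the
#' simulator, for single-guide cells at sequencing depth -> infinity:
#' a guide with editing efficiency \code{eff} targeting a residue with
#' effects \code{(function_effect, dropout_effect)} yields a mixture of
#' edited and unedited cells, giving
#' \code{log2(odds(w)) - log2(odds(p_act))} for the function score
#' (where \code{w = eff * plogis(qlogis(p_act) + effect) +
#' (1 - eff) * p_act}) and \code{log2(eff * 2^effect + 1 - eff)} for the
#' dropout score (up to a library-wide normalisation offset that is
#' negligible when few guides carry effects). These are the oracles used
#' to check parameter recovery.
#'
#' @param effect per-residue effect (logit shift for function, log2
#'   fitness for dropout).
#' @param eff editing efficiency in [0, 1].
#' @param p_act baseline activation probability.
#' @return Expected score(s).
#' @export
expectedFunctionScore <- function(effect, eff = 1, p_act = 0.5) {
  w <- eff * stats::plogis(stats::qlogis(p_act) + effect) +
    (1 - eff) * p_act
  log2(w / (1 - w)) - log2(p_act / (1 - p_act))
}

#' @rdname expectedFunctionScore
#' @export
expectedDropoutScore <- function(effect, eff = 1) {
  log2(eff * 2^effect + 1 - eff)
}
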