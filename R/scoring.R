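#' Score guides from a screen count table
#'
#' Computes, per biological replicate, the dropout score
#' \code{log2((day14 + a)/(day6 + a))} and the function score
#' \code{log2((activated + a)/(unactivated + a))}, optionally on
#' counts-per-million-normalised counts, then averages replicates into a
#' mean score per unique sgRNA. With normalisation on, the pseudocount is
#' applied on the CPM scale (a CPM-equivalents), so a sample's total depth
#' cancels out of the fold change.
#'
#' @param counts a \linkS4class{ScreenCounts}.
#' @param pseudocount positive pseudocount \code{a}.
#' @param normalize logical; per-sample counts-per-million normalisation.
#' @return data.frame with \code{guide_id}, \code{gene}, per-replicate
#'   columns \code{dropout_r<i>} / \code{function_r<i>}, and the
#'   replicate means \code{dropout} and \code{function}.
#' @examples
#' lib <- simulateLibrary(50, skew_sd = 0.5, seed = 1, landscape_length = 30)
#' sc <- simulateScreen(lib, effectLandscape(30), cells = 5000,
#'                      depth = 50000, seed = 1)
#' head(scoreGuides(sc))
#' @export
scoreGuides <- function(counts, pseudocount = 1, normalize = TRUE) {
  stopifnot(is(counts, "ScreenCounts"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  cd <- as.data.frame(colData(counts))
  m <- assay(counts, "counts")
  if (normalize) {
    tot <- colSums(m)
    tot[tot == 0] <- 1
    m <- sweep(m, 2, tot, "/") * 1e6
  }
  reps <- sort(unique(cd$replicate))
  pick <- function(condition, r) {
    j <- which(cd$condition == condition & cd$replicate == r)
    if (length(j) != 1L)
      stop("need exactly one '", condition, "' sample in replicate ", r)
    m[, j]
  }
  out <- data.frame(guide_id = rowData(counts)$guide_id,
                    gene = rowData(counts)$gene,
                    stringsAsFactors = FALSE)
  lfc <- function(num, den) log2((num + pseudocount) / (den + pseudocount))
  for (r in reps) {
    out[[paste0("dropout_r", r)]] <- lfc(pick("day14", r), pick("day6", r))
    out[[paste0("function_r", r)]] <- lfc(pick("activated", r),
                                          pick("unactivated", r))
  }
  out$dropout <- rowMeans(out[, paste0("dropout_r", reps), drop = FALSE])
  out$functional <- rowMeans(out[, paste0("function_r", reps), drop = FALSE])
  out
}

#' Map guide cut sites onto protein residues
#'
#' Cas9 cuts bluntly ~3 bp 5' of the NGG PAM, i.e. between protospacer
#' positions 17 and 18. For each guide the cut is treated as the genomic
#' boundary between \code{cut_site} and \code{cut_site + 1} (plus-strand
#' coordinates) and projected onto the coding sequence: if the boundary
#' coincides with a codon boundary the two flanking residues are
#' returned; otherwise the containing residue and its nearest neighbour
#' (the one sharing the closer codon edge), clipped into the protein.
#'
#' @param library a \linkS4class{GuideLibrary} whose table carries
#'   \code{cut_site} (genomic coordinate of the base immediately 5' of
#'   the blunt cut, plus-strand) -- see \code{\link{cutSiteFromPam}}.
#' @param cds coding-sequence annotation: a data.frame of exons with
#'   columns \code{start, end} (1-based inclusive genomic, in genomic
#'   order) plus an attribute-free \code{strand} argument.
#' @param strand \code{"+"} or \code{"-"}: strand of the CDS.
#' @return data.frame(guide_id, residue1, residue2, mapped); unmapped
#'   guides (cut outside the CDS) have NA residues and
#'   \code{mapped = FALSE}.
#' @export
mapGuidesToResidues <- function(library, cds, strand = "+") {
  tab <- guideTable(library)
  if (!"cut_site" %in% names(tab))
    stop("library needs a 'cut_site' column")
  stopifnot(all(c("start", "end") %in% names(cds)),
            strand %in% c("+", "-"))
  ## genomic positions of CDS nucleotides in translation order
  pos <- unlist(lapply(seq_len(nrow(cds)),
                       function(i) cds$start[i]:cds$end[i]))
  if (strand == "-") pos <- rev(pos)
  n_nt <- length(pos)
  if (n_nt %% 3 != 0)
    warning("CDS length is not a multiple of 3; trailing bases ignored")
  n_res <- n_nt %/% 3
  idx_of <- function(p) match(p, pos)  # translation-order index or NA

  res1 <- res2 <- rep(NA_integer_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cs <- tab$cut_site[i]
    if (is.na(cs)) next
    ## genomic boundary between cs and cs+1 -> translation-order boundary
    a <- idx_of(cs); b <- idx_of(cs + 1L)
    if (is.na(a) && is.na(b)) next
    ## n = translation index of the base 5' of the cut (strand-aware)
    n <- if (strand == "+") a else b
    if (is.na(n)) n <- (if (strand == "+") b else a) - 1L
    if (is.na(n) || n < 0L || n > n_res * 3L) next
    r <- ceiling(n / 3)
    phase <- n %% 3L
    pair <- if (phase == 0L) c(r, r + 1L)         # codon boundary
            else if (phase == 1L) c(r - 1L, r)    # after base 1: left edge
            else c(r, r + 1L)                     # after base 2: right edge
    pair <- pmin(pmax(pair, 1L), n_res)
    res1[i] <- min(pair); res2[i] <- max(pair)
  }
  data.frame(guide_id = tab$guide_id, residue1 = res1, residue2 = res2,
             mapped = !is.na(res1))
}

#' Genomic cut coordinate from a PAM location
#'
#' Returns the plus-strand genomic coordinate of the base immediately 5'
#' of the blunt Cas9 cut (between protospacer positions 17 and 18, 3 bp
#' from the PAM), given where the NGG PAM starts.
#'
#' @param pam_start genomic coordinate of the first PAM base (the N).
#' @param strand guide strand, \code{"+"} or \code{"-"}.
#' @return Integer coordinate; the cut is the boundary between the
#'   returned position and the next one.
#' @export
cutSiteFromPam <- function(pam_start, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  ifelse(strand == "+", pam_start - 4L, pam_start + 3L)
}

#' Aggregate guide scores onto residues
#'
#' Each mapped guide contributes its replicate-mean score to both
#' residues of its pair; a residue's raw score is the mean over all
#' contributions. Residues with no guides are absent from the output.
#'
#' @param scores guide-score table from \code{\link{scoreGuides}}.
#' @param mapping data.frame from \code{\link{mapGuidesToResidues}}, or
#'   NULL to use a \code{residue} column already present in
#'   \code{scores} (pair \code{(residue, residue + 1)}).
#' @param score_cols which score columns to aggregate.
#' @return A \linkS4class{ResidueProfile} with columns \code{position},
#'   one \code{<score>_raw} per score type and \code{n_guides}.
#' @export
aggregateByResidue <- function(scores,
                               mapping = NULL,
                               score_cols = c("dropout", "functional")) {
  if (is.null(mapping)) {
    if (!"residue" %in% names(scores))
      stop("provide 'mapping' or a 'residue' column in scores")
    mapping <- data.frame(guide_id = scores$guide_id,
                          residue1 = scores$residue,
                          residue2 = scores$residue + 1L,
                          mapped = !is.na(scores$residue))
  }
  df <- merge(scores, mapping, by = "guide_id")
  df <- df[df$mapped, , drop = FALSE]
  if (!nrow(df))
    return(ResidueProfile(data.frame(position = integer(0))))
  long <- rbind(data.frame(position = df$residue1, df[score_cols]),
                data.frame(position = df$residue2, df[score_cols]))
  agg <- stats::aggregate(long[score_cols], by = list(position = long$position),
                          FUN = mean)
  names(agg)[-1] <- paste0(score_cols, "_raw")
  agg$n_guides <- stats::aggregate(list(n = rep(1, nrow(long))),
                                   by = list(position = long$position),
                                   FUN = sum)$n
  ResidueProfile(agg)
}

## Dunn's post-hoc z-tests with tie correction and Bonferroni adjustment
.dunn_test <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  rk <- rank(x)
  ties <- table(rk)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, g, mean)
  n <- table(g)
  lev <- levels(g)
  cmb <- utils::combn(lev, 2)
  m <- ncol(cmb)
  z <- p <- numeric(m)
  for (i in seq_len(m)) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt((N * (N + 1) / 12 - tiecorr) * (1 / n[a] + 1 / n[b]))
    z[i] <- (rbar[a] - rbar[b]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = z,
             p = p, p_bonferroni = pmin(p * m, 1))
}

#' Group statistics for guide scores across target genes
#'
#' Kruskal-Wallis rank test (tie-corrected) across gene groups, followed
#' by Dunn's pairwise z-tests with Bonferroni correction, per-group
#' medians and percent changes relative to a control group. Because the
#' scores are log2 fold changes, percent change is reported both on the
#' ratio scale (group median of \code{2^score} vs control, the default
#' reading of a "percent reduction in median read-count ratio") and on
#' the back-transformed median log2 score.
#'
#' @param scores numeric vector of per-guide mean scores.
#' @param groups group (gene) labels, same length.
#' @param control name of the control group for percent changes.
#' @return list(H, df, p, dunn, medians, percent_change_ratio,
#'   percent_change_medianlog) -- the two percent-change tables are NULL
#'   when \code{control} is absent. Groups with fewer than 2 observations
#'   are dropped with a warning.
#' @examples
#' groupStats(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3), control = "a")
#' @export
groupStats <- function(scores, groups, control = "control") {
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]; groups <- as.character(groups)[keep]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping groups with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    scores <- scores[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need >= 2 groups with >= 2 values")
  if (length(unique(scores)) == 1) {
    ## all observations tied: no rank variation, H = 0 by convention
    kw <- list(statistic = c(H = 0), parameter =
                 c(df = length(unique(groups)) - 1), p.value = 1)
  } else {
    kw <- stats::kruskal.test(scores, factor(groups))
  }
  med <- tapply(scores, groups, stats::median)
  pc_ratio <- pc_mlog <- NULL
  if (control %in% groups) {
    med_ratio <- tapply(2^scores, groups, stats::median)
    pc_ratio <- 100 * (med_ratio / med_ratio[[control]] - 1)
    pc_mlog <- 100 * (2^med / 2^med[[control]] - 1)
  }
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, dunn = .dunn_test(scores, groups),
       medians = med, percent_change_ratio = pc_ratio,
       percent_change_medianlog = pc_mlog)
}
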