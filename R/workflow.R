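#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
NULL

.default_config <- function() {
  list(
    seed = 1L,
    outdir = "tilescreen_run",
    library = list(g = 500L, skew_sd = 1.5, n_controls = 50L),
    landscape = list(length = 200L,
                     function_center = 100, function_depth = -3,
                     function_sd = 20,
                     dropout_center = 60, dropout_depth = -1,
                     dropout_sd = 15),
    efficiency = list(mean_eff = 0.7, concentration = 8,
                      score_noise_sd = 0.05),
    screen = list(cells = 30000L, moi = 0.3, depth = 300000L,
                  replicates = 3L, p_act = 0.5),
    design = list(k = 1L, r = 100L, titer_f0 = 0.7, titer_cells = 1e6,
                  titer_volume = 10),
    score = list(pseudocount = 1, normalize = TRUE),
    correct = list(n_folds = 8L, nrounds = 150L),
    funcseq = list(score_col = "functional_corrected"))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and normalise a pipeline configuration
#'
#' @param config a named list of overrides, or the path to a YAML file
#'   with the same structure; missing fields take package defaults.
#' @return Complete configuration list.
#' @export
loadConfig <- function(config = list()) {
  if (is.character(config)) config <- read_yaml(config)
  .merge_config(.default_config(), config)
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks with actionable messages; never throws.
#'
#' @param config list or YAML path (see \code{\link{loadConfig}}).
#' @return list(ok = logical, failures = character vector).
#' @export
validateConfig <- function(config) {
  cfg <- tryCatch(loadConfig(config), error = function(e) NULL)
  if (is.null(cfg))
    return(list(ok = FALSE, failures = "config could not be parsed"))
  fail <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) fail <<- c(fail, msg)
  chk(is.numeric(cfg$seed), "seed must be numeric")
  chk(cfg$design$k >= 1, "design$k must be >= 1")
  chk(cfg$design$r >= 1, "design$r must be >= 1")
  chk(cfg$library$g >= 1, "library$g must be >= 1")
  chk(cfg$library$skew_sd >= 0, "library$skew_sd must be >= 0")
  chk(cfg$landscape$length >= 3, "landscape$length must be >= 3")
  chk(cfg$screen$moi > 0, "screen$moi must be > 0")
  chk(cfg$screen$replicates >= 1, "screen$replicates must be >= 1")
  chk(cfg$score$pseudocount > 0, "score$pseudocount must be > 0")
  chk(cfg$correct$n_folds >= 2, "correct$n_folds must be >= 2")
  n_res <- cfg$landscape$length
  chk(n_res >= 2 * cfg$correct$n_folds,
      "landscape$length must be >= 2 * correct$n_folds rows for OOF")
  if (!is.null(cfg$design$titer_f0))
    chk(cfg$design$titer_f0 > 0 && cfg$design$titer_f0 < 1,
        "design$titer_f0 must be in (0, 1)")
  for (p in c(cfg$library$path, cfg$rank$compounds))
    if (!is.null(p) && !file.exists(p))
      fail <- c(fail, paste("missing file:", p))
  list(ok = length(fail) == 0, failures = fail)
}

#' Run the end-to-end tiling-screen pipeline
#'
#' Executes design -> simulate -> score -> correct -> funcseq (and
#' optionally compound ranking) from a single configuration, writing
#' per-stage plain-text outputs and a JSON manifest (seeds, parameters,
#' output hashes) to the output directory. A stage is skipped when its
#' outputs already exist and no upstream stage was re-run, so deleting
#' one stage's outputs regenerates only that stage and everything
#' downstream.
#'
#' @param config list or YAML path (see \code{\link{loadConfig}}).
#' @param force re-run every stage regardless of existing outputs.
#' @return The manifest, invisibly; also written to
#'   \code{<outdir>/manifest.json}.
#' @export
runPipeline <- function(config = list(), force = FALSE) {
  cfg <- loadConfig(config)
  v <- validateConfig(cfg)
  if (!v$ok)
    stop("invalid config:\n  ", paste(v$failures, collapse = "\n  "))
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out, f)
  ran <- c()
  upstream_ran <- FALSE
  stage <- function(name, outputs, fn) {
    need <- force || upstream_ran || !all(file.exists(path(outputs)))
    if (need) {
      res <- tryCatch(fn(), error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
      upstream_ran <<- TRUE
      ran <<- c(ran, name)
      res
    } else NULL
  }

  ## design + library ------------------------------------------------
  stage("design", c("library.tsv", "design.json"), function() {
    lib <- if (!is.null(cfg$library$path)) readGuideLibrary(cfg$library$path)
           else simulateLibrary(cfg$library$g, cfg$library$skew_sd,
                                seed = cfg$seed,
                                landscape_length = cfg$landscape$length,
                                n_controls = cfg$library$n_controls)
    writeGuideLibrary(lib, path("library.tsv"))
    des <- coverageDesign(lib, k = cfg$design$k, r = cfg$design$r,
                          titer_f0 = cfg$design$titer_f0,
                          titer_cells = cfg$design$titer_cells,
                          titer_volume = cfg$design$titer_volume)
    write_json(list(k = des@k, r = des@r,
                    n_combinations = des@n_combinations,
                    draws_bound = des@draws_bound,
                    cells_required = des@cells_required,
                    virions_required = des@virions_required,
                    titer = des@titer, approximate = des@approximate),
               path("design.json"), auto_unbox = TRUE, digits = NA)
  })
  lib <- readGuideLibrary(path("library.tsv"))

  ## simulate ---------------------------------------------------------
  stage("simulate", c("counts.tsv", "truth_landscape.csv",
                      "guide_truth.csv"), function() {
    ls <- cfg$landscape
    land <- effectLandscape(
      ls$length,
      function_bumps = data.frame(center = ls$function_center,
                                  depth = ls$function_depth,
                                  sd = ls$function_sd),
      dropout_bumps = data.frame(center = ls$dropout_center,
                                 depth = ls$dropout_depth,
                                 sd = ls$dropout_sd))
    eff <- guideEfficiencyModel(nGuides(lib),
                                mean_eff = cfg$efficiency$mean_eff,
                                concentration = cfg$efficiency$concentration,
                                score_noise_sd = cfg$efficiency$score_noise_sd,
                                seed = cfg$seed + 1L)
    sc <- simulateScreen(lib, land, eff, cells = cfg$screen$cells,
                         moi = cfg$screen$moi, depth = cfg$screen$depth,
                         replicates = cfg$screen$replicates,
                         p_act = cfg$screen$p_act, seed = cfg$seed + 2L)
    writeScreenCounts(sc, path("counts.tsv"))
    utils::write.csv(land, path("truth_landscape.csv"), row.names = FALSE)
    utils::write.csv(cbind(guide_id = guideTable(lib)$guide_id, eff,
                           residue = guideTable(lib)$residue),
                     path("guide_truth.csv"), row.names = FALSE)
  })

  ## score ------------------------------------------------------------
  stage("score", c("guide_scores.tsv", "profile_raw.csv"), function() {
    counts <- readScreenCounts(path("counts.tsv"))
    gs <- scoreGuides(counts, pseudocount = cfg$score$pseudocount,
                      normalize = cfg$score$normalize)
    gs$residue <- guideTable(lib)$residue[match(gs$guide_id,
                                                guideTable(lib)$guide_id)]
    utils::write.table(gs, path("guide_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    prof <- aggregateByResidue(gs)
    utils::write.csv(profileData(prof), path("profile_raw.csv"),
                     row.names = FALSE)
  })

  ## correct ----------------------------------------------------------
  stage("correct", c("profile_corrected.csv", "profile_plot.pdf"),
        function() {
    prof <- ResidueProfile(utils::read.csv(path("profile_raw.csv")))
    gs <- utils::read.delim(path("guide_scores.tsv"))
    truth <- utils::read.csv(path("guide_truth.csv"))
    feats <- residueFeatures(profileData(prof)$position, gs, truth)
    corrected <- correctProfile(prof, feats,
                                guide_cols = "efficiency_score",
                                n_folds = cfg$correct$n_folds,
                                seed = cfg$seed + 3L,
                                nrounds = cfg$correct$nrounds)
    utils::write.csv(profileData(corrected), path("profile_corrected.csv"),
                     row.names = FALSE)
    d <- profileData(corrected)
    grDevices::pdf(path("profile_plot.pdf"), width = 8, height = 5)
    graphics::plot(d$position, d$functional_raw, pch = 16, cex = 0.5,
         col = "grey60", xlab = "residue position",
         ylab = "function score (log2 act/unact)",
         main = "raw vs OOF vs bias-corrected function landscape")
    graphics::lines(d$position, d$functional_oof, col = "steelblue", lwd = 2)
    graphics::lines(d$position, d$functional_corrected, col = "firebrick",
                    lwd = 2)
    graphics::legend("bottomleft",
                     c("raw residue mean", "pre-correction OOF",
                       "bias-corrected"),
                     col = c("grey60", "steelblue", "firebrick"),
                     pch = c(16, NA, NA), lty = c(NA, 1, 1), bty = "n")
    grDevices::dev.off()
  })

  ## funcseq ----------------------------------------------------------
  stage("funcseq", "interval.json", function() {
    prof <- ResidueProfile(utils::read.csv(path("profile_corrected.csv")))
    iv <- fwhmInterval(prof, score_col = cfg$funcseq$score_col)
    write_json(intervalAsList(iv), path("interval.json"),
               auto_unbox = TRUE, digits = NA)
  })

  ## rank (optional) --------------------------------------------------
  if (!is.null(cfg$rank$compounds) && !is.null(cfg$rank$sequence)) {
    stage("rank", "compound_ranks.csv", function() {
      cmp <- readCompoundLibrary(cfg$rank$compounds)
      iv <- read_json(path("interval.json"))
      seqs <- cfg$rank$sequence
      scorer <- kmerStubScorer()
      region <- substr(seqs, iv$start, iv$end)
      sc <- vapply(cmp$smiles, scorer, numeric(1), sequence = region,
                   USE.NAMES = FALSE)
      rk <- rankCompounds(data.frame(compound_id = cmp$compound_id,
                                     score = sc))
      utils::write.csv(rk, path("compound_ranks.csv"), row.names = FALSE)
    })
  }

  outputs <- list.files(out, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.json")
  manifest <- list(
    package = "tilescreen",
    version = as.character(utils::packageVersion("tilescreen")),
    seed = cfg$seed, config = cfg, stages_run = as.list(ran),
    outputs = as.list(tools::md5sum(file.path(out, outputs))))
  write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
             digits = NA)
  invisible(manifest)
}

#' Per-residue feature table for bias correction
#'
#' Aggregates the guide-dependent efficiency score onto residues (mean
#' over guides assigned to each position, both members of the pair) and
#' adds the residue position itself as a context feature. Used by the
#' pipeline's correction stage; analyses with richer annotations
#' (conservation, disorder, SASA, 3D coordinates, amino-acid identity)
#' pass their own feature table to \code{\link{correctProfile}}.
#'
#' @param positions residue positions (profile rows, in order).
#' @param guide_scores guide-score table with a \code{residue} column.
#' @param guide_truth data.frame with \code{guide_id} and
#'   \code{efficiency_score}.
#' @return data.frame of features aligned with \code{positions}.
#' @export
residueFeatures <- function(positions, guide_scores, guide_truth) {
  df <- merge(guide_scores[, c("guide_id", "residue")],
              guide_truth[, c("guide_id", "efficiency_score")],
              by = "guide_id")
  df <- df[!is.na(df$residue), ]
  long <- rbind(data.frame(position = df$residue, es = df$efficiency_score),
                data.frame(position = df$residue + 1L,
                           es = df$efficiency_score))
  agg <- stats::aggregate(list(efficiency_score = long$es),
                          by = list(position = long$position), FUN = mean)
  out <- data.frame(position = positions)
  out$efficiency_score <- agg$efficiency_score[match(positions,
                                                     agg$position)]
  out
}
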