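#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' GuideLibrary: a pooled sgRNA library with abundances
#'
#' Container for a guide library table: one row per sgRNA with its
#' plasmid-pool abundance (raw read count or frequency; normalisation is
#' internal to whatever consumes it) and optional protospacer, target gene,
#' genomic cut coordinate and strand. Abundances must be strictly positive
#' and guide ids unique; abundances need not sum to one.
#'
#' @slot guides data.frame with at least columns \code{guide_id} and
#'   \code{abundance}; optional columns \code{gene}, \code{protospacer},
#'   \code{cut_site}, \code{strand}, \code{residue}.
#' @export
setClass("GuideLibrary", representation(guides = "data.frame"))

setValidity("GuideLibrary", function(object) {
  g <- object@guides
  msg <- character()
  if (!all(c("guide_id", "abundance") %in% names(g)))
    msg <- c(msg, "guides must have columns 'guide_id' and 'abundance'")
  else {
    if (anyDuplicated(g$guide_id))
      msg <- c(msg, "guide_ids must be unique")
    if (!is.numeric(g$abundance) || any(!is.finite(g$abundance)) ||
        any(g$abundance <= 0))
      msg <- c(msg, "all abundances must be finite and strictly > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GuideLibrary
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param abundance strictly positive numeric vector (read counts or
#'   frequencies).
#' @param gene optional target gene labels (use e.g. \code{"control"} for
#'   non-targeting guides).
#' @param ... further per-guide columns (e.g. \code{protospacer},
#'   \code{cut_site}, \code{strand}, \code{residue}).
#' @return A \linkS4class{GuideLibrary}.
#' @examples
#' lib <- GuideLibrary(paste0("g", 1:4), c(10, 20, 5, 5))
#' nGuides(lib)
#' @export
GuideLibrary <- function(guide_id, abundance, gene = NULL, ...) {
  df <- data.frame(guide_id = as.character(guide_id),
                   abundance = as.numeric(abundance),
                   stringsAsFactors = FALSE)
  if (!is.null(gene)) df$gene <- as.character(gene)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  new("GuideLibrary", guides = df)
}

#' @describeIn GuideLibrary number of guides in the library
#' @param x,object a \code{GuideLibrary}
#' @export
nGuides <- function(x) nrow(x@guides)

#' @describeIn GuideLibrary abundance vector, named by guide id
#' @export
guideAbundance <- function(x) {
  stats::setNames(x@guides$abundance, x@guides$guide_id)
}

#' @describeIn GuideLibrary the underlying per-guide table
#' @export
guideTable <- function(x) x@guides

setMethod("show", "GuideLibrary", function(object) {
  a <- object@guides$abundance
  cat("GuideLibrary with", nrow(object@guides), "guides\n")
  cat(sprintf("  abundance range: %.4g .. %.4g (skew %.3g orders)\n",
              min(a), max(a), log10(max(a) / min(a))))
  if ("gene" %in% names(object@guides)) {
    tab <- sort(table(object@guides$gene), decreasing = TRUE)
    cat("  genes:", paste(utils::head(names(tab), 6), collapse = ", "),
        if (length(tab) > 6) "..." else "", "\n")
  }
})

#' Read a guide library from a tab-separated file
#'
#' Expected columns: \code{guide_id, protospacer, gene, abundance} and
#' optionally \code{chrom, cut_pos, strand}; header required.
#'
#' @param path path to a TSV file.
#' @return A \linkS4class{GuideLibrary}.
#' @export
readGuideLibrary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("guide_id", "abundance") %in% names(df)))
    stop("library TSV needs 'guide_id' and 'abundance' columns")
  if ("cut_pos" %in% names(df) && !("cut_site" %in% names(df)))
    df$cut_site <- df$cut_pos
  new("GuideLibrary", guides = df)
}

#' Write a guide library to TSV
#' @param x a \linkS4class{GuideLibrary}
#' @param path output path
#' @export
writeGuideLibrary <- function(x, path) {
  utils::write.table(x@guides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' CoverageDesign: screen-scale numbers derived from a library
#'
#' Result container for the transduction design calculations: the
#' weighted coupon-collector bound on draws, cells required, effective
#' virions at the Poisson optimum, and (optionally) titer inversion and
#' the volume of titer stock to add.
#'
#' @slot k integer, guides per cell.
#' @slot r integer, single-cell replicates per guide combination.
#' @slot n_combinations numeric, \code{choose(g, k)}.
#' @slot draws_bound numeric upper bound on expected draws to collect
#'   every k-guide combination.
#' @slot cells_required numeric.
#' @slot virions_required numeric (\code{k * cells_required}).
#' @slot titer list with \code{f0}, \code{initial_cells}, \code{volume},
#'   \code{virions}, \code{volume_to_add} when titer inputs were given,
#'   else empty.
#' @slot approximate logical, TRUE when the bound was Monte-Carlo
#'   estimated; \code{mc_se} then holds its standard error.
#' @slot mc_se numeric.
#' @export
setClass("CoverageDesign",
         representation(k = "integer", r = "integer",
                        n_combinations = "numeric",
                        draws_bound = "numeric", cells_required = "numeric",
                        virions_required = "numeric", titer = "list",
                        approximate = "logical", mc_se = "numeric"))

setMethod("show", "CoverageDesign", function(object) {
  cat("CoverageDesign (k =", object@k, ", r =", object@r, ")\n")
  cat(sprintf("  combinations:     %.6g\n", object@n_combinations))
  cat(sprintf("  draws bound:      %.6g%s\n", object@draws_bound,
              if (object@approximate)
                sprintf(" (Monte-Carlo, se %.3g)", object@mc_se) else ""))
  cat(sprintf("  cells required:   %.6g\n", object@cells_required))
  cat(sprintf("  virions required: %.6g\n", object@virions_required))
  if (length(object@titer)) {
    cat(sprintf("  titer virions:    %.6g (in %.4g volume units)\n",
                object@titer$virions, object@titer$volume))
    cat(sprintf("  volume to add:    %.6g volume units\n",
                object@titer$volume_to_add))
  }
})

#' ScreenCounts: guide read counts across screen samples
#'
#' A \code{SummarizedExperiment} subclass holding one \code{counts} assay
#' (guides x samples). \code{rowData} carries \code{guide_id} and
#' \code{gene}; \code{colData} carries \code{condition} (one of
#' \code{day6, day14, activated, unactivated}) and \code{replicate}.
#'
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

.screen_conditions <- c("day6", "day14", "activated", "unactivated")

setValidity("ScreenCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "need a 'counts' assay")
  cd <- colData(object)
  if (!all(c("condition", "replicate") %in% names(cd)))
    msg <- c(msg, "colData needs 'condition' and 'replicate'")
  else if (!all(cd$condition %in% .screen_conditions))
    msg <- c(msg, paste("condition must be one of:",
                        paste(.screen_conditions, collapse = ", ")))
  if (!all(c("guide_id", "gene") %in% names(rowData(object))))
    msg <- c(msg, "rowData needs 'guide_id' and 'gene'")
  if ("counts" %in% SummarizedExperiment::assayNames(object) &&
      any(assay(object, "counts") < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, guides x samples.
#' @param guide_id,gene per-guide annotation (rows of \code{counts}).
#' @param condition per-sample condition, one of \code{day6, day14,
#'   activated, unactivated}.
#' @param replicate per-sample replicate index.
#' @param ... passed to \code{SummarizedExperiment} (e.g. metadata).
#' @return A \linkS4class{ScreenCounts}.
#' @export
ScreenCounts <- function(counts, guide_id, gene, condition, replicate, ...) {
  colnames(counts) <- paste(condition, replicate, sep = "_r")
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(guide_id = guide_id, gene = gene),
    colData = DataFrame(condition = condition,
                        replicate = as.integer(replicate),
                        row.names = colnames(counts)), ...)
  new("ScreenCounts", se)
}

#' Read a MAGeCK-style count table as ScreenCounts
#'
#' First two columns are \code{sgRNA} and \code{gene}; remaining columns
#' are samples named \code{<condition>_r<replicate>}.
#'
#' @param path count TSV path.
#' @return A \linkS4class{ScreenCounts}.
#' @export
readScreenCounts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  samp <- names(df)[-(1:2)]
  m <- regmatches(samp, regexec("^(.*)_r([0-9]+)$", samp))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("sample columns must be named <condition>_r<replicate>: ",
         paste(samp[bad], collapse = ", "))
  cond <- vapply(m, `[`, "", 2L)
  repl <- as.integer(vapply(m, `[`, "", 3L))
  ScreenCounts(as.matrix(df[, -(1:2), drop = FALSE]),
               guide_id = df[[1]], gene = df[[2]],
               condition = cond, replicate = repl)
}

#' Write ScreenCounts as a MAGeCK-style count TSV
#' @param x a \linkS4class{ScreenCounts}
#' @param path output path
#' @export
writeScreenCounts <- function(x, path) {
  df <- data.frame(sgRNA = rowData(x)$guide_id, gene = rowData(x)$gene,
                   as.data.frame(assay(x, "counts")), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ResidueProfile: per-residue score landscape
#'
#' One row per covered protein residue with the raw (guide-mean) score,
#' model features, out-of-fold prediction, bias-corrected score and
#' prediction interval, for one score type (dropout or function) or both.
#'
#' @slot data data.frame with column \code{position} (unique, 1-based)
#'   plus score/feature columns.
#' @export
setClass("ResidueProfile", representation(data = "data.frame"))

setValidity("ResidueProfile", function(object) {
  d <- object@data
  msg <- character()
  if (!"position" %in% names(d))
    msg <- c(msg, "need a 'position' column")
  else if (anyDuplicated(d$position))
    msg <- c(msg, "positions must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a ResidueProfile from a per-residue table
#' @param data data.frame with a unique 1-based \code{position} column
#'   and score/feature columns.
#' @return A \linkS4class{ResidueProfile}.
#' @export
ResidueProfile <- function(data) {
  data <- data[order(data$position), , drop = FALSE]
  rownames(data) <- NULL
  new("ResidueProfile", data = data)
}

#' @describeIn ResidueProfile the underlying per-residue table
#' @param x,object a \code{ResidueProfile}
#' @export
profileData <- function(x) x@data

setMethod("show", "ResidueProfile", function(object) {
  d <- object@data
  cat("ResidueProfile:", nrow(d), "residues, positions",
      min(d$position), "..", max(d$position), "\n")
  cat("  columns:", paste(setdiff(names(d), "position"), collapse = ", "),
      "\n")
})

#' FunctionalInterval: FWHM-derived functional sequence span
#'
#' @slot start,end 1-based inclusive residue positions.
#' @slot baseline profile median.
#' @slot trough minimum corrected score.
#' @slot half_level baseline - (baseline - trough)/2.
#' @slot width end - start + 1.
#' @slot trough_position position of the global minimum.
#' @slot secondary data.frame of other sub-half-level runs (start, end).
#' @slot tie_flag TRUE when multiple positions attain the trough.
#' @export
setClass("FunctionalInterval",
         representation(start = "integer", end = "integer",
                        baseline = "numeric", trough = "numeric",
                        half_level = "numeric", width = "integer",
                        trough_position = "integer",
                        secondary = "data.frame", tie_flag = "logical"))

setValidity("FunctionalInterval", function(object) {
  msg <- character()
  if (object@start > object@end) msg <- c(msg, "start must be <= end")
  if (!(object@trough <= object@half_level &&
        object@half_level <= object@baseline))
    msg <- c(msg, "need trough <= half_level <= baseline")
  if (object@width != object@end - object@start + 1L)
    msg <- c(msg, "width must equal end - start + 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FunctionalInterval", function(object) {
  cat(sprintf("FunctionalInterval AA%d-%d (width %d)\n",
              object@start, object@end, object@width))
  cat(sprintf("  baseline %.4g, trough %.4g at %d, half level %.4g\n",
              object@baseline, object@trough, object@trough_position,
              object@half_level))
  if (nrow(object@secondary))
    cat("  secondary runs:",
        paste(sprintf("%d-%d", object@secondary$start,
                      object@secondary$end), collapse = ", "), "\n")
  if (object@tie_flag) cat("  note: tied troughs, lower index kept\n")
})

#' @describeIn FunctionalInterval start position
#' @param x a \code{FunctionalInterval}
#' @export
intervalStart <- function(x) x@start

#' @describeIn FunctionalInterval end position
#' @export
intervalEnd <- function(x) x@end

#' @describeIn FunctionalInterval interval width in residues
#' @export
intervalWidth <- function(x) x@width

#' GateModel: fitted FACS gating classifier
#'
#' Gradient-boosted binary classifier over cytometry channels plus the
#' held-out calibration split used to turn a target false-discovery rate
#' into per-class posterior cutoffs.
#'
#' @slot booster the fitted xgboost model.
#' @slot channels channel (feature) names.
#' @slot classes the two condition labels; \code{classes[2]} is the
#'   positive class of the booster.
#' @slot calibration data.frame(posterior, label) on held-out events.
#' @slot cofactor arcsinh cofactor used in preprocessing (NA = none).
#' @slot seed integer seed used for the split.
#' @export
setClass("GateModel",
         representation(booster = "ANY", channels = "character",
                        classes = "character", calibration = "data.frame",
                        cofactor = "numeric", seed = "integer"))

setMethod("show", "GateModel", function(object) {
  cat("GateModel:", paste(object@classes, collapse = " vs "),
      "on", length(object@channels), "channels\n")
  acc <- mean((object@calibration$posterior >= 0.5) ==
              (object@calibration$label == object@classes[2]))
  cat(sprintf("  calibration events: %d (held-out accuracy %.3f)\n",
              nrow(object@calibration), acc))
})

#' StackedBBBModel: stacked brain-penetration predictor
#'
#' Stage 1 is a binary blood-brain-barrier penetrance classifier trained
#' with out-of-fold folds; its probability, appended to the molecular
#' descriptors, feeds the stage-2 logBB regressor.
#'
#' @slot stage1,stage2 fitted xgboost models.
#' @slot descriptors descriptor column names (stage-2 features are these
#'   plus \code{bbb_prob}).
#' @slot fold_id stage-1 fold assignment.
#' @slot oof_auc out-of-fold AUC of stage 1 on its training data.
#' @slot medians training medians used to impute missing descriptors.
#' @slot seed integer.
#' @export
setClass("StackedBBBModel",
         representation(stage1 = "ANY", stage2 = "ANY",
                        descriptors = "character", fold_id = "integer",
                        oof_auc = "numeric", medians = "numeric",
                        seed = "integer"))

setMethod("show", "StackedBBBModel", function(object) {
  cat("StackedBBBModel:", length(object@descriptors), "descriptors +",
      "stage-1 probability\n")
  cat(sprintf("  stage-1 folds: %d, out-of-fold AUC %.3f\n",
              max(object@fold_id), object@oof_auc))
})
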