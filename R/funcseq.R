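#' Functional sequence interval by full width at half maximum
#'
#' Finds the contiguous residue interval where the corrected function
#' score drops below halfway between the profile's median baseline and
#' its global minimum (the trough). Uncovered positions inside the
#' covered range are filled by linear interpolation between their
#' flanking covered neighbours before thresholding, so tiling gaps do
#' not split one physical region. The returned interval is the maximal
#' run of positions with score <= half level that contains the trough;
#' other sub-half-level runs are reported as secondary. When several
#' positions tie for the trough the lowest index is used and the result
#' is flagged.
#'
#' @param profile a \linkS4class{ResidueProfile}, or a data.frame with a
#'   \code{position} column.
#' @param score_col name of the score column (default
#'   \code{"functional_corrected"}, falling back to
#'   \code{"functional_raw"}).
#' @return A \linkS4class{FunctionalInterval}.
#' @examples
#' prof <- data.frame(position = 1:100,
#'                    functional_corrected =
#'                      -3 * exp(-(1:100 - 50)^2 / (2 * 5^2)))
#' fwhmInterval(prof)
#' @export
fwhmInterval <- function(profile, score_col = "functional_corrected") {
  d <- if (is(profile, "ResidueProfile")) profileData(profile) else profile
  if (!score_col %in% names(d) && score_col == "functional_corrected" &&
      "functional_raw" %in% names(d))
    score_col <- "functional_raw"
  if (!score_col %in% names(d))
    stop("no score column '", score_col, "' in profile")
  d <- d[!is.na(d[[score_col]]), c("position", score_col)]
  d <- d[order(d$position), ]
  if (nrow(d) < 3) stop("need at least 3 covered positions")

  ## fill tiling gaps by linear interpolation over the covered range
  pos <- seq(min(d$position), max(d$position))
  score <- stats::approx(d$position, d[[score_col]], xout = pos)$y

  baseline <- median(d[[score_col]])  # median over covered positions
  trough <- min(score)
  if (trough >= baseline)
    stop("flat profile: no trough below the median baseline")
  half <- baseline - (baseline - trough) / 2

  below <- score <= half
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  run_df <- data.frame(start = pos[starts[runs$values]],
                       end = pos[ends[runs$values]])

  trough_pos <- pos[which(score == trough)]
  tie <- length(trough_pos) > 1L
  tp <- min(trough_pos)
  main <- which(run_df$start <= tp & run_df$end >= tp)
  sec <- run_df[-main, , drop = FALSE]
  rownames(sec) <- NULL
  new("FunctionalInterval",
      start = as.integer(run_df$start[main]),
      end = as.integer(run_df$end[main]),
      baseline = baseline, trough = trough, half_level = half,
      width = as.integer(run_df$end[main] - run_df$start[main] + 1L),
      trough_position = as.integer(tp), secondary = sec, tie_flag = tie)
}

#' Serialize a FunctionalInterval to a JSON-ready list
#' @param x a \linkS4class{FunctionalInterval}
#' @return list of scalar fields plus secondary runs.
#' @export
intervalAsList <- function(x) {
  list(start = x@start, end = x@end, width = x@width,
       baseline = x@baseline, trough = x@trough,
       half_level = x@half_level, trough_position = x@trough_position,
       tie_flag = x@tie_flag,
       secondary_runs = if (nrow(x@secondary)) x@secondary else list())
}
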