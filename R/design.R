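#' @importFrom stats dpois median quantile rnorm runif rbinom rpois setNames
NULL

## log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Binary min-heap keyed on numeric 'key' with integer payload; used by the
## best-first enumeration of the largest combination weights.
.heap_new <- function(cap = 1024L) {
  env <- new.env(parent = emptyenv())
  env$key <- numeric(cap); env$val <- vector("list", cap); env$n <- 0L
  env
}
.heap_push <- function(h, key, val) {
  n <- h$n + 1L
  if (n > length(h$key)) {
    h$key <- c(h$key, numeric(length(h$key)))
    h$val <- c(h$val, vector("list", length(h$val)))
  }
  h$key[n] <- key; h$val[[n]] <- val; h$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (h$key[p] <= h$key[i]) break
    tmp <- h$key[p]; h$key[p] <- h$key[i]; h$key[i] <- tmp
    tmpv <- h$val[[p]]; h$val[[p]] <- h$val[[i]]; h$val[[i]] <- tmpv
    i <- p
  }
  invisible(h)
}
.heap_pop <- function(h) {
  out <- list(key = h$key[1L], val = h$val[[1L]])
  n <- h$n
  h$key[1L] <- h$key[n]; h$val[[1L]] <- h$val[[n]]; h$n <- n - 1L
  n <- h$n; i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; s <- i
    if (l <= n && h$key[l] < h$key[s]) s <- l
    if (r <= n && h$key[r] < h$key[s]) s <- r
    if (s == i) break
    tmp <- h$key[s]; h$key[s] <- h$key[i]; h$key[i] <- tmp
    tmpv <- h$val[[s]]; h$val[[s]] <- h$val[[i]]; h$val[[i]] <- tmpv
    i <- s
  }
  out
}

## The m smallest values of sum(loga[S]) over k-subsets S of 1..g, where
## loga is sorted ascending. Best-first search from {1..k}; neighbours
## increment one index (keeping the tuple strictly increasing), which never
## decreases the sum, so pops come out in nondecreasing order.
.smallest_subset_sums <- function(loga, k, m) {
  g <- length(loga)
  h <- .heap_new()
  start <- seq_len(k)
  .heap_push(h, sum(loga[start]), start)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(paste(start, collapse = ","), TRUE, envir = seen)
  out <- numeric(m); got <- 0L
  while (got < m && h$n > 0L) {
    top <- .heap_pop(h)
    got <- got + 1L; out[got] <- top$key
    S <- top$val
    for (j in seq_len(k)) {
      nxt <- if (j == k) g + 1L else S[j + 1L]
      if (S[j] + 1L < nxt || (j == k && S[j] < g)) {
        S2 <- S; S2[j] <- S[j] + 1L
        key <- paste(S2, collapse = ",")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          .heap_push(h, top$key - loga[S[j]] + loga[S2[j]], S2)
        }
      }
    }
  }
  out[seq_len(got)]
}

#' Weighted coupon-collector bound on draws to acquire a library
#'
#' Upper-bounds the expected number of transduction draws needed before
#' every k-guide combination has been seen at least once, for a library
#' whose guides have unequal abundances. Writing \eqn{a_s} for the total
#' abundance and \eqn{a_n} for the product of abundances of the n-th
#' k-combination, the bound is
#' \deqn{E[C] \le \sum_{i=1}^{n} \frac{(a_s)^k}{i\, a_n},}
#' with combinations indexed by ascending probability, so that the rarest
#' combination takes index 1 and contributes its full weight.
#'
#' All \code{choose(g, k)} combinations are enumerated exactly while their
#' number stays at or below \code{max_enumerate}. Beyond that the sum is
#' estimated by a stratified scheme: the head (the \code{head_m} largest
#' weights, found by best-first search without enumeration) is summed
#' exactly, and the remaining stratum -- where the \code{1/i} factor is
#' nearly flat -- is estimated by Monte-Carlo with a reported standard
#' error; the result is then flagged approximate.
#'
#' @param library a \linkS4class{GuideLibrary}.
#' @param k guides per cell (1 for a standard screen).
#' @param max_enumerate exact-enumeration cap on \code{choose(g, k)}.
#' @param head_m exact head size for the stratified estimate.
#' @param mc_samples,mc_batches tail sample size and number of independent
#'   batches for the standard error.
#' @param seed seed for the Monte-Carlo path (ignored when exact).
#' @return The bound as a numeric scalar, with attributes
#'   \code{approximate} (logical) and, when approximate, \code{se}.
#' @examples
#' lib <- GuideLibrary(paste0("g", 1:2), c(1, 1))
#' couponBound(lib, k = 1)  # 2 * (1 + 1/2) = 3
#' @export
couponBound <- function(library, k = 1L, max_enumerate = 5e6,
                        head_m = 20000L, mc_samples = 50000L,
                        mc_batches = 8L, seed = 1L) {
  stopifnot(is(library, "GuideLibrary"))
  a <- guideAbundance(library)
  g <- length(a)
  k <- as.integer(k)
  if (k < 1L || k > g) stop("k must satisfy 1 <= k <= number of guides")
  if (any(a <= 0)) stop("abundances must be strictly positive")
  loga <- log(a)
  las <- log(sum(a))
  n_comb <- choose(g, k)

  if (n_comb <= max_enumerate) {
    ## log-weights log((a_s)^k / a_n) for every combination
    lw <- if (k == 1L) k * las - loga
          else k * las - colSums(matrix(loga[utils::combn(g, k)], nrow = k))
    lw <- sort(lw, decreasing = TRUE)
    out <- exp(.logsumexp(lw - log(seq_along(lw))))
    attr(out, "approximate") <- FALSE
    return(out)
  }

  ## stratified estimate: exact head of the m largest weights ...
  sloga <- sort(loga)
  m <- min(head_m, n_comb)
  head_sums <- .smallest_subset_sums(sloga, k, m)
  head_lw <- k * las - head_sums
  head_part <- exp(.logsumexp(head_lw - log(seq_along(head_lw))))
  ## ... plus a Monte-Carlo tail where 1/i is nearly constant
  set.seed(seed)
  ests <- vapply(seq_len(mc_batches), function(b) {
    idx <- replicate(ceiling(mc_samples / mc_batches),
                     sample.int(g, k), simplify = TRUE)
    lw <- k * las - if (k == 1L) loga[idx] else colSums(matrix(loga[idx], nrow = k))
    lw <- sort(lw, decreasing = TRUE)
    M <- length(lw)
    ## j-th largest of the sample estimates overall rank ~ (j - 0.5) n/M;
    ## drop sampled weights that fall inside the exactly-summed head
    rank_est <- (seq_len(M) - 0.5) * n_comb / M
    keep <- rank_est > m
    sum(exp(lw[keep]) / rank_est[keep]) * (n_comb / M)
  }, numeric(1))
  tail_part <- mean(ests)
  out <- head_part + tail_part
  attr(out, "approximate") <- TRUE
  attr(out, "se") <- stats::sd(ests) / sqrt(mc_batches)
  out
}

#' Cells required to cover a library
#'
#' Number of cells to transduce so that, at the optimal virion amount,
#' every k-guide combination is expected to be acquired with r single-cell
#' replicates:
#' \deqn{c = r\, k!\, (e/k)^k \sum_i \frac{(a_s)^k}{i\, a_n}.}
#'
#' @inheritParams couponBound
#' @param r single-cell replicates per combination (coverage multiplier).
#' @param ... passed to \code{\link{couponBound}}.
#' @return Required cell number (numeric scalar, usually non-integer).
#' @examples
#' lib <- GuideLibrary("g1", 1)
#' cellsRequired(lib, k = 1, r = 1)  # exp(1)
#' @export
cellsRequired <- function(library, k = 1L, r = 1L, ...) {
  r <- as.numeric(r)
  if (r < 1) stop("r must be >= 1")
  k <- as.integer(k)
  bound <- couponBound(library, k, ...)
  out <- r * factorial(k) * (exp(1) / k)^k * as.numeric(bound)
  attributes(out) <- attributes(bound)
  out
}

#' Optimal number of effective virions
#'
#' The virion amount maximizing the fraction of cells carrying exactly k
#' guides under Poisson transduction is \eqn{v = k c}.
#'
#' @param c number of cells.
#' @param k target guides per cell.
#' @return \code{k * c}.
#' @export
optimalVirions <- function(c, k = 1L) {
  if (!is.numeric(c) || any(c <= 0)) stop("c must be positive")
  if (any(k < 1)) stop("k must be >= 1")
  k * c
}

#' Fraction of cells with exactly k guides
#'
#' Poisson transduction: with v effective virions on c cells the MOI is
#' v/c and the fraction of cells with exactly k integrations is the
#' Poisson pmf at k.
#'
#' @param v effective virions (>= 0).
#' @param c cells (> 0).
#' @param k integer >= 0.
#' @return Probability in [0, 1].
#' @export
poissonFraction <- function(v, c, k) {
  if (any(v < 0)) stop("v must be non-negative")
  if (any(c <= 0)) stop("c must be positive")
  if (any(k < 0) || any(k != round(k))) stop("k must be a non-negative integer")
  dpois(k, lambda = v / c)
}

#' Effective virions in a titer from the uninfected fraction
#'
#' Inverts the zero-class of the binomial infection model: if a titration
#' on \code{c_i} cells leaves a fraction \code{f0} with no integration,
#' the effective virion count is
#' \deqn{v = \ln(f_0) / \ln(1 - 1/c_i).}
#'
#' @param f0 observed uninfected fraction, in (0, 1).
#' @param c_i number of cells in the titration (>= 2).
#' @return Effective virions (positive).
#' @export
titerVirions <- function(f0, c_i) {
  if (any(f0 <= 0 | f0 >= 1)) stop("f0 must lie strictly in (0, 1)")
  if (any(c_i < 2)) stop("c_i must be >= 2")
  log(f0) / log(1 - 1 / c_i)
}

#' Volume of titer stock to add to a screen
#'
#' Converts the virion requirement \eqn{k c} into a pipettable volume
#' given a titration read-out: \eqn{A = c k L \ln(1 - 1/c_i)/\ln(f_0)},
#' i.e. requirement divided by titer concentration. Volume units follow
#' \code{L} unchanged.
#'
#' @param c cells in the screen.
#' @param k guides per cell (>= 1).
#' @param L volume used for the titration (any unit).
#' @param c_i cells in the titration.
#' @param f0 uninfected fraction observed in the titration.
#' @return Volume in the units of \code{L}.
#' @export
transductionVolume <- function(c, k, L, c_i, f0) {
  if (any(c <= 0) || any(L <= 0)) stop("c and L must be positive")
  if (any(k < 1)) stop("k must be >= 1")
  c * k * L * log(1 - 1 / c_i) / log(f0)
}

#' Full transduction design for a guide library
#'
#' Bundles the coverage chain: coupon-collector bound, cells required,
#' optimal virions and -- when titration inputs are supplied -- the titer
#' inversion and volume of stock to add.
#'
#' @inheritParams cellsRequired
#' @param titer_f0,titer_cells,titer_volume optional titration read-out:
#'   uninfected fraction, cells plated and volume of stock used.
#' @return A \linkS4class{CoverageDesign}.
#' @examples
#' lib <- simulateLibrary(100, skew_sd = 1, seed = 1)
#' coverageDesign(lib, k = 1, r = 100,
#'                titer_f0 = 0.7, titer_cells = 1e6, titer_volume = 10)
#' @export
coverageDesign <- function(library, k = 1L, r = 1L, titer_f0 = NULL,
                           titer_cells = NULL, titer_volume = NULL, ...) {
  k <- as.integer(k)
  bound <- couponBound(library, k, ...)
  cells <- r * factorial(k) * (exp(1) / k)^k * as.numeric(bound)
  titer <- list()
  if (!is.null(titer_f0)) {
    stopifnot(!is.null(titer_cells), !is.null(titer_volume))
    titer <- list(f0 = titer_f0, initial_cells = titer_cells,
                  volume = titer_volume,
                  virions = titerVirions(titer_f0, titer_cells),
                  volume_to_add = transductionVolume(cells, k, titer_volume,
                                                     titer_cells, titer_f0))
  }
  new("CoverageDesign", k = k, r = as.integer(r),
      n_combinations = choose(nGuides(library), k),
      draws_bound = as.numeric(bound), cells_required = cells,
      virions_required = k * cells, titer = titer,
      approximate = isTRUE(attr(bound, "approximate")),
      mc_se = if (isTRUE(attr(bound, "approximate")))
        attr(bound, "se") else NA_real_)
}
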