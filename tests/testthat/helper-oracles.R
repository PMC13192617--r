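# Independent oracles and fixture builders shared across test files.

# Draws needed to see every coupon at least once (weighted coupon
# collector), simulated directly; block sampling for speed.
draws_to_complete <- function(prob, block = 1000L) {
  g <- length(prob)
  seen <- logical(g)
  draws <- 0L
  repeat {
    x <- sample.int(g, block, replace = TRUE, prob = prob)
    for (i in seq_along(x)) {
      draws <- draws + 1L
      seen[x[i]] <- TRUE
      if (all(seen)) return(draws)
    }
  }
}

# Brute-force coupon bound: enumerate combinations, sort by ascending
# probability, sum weights/i. Kept free of the package's log-space path.
brute_coupon_bound <- function(ab, k) {
  as_ <- sum(ab)
  combos <- utils::combn(length(ab), k)
  w <- apply(combos, 2, function(ix) as_^k / prod(ab[ix]))
  w <- sort(w, decreasing = TRUE)  # ascending probability
  sum(w / seq_along(w))
}

# Two well-separated FACS populations on ASC area/height-like channels.
facs_two_pops <- function(sep = 6, sd = 0.5) {
  list(
    list(mean = c(asc_area = 0, asc_height = 0),
         cov = diag(2) * sd^2, weight = 0.5, label = "unactivated"),
    list(mean = c(asc_area = sep * sd, asc_height = sep * sd),
         cov = diag(2) * sd^2, weight = 0.5, label = "activated"))
}

# Toy plus-strand CDS: single exon, 12 codons, genomic 101..136.
toy_cds_plus <- function() data.frame(start = 101, end = 136)

# Toy minus-strand CDS: two exons (genomic order), 16 codons total.
toy_cds_minus <- function() data.frame(start = c(101, 201),
                                       end = c(118, 230))

# Standard small synthetic screen with injected efficiency bias, used by
# bias-correction recovery tests; returns profile, features and the
# analytic truth in score units at the median efficiency.
biased_screen_fixture <- function(seed, g = 1000L, n_res = 300L,
                                  cells = 50000L, depth = 500000L) {
  lib <- simulateLibrary(g, skew_sd = 1.5, seed = seed,
                         landscape_length = n_res, n_controls = 100L)
  land <- effectLandscape(
    n_res,
    function_bumps = data.frame(center = c(0.3, 0.6) * n_res,
                                depth = c(-3, -2),
                                sd = c(n_res / 15, n_res / 25)),
    dropout_bumps = data.frame(center = 0.2 * n_res, depth = -1,
                               sd = n_res / 20))
  eff <- guideEfficiencyModel(nGuides(lib), seed = seed + 1000L)
  sc <- simulateScreen(lib, land, eff, cells = cells, depth = depth,
                       replicates = 3L, seed = seed + 2000L)
  gs <- scoreGuides(sc)
  gs$residue <- guideTable(lib)$residue
  prof <- aggregateByResidue(gs)
  feats <- residueFeatures(profileData(prof)$position, gs,
                           cbind(guide_id = guideTable(lib)$guide_id, eff))
  truth <- expectedFunctionScore(land$function_effect,
                                 eff = median(eff$efficiency))
  list(profile = prof, features = feats, landscape = land,
       truth_score = truth[profileData(prof)$position])
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
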