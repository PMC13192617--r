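test_that("library generator is deterministic and honours skew", {
  a <- simulateLibrary(100, skew_sd = 1.5, seed = 9)
  b <- simulateLibrary(100, skew_sd = 1.5, seed = 9)
  expect_identical(guideTable(a), guideTable(b))
  flat <- simulateLibrary(20, skew_sd = 0, seed = 1)
  expect_true(all(guideAbundance(flat) == guideAbundance(flat)[1]))
  expect_error(simulateLibrary(0), "g must")
})

test_that("skew_sd 2.8 spans four orders of magnitude in most pools", {
  hits <- vapply(1:100, function(s) {
    ab <- guideAbundance(simulateLibrary(1000, skew_sd = 2.8, seed = s))
    max(ab) / min(ab) >= 1e4
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("residue tiling covers the landscape and controls stay unmapped", {
  lib <- simulateLibrary(200, skew_sd = 1, seed = 2, landscape_length = 100,
                         n_controls = 20)
  tab <- guideTable(lib)
  expect_equal(sum(is.na(tab$residue)), 20)
  expect_true(all(tab$gene[is.na(tab$residue)] == "control"))
  expect_true(all(tab$residue[!is.na(tab$residue)] %in% 1:99))
})

test_that("screen counts conserve the requested depth and are reproducible", {
  lib <- simulateLibrary(60, skew_sd = 1, seed = 3, landscape_length = 40)
  land <- effectLandscape(40)
  sc <- simulateScreen(lib, land, cells = 3000, depth = 40000,
                       replicates = 2, seed = 4)
  expect_s4_class(sc, "ScreenCounts")
  expect_true(all(colSums(SummarizedExperiment::assay(sc, "counts")) ==
                  40000))
  sc2 <- simulateScreen(lib, land, cells = 3000, depth = 40000,
                        replicates = 2, seed = 4)
  expect_identical(SummarizedExperiment::assay(sc, "counts"),
                   SummarizedExperiment::assay(sc2, "counts"))
  expect_error(simulateScreen(simulateLibrary(5, seed = 1,
                                              landscape_length = 100),
                              effectLandscape(40)),
               "residues must lie")
})

test_that("null screens centre guide scores on zero", {
  lib <- simulateLibrary(80, skew_sd = 0.5, seed = 5, landscape_length = 50,
                         n_controls = 10)
  null_land <- effectLandscape(50, function_bumps = NULL,
                               dropout_bumps = NULL)
  sc <- simulateScreen(lib, null_land, cells = 20000, depth = 300000,
                       replicates = 3, seed = 6)
  gs <- scoreGuides(sc)
  for (col in c("dropout", "functional")) {
    se <- sd(gs[[col]]) / sqrt(nrow(gs))
    expect_lt(abs(mean(gs[[col]])), 3 * se)
  }
})

test_that("a -1 log2 dropout effect is recovered at full efficiency", {
  n_res <- 20L
  lib <- simulateLibrary(40, skew_sd = 0, seed = 7,
                         landscape_length = n_res)
  land <- effectLandscape(n_res, function_bumps = NULL,
                          dropout_bumps = NULL)
  land$dropout_effect[10:11] <- -1   # guides on the pair (10, 11)
  sc <- simulateScreen(lib, land, cells = 60000, moi = 0.3,
                       depth = 40 * 600, replicates = 3, seed = 8)
  gs <- scoreGuides(sc)
  hit <- guideTable(lib)$residue == 10
  affected <- mean(gs$dropout[hit])
  expect_lt(abs(affected - expectedDropoutScore(-1, 1)), 0.25)
  # halved efficiency attenuates strictly toward zero
  eff <- data.frame(efficiency = rep(0.5, nGuides(lib)),
                    efficiency_score = rep(0.5, nGuides(lib)))
  sc5 <- simulateScreen(lib, land, eff, cells = 60000, moi = 0.3,
                        depth = 40 * 600, replicates = 3, seed = 8)
  att <- mean(scoreGuides(sc5)$dropout[hit])
  expect_lt(att, 0)
  expect_gt(att, affected + 0.1)
  expect_lt(abs(att - expectedDropoutScore(-1, 0.5)), 0.25)
})

test_that("null screens give calibrated Kruskal-Wallis type-I error", {
  n_seeds <- 200L
  lib <- simulateLibrary(60, skew_sd = 0.5, seed = 1,
                         landscape_length = 30)
  tab <- guideTable(lib)
  genes <- rep(c("geneA", "geneB", "geneC"), each = 20)
  land <- effectLandscape(30, function_bumps = NULL, dropout_bumps = NULL)
  pvals <- vapply(seq_len(n_seeds), function(s) {
    sc <- simulateScreen(lib, land, cells = 1500, depth = 30000,
                         replicates = 2, seed = 100 + s)
    gs <- scoreGuides(sc)
    groupStats(gs$functional, genes, control = "geneA")$p
  }, numeric(1))
  rejections <- sum(pvals < 0.05)
  expect_gte(rejections, qbinom(0.005, n_seeds, 0.05))
  expect_lte(rejections, qbinom(0.995, n_seeds, 0.05))
})

test_that("FACS event generator handles edge cases and separability", {
  pops <- facs_two_pops()
  expect_equal(nrow(simulateFacsEvents(0, pops, seed = 1)), 0)
  one <- list(list(mean = c(x = 0, y = 0), cov = diag(2), weight = 1,
                   label = "only"))
  ev1 <- simulateFacsEvents(50, one, seed = 2)
  expect_true(all(ev1$label == "only"))
  # 6-sd separation: midpoint hyperplane misclassifies < 0.2%
  ev <- simulateFacsEvents(20000, pops, seed = 3)
  called <- ifelse(ev$asc_area + ev$asc_height > 3, "activated",
                   "unactivated")
  expect_lt(mean(called != ev$label), 0.002)
  bad <- facs_two_pops(); bad[[1]]$cov <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulateFacsEvents(10, bad, seed = 1), "semi-definite")
  bad2 <- facs_two_pops(); bad2[[1]]$weight <- 0.8
  expect_error(simulateFacsEvents(10, bad2, seed = 1), "sum to 1")
})

test_that("BBB dataset generator matches its own analytic structure", {
  d0 <- simulateBBBDataset(500, 5, coef = c(2, 1, 0, 0, 1), noise_sd = 0,
                           seed = 4)
  lin <- as.matrix(d0$descriptors) %*% c(2, 1, 0, 0, 1)
  expect_true(all((lin >= 0) == (d0$bbb_class == 1)))
  d1 <- simulateBBBDataset(500, 5, coef = c(2, 1, 0, 0, 1), noise_sd = 0,
                           seed = 4)
  expect_identical(d0, d1)
  # class balance follows the normal CDF of the linear score
  n <- 4000L; coef <- rep(1, 6); tau <- 1
  d <- simulateBBBDataset(n, 6, coef = coef, noise_sd = 0.5,
                          class_threshold = tau, seed = 5)
  p_expected <- pnorm(tau, 0, sqrt(sum(coef^2) + 0.25), lower.tail = FALSE)
  half_width <- 3 * sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(mean(d$bbb_class) - p_expected), half_width)
  expect_error(simulateBBBDataset(1, 2, coef = c(1, 1)), "n must")
  expect_error(simulateBBBDataset(10, 2, coef = 1), "length")
})
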