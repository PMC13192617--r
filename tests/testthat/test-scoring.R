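make_counts <- function(mat, gene = NULL, reps = 1L) {
  # mat: guides x (day6, day14, activated, unactivated) per replicate
  g <- nrow(mat)
  ScreenCounts(mat, guide_id = paste0("sg", seq_len(g)),
               gene = if (is.null(gene)) rep("target", g) else gene,
               condition = rep(c("day6", "day14", "activated",
                                 "unactivated"), reps),
               replicate = rep(seq_len(reps), each = 4))
}

test_that("log2 fold-change scoring matches direct evaluation", {
  m <- matrix(c(100, 100, 100, 100,
                50, 100, 200, 100,
                0, 10, 10, 10), nrow = 3, byrow = TRUE)
  sc <- make_counts(m)
  gs <- scoreGuides(sc, pseudocount = 1, normalize = FALSE)
  expect_equal(gs$dropout[1], 0)
  expect_equal(gs$functional[1], 0)
  # numerator double the denominator, alpha -> 0
  gs0 <- scoreGuides(sc, pseudocount = 1e-9, normalize = FALSE)
  expect_equal(gs0$dropout[2], 1, tolerance = 1e-6)
  expect_equal(gs0$functional[2], 1, tolerance = 1e-6)
  # counts (0, 10), alpha = 1 -> log2(11/1) for day14/day6 direction
  expect_equal(gs$dropout[3], log2(11 / 1))
  expect_error(scoreGuides(sc, pseudocount = 0), "positive")
})

test_that("replicate scores average into the mean per sgRNA", {
  m <- cbind(matrix(c(10, 20, 30, 40), 1), matrix(c(10, 80, 30, 40), 1))
  sc <- make_counts(m, reps = 2L)
  gs <- scoreGuides(sc, pseudocount = 1, normalize = FALSE)
  expect_equal(gs$dropout, mean(c(log2(21 / 11), log2(81 / 11))))
  expect_equal(gs$functional, mean(c(log2(31 / 41), log2(31 / 41))))
})

test_that("scores are antisymmetric under sample swap and CPM-invariant", {
  set.seed(10)
  m <- matrix(rpois(80, 200), nrow = 20)
  sc <- make_counts(m)
  gs <- scoreGuides(sc, normalize = TRUE)
  m_swap <- m[, c(2, 1, 4, 3)]
  gs_swap <- scoreGuides(make_counts(m_swap), normalize = TRUE)
  expect_equal(gs_swap$dropout, -gs$dropout)
  expect_equal(gs_swap$functional, -gs$functional)
  # scaling one sample's depth leaves normalized scores unchanged
  m_scaled <- m; m_scaled[, 2] <- m[, 2] * 7L
  gs_scaled <- scoreGuides(make_counts(m_scaled), normalize = TRUE)
  expect_equal(gs_scaled$dropout, gs$dropout, tolerance = 1e-12)
  # and guide order does not matter
  perm <- sample(20)
  m_perm <- m[perm, ]
  gs_perm <- scoreGuides(make_counts(m_perm), normalize = TRUE)
  expect_equal(gs_perm$dropout[order(perm)], gs$dropout)
})

test_that("cut sites map to the two nearest residues on the plus strand", {
  # 12-codon CDS at genomic 101..136; codon 10 occupies 128..130
  lib <- GuideLibrary(paste0("g", 1:4), rep(1, 4),
                      cut_site = c(130L, 128L, 129L, 50L))
  mp <- mapGuidesToResidues(lib, toy_cds_plus(), strand = "+")
  expect_equal(unlist(mp[1, c("residue1", "residue2")]),
               c(residue1 = 10, residue2 = 11))   # codon boundary
  expect_equal(unlist(mp[2, c("residue1", "residue2")]),
               c(residue1 = 9, residue2 = 10))    # after base 1
  expect_equal(unlist(mp[3, c("residue1", "residue2")]),
               c(residue1 = 10, residue2 = 11))   # after base 2
  expect_false(mp$mapped[4])                       # outside the CDS
})

test_that("minus-strand cuts map through the strand flip", {
  # two-exon minus-strand CDS; translation order 230..201 then 118..101;
  # codon 7 = translation nt 19..21 = genomic 212, 211, 210
  lib <- GuideLibrary("g1", 1, cut_site = 211L)
  mp <- mapGuidesToResidues(lib, toy_cds_minus(), strand = "-")
  expect_true(mp$mapped)
  expect_true(7 %in% c(mp$residue1, mp$residue2))
  # cut after base 2 of codon 1 (genomic boundary 228/229)
  libj <- GuideLibrary("g2", 1, cut_site = 228L)
  mpj <- mapGuidesToResidues(libj, toy_cds_minus(), strand = "-")
  expect_equal(c(mpj$residue1, mpj$residue2), c(1, 2))
})

test_that("PAM coordinates convert to blunt-cut coordinates", {
  expect_equal(cutSiteFromPam(121L, "+"), 117L)
  expect_equal(cutSiteFromPam(100L, "-"), 103L)
})

test_that("residue aggregation matches a brute-force group-by", {
  set.seed(12)
  n <- 50
  scores <- data.frame(guide_id = paste0("sg", 1:n),
                       gene = "t",
                       dropout = rnorm(n), functional = rnorm(n))
  mapping <- data.frame(guide_id = scores$guide_id,
                        residue1 = sample(1:30, n, replace = TRUE))
  mapping$residue2 <- mapping$residue1 + 1L
  mapping$mapped <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 10)
  prof <- profileData(aggregateByResidue(scores, mapping))
  # independent loop-based reimplementation
  for (p in prof$position) {
    vals <- c()
    for (i in seq_len(n)) {
      if (!mapping$mapped[i]) next
      if (mapping$residue1[i] == p || mapping$residue2[i] == p)
        vals <- c(vals, scores$dropout[i])
    }
    expect_equal(prof$dropout_raw[prof$position == p], mean(vals))
  }
  # single guide contributes to both residues of its pair
  one <- aggregateByResidue(scores[1, ],
                            mapping = data.frame(guide_id = scores$guide_id[1],
                                                 residue1 = 10L,
                                                 residue2 = 11L,
                                                 mapped = TRUE))
  expect_equal(profileData(one)$dropout_raw, rep(scores$dropout[1], 2))
})

test_that("group statistics reproduce rank-test oracles", {
  # all values identical -> H = 0
  expect_equal(groupStats(rep(1, 8), rep(c("a", "b"), 4))$H, 0)
  # two groups, no ties: H equals the squared MWU z (1-df equivalence)
  x <- c(1.2, 2.1, 3.3, 4.0, 4.9, 0.7, 1.9, 2.8, 6.2, 7.5)
  g <- rep(c("a", "b"), each = 5)
  gstat <- groupStats(x, g, control = "a")
  n1 <- 5; n2 <- 5; N <- 10
  U <- sum(rank(x)[g == "a"]) - n1 * (n1 + 1) / 2
  z <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(gstat$H, z^2, tolerance = 1e-10)
  # two-group Dunn z^2 equals H as well
  expect_equal(gstat$dunn$z^2, gstat$H, tolerance = 1e-10)
  expect_true(all(gstat$dunn$p_bonferroni >= gstat$dunn$p - 1e-15))
  # percent change on the ratio scale: group ratios exactly half control
  sc <- c(log2(c(4, 4, 4)), log2(c(2, 2, 2)))
  gr <- rep(c("control", "hit"), each = 3)
  ps <- groupStats(sc, gr, control = "control")
  expect_equal(unname(ps$percent_change_ratio["hit"]), -50)
  # small groups dropped with a warning
  expect_warning(groupStats(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "dropping")
})

test_that("ScreenCounts round-trips through the MAGeCK-style TSV", {
  lib <- simulateLibrary(30, skew_sd = 0.5, seed = 1, landscape_length = 20)
  sc <- simulateScreen(lib, effectLandscape(20), cells = 1000,
                       depth = 20000, replicates = 2, seed = 2)
  f <- tempfile(fileext = ".tsv")
  writeScreenCounts(sc, f)
  rt <- readScreenCounts(f)
  expect_equal(SummarizedExperiment::assay(rt, "counts"),
               SummarizedExperiment::assay(sc, "counts"),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(SummarizedExperiment::colData(rt)),
               as.data.frame(SummarizedExperiment::colData(sc)))
})
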