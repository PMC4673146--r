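# TMA score aggregation, CI-overlap heuristic, profile clustering.

test_that("class aggregation matches hand computations", {
  sc <- data.frame(core = c("c1", "c2", "c3", "d1", "d2"),
                   tumor_class = c("A", "A", "A", "B", "B"),
                   marker = "CSK",
                   score = c(3, 3, 3, 0, 2))
  s <- aggregate_by_class(sc)
  a <- s[s$tumor_class == "A", ]
  expect_equal(a$mean_score, 3)
  expect_equal(a$se, 0)
  b <- s[s$tumor_class == "B", ]
  expect_equal(b$mean_score, 1)
  expect_equal(b$se, 1) # sd sqrt(2) / sqrt(2)
  expect_equal(b$bar_halfwidth, 2)
})

test_that("aggregation excludes missing scores pairwise and skips empty groups", {
  sc <- data.frame(core = c("c1", "c2", "c1", "c2"),
                   tumor_class = "A",
                   marker = c("CSK", "CSK", "SRC", "SRC"),
                   score = c(2, NA, NA, NA))
  expect_message(s <- aggregate_by_class(sc), "skipped")
  expect_equal(nrow(s), 1L)
  expect_equal(s$n_cores, 1L)
})

test_that("aggregation is invariant to core order", {
  set.seed(2)
  tsim <- simulate_tma(truth = tma_truth(seed = 2))
  s1 <- aggregate_by_class(tsim$scores)
  shuffled <- tsim$scores[sample(nrow(tsim$scores)), ]
  s2 <- aggregate_by_class(shuffled)
  key <- function(s) s[order(s$tumor_class, s$marker), c("mean_score", "se", "n_cores")]
  expect_equal(key(s1), key(s2), ignore_attr = TRUE)
})

test_that("class means recover latent truth within 2 SE most of the time", {
  hitrate <- mean(vapply(test_seeds(20), function(s) {
    tsim <- simulate_tma(classes = "PPCa", cores_per_class = 40,
                         truth = tma_truth(seed = s))
    agg <- aggregate_by_class(tsim$scores)
    row <- agg[agg$marker == "FAK", ]
    abs(row$mean_score - default_tma_means()["PPCa", "FAK"]) <= row$bar_halfwidth
  }, logical(1)))
  expect_gte(hitrate, 0.8)
})

test_that("touching 2-SE bars give exact p near 0.01, half overlap near 0.05", {
  se <- 0.25
  a <- list(mean_score = 2.0, se = se, n_cores = 10)
  touch <- list(mean_score = 2.0 - 4 * se, se = se, n_cores = 10)
  r <- ci_overlap_p(a, touch)
  expect_equal(r$overlap_proportion, 0)
  expect_identical(r$approx_p, "~0.01")
  expect_equal(r$t_statistic, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(r$df, 18)
  expect_equal(r$exact_p, 2 * pt(-2 * sqrt(2), 18), tolerance = 1e-12)

  half <- list(mean_score = 2.0 - 3 * se, se = se, n_cores = 10)
  r2 <- ci_overlap_p(a, half)
  expect_equal(r2$overlap_proportion, 0.5)
  expect_identical(r2$approx_p, "~0.05")
  expect_equal(r2$exact_p, 2 * pt(-3 / sqrt(2), 18), tolerance = 1e-12)

  # identical groups: bars overlap fully (twice the average halfwidth), ns
  r3 <- ci_overlap_p(a, a)
  expect_equal(r3$overlap_proportion, 2)
  expect_identical(r3$approx_p, "ns")
  expect_equal(r3$exact_p, 1)

  apart <- list(mean_score = 2.0 - 8 * se, se = se, n_cores = 10)
  expect_identical(ci_overlap_p(a, apart)$approx_p, "<0.01")

  degen <- list(mean_score = 2, se = 0, n_cores = 10)
  expect_identical(ci_overlap_p(degen, degen)$approx_p, "degenerate")
})

test_that("heuristic ~0.05 label and exact Welch p agree in direction", {
  # equal-SE groups across n = 10..50 whose bars overlap in the ~0.05 band
  set.seed(33)
  ok <- vapply(1:200, function(i) {
    n <- sample(c(10, 20, 30, 50), 1)
    se <- runif(1, 0.05, 0.3)
    ov <- runif(1, 0.06, 0.5)
    a <- list(mean_score = 2, se = se, n_cores = n)
    b <- list(mean_score = 2 - (4 - 2 * ov) * se, se = se, n_cores = n)
    r <- ci_overlap_p(a, b)
    stopifnot(r$approx_p == "~0.05")
    r$exact_p >= 0.01 && r$exact_p <= 0.10
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("uncentered absolute correlation behaves as a cosine similarity", {
  expect_equal(uncentered_abs_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(uncentered_abs_correlation(c(1, 2, 3), -c(1, 2, 3)), 1)
  expect_equal(uncentered_abs_correlation(c(1, 0), c(0, 1)), 0)
  expect_error(uncentered_abs_correlation(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("single-linkage merge heights match a brute-force recount", {
  set.seed(21)
  tsim <- simulate_tma(classes = "CRPC", cores_per_class = 9,
                       truth = tma_truth(seed = 21))
  dend <- cluster_cores(tsim$scores, "CRPC")
  expect_equal(sort(dend$hclust$height),
               single_linkage_heights_bruteforce(dend$dist),
               tolerance = 1e-12)
  expect_true(all(diff(dend$hclust$height) >= -1e-12)) # non-decreasing
  # distance matrix: symmetric, zero diagonal, within [0, 1]
  expect_equal(dend$dist, t(dend$dist))
  expect_true(all(diag(dend$dist) == 0))
  expect_true(all(dend$dist >= 0 & dend$dist <= 1))
})

test_that("two identical cores merge at height zero", {
  sc <- data.frame(core = rep(c("c1", "c2"), each = 2),
                   tumor_class = "CRPC",
                   marker = rep(c("CSK", "SRC"), 2),
                   score = c(2, 1, 2, 1))
  dend <- cluster_cores(sc, "CRPC")
  expect_equal(dend$hclust$height, 0)
})

test_that("planted CRPC subclasses are recovered by clustering", {
  tsim <- simulate_tma(truth = tma_truth(seed = 10))
  dend <- cluster_cores(tsim$scores, "CRPC")
  cl <- cut_cores(dend, 2)
  truth <- tsim$truth$crpc_subclass_assignment[names(cl)]
  expect_gte(rand_index(cl, truth), 0.9)
})

test_that("cores with incomplete profiles are dropped before clustering", {
  sc <- data.frame(core = rep(c("c1", "c2", "c3"), each = 2),
                   tumor_class = "CRPC",
                   marker = rep(c("CSK", "SRC"), 3),
                   score = c(2, 1, NA, 1, 3, 2))
  dend <- cluster_cores(sc, "CRPC")
  expect_setequal(dend$cores, c("c1", "c3"))
  sc$score[c(2, 6)] <- NA
  expect_error(cluster_cores(sc, "CRPC"), "at least 2")
})

test_that("TMA exports round-trip", {
  tsim <- simulate_tma(classes = "CRPC", cores_per_class = 8,
                       truth = tma_truth(seed = 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_tma(tsim$scores, csv)
  back <- read_tma(csv)
  expect_equal(back$score, tsim$scores$score)
  dend <- cluster_cores(tsim$scores, "CRPC")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_map(dend, tsv)
  imap <- utils::read.delim(tsv, check.names = FALSE)
  expect_identical(imap$core, rownames(dend$scores)) # leaf order preserved
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend, nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, dend$cores)
})
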