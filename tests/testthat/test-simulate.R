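# Synthetic-data generators: determinism, planted truth, study layout.

test_that("screen layout carries exactly 48 controls per plate and all genes", {
  sim <- simulate_screen(n_genes = 704, n_controls_per_plate = 48,
                         replicates = 2, truth = screen_truth(seed = 1))
  wells <- sim$wells
  per_plate <- tapply(wells$is_control, wells$plate, sum)
  expect_true(all(per_plate == 48))
  for (r in 1:2) {
    expect_setequal(unique(stats::na.omit(wells$gene[wells$replicate == r])),
                    kinome_gene_ids(704))
  }
  expect_error(simulate_screen(n_genes = 10, n_controls_per_plate = 48,
                               plate_capacity = 48,
                               truth = screen_truth(seed = 1)),
               "cannot hold")
})

test_that("generators are deterministic given the truth seed", {
  a <- simulate_screen(n_genes = 50, truth = default_screen_truth(n_genes = 50, n_hits = 3, seed = 9))
  b <- simulate_screen(n_genes = 50, truth = default_screen_truth(n_genes = 50, n_hits = 3, seed = 9))
  expect_identical(a, b)

  ia <- simulate_interactome(n_nodes = 80, truth = interactome_truth(seed = 4))
  ib <- simulate_interactome(n_nodes = 80, truth = interactome_truth(seed = 4))
  expect_identical(ia, ib)
  ic <- simulate_interactome(n_nodes = 80, truth = interactome_truth(seed = 5))
  expect_false(identical(ia$edges, ic$edges))

  ca <- simulate_confirmation(c("g1", "g2"), seed = 2)
  cb <- simulate_confirmation(c("g1", "g2"), seed = 2)
  expect_identical(ca, cb)

  ta <- simulate_tma(truth = tma_truth(seed = 8))
  tb <- simulate_tma(truth = tma_truth(seed = 8))
  expect_identical(ta, tb)
})

test_that("null-only screens hit at roughly the Gaussian upper-tail rate", {
  # single-replicate null screen; the raw-MAD plate scale estimated from 48
  # controls inflates the analytic 3.6% tail somewhat
  fr <- vapply(test_seeds(5), function(s) {
    sim <- simulate_screen(n_genes = 704, replicates = 1,
                           truth = screen_truth(seed = s))
    mean(call_primary_hits(score_genes(sim$wells))$is_hit)
  }, numeric(1))
  expect_equal(mean(fr), 1 - pnorm(1.8), tolerance = 0.45)
  expect_gt(mean(fr), 0.015)
  expect_lt(mean(fr), 0.07)
})

test_that("control wells carry no planted effect", {
  sim <- simulate_screen(n_genes = 300, replicates = 2,
                         truth = default_screen_truth(n_genes = 300, n_hits = 20,
                                                      effect_range = c(8, 10),
                                                      seed = 13))
  pe <- sim$truth$plate_effects
  for (p in unique(sim$wells$plate)) {
    ctrl <- sim$wells$readout[sim$wells$plate == p & sim$wells$is_control]
    eff <- pe[pe$plate == p, ]
    expect_equal(median(ctrl), 100 + eff$location_shift,
                 tolerance = 6 * 5 * eff$scale_factor / sqrt(48))
  }
})

test_that("planted hits are shifted by effect x true control MAD", {
  tr <- screen_truth(hit_genes = "KIN001",
                     effect_sizes = c(KIN001 = 6), seed = 21)
  sim <- simulate_screen(n_genes = 100, replicates = 2, truth = tr)
  sc <- score_genes(sim$wells)
  # effect of 6 raw MADs is 6/1.4826 ~ 4.05 on the Z scale
  expect_equal(sc$z_summary[sc$gene == "KIN001"], 6 / 1.4826, tolerance = 0.75)
})

test_that("interactome is connected, simple, weight-bounded, hub-biased", {
  isim <- simulate_interactome(n_nodes = 120, truth = interactome_truth(seed = 3))
  net <- as_interactome(isim$edges)
  expect_true(all(net$edges$weight > 0 & net$edges$weight <= 1))
  expect_false(any(net$edges$node_a == net$edges$node_b))
  g <- igraph::graph_from_data_frame(net$edges[1:2], directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)

  expect_error(interactome_truth(hub_attachment_bias = 0.5), ">= 1")

  # a strongly biased hub has the maximum degree in >= 95% of seeds
  top <- vapply(test_seeds(40), function(s) {
    e <- simulate_interactome(n_nodes = 200,
                              truth = interactome_truth(hub_attachment_bias = 10,
                                                        seed = s))$edges
    deg <- table(c(e$node_a, e$node_b))
    deg["AR"] == max(deg)
  }, logical(1))
  expect_gte(mean(top), 0.95)
})

test_that("minimal 3-node interactome is a valid path or triangle", {
  isim <- simulate_interactome(n_nodes = 3, truth = interactome_truth(seed = 1))
  expect_true(nrow(isim$edges) %in% c(2L, 3L))
  expect_setequal(unique(c(isim$edges$node_a, isim$edges$node_b)),
                  c("AR", "KIN001", "KIN002"))
})

test_that("planted hub neighbors are wired to the hub with confident edges", {
  tr <- interactome_truth(planted_hit_neighbors = c("KIN010", "KIN050"), seed = 2)
  isim <- simulate_interactome(n_nodes = 100, truth = tr)
  e <- isim$edges
  for (g in c("KIN010", "KIN050")) {
    hit <- (e$node_a == "AR" & e$node_b == g) | (e$node_b == "AR" & e$node_a == g)
    expect_equal(sum(hit), 1L)
    expect_equal(e$weight[hit], 0.9)
  }
  expect_error(simulate_interactome(n_nodes = 10,
                                    truth = interactome_truth(
                                      planted_hit_neighbors = "KIN999", seed = 1)),
               "must be graph nodes")
})

test_that("confirmation screen yields one readout per gene-siRNA-assay", {
  w <- simulate_confirmation(c("gA", "gB"), sirnas_per_gene = 8, assays = 2,
                             seed = 4)
  test_wells <- w[!w$is_control, ]
  expect_equal(nrow(test_wells), 2 * 8 * 2)
  expect_equal(sum(test_wells$gene == "gA"), 16) # 8 siRNAs x 2 assays
  z <- score_confirmation(w)
  expect_equal(nrow(z), 32)
  # zero effects: confirmation caller finds nothing at default thresholds
  conf <- call_confirmed_hits(z)
  expect_false(any(conf$is_hit))
})

test_that("a gene with three strong siRNAs is confirmed", {
  w <- simulate_confirmation(c("gA", "gB"),
                             per_sirna_effect = list(gA = c(5, 5, 5, 0, 0, 0, 0, 0)),
                             seed = 6)
  conf <- call_confirmed_hits(score_confirmation(w))
  expect_true(conf$is_hit[conf$gene == "gA"])
  expect_false(conf$is_hit[conf$gene == "gB"])
})

test_that("TMA scores stay on the ordinal 0-3 scale", {
  # > 10^4 draws at high latent noise: clipping must never leak
  tsim <- simulate_tma(cores_per_class = c(500, 500, 500),
                       truth = tma_truth(noise_sd = 1.5, seed = 17))
  expect_true(all(tsim$scores$score %in% 0:3))
  expect_gte(nrow(tsim$scores), 1e4)
  # zero noise with integer means gives constant scores
  m <- default_tma_means(); m[] <- 2
  s2 <- rbind(`low-CSK` = rep(2, 7), `normal-CSK` = rep(2, 7))
  colnames(s2) <- tma_markers()
  const <- simulate_tma(truth = tma_truth(class_marker_means = m,
                                          crpc_subclass_means = s2,
                                          noise_sd = 0, seed = 1))
  expect_true(all(const$scores$score == 2L))
  expect_error(tma_truth(class_marker_means = default_tma_means() * 2),
               "within \\[0, 3\\]")
})

test_that("every CRPC core gets exactly one planted subclass", {
  tsim <- simulate_tma(truth = tma_truth(seed = 2))
  asg <- tsim$truth$crpc_subclass_assignment
  crpc <- unique(tsim$scores$core[tsim$scores$tumor_class == "CRPC"])
  expect_setequal(names(asg), crpc)
  expect_true(all(asg %in% c("low-CSK", "normal-CSK")))
})
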