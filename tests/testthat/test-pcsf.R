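# Interactome I/O, edge costs, PCSF solver and oracle, betweenness.

test_that("interactome loading collapses duplicates and drops self-loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.9", "B\tC\t0.5", "A\tB\t0.7"), path)
  net <- load_interactome(path)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$weight[net$edges$node_a == "A"], 0.9)

  writeLines(c("A\tA\t0.4", "A\tB\t0.9"), path)
  expect_message(net2 <- load_interactome(path), "1 self-loop")
  expect_equal(nrow(net2$edges), 1L)

  writeLines(c("A\tB\t900", "B\tC\t450"), path)
  string <- load_interactome(path)
  expect_equal(sort(string$edges$weight), c(0.45, 0.9))

  writeLines(c("A\tB\t0.9", "B\tC\txyz"), path)
  expect_error(load_interactome(path), "line 2")
  writeLines(c("node_a\tnode_b\tweight", "A\tB\t1.7"), path)
  expect_error(load_interactome(path), "line 2.*range")
})

test_that("edge-cost transforms are positive and match their formulas", {
  net <- as_interactome(data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                                   weight = c(0.9, 1.0)))
  expect_equal(make_costed(net, "one_minus_weight")$edges$cost[1], 0.100001)
  expect_equal(make_costed(net, "weight_as_cost")$edges$cost, c(0.9, 1.0))
  nl <- make_costed(net, "neg_log_weight")$edges$cost
  expect_equal(nl[1], -log(0.9))
  expect_equal(nl[2], 1e-6) # weight 1 floored at epsilon
  expect_true(all(make_costed(net)$edges$cost > 0))
})

test_that("two prized nodes join when the edge is cheap and split when dear", {
  cheap <- make_cg(c("A", "B", "0.999999"), cost_mode = "weight_as_cost")
  # edge cost ~1, prizes 5 each, omega 3: connect
  f <- solve_pcsf(cheap, c(A = 5, B = 5), omega = 3)
  expect_setequal(f$nodes, c("A", "B"))
  expect_equal(nrow(f$edges), 1L)
  expect_equal(f$components, 1L)
  expect_equal(f$objective_total, 0.999999, tolerance = 1e-9)
  expect_equal(f$objective_excluded_prize, 0)
  b <- brute_force_pcsf(cheap, c(A = 5, B = 5), omega = 3)
  expect_equal(b$augmented_objective, f$augmented_objective)

  dear <- make_cg(c("A", "B", "0.9"), cost_mode = "weight_as_cost")
  # edge cost 0.9 vs two root edges at omega 0.2: two singleton trees
  f2 <- solve_pcsf(dear, c(A = 5, B = 5), omega = 0.2)
  expect_setequal(f2$nodes, c("A", "B"))
  expect_equal(nrow(f2$edges), 0L)
  expect_equal(f2$components, 2L)
  b2 <- brute_force_pcsf(dear, c(A = 5, B = 5), omega = 0.2)
  expect_equal(b2$augmented_objective, f2$augmented_objective)
})

test_that("zero prizes give the empty forest and negative prizes error", {
  cg <- make_cg(c("A", "B", "0.9"), c("B", "C", "0.8"))
  f <- solve_pcsf(cg, c(A = 0, B = 0), omega = 1)
  expect_length(f$nodes, 0L)
  expect_equal(f$objective_total, 0)
  expect_error(solve_pcsf(cg, c(A = -1), omega = 1), "nonnegative")
})

test_that("isolated prized node is collected when its prize beats omega", {
  cg <- make_cg(c("A", "B", "0.9"), nodes = "LONER")
  f <- brute_force_pcsf(cg, c(LONER = 5), omega = 0.5)
  expect_identical(f$nodes, "LONER")
  expect_equal(f$objective_excluded_prize, 0)
  expect_equal(f$objective_total, 0)
  s <- solve_pcsf(cg, c(LONER = 5), omega = 0.5)
  expect_identical(s$nodes, "LONER")
})

test_that("brute force rejects large graphs and handles the empty graph", {
  edges <- data.frame(node_a = sprintf("a%02d", 1:13),
                      node_b = sprintf("b%02d", 1:13), weight = 0.5)
  cg <- make_costed(as_interactome(edges))
  expect_error(brute_force_pcsf(cg, c(a01 = 1), omega = 1), "12 nodes")

  empty <- make_costed(as_interactome(
    data.frame(node_a = character(0), node_b = character(0),
               weight = numeric(0))))
  f <- brute_force_pcsf(empty, numeric(0), omega = 1)
  expect_length(f$nodes, 0L)
  expect_equal(f$objective_total, 0)
})

test_that("unmapped prize nodes are surfaced, not dropped", {
  cg <- make_cg(c("A", "B", "0.9"))
  f <- solve_pcsf(cg, c(A = 2, GHOST1 = 3, GHOST2 = 1), omega = 0.3)
  expect_identical(f$unmapped, c("GHOST1", "GHOST2"))
})

test_that("forests are acyclic with endpoints among selected nodes", {
  set.seed(31)
  for (rep in 1:25) {
    inst <- random_small_instance()
    f <- solve_pcsf(inst$cg, inst$prizes, beta = inst$beta, omega = inst$omega)
    expect_true(all(c(f$edges$node_a, f$edges$node_b) %in% f$nodes))
    if (length(f$nodes)) {
      expect_equal(nrow(f$edges), length(f$nodes) - f$components)
      if (nrow(f$edges)) {
        g <- igraph::graph_from_data_frame(f$edges[1:2], directed = FALSE,
                                           vertices = data.frame(name = f$nodes))
        expect_equal(igraph::components(g)$no, f$components)
        expect_false(igraph::girth(g, circle = FALSE)$girth > 0 &&
                       is.finite(igraph::girth(g, circle = FALSE)$girth))
      }
    }
    expect_equal(f$objective_total,
                 f$objective_excluded_prize + f$objective_edge_cost)
    # guaranteed improvement over empty forest
    expect_lte(f$augmented_objective,
               inst$beta * sum(inst$prizes[names(inst$prizes) %in% inst$cg$nodes]) + 1e-9)
  }
})

test_that("solver equals the oracle; forced heuristic stays near-optimal", {
  set.seed(97)
  heur_match <- logical(40)
  for (rep in 1:40) {
    inst <- random_small_instance()
    fe <- solve_pcsf(inst$cg, inst$prizes, beta = inst$beta, omega = inst$omega)
    fh <- solve_pcsf(inst$cg, inst$prizes, beta = inst$beta, omega = inst$omega,
                     control = pcsf_control(exact_limit = 0L))
    fb <- brute_force_pcsf(inst$cg, inst$prizes, beta = inst$beta,
                           omega = inst$omega)
    # the default solver (complete subset search at this size) is exact
    expect_equal(fe$augmented_objective, fb$augmented_objective,
                 tolerance = 1e-9)
    # the large-graph heuristic, forced on, never beats the optimum and
    # finds it in the vast majority of instances
    expect_gte(fh$augmented_objective, fb$augmented_objective - 1e-9)
    heur_match[rep] <- abs(fh$augmented_objective - fb$augmented_objective) < 1e-9
  }
  expect_gte(mean(heur_match), 0.9)
})

test_that("prize scaling drives inclusion monotonically", {
  cg <- make_cg(c("A", "B", "0.6"), c("B", "C", "0.7"), c("C", "D", "0.8"))
  prizes <- c(A = 0.5, C = 0.4, D = 0.3)
  # beta -> 0: nothing worth collecting
  f0 <- solve_pcsf(cg, prizes, beta = 1e-9, omega = 0.5)
  expect_length(f0$nodes, 0L)
  # beta large: every prized node (all reachable) collected
  f1 <- solve_pcsf(cg, prizes, beta = 1e4, omega = 0.5)
  expect_true(all(c("A", "C", "D") %in% f1$nodes))
})

test_that("betweenness matches closed forms and a brute-force recount", {
  path_g <- make_cg(c("A", "B", "0.9"), c("B", "C", "0.9"))
  f <- solve_pcsf(path_g, c(A = 5, C = 5), omega = 5)
  b <- betweenness_report(f)
  expect_equal(unname(b["B"]), 1.0)
  expect_equal(unname(b[c("A", "C")]), c(0, 0))

  star <- make_cg(c("H", "L1", "0.9"), c("H", "L2", "0.9"), c("H", "L3", "0.9"),
                  c("H", "L4", "0.9"))
  fs <- solve_pcsf(star, c(L1 = 5, L2 = 5, L3 = 5, L4 = 5), omega = 5)
  expect_equal(unname(betweenness_report(fs)["H"]), 1.0)

  # random tree: igraph's normalized betweenness vs explicit path recount
  set.seed(12)
  n <- 20
  parents <- c(NA, sapply(2:n, function(i) sample(i - 1, 1)))
  ed <- data.frame(node_a = sprintf("t%02d", parents[-1]),
                   node_b = sprintf("t%02d", 2:n),
                   weight = 0.9)
  cg <- make_costed(as_interactome(ed))
  f <- solve_pcsf(cg, stats::setNames(rep(5, n), sort(unique(c(ed$node_a, ed$node_b)))),
                  omega = 50)
  got <- betweenness_report(f)
  oracle <- tree_betweenness_recount(f$edges, f$nodes)
  expect_equal(unname(got[names(oracle)]), unname(oracle), tolerance = 1e-12)
})

test_that("forest exports round-trip as SIF and JSON", {
  cg <- make_cg(c("A", "B", "0.9"), c("B", "C", "0.8"), nodes = "ISO")
  f <- solve_pcsf(cg, c(A = 3, C = 3, ISO = 3), omega = 0.4)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_forest_sif(f, sif)
  lines <- readLines(sif)
  expect_true(any(grepl("\tpp\t", lines)))
  expect_true("ISO" %in% lines) # isolated tree survives export
  js <- withr::local_tempfile(fileext = ".json")
  forest_report(f, js)
  rep <- jsonlite::read_json(js)
  expect_equal(unlist(rep$nodes), f$nodes)
  expect_equal(rep$objective$total, f$objective_total, tolerance = 1e-12)
})
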