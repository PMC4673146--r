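# Prize-collecting Steiner forest over a costed interactome.
#
# Objective (minimized): beta * sum of prizes of EXCLUDED nodes
#                        + sum of costs of forest edges,
# with multiple trees permitted through the standard artificial-root
# construction: a root is connected to every prized node by an edge of cost
# omega, a tree containing the root is sought, and the root with its edges
# is removed from the reported forest (so omega acts as a per-tree charge
# during optimization). For a FIXED node set S the optimal structure is the
# minimum spanning tree of the root-augmented subgraph induced by S; the
# solver searches over node sets (shortest-path terminal-tree construction,
# strong pruning, best-improvement add/remove local search), and an
# exhaustive oracle (`brute_force_pcsf`) certifies small instances.

#' Solver settings for [solve_pcsf()]
#'
#' @param local_search run best-improvement add/remove local search after
#'   construction (default TRUE).
#' @param max_iter cap on local-search moves.
#' @param all_start additionally start from the full (feasible) node set and
#'   prune down; improves quality, costs one dense MST per pass.
#' @param exact_limit graphs with at most this many nodes are solved by
#'   complete search over node subsets (exact by construction, since the
#'   optimal structure for a fixed subset is the root-augmented MST);
#'   larger graphs use the heuristic. Default 12.
#' @return list of settings.
#' @export
pcsf_control <- function(local_search = TRUE, max_iter = 100L,
                         all_start = TRUE, exact_limit = 12L) {
  list(local_search = isTRUE(local_search),
       max_iter = as.integer(max_iter),
       all_start = isTRUE(all_start),
       exact_limit = as.integer(exact_limit))
}

# Precompute adjacency and all-pairs shortest-path costs so repeated solves
# on the same graph (randomization tests) stay cheap.
#' @rdname solve_pcsf
#' @export
pcsf_prep <- function(graph) {
  stopifnot(inherits(graph, "costed_graph"))
  nodes <- graph$nodes
  n <- length(nodes)
  ei <- match(graph$edges$node_a, nodes)
  ej <- match(graph$edges$node_b, nodes)
  cost <- graph$edges$cost
  adj <- vector("list", n)
  adjc <- vector("list", n)
  for (v in seq_len(n)) {
    sel_i <- ei == v
    sel_j <- ej == v
    nb <- c(ej[sel_i], ei[sel_j])
    cc <- c(cost[sel_i], cost[sel_j])
    o <- order(nb)
    adj[[v]] <- nb[o]
    adjc[[v]] <- cc[o]
  }
  g <- costed_igraph(graph)
  dist <- igraph::distances(g, weights = igraph::E(g)$cost)
  dist <- dist[nodes, nodes, drop = FALSE]
  comp <- igraph::components(g)$membership[nodes]
  structure(list(nodes = nodes, n = n, ei = ei, ej = ej, cost = cost,
                 adj = adj, adjc = adjc, dist = dist, comp = comp,
                 median_cost = stats::median(cost)),
            class = "pcsf_prep")
}

# Prim's algorithm on a dense symmetric cost matrix (Inf = absent edge),
# rooted at vertex 1. Returns parent/key vectors; feasible = all reached.
prim_dense <- function(W) {
  m <- nrow(W)
  intree <- rep(FALSE, m)
  intree[1] <- TRUE
  key <- W[1, ]
  key[1] <- 0
  parent <- rep(1L, m)
  for (iter in seq_len(m - 1L)) {
    cand <- which(!intree)
    u <- cand[which.min(key[cand])]
    if (!is.finite(key[u])) {
      return(list(feasible = FALSE))
    }
    intree[u] <- TRUE
    upd <- which(!intree & W[u, ] < key)
    parent[upd] <- u
    key[upd] <- W[u, upd]
  }
  list(feasible = TRUE, parent = parent, key = key,
       cost = sum(key[-1]))
}

# Minimum spanning tree of the root-augmented subgraph induced by node set
# S (integer indices). Vertex 1 of the dense matrix is the artificial root;
# vertex k+1 is S[k]. Root edges (cost omega) exist only to prized nodes.
augmented_mst <- function(prep, S, prize, omega) {
  m <- length(S)
  if (m == 0L) {
    return(list(feasible = TRUE, S = S, edge_cost = 0, n_components = 0L,
                total = 0, parent = integer(0), key = numeric(0)))
  }
  pos <- integer(prep$n)
  pos[S] <- seq_len(m)
  W <- matrix(Inf, m + 1L, m + 1L)
  W[1L, pos[S[prize[S] > 0]] + 1L] <- omega
  W[pos[S[prize[S] > 0]] + 1L, 1L] <- omega
  for (v in S) {
    nb <- prep$adj[[v]]
    keep <- pos[nb] > 0L
    if (any(keep)) {
      W[pos[v] + 1L, pos[nb[keep]] + 1L] <- prep$adjc[[v]][keep]
    }
  }
  pr <- prim_dense(W)
  if (!pr$feasible) return(list(feasible = FALSE))
  root_child <- which(pr$parent == 1L)
  root_child <- root_child[root_child != 1L]
  list(feasible = TRUE, S = S, parent = pr$parent, key = pr$key,
       n_components = length(root_child),
       edge_cost = sum(pr$key[-1]) - length(root_child) * omega,
       total = sum(pr$key[-1]))
}

# Objective value of a node set (Inf if infeasible under the root
# construction), via the augmented MST.
score_set <- function(prep, S, prize, beta, omega, total_prize) {
  mst <- augmented_mst(prep, S, prize, omega)
  if (!mst$feasible) return(list(score = Inf, mst = NULL))
  excl <- beta * (total_prize - sum(prize[S]))
  list(score = excl + mst$total, mst = mst)
}

# Strong pruning: on the rooted MST, drop every subtree whose collectible
# net worth does not exceed the cost of its attaching edge. Returns the
# retained node set (possibly empty).
strong_prune <- function(mst, prize, beta, omega) {
  S <- mst$S
  m <- length(S)
  if (m == 0L) return(S)
  parent <- mst$parent
  key <- mst$key
  children <- vector("list", m + 1L)
  for (k in seq(2L, m + 1L)) {
    p <- parent[k]
    children[[p]] <- c(children[[p]], k)
  }
  # process vertices in reverse BFS order (children before parents)
  ord <- integer(0)
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    queue <- c(queue, children[[v]])
  }
  net <- numeric(m + 1L)
  keep_edge <- rep(FALSE, m + 1L)
  for (v in rev(ord)) {
    w <- if (v == 1L) 0 else beta * prize[S[v - 1L]]
    for (ch in children[[v]]) {
      if (net[ch] > key[ch]) {
        keep_edge[ch] <- TRUE
        w <- w + net[ch] - key[ch]
      }
    }
    net[v] <- w
  }
  kept <- rep(FALSE, m + 1L)
  kept[1L] <- TRUE
  for (v in ord[-1]) {
    kept[v] <- kept[parent[v]] && keep_edge[v]
  }
  S[which(kept[-1])]
}

# One construction pass: terminal-metric MST expanded along shortest paths,
# then MST + strong-prune iterations until stable.
pcsf_construct <- function(prep, prize, beta, omega) {
  terminals <- which(prize > 0)
  if (!length(terminals)) return(integer(0))
  tm <- length(terminals)
  W <- matrix(Inf, tm + 1L, tm + 1L)
  W[1L, -1L] <- omega
  W[-1L, 1L] <- omega
  W[-1L, -1L] <- prep$dist[terminals, terminals]
  diag(W) <- Inf
  pr <- prim_dense(W)
  S <- terminals
  if (pr$feasible) {
    for (k in seq(2L, tm + 1L)) {
      p <- pr$parent[k]
      if (p > 1L) {
        S <- union(S, shortest_path_nodes(prep, terminals[p - 1L],
                                          terminals[k - 1L]))
      }
    }
  }
  sort(S)
}

# Node indices along one shortest path, reconstructed greedily from the
# all-pairs distance matrix.
shortest_path_nodes <- function(prep, u, v) {
  path <- u
  cur <- u
  guard <- 0L
  while (cur != v) {
    nb <- prep$adj[[cur]]
    tot <- prep$adjc[[cur]] + prep$dist[nb, v]
    cur <- nb[which.min(tot)]
    path <- c(path, cur)
    guard <- guard + 1L
    if (guard > prep$n) stop("shortest-path reconstruction failed", call. = FALSE)
  }
  path
}

refine_set <- function(prep, S, prize, beta, omega, total_prize) {
  repeat {
    sc <- score_set(prep, S, prize, beta, omega, total_prize)
    if (!is.finite(sc$score)) return(list(S = integer(0), score = beta * total_prize,
                                          mst = augmented_mst(prep, integer(0), prize, omega)))
    pruned <- strong_prune(sc$mst, prize, beta, omega)
    if (length(pruned) == length(S)) return(list(S = S, score = sc$score, mst = sc$mst))
    S <- pruned
  }
}

# Best-improvement search over node sets; every candidate set is scored
# exactly via the augmented MST. Move types (all O(|S| + boundary) sets per
# iteration):
#   - strong pruning of the current tree (a move among others, not a
#     mandatory step: greedily pruning a whole root-subtree can mask a
#     better removal inside it);
#   - add one boundary node or excluded terminal;
#   - add an excluded terminal together with its shortest path to the
#     current set or to its nearest excluded terminal (so profitable
#     two-terminal trees can form from scratch);
#   - remove one node, or a pair of nodes adjacent in the current tree
#     (single removals of chain nodes can each look unprofitable while the
#     pair is profitable).
local_search <- function(prep, S, prize, beta, omega, total_prize, max_iter) {
  terminals <- which(prize > 0)
  cur <- score_set(prep, S, prize, beta, omega, total_prize)
  if (!is.finite(cur$score)) {
    S <- integer(0)
    cur <- score_set(prep, S, prize, beta, omega, total_prize)
  }
  best <- list(S = S, score = cur$score, mst = cur$mst)
  for (iter in seq_len(max_iter)) {
    S <- best$S
    cand_sets <- list()
    if (length(S)) {
      pruned <- strong_prune(best$mst, prize, beta, omega)
      if (length(pruned) < length(S)) cand_sets <- list(sort(pruned))
    }
    boundary <- setdiff(sort(unique(c(unlist(prep$adj[S]), terminals))), S)
    cand_sets <- c(cand_sets,
                   lapply(boundary, function(u) sort(c(S, u))),
                   lapply(seq_along(S), function(k) S[-k]))
    out_terms <- setdiff(terminals, S)
    for (t in out_terms) {
      anchors <- S[is.finite(prep$dist[t, S])]
      if (length(anchors)) {
        a <- anchors[which.min(prep$dist[t, anchors])]
        cand_sets <- c(cand_sets,
                       list(sort(union(S, shortest_path_nodes(prep, t, a)))))
      }
      others <- setdiff(out_terms, t)
      others <- others[is.finite(prep$dist[t, others])]
      if (length(others)) {
        a <- others[which.min(prep$dist[t, others])]
        cand_sets <- c(cand_sets,
                       list(sort(union(S, shortest_path_nodes(prep, t, a)))))
      }
    }
    if (length(S) > 1L) {
      mst <- best$mst
      for (k in seq(2L, length(S) + 1L)) {
        p <- mst$parent[k]
        if (p > 1L) {
          cand_sets <- c(cand_sets,
                         list(setdiff(S, c(mst$S[k - 1L], mst$S[p - 1L]))))
        }
      }
    }
    if (!length(cand_sets)) break
    cand <- lapply(cand_sets, function(cs) {
      score_set(prep, cs, prize, beta, omega, total_prize)
    })
    scores <- vapply(cand, `[[`, numeric(1), "score")
    k <- which.min(scores)
    if (scores[k] < best$score - 1e-12) {
      best <- list(S = cand_sets[[k]], score = scores[k], mst = cand[[k]]$mst)
    } else break
  }
  best
}

#' Solve the prize-collecting Steiner forest problem
#'
#' Finds a low-objective forest in a costed interactome where node prizes
#' (screen Z-scores) reward inclusion and edge costs penalize it. The
#' solver is deterministic. Instances with at most `control$exact_limit`
#' nodes are solved by complete search over node subsets (exact, since the
#' optimal structure for a fixed subset is the root-augmented minimum
#' spanning tree); larger instances use terminal-tree construction along
#' shortest paths, strong pruning, an optional full-graph start, and
#' best-improvement local search, each candidate node set scored exactly
#' through the root-augmented MST.
#'
#' @param graph a [make_costed()] graph.
#' @param prizes named nonnegative numeric vector of node prizes; names not
#'   present in the graph are reported in the result's `unmapped` field
#'   rather than silently dropped.
#' @param beta prize scaling factor (default 1).
#' @param omega artificial root-edge cost, i.e. the per-tree charge; default
#'   5 x median edge cost.
#' @param control a [pcsf_control()] list.
#' @param prep optional precomputed [pcsf_prep()] for repeated solves on the
#'   same graph.
#' @return Object of class `pcsf_forest`: `nodes`, `edges`
#'   (`node_a, node_b, cost`), `components`, `objective_excluded_prize`,
#'   `objective_edge_cost`, `objective_total` (their sum; artificial root
#'   edges are excluded from the report), `augmented_objective`
#'   (`objective_total + omega * components`, the quantity optimized),
#'   `beta`, `omega`, `unmapped`.
#' @export
solve_pcsf <- function(graph, prizes, beta = 1, omega = NULL,
                       control = pcsf_control(), prep = NULL) {
  if (is.null(prep)) prep <- pcsf_prep(graph)
  stopifnot(inherits(prep, "pcsf_prep"))
  stop_if_not_scalar_number(beta, "beta", strict_min = 0)
  if (is.null(names(prizes)) && length(prizes)) {
    stop("`prizes` must be a named vector", call. = FALSE)
  }
  if (any(!is.finite(prizes)) || any(prizes < 0)) {
    stop("prizes must be finite and nonnegative", call. = FALSE)
  }
  omega <- omega %||% (5 * prep$median_cost)
  stop_if_not_scalar_number(omega, "omega", strict_min = 0)
  unmapped <- sort(names(prizes)[!(names(prizes) %in% prep$nodes) & prizes > 0])
  prize <- numeric(prep$n)
  mapped <- names(prizes)[names(prizes) %in% prep$nodes]
  prize[match(mapped, prep$nodes)] <- prizes[mapped]
  total_prize <- sum(prize)

  if (prep$n <= control$exact_limit) {
    best <- exact_subset_search(prep, prize, beta, omega, total_prize)
    return(build_forest(prep, best, prize, beta, omega, total_prize, unmapped))
  }
  starts <- list(pcsf_construct(prep, prize, beta, omega))
  if (control$all_start) {
    starts <- c(starts,
                list(which(prep$comp %in% unique(prep$comp[prize > 0]))))
  }
  candidates <- lapply(starts, function(S0) {
    if (control$local_search) {
      local_search(prep, S0, prize, beta, omega, total_prize, control$max_iter)
    } else {
      refine_set(prep, S0, prize, beta, omega, total_prize)
    }
  })
  # guaranteed-improvement baselines: empty forest and single-terminal trees
  candidates <- c(candidates,
                  list(refine_set(prep, integer(0), prize, beta, omega, total_prize)),
                  lapply(which(prize > 0), function(t) {
                    refine_set(prep, t, prize, beta, omega, total_prize)
                  }))
  scores <- vapply(candidates, `[[`, numeric(1), "score")
  sizes <- vapply(candidates, function(x) length(x$S), integer(1))
  ord <- order(scores, sizes)
  best <- candidates[[ord[1]]]
  build_forest(prep, best, prize, beta, omega, total_prize, unmapped)
}

# Complete search over node subsets (exact for a fixed subset via the
# augmented MST). Ties broken by fewer forest edges, then lexicographic
# node set, matching the oracle's rule.
exact_subset_search <- function(prep, prize, beta, omega, total_prize) {
  n <- prep$n
  best <- NULL
  for (mask in 0:(2^n - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    sc <- score_set(prep, S, prize, beta, omega, total_prize)
    if (!is.finite(sc$score)) next
    n_edges <- length(S) - sc$mst$n_components
    key <- paste(prep$nodes[S], collapse = ",")
    if (is.null(best) || sc$score < best$score - 1e-12 ||
        (abs(sc$score - best$score) <= 1e-12 &&
         (n_edges < best$n_edges ||
          (n_edges == best$n_edges && key < best$key)))) {
      best <- list(S = S, score = sc$score, mst = sc$mst,
                   n_edges = n_edges, key = key)
    }
  }
  best
}

build_forest <- function(prep, best, prize, beta, omega, total_prize, unmapped) {
  S <- sort(best$S)
  mst <- augmented_mst(prep, S, prize, omega)
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      cost = numeric(0), stringsAsFactors = FALSE)
  if (length(S) > 1L) {
    ks <- which(mst$parent[-1] != 1L) + 1L # dense positions with real parent edges
    if (length(ks)) {
      a <- prep$nodes[mst$S[mst$parent[ks] - 1L]]
      b <- prep$nodes[mst$S[ks - 1L]]
      edges <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b),
                          cost = mst$key[ks], stringsAsFactors = FALSE)
      edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  excl <- beta * (total_prize - sum(prize[S]))
  structure(list(nodes = prep$nodes[S],
                 edges = edges,
                 components = mst$n_components,
                 objective_excluded_prize = excl,
                 objective_edge_cost = mst$edge_cost,
                 objective_total = excl + mst$edge_cost,
                 augmented_objective = excl + mst$total,
                 beta = beta, omega = omega,
                 prizes = stats::setNames(prize[S], prep$nodes[S]),
                 unmapped = unmapped),
            class = "pcsf_forest")
}

#' @export
print.pcsf_forest <- function(x, ...) {
  cat(sprintf("PCSF forest: %d nodes, %d edges, %d tree(s)\n",
              length(x$nodes), nrow(x$edges), x$components))
  cat(sprintf("  objective %.6g = excluded prize %.6g + edge cost %.6g (beta %.3g, omega %.3g)\n",
              x$objective_total, x$objective_excluded_prize,
              x$objective_edge_cost, x$beta, x$omega))
  if (length(x$unmapped)) {
    cat("  unmapped prize nodes:", paste(x$unmapped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exhaustive PCSF oracle for small instances
#'
#' Enumerates every node subset and, for each, the optimal spanning
#' structure of the root-augmented induced subgraph (by Kruskal's algorithm
#' with union-find), returning the global optimum of the same augmented
#' objective optimized by [solve_pcsf()]. Ties are broken by fewer edges,
#' then lexicographic node set. Enforced to at most 12 nodes.
#'
#' @inheritParams solve_pcsf
#' @return a `pcsf_forest` (global optimum).
#' @export
brute_force_pcsf <- function(graph, prizes, beta = 1, omega = NULL) {
  stopifnot(inherits(graph, "costed_graph"))
  nodes <- graph$nodes
  n <- length(nodes)
  if (n > 12L) {
    stop(sprintf("brute force is limited to 12 nodes (got %d)", n), call. = FALSE)
  }
  omega <- omega %||% (5 * stats::median(graph$edges$cost))
  prize <- numeric(n)
  mapped <- names(prizes)[names(prizes) %in% nodes]
  prize[match(mapped, nodes)] <- prizes[mapped]
  unmapped <- sort(names(prizes)[!(names(prizes) %in% nodes) & prizes > 0])
  total_prize <- sum(prize)
  ei <- match(graph$edges$node_a, nodes)
  ej <- match(graph$edges$node_b, nodes)
  ecost <- graph$edges$cost

  best <- NULL
  for (mask in 0:(2^n - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    res <- kruskal_augmented(S, prize, ei, ej, ecost, omega)
    if (is.null(res)) next
    score <- beta * (total_prize - sum(prize[S])) + res$total
    cand <- list(S = S, score = score, n_edges = nrow(res$edges),
                 edges = res$edges, n_components = res$n_components,
                 edge_cost = res$edge_cost, total = res$total)
    if (is.null(best) || score < best$score - 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
         (cand$n_edges < best$n_edges ||
          (cand$n_edges == best$n_edges &&
           paste(nodes[S], collapse = ",") < paste(nodes[best$S], collapse = ","))))) {
      best <- cand
    }
  }
  excl <- beta * (total_prize - sum(prize[best$S]))
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      cost = numeric(0), stringsAsFactors = FALSE)
  if (nrow(best$edges)) {
    a <- nodes[best$edges[, 1]]
    b <- nodes[best$edges[, 2]]
    edges <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b),
                        cost = best$edges[, 3], stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes[best$S], edges = edges,
                 components = best$n_components,
                 objective_excluded_prize = excl,
                 objective_edge_cost = best$edge_cost,
                 objective_total = excl + best$edge_cost,
                 augmented_objective = excl + best$total,
                 beta = beta, omega = omega,
                 prizes = stats::setNames(prize[best$S], nodes[best$S]),
                 unmapped = unmapped),
            class = "pcsf_forest")
}

# Kruskal MST of the root-augmented subgraph induced by S. Returns NULL when
# the augmented subgraph is disconnected (S infeasible). Vertex 0 = root.
kruskal_augmented <- function(S, prize, ei, ej, ecost, omega) {
  m <- length(S)
  if (m == 0L) {
    return(list(total = 0, edge_cost = 0, n_components = 0L,
                edges = matrix(numeric(0), 0, 3)))
  }
  pos <- integer(length(prize))
  pos[S] <- seq_len(m)
  keep <- pos[ei] > 0L & pos[ej] > 0L
  prized <- S[prize[S] > 0]
  ea <- c(pos[ei[keep]] , rep(0L, length(prized)))
  eb <- c(pos[ej[keep]], pos[prized])
  ec <- c(ecost[keep], rep(omega, length(prized)))
  is_root <- c(rep(FALSE, sum(keep)), rep(TRUE, length(prized)))
  orig_i <- c(ei[keep], rep(NA_integer_, length(prized)))
  orig_j <- c(ej[keep], rep(NA_integer_, length(prized)))
  o <- order(ec, ea, eb)
  parent <- 0:(m) # union-find over vertices 0..m (index offset +1)
  find <- function(x) {
    while (parent[x + 1L] != x) {
      parent[x + 1L] <<- parent[parent[x + 1L] + 1L]
      x <- parent[x + 1L]
    }
    x
  }
  total <- 0
  edge_cost <- 0
  n_root_edges <- 0L
  picked <- matrix(numeric(0), 0, 3)
  n_joined <- 0L
  for (k in o) {
    ra <- find(ea[k]); rb <- find(eb[k])
    if (ra != rb) {
      parent[ra + 1L] <- rb
      total <- total + ec[k]
      n_joined <- n_joined + 1L
      if (is_root[k]) {
        n_root_edges <- n_root_edges + 1L
      } else {
        edge_cost <- edge_cost + ec[k]
        picked <- rbind(picked, c(orig_i[k], orig_j[k], ec[k]))
      }
      if (n_joined == m) break
    }
  }
  if (n_joined < m) return(NULL) # augmented subgraph disconnected
  list(total = total, edge_cost = edge_cost, n_components = n_root_edges,
       edges = picked)
}

#' Normalized betweenness centrality of a forest or graph
#'
#' Shortest-path betweenness normalized by (n-1)(n-2)/2, so values lie in
#' \[0, 1\]. By default computed on an inferred PCSF forest (path structure is
#' unique on a forest); for a `costed_graph`, shortest paths use edge costs.
#'
#' @param x a `pcsf_forest`, `costed_graph`, `interactome`, or igraph object.
#' @return named numeric vector of centralities with attribute `scope`.
#' @export
betweenness_report <- function(x) {
  if (inherits(x, "pcsf_forest")) {
    g <- igraph::graph_from_data_frame(
      if (nrow(x$edges)) x$edges[c("node_a", "node_b")] else
        data.frame(node_a = character(0), node_b = character(0)),
      directed = FALSE, vertices = data.frame(name = x$nodes))
    w <- NA
    scope <- "forest"
  } else if (inherits(x, "costed_graph")) {
    g <- costed_igraph(x)
    w <- igraph::E(g)$cost
    scope <- "graph"
  } else if (inherits(x, "interactome")) {
    g <- igraph::graph_from_data_frame(x$edges[c("node_a", "node_b")],
                                       directed = FALSE,
                                       vertices = data.frame(name = x$nodes))
    w <- NA
    scope <- "graph"
  } else if (inherits(x, "igraph")) {
    g <- x
    w <- NA
    scope <- "graph"
  } else {
    stop("unsupported input for betweenness_report()", call. = FALSE)
  }
  n <- igraph::vcount(g)
  if (n < 3L) {
    out <- stats::setNames(rep(0, n), igraph::V(g)$name)
  } else {
    out <- igraph::betweenness(g, directed = FALSE,
                               weights = if (all(is.na(w))) NULL else w,
                               normalized = TRUE)
  }
  attr(out, "scope") <- scope
  out
}

#' Export a forest as SIF and a JSON report
#'
#' @param forest a `pcsf_forest`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_forest_sif <- function(forest, path) {
  stopifnot(inherits(forest, "pcsf_forest"))
  lines <- if (nrow(forest$edges)) {
    sprintf("%s\tpp\t%s", forest$edges$node_a, forest$edges$node_b)
  } else character(0)
  iso <- setdiff(forest$nodes, unique(c(forest$edges$node_a, forest$edges$node_b)))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' @rdname write_forest_sif
#' @export
forest_report <- function(forest, path = NULL) {
  stopifnot(inherits(forest, "pcsf_forest"))
  btw <- betweenness_report(forest)
  rep <- list(nodes = forest$nodes,
              edges = forest$edges,
              components = forest$components,
              objective = list(total = forest$objective_total,
                               excluded_prize = forest$objective_excluded_prize,
                               edge_cost = forest$objective_edge_cost,
                               augmented = forest$augmented_objective,
                               beta = forest$beta, omega = forest$omega),
              betweenness = as.list(unclass(btw)),
              unmapped_prize_nodes = forest$unmapped)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
  } else {
    rep
  }
}
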