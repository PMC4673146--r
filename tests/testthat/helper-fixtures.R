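# Shared fixtures and independent oracles used across the suite.

# Costed graph from a terse edge spec: list of c(a, b, weight).
make_cg <- function(..., cost_mode = "one_minus_weight", nodes = NULL) {
  sp <- list(...)
  ed <- data.frame(node_a = vapply(sp, `[[`, "", 1),
                   node_b = vapply(sp, `[[`, "", 2),
                   weight = as.numeric(vapply(sp, `[[`, "", 3)),
                   stringsAsFactors = FALSE)
  make_costed(as_interactome(ed, nodes = nodes), cost_mode = cost_mode)
}

# Random small PCSF instance (relies on the caller's RNG state).
random_small_instance <- function(n_max = 8, density = 0.45) {
  n <- sample(3:n_max, 1)
  repeat {
    am <- matrix(stats::runif(n * n) < density, n, n)
    am[lower.tri(am, diag = TRUE)] <- FALSE
    idx <- which(am, arr.ind = TRUE)
    if (nrow(idx) >= 1) break
  }
  nodes <- sprintf("n%02d", seq_len(n))
  ed <- data.frame(node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]],
                   weight = stats::runif(nrow(idx), 0.05, 1),
                   stringsAsFactors = FALSE)
  net <- as_interactome(ed)
  cg <- make_costed(net, sample(c("one_minus_weight", "weight_as_cost",
                                  "neg_log_weight"), 1))
  nterm <- sample(seq_len(n), 1)
  pr <- stats::setNames(stats::runif(nterm, 0, 2.5),
                        sample(net$nodes, min(nterm, length(net$nodes))))
  list(cg = cg, prizes = pr,
       beta = stats::runif(1, 0.5, 2), omega = stats::runif(1, 0.2, 1.5))
}

# Naive single-linkage agglomeration: returns the sorted merge heights.
# Independent of stats::hclust (direct min-distance cluster merging).
single_linkage_heights_bruteforce <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- min(d[clusters[[i]], clusters[[j]]])
          if (h < best[1]) best <- c(h, i, j)
        }
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# Betweenness on a tree by explicit path enumeration: for every node pair,
# walk the unique path (BFS parent pointers) and count interior nodes.
tree_betweenness_recount <- function(edges, nodes) {
  n <- length(nodes)
  adj <- lapply(stats::setNames(seq_len(n), nodes), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$node_a[k], nodes)
    j <- match(edges$node_b[k], nodes)
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  count <- stats::setNames(numeric(n), nodes)
  path_between <- function(s, t) {
    parent <- rep(NA_integer_, n)
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == t) break
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (!visited[t]) return(NULL)
    path <- t
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    path
  }
  for (s in seq_len(n - 1L)) {
    for (t in seq((s + 1L), n)) {
      p <- path_between(s, t)
      if (!is.null(p) && length(p) > 2L) {
        mid <- p[-c(1, length(p))]
        count[mid] <- count[mid] + 1
      }
    }
  }
  count / (n - 1) / (n - 2) * 2
}

# Random integer seed space kept well below 2^31.
test_seeds <- function(n, from = 1L) seq(from, length.out = n)
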