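# Weighted-interactome containers and edge-cost transforms.

#' Build an interactome from an edge table
#'
#' Undirected simple graph with confidence weights in (0, 1]. Duplicate
#' edges are collapsed keeping the maximum weight; self-loops are dropped
#' (with a message giving the count).
#'
#' @param edges data frame with columns `node_a, node_b, weight`.
#' @param nodes optional node ids to include even when they carry no edge
#'   (isolated nodes).
#' @return object of class `interactome`: list with `edges` (canonicalized,
#'   `node_a < node_b`, sorted) and `nodes`.
#' @export
as_interactome <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "weight") %in% names(edges)))
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (!is.numeric(edges$weight) || !all(is.finite(edges$weight))) {
    stop("edge weights must be finite numbers", call. = FALSE)
  }
  if (any(edges$weight <= 0 | edges$weight > 1)) {
    stop("edge weights must lie in (0, 1]", call. = FALSE)
  }
  loops <- edges$node_a == edges$node_b
  if (any(loops)) {
    message(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  edges <- data.frame(node_a = a, node_b = b, weight = edges$weight,
                      stringsAsFactors = FALSE)
  # collapse duplicates keeping the maximum confidence
  edges <- edges[order(edges$node_a, edges$node_b, -edges$weight), , drop = FALSE]
  edges <- edges[!duplicated(edges[c("node_a", "node_b")]), , drop = FALSE]
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$node_a, edges$node_b,
                                       as.character(nodes))))),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("Interactome: %d nodes, %d edges, weights in [%.3g, %.3g]\n",
              length(x$nodes), nrow(x$edges), min(x$edges$weight),
              max(x$edges$weight)))
  invisible(x)
}

#' Read an interactome edge list
#'
#' Tab-separated `node_a<TAB>node_b<TAB>weight` with weights in (0, 1]; a
#' STRING-style dialect with integer combined scores in (1, 1000] is
#' detected and normalized by 1000. A header line is skipped when its third
#' field is not numeric.
#'
#' @param path TSV file path.
#' @return an [as_interactome()] object.
#' @export
load_interactome <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty interactome file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first_line <- 1L
  if (suppressWarnings(is.na(as.numeric(fields[[1]][3])))) first_line <- 2L
  n <- length(lines)
  if (first_line > n) stop("interactome file has no edge lines", call. = FALSE)
  a <- character(n); b <- character(n); w <- numeric(n)
  for (i in seq(first_line, n)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop(sprintf("line %d: expected 3 tab-separated fields", i), call. = FALSE)
    }
    wi <- suppressWarnings(as.numeric(f[3]))
    if (is.na(wi)) {
      stop(sprintf("line %d: non-numeric weight '%s'", i, f[3]), call. = FALSE)
    }
    a[i] <- f[1]; b[i] <- f[2]; w[i] <- wi
  }
  keep <- seq(first_line, n)
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  if (all(w == round(w)) && any(w > 1)) {
    # STRING dialect: integer combined scores 0-1000
    if (any(w > 1000)) {
      idx <- which(w > 1000)[1]
      stop(sprintf("line %d: score %g out of range (0, 1000]", keep[idx], w[idx]),
           call. = FALSE)
    }
    w <- w / 1000
  }
  bad <- which(w <= 0 | w > 1)
  if (length(bad)) {
    stop(sprintf("line %d: weight %g out of range (0, 1]",
                 keep[bad[1]], w[bad[1]]), call. = FALSE)
  }
  as_interactome(data.frame(node_a = a, node_b = b, weight = w,
                            stringsAsFactors = FALSE))
}

#' @rdname load_interactome
#' @param x an `interactome`.
#' @export
write_interactome <- function(x, path) {
  stopifnot(inherits(x, "interactome"))
  utils::write.table(x$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach edge costs to an interactome
#'
#' Converts confidence weights to positive edge costs for the PCSF
#' objective. `one_minus_weight` (default) makes confident interactions
#' cheap: cost = 1 - weight + epsilon. `weight_as_cost` uses the weight
#' itself as the cost (the literal reading of using edge weights as edge
#' costs). `neg_log_weight` uses -log(weight), floored at epsilon.
#'
#' @param x an `interactome` (or edge data frame).
#' @param cost_mode one of `"one_minus_weight"`, `"weight_as_cost"`,
#'   `"neg_log_weight"`.
#' @param epsilon positive guard so costs never reach zero.
#' @return object of class `costed_graph`: `interactome` fields plus a
#'   `cost` column and `cost_mode`.
#' @export
make_costed <- function(x, cost_mode = c("one_minus_weight", "weight_as_cost",
                                         "neg_log_weight"),
                        epsilon = 1e-6) {
  cost_mode <- match.arg(cost_mode)
  if (!inherits(x, "interactome")) x <- as_interactome(x)
  stop_if_not_scalar_number(epsilon, "epsilon", strict_min = 0)
  w <- x$edges$weight
  cost <- switch(cost_mode,
                 one_minus_weight = 1 - w + epsilon,
                 weight_as_cost = w,
                 neg_log_weight = pmax(-log(w), epsilon))
  edges <- x$edges
  edges$cost <- cost
  structure(list(edges = edges, nodes = x$nodes, cost_mode = cost_mode,
                 epsilon = epsilon),
            class = "costed_graph")
}

#' @export
print.costed_graph <- function(x, ...) {
  cat(sprintf("Costed graph (%s): %d nodes, %d edges, costs in [%.3g, %.3g]\n",
              x$cost_mode, length(x$nodes), nrow(x$edges),
              min(x$edges$cost), max(x$edges$cost)))
  invisible(x)
}

# igraph view of a costed graph (vertices in sorted-id order).
costed_igraph <- function(x) {
  stopifnot(inherits(x, "costed_graph"))
  g <- igraph::graph_from_data_frame(x$edges[c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = x$nodes))
  igraph::E(g)$cost <- x$edges$cost
  igraph::E(g)$weight <- x$edges$weight
  g
}
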