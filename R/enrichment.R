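# Randomization test for enrichment of a query node in PCSF networks.
#
# The observed statistic is computed from the forest built on the hit set;
# null statistics come from size-matched node sets drawn uniformly from the
# background, with the observed prize values permuted onto them so the
# prize-magnitude distribution is preserved.

#' Randomization test for query-node enrichment
#'
#' Builds the PCSF network from the observed hit prizes, records the query
#' node's statistic (its normalized betweenness in the forest, or a 0/1
#' inclusion indicator), and compares it with `n_iterations` forests built
#' from random size-matched node sets. The empirical p-value uses the
#' add-one estimator (1 + #\{null >= observed\}) / (n_iterations + 1), which
#' is never zero.
#'
#' @param graph a [make_costed()] graph.
#' @param hit_prizes named nonnegative vector of prizes for the hit set
#'   (e.g. screen Z-scores of the primary hits).
#' @param background character vector of node ids to sample random sets
#'   from (e.g. all screened kinases present in the graph). Must not be
#'   smaller than the hit set; the query node is excluded automatically.
#' @param query_node node whose enrichment is tested (e.g. `"AR"`).
#' @param n_iterations number of random sets (default 1000).
#' @param criterion `"betweenness"` (default) or `"inclusion"`.
#' @param beta,omega passed to [solve_pcsf()].
#' @param control solver settings; defaults to the fast construction-only
#'   solver so the null ensemble is affordable (identical settings are used
#'   for the observed and every null network, preserving exchangeability).
#' @param seed integer seed; the null sequence is reproducible given it.
#' @return object of class `enrichment_result` with fields `query_node`,
#'   `criterion`, `n_iterations`, `observed_statistic`, `observed_included`,
#'   `null_statistics`, `null_included`, `empirical_p`, `observed_forest`.
#' @export
randomization_test <- function(graph, hit_prizes, background, query_node,
                               n_iterations = 1000,
                               criterion = c("betweenness", "inclusion"),
                               beta = 1, omega = NULL,
                               control = pcsf_control(local_search = FALSE,
                                                      all_start = FALSE),
                               seed = 1L) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(graph, "costed_graph"))
  prep <- pcsf_prep(graph)
  if (!query_node %in% prep$nodes) {
    stop(sprintf("query node '%s' is not in the graph", query_node), call. = FALSE)
  }
  background <- setdiff(unique(as.character(background)), query_node)
  miss <- setdiff(background, prep$nodes)
  if (length(miss)) {
    stop("background nodes absent from the graph: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  k <- length(hit_prizes)
  if (k > length(background)) {
    stop("background is smaller than the hit set", call. = FALSE)
  }
  stat_of <- function(forest) {
    included <- query_node %in% forest$nodes
    s <- if (criterion == "inclusion") {
      as.numeric(included)
    } else if (included) {
      unname(betweenness_report(forest)[query_node])
    } else 0
    list(stat = s, included = included)
  }
  observed_forest <- solve_pcsf(graph, hit_prizes, beta = beta, omega = omega,
                                control = control, prep = prep)
  obs <- stat_of(observed_forest)
  prize_values <- unname(hit_prizes)
  null_stats <- numeric(n_iterations)
  null_incl <- logical(n_iterations)
  with_seed(seed, {
    for (i in seq_len(n_iterations)) {
      nodes_i <- sample(background, k)
      prizes_i <- stats::setNames(sample(prize_values), nodes_i)
      f <- solve_pcsf(graph, prizes_i, beta = beta, omega = omega,
                      control = control, prep = prep)
      si <- stat_of(f)
      null_stats[i] <- si$stat
      null_incl[i] <- si$included
    }
  })
  p <- (1 + sum(null_stats >= obs$stat)) / (n_iterations + 1)
  structure(list(query_node = query_node, criterion = criterion,
                 n_iterations = as.integer(n_iterations),
                 observed_statistic = obs$stat,
                 observed_included = obs$included,
                 null_statistics = null_stats,
                 null_included = null_incl,
                 empirical_p = p,
                 observed_forest = observed_forest,
                 seed = as.integer(seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Randomization test for '%s' (%s criterion, %d iterations)\n",
              x$query_node, x$criterion, x$n_iterations))
  cat(sprintf("  observed statistic %.4g (query %sincluded in observed forest)\n",
              x$observed_statistic, if (x$observed_included) "" else "not "))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}

#' Summarize the null distribution of an enrichment test
#'
#' @param result an [randomization_test()] result.
#' @return one-row data frame: mean, SD and quantiles of the null
#'   statistics, the query node's inclusion frequency across null forests,
#'   the observed statistic and the empirical p.
#' @export
null_summary <- function(result) {
  stopifnot(inherits(result, "enrichment_result"))
  ns <- result$null_statistics
  q <- stats::quantile(ns, c(0, 0.25, 0.5, 0.75, 0.95, 1), names = FALSE)
  data.frame(criterion = result$criterion,
             n_iterations = result$n_iterations,
             null_mean = mean(ns),
             null_sd = stats::sd(ns),
             null_q00 = q[1], null_q25 = q[2], null_q50 = q[3],
             null_q75 = q[4], null_q95 = q[5], null_q100 = q[6],
             inclusion_frequency = mean(result$null_included),
             observed = result$observed_statistic,
             empirical_p = result$empirical_p,
             stringsAsFactors = FALSE)
}
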