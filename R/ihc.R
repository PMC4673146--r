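# Ordinal IHC tissue-microarray scores: class aggregation, the 2-SE
# confidence-bar overlap significance heuristic, and clustering of core
# staining profiles.

#' Read / write TMA score tables
#'
#' CSV dialect `core,tumor_class,marker,score` with integer scores 0-3
#' (missing allowed as empty/NA).
#'
#' @param path file path.
#' @return `read_tma()`: long data frame.
#' @export
read_tma <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("core", "tumor_class", "marker", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("TMA table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- is.na(df$score) | (df$score %in% 0:3)
  if (!all(ok)) {
    stop("TMA scores must be integers in 0..3 (or missing)", call. = FALSE)
  }
  df
}

#' @rdname read_tma
#' @param scores long TMA data frame.
#' @export
write_tma <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Per-class marker summaries with 2-SE bars
#'
#' Averages staining scores across all cores of each tumor class, per
#' marker. The error-bar halfwidth is twice the standard error of the mean
#' (sample SD / sqrt(n)), corresponding approximately to a 95% confidence
#' interval. Missing scores are excluded pairwise; empty (class, marker)
#' groups are skipped with a message.
#'
#' @param scores long TMA data frame (`core, tumor_class, marker, score`).
#' @return data frame `tumor_class, marker, mean_score, se, bar_halfwidth,
#'   n_cores`.
#' @export
aggregate_by_class <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("core", "tumor_class", "marker", "score") %in% names(scores)))
  classes <- unique(scores$tumor_class)
  markers <- unique(scores$marker)
  out <- list()
  for (cl in classes) {
    for (mk in markers) {
      x <- scores$score[scores$tumor_class == cl & scores$marker == mk]
      x <- x[!is.na(x)]
      if (!length(x)) {
        message(sprintf("no scores for class '%s', marker '%s'; group skipped",
                        cl, mk))
        next
      }
      se <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
      out[[length(out) + 1L]] <- data.frame(
        tumor_class = cl, marker = mk, mean_score = mean(x), se = se,
        bar_halfwidth = 2 * se, n_cores = length(x),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Significance from 2-SE confidence-bar overlap
#'
#' Implements the rule-of-eye for comparing two group means by their 2-SE
#' bars: with group sizes of at least 10, bars overlapping by about half
#' the average bar halfwidth correspond to p ~ 0.05, and bars just touching
#' (zero overlap) to p ~ 0.01. The overlap is measured as
#' (sum of halfwidths - |mean difference|) / (average halfwidth), so
#' positive values mean overlapping bars. A two-sided Welch t-test computed
#' from the same summaries is returned alongside for calibration.
#'
#' @param summary_a,summary_b one-row data frames (or lists) with
#'   `mean_score`, `se`, `n_cores` (as from [aggregate_by_class()]).
#' @return list with `overlap_proportion`, `approx_p` (one of `"<0.01"`,
#'   `"~0.01"`, `"~0.05"`, `"ns"`, `"degenerate"`), `exact_p` (Welch),
#'   `t_statistic`, `df`.
#' @examples
#' a <- list(mean_score = 2.0, se = 0.25, n_cores = 10)
#' b <- list(mean_score = 1.0, se = 0.25, n_cores = 10) # bars exactly touch
#' ci_overlap_p(a, b)$exact_p # ~0.011
#' @export
ci_overlap_p <- function(summary_a, summary_b) {
  g <- function(s, f) as.numeric(s[[f]])
  ma <- g(summary_a, "mean_score"); mb <- g(summary_b, "mean_score")
  sa <- g(summary_a, "se"); sb <- g(summary_b, "se")
  na <- g(summary_a, "n_cores"); nb <- g(summary_b, "n_cores")
  if (na < 2 || nb < 2) stop("both groups need n >= 2", call. = FALSE)
  delta <- abs(ma - mb)
  half_sum <- 2 * sa + 2 * sb
  if (half_sum == 0) {
    if (delta == 0) {
      return(list(overlap_proportion = NA_real_, approx_p = "degenerate",
                  exact_p = NA_real_, t_statistic = NA_real_, df = NA_real_))
    }
    # zero-width bars, distinct means: no overlap, difference certain
    return(list(overlap_proportion = -Inf, approx_p = "<0.01",
                exact_p = 0, t_statistic = Inf, df = na + nb - 2))
  }
  overlap <- (half_sum - delta) / (half_sum / 2)
  approx_p <- if (overlap < -0.05) {
    "<0.01"
  } else if (overlap <= 0.05) {
    "~0.01"
  } else if (overlap <= 0.5) {
    "~0.05"
  } else "ns"
  se2 <- sa^2 + sb^2
  tstat <- delta / sqrt(se2)
  df <- se2^2 / (sa^4 / (na - 1) + sb^4 / (nb - 1))
  exact_p <- 2 * stats::pt(-tstat, df)
  list(overlap_proportion = overlap, approx_p = approx_p, exact_p = exact_p,
       t_statistic = tstat, df = df)
}

#' Uncentered absolute correlation
#'
#' |sum(x y)| / (||x|| ||y||): the cosine similarity of raw (not
#' mean-centered) score vectors, with sign discarded. Used as the
#' similarity metric for clustering staining profiles; the associated
#' distance is 1 - similarity.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return similarity in \[0, 1\].
#' @export
uncentered_abs_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("uncentered correlation is undefined for a zero-norm vector",
         call. = FALSE)
  }
  abs(sum(x * y) / (nx * ny))
}

# Core x marker score matrix for one tumor class, keeping only
# "informative" cores (complete profiles). Cores sorted by id.
tma_score_matrix <- function(scores, tumor_class, markers = NULL) {
  sub <- scores[scores$tumor_class == tumor_class, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("no cores of class '%s'", tumor_class), call. = FALSE)
  markers <- markers %||% unique(sub$marker)
  cores <- sort(unique(sub$core))
  m <- matrix(NA_real_, length(cores), length(markers),
              dimnames = list(cores, markers))
  m[cbind(match(sub$core, cores), match(sub$marker, markers))] <- sub$score
  complete <- rowSums(is.na(m)) == 0
  m[complete, , drop = FALSE]
}

#' Cluster TMA cores by staining profile
#'
#' Restricts to one tumor class, drops cores with incomplete marker
#' profiles, computes pairwise distances 1 - |uncentered correlation|, and
#' performs single-linkage agglomerative clustering. Cores are ordered by
#' id before clustering so leaf order is deterministic.
#'
#' @param scores long TMA data frame.
#' @param tumor_class class to cluster (default `"CRPC"`).
#' @param markers marker subset (default: all markers present).
#' @return object of class `tma_dendrogram`: `hclust` (the merge tree),
#'   `dist` (distance matrix), `scores` (core x marker matrix in leaf
#'   order), `cores`, `markers`, `tumor_class`.
#' @export
cluster_cores <- function(scores, tumor_class = "CRPC", markers = NULL) {
  m <- tma_score_matrix(scores, tumor_class, markers)
  if (nrow(m) < 2L) {
    stop("need at least 2 cores with complete profiles to cluster",
         call. = FALSE)
  }
  zero <- rowSums(m^2) == 0
  if (any(zero)) {
    stop("cores with all-zero profiles have undefined uncentered correlation: ",
         paste(rownames(m)[zero], collapse = ", "), call. = FALSE)
  }
  nrm <- m / sqrt(rowSums(m^2))
  sim <- abs(tcrossprod(nrm))
  sim[sim > 1] <- 1
  d <- 1 - sim
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  structure(list(hclust = hc, dist = d,
                 scores = m[hc$order, , drop = FALSE],
                 cores = rownames(m), markers = colnames(m),
                 tumor_class = tumor_class),
            class = "tma_dendrogram")
}

#' @export
print.tma_dendrogram <- function(x, ...) {
  cat(sprintf("Single-linkage dendrogram of %d %s cores x %d markers (1 - |uncentered r| distance)\n",
              length(x$cores), x$tumor_class, length(x$markers)))
  cat(sprintf("  merge heights: %.3g .. %.3g\n",
              min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Cut a core dendrogram into k subclasses
#'
#' @param x a `tma_dendrogram`.
#' @param k number of clusters (default 2).
#' @return named integer vector of cluster labels per core.
#' @export
cut_cores <- function(x, k = 2) {
  stopifnot(inherits(x, "tma_dendrogram"))
  stats::cutree(x$hclust, k = k)
}

#' Export the intensity map and the dendrogram
#'
#' `write_intensity_map()` writes the score matrix in dendrogram leaf order
#' as TSV; `write_dendrogram_newick()` writes the merge tree in Newick
#' format (ultrametric branch lengths derived from merge heights).
#'
#' @param x a `tma_dendrogram`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_intensity_map <- function(x, path) {
  stopifnot(inherits(x, "tma_dendrogram"))
  df <- data.frame(core = rownames(x$scores), x$scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_map
#' @export
write_dendrogram_newick <- function(x, path) {
  stopifnot(inherits(x, "tma_dendrogram"))
  phy <- ape::as.phylo(x$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Pairwise class comparisons for every marker
#'
#' Applies [ci_overlap_p()] to each marker for a pair of tumor classes.
#'
#' @param class_summaries output of [aggregate_by_class()].
#' @param class_a,class_b tumor classes to compare.
#' @return data frame with one row per marker: overlap proportion, heuristic
#'   label and exact Welch p.
#' @export
compare_classes <- function(class_summaries, class_a, class_b) {
  markers <- intersect(
    class_summaries$marker[class_summaries$tumor_class == class_a],
    class_summaries$marker[class_summaries$tumor_class == class_b])
  if (!length(markers)) stop("no shared markers between classes", call. = FALSE)
  rows <- lapply(markers, function(mk) {
    a <- class_summaries[class_summaries$tumor_class == class_a &
                           class_summaries$marker == mk, ]
    b <- class_summaries[class_summaries$tumor_class == class_b &
                           class_summaries$marker == mk, ]
    cp <- ci_overlap_p(a, b)
    data.frame(marker = mk, class_a = class_a, class_b = class_b,
               mean_a = a$mean_score, mean_b = b$mean_score,
               overlap_proportion = cp$overlap_proportion,
               approx_p = cp$approx_p, exact_p = cp$exact_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
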