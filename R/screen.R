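# Robust plate normalization and hit calling for arrayed siRNA screens.
#
# Each 384-well plate carries non-targeting control siRNAs; test-well
# readouts are converted to robust Z-scores against the plate's control
# median and MAD, so plate-to-plate location/scale drift cancels.

#' Control-well statistics for one plate
#'
#' Computes the robust location and scale of the non-targeting control wells
#' of a single plate: the control median and the raw (unscaled) median
#' absolute deviation. The 1.4826 normal-consistency factor is applied later,
#' in [z_score()].
#'
#' @param wells data frame of wells from one plate with columns `readout`
#'   and `is_control` (and optionally `plate`).
#' @return An object of class `control_stats`: list with `plate`,
#'   `control_median`, `control_mad` (raw MAD), `n_controls`.
#' @examples
#' w <- data.frame(plate = "p1", readout = c(98, 99, 100, 101, 102),
#'                 is_control = TRUE)
#' control_stats(w) # median 100, MAD 1
#' @export
control_stats <- function(wells) {
  stopifnot(is.data.frame(wells), all(c("readout", "is_control") %in% names(wells)))
  plate <- if ("plate" %in% names(wells)) unique(as.character(wells$plate)) else NA_character_
  if (length(plate) != 1L) {
    stop("`wells` must contain wells from exactly one plate", call. = FALSE)
  }
  ctrl <- wells$readout[as.logical(wells$is_control)]
  if (!all(is.finite(ctrl))) stop("control readouts must be finite", call. = FALSE)
  if (length(ctrl) < 2L) {
    stop(sprintf("plate %s has %d control wells; at least 2 are required",
                 plate, length(ctrl)), call. = FALSE)
  }
  m <- stats::median(ctrl)
  raw_mad <- stats::median(abs(ctrl - m))
  if (raw_mad == 0) {
    stop(sprintf("plate %s has zero control MAD (degenerate scale); Z-scores are undefined",
                 plate), call. = FALSE)
  }
  structure(
    list(plate = plate, control_median = m, control_mad = raw_mad,
         n_controls = length(ctrl)),
    class = "control_stats"
  )
}

#' @export
print.control_stats <- function(x, ...) {
  cat(sprintf("Plate %s: %d controls, median %.4g, MAD %.4g (scaled MAD %.4g)\n",
              x$plate, x$n_controls, x$control_median, x$control_mad,
              1.4826 * x$control_mad))
  invisible(x)
}

#' Robust Z-score against plate controls
#'
#' Z = (readout - control median) / (1.4826 x control MAD). The factor
#' 1.4826 makes the MAD a consistent estimator of the standard deviation
#' under normality, so Z is on the usual standard-deviation scale.
#'
#' @param readout numeric vector of well readouts.
#' @param stats a `control_stats` object for the well's plate.
#' @return Numeric vector of Z-scores.
#' @examples
#' cs <- control_stats(data.frame(plate = "p", readout = c(98, 99, 100, 101, 102),
#'                                is_control = TRUE))
#' z_score(102.9652, cs) # 2
#' @export
z_score <- function(readout, stats) {
  stopifnot(inherits(stats, "control_stats"), is.numeric(readout))
  (readout - stats$control_median) / (1.4826 * stats$control_mad)
}

#' Summarize per-replicate Z-scores for one gene
#'
#' @param z_per_replicate numeric vector of per-replicate Z-scores.
#' @param policy `"mean"` (default) averages replicates; `"min"` and
#'   `"require_all"` both summarize by the minimum, so that thresholding the
#'   summary requires every replicate to pass (they differ only in the rule
#'   tag attached to downstream hit calls).
#' @return list with `z_per_replicate`, `z_summary`, `n_replicates`, `policy`.
#' @export
summarize_gene <- function(z_per_replicate, policy = c("mean", "min", "require_all")) {
  policy <- match.arg(policy)
  z <- as.numeric(z_per_replicate)
  if (length(z) == 0L) stop("no replicate Z-scores supplied", call. = FALSE)
  if (!all(is.finite(z))) stop("replicate Z-scores must be finite", call. = FALSE)
  zs <- switch(policy, mean = mean(z), min = min(z), require_all = min(z))
  list(z_per_replicate = z, z_summary = zs, n_replicates = length(z),
       policy = policy)
}

#' Gene-level Z-scores from a well table
#'
#' Normalizes every test well against its own plate's controls and summarizes
#' replicate Z-scores per gene. Wells sharing a gene and replicate (e.g.
#' duplicate spots) are averaged on the Z scale before replicate aggregation.
#'
#' @param wells well table with columns
#'   `plate, well, gene, sirna, replicate, readout, is_control`.
#' @inheritParams summarize_gene
#' @return data frame with one row per gene: `gene`, one `z_rep<k>` column
#'   per replicate, `z_summary`, `n_replicates`, sorted by gene id.
#' @export
score_genes <- function(wells, policy = c("mean", "min", "require_all")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(wells),
            all(c("plate", "gene", "replicate", "readout", "is_control") %in% names(wells)))
  z_all <- rep(NA_real_, nrow(wells))
  for (p in unique(wells$plate)) {
    idx <- wells$plate == p
    cs <- control_stats(wells[idx, , drop = FALSE])
    z_all[idx] <- z_score(wells$readout[idx], cs)
  }
  test <- !as.logical(wells$is_control) & !is.na(wells$gene)
  df <- data.frame(gene = as.character(wells$gene[test]),
                   replicate = wells$replicate[test],
                   z = z_all[test], stringsAsFactors = FALSE)
  # mean Z per gene x replicate, then aggregate across replicates
  per_rep <- stats::aggregate(z ~ gene + replicate, data = df, FUN = mean)
  genes <- sort(unique(per_rep$gene))
  reps <- sort(unique(per_rep$replicate))
  zmat <- matrix(NA_real_, length(genes), length(reps),
                 dimnames = list(genes, paste0("z_rep", reps)))
  zmat[cbind(match(per_rep$gene, genes),
             match(per_rep$replicate, reps))] <- per_rep$z
  summ <- vapply(genes, function(g) {
    zz <- zmat[g, ]
    summarize_gene(zz[is.finite(zz)], policy)$z_summary
  }, numeric(1))
  nrep <- rowSums(is.finite(zmat))
  out <- data.frame(gene = genes, zmat, z_summary = unname(summ),
                    n_replicates = unname(nrep),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "policy") <- policy
  out
}

#' Call primary screen hits
#'
#' A gene is a primary hit when its summary Z-score meets the threshold
#' (inclusive). Output is ranked by descending summary Z, ties broken by
#' gene id.
#'
#' @param scores data frame from [score_genes()] (needs `gene`, `z_summary`).
#' @param z_min hit threshold, default 1.8.
#' @return data frame `gene, z_summary, is_hit, rule`.
#' @examples
#' sc <- data.frame(gene = c("A", "B", "C"), z_summary = c(2, 1.8, 1.79))
#' call_primary_hits(sc)$gene[call_primary_hits(sc)$is_hit] # "A" "B"
#' @export
call_primary_hits <- function(scores, z_min = 1.8) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L,
            all(c("gene", "z_summary") %in% names(scores)))
  if (!is.numeric(z_min) || length(z_min) != 1L || is.na(z_min)) {
    stop("`z_min` must be a single number (-Inf allowed)", call. = FALSE)
  }
  ord <- order(-scores$z_summary, scores$gene)
  out <- data.frame(gene = scores$gene[ord],
                    z_summary = scores$z_summary[ord],
                    is_hit = scores$z_summary[ord] >= z_min,
                    rule = sprintf("z_summary >= %g", z_min),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Call confirmed hits from a per-siRNA deconvolution screen
#'
#' In the confirmation screen each gene's pooled siRNAs are transfected
#' individually (plus additional distinct siRNAs) and assayed with two
#' readouts. A gene is confirmed when at least `min_sirnas` distinct siRNAs
#' score, where a siRNA scores if its Z aggregated across assays meets
#' `z_min`.
#'
#' @param per_sirna_z data frame with columns `gene, sirna, assay, z`.
#' @param min_sirnas minimum number of scoring siRNAs, default 3.
#' @param z_min per-siRNA Z threshold, default 1.8.
#' @param assay_rule `"mean"` (default): a siRNA scores if its mean Z across
#'   assays meets `z_min`; `"both"`: every assay must meet it.
#' @return data frame `gene, n_scoring_sirnas, n_sirnas, is_hit, rule`,
#'   sorted by descending scoring count then gene id.
#' @export
call_confirmed_hits <- function(per_sirna_z, min_sirnas = 3, z_min = 1.8,
                                assay_rule = c("mean", "both")) {
  assay_rule <- match.arg(assay_rule)
  stopifnot(is.data.frame(per_sirna_z),
            all(c("gene", "sirna", "z") %in% names(per_sirna_z)))
  stop_if_not_scalar_number(min_sirnas, "min_sirnas", min = 1)
  agg_fun <- if (assay_rule == "mean") mean else min
  sir <- stats::aggregate(z ~ gene + sirna, data = per_sirna_z, FUN = agg_fun)
  sir$scores <- sir$z >= z_min
  counts <- stats::aggregate(cbind(n_scoring_sirnas = scores) ~ gene,
                             data = sir, FUN = sum)
  totals <- stats::aggregate(cbind(n_sirnas = scores) ~ gene, data = sir,
                             FUN = length)
  out <- merge(counts, totals, by = "gene")
  out$is_hit <- out$n_scoring_sirnas >= min_sirnas
  out$rule <- sprintf(">=%d siRNAs with %s-assay z >= %g",
                      as.integer(min_sirnas), assay_rule, z_min)
  out <- out[order(-out$n_scoring_sirnas, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of a target transcript in a sample relative to a control
#' condition, normalized to a reference transcript:
#' 2^-((Ct_target,sample - Ct_ref,sample) - (Ct_target,control - Ct_ref,control)).
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   qPCR threshold-cycle numbers (vectors recycle).
#' @return relative expression (1 = no change; 0.5 = one-cycle loss).
#' @examples
#' ddct_fold_change(21, 15, 20, 15) # 0.5
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (!all(is.finite(cts)) || any(cts <= 0)) {
    stop("all Ct values must be finite and positive", call. = FALSE)
  }
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Read / write the well-table CSV dialect
#'
#' Columns: `plate,well,gene,sirna,replicate,readout,is_control`. Control
#' wells may have an empty gene field.
#'
#' @param path file path.
#' @return `read_wells()`: the well data frame.
#' @export
read_wells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "well", "gene", "sirna", "replicate", "readout", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("well table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$gene[df$gene %in% c("", "NA")] <- NA_character_
  df$is_control <- as.logical(df$is_control)
  df
}

#' @rdname read_wells
#' @param wells well data frame.
#' @export
write_wells <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
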