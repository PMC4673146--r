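# Synthetic-data generators with planted ground truth.
#
# The generators emulate the study conditions of the screen they stand in
# for: a 704-gene kinome library arrayed on 384-well plates with 48
# non-targeting control siRNAs per plate, duplicate replicate screens,
# a scale-free confidence-weighted interactome with a planted hub, a
# per-siRNA confirmation screen, and ordinal TMA score tables. Every
# generator is deterministic given its truth seed.

BASELINE_LOCATION <- 100 # plate-null readout location (arbitrary absorbance units)
BASELINE_SCALE <- 5      # plate-null readout SD before plate scale factors

#' Ground truth for a simulated primary screen
#'
#' @param hit_genes character vector of planted hit gene ids (may be empty).
#' @param effect_sizes named numeric vector, gene -> readout shift in units
#'   of the plate's true control MAD (invariant to plate effects). Unnamed
#'   scalar recycles over `hit_genes`.
#' @param plate_effects optional data frame `plate, location_shift,
#'   scale_factor`; drawn by [simulate_screen()] when `NULL`.
#' @param seed integer RNG seed.
#' @return object of class `screen_truth`.
#' @export
screen_truth <- function(hit_genes = character(), effect_sizes = numeric(),
                         plate_effects = NULL, seed = 1L) {
  hit_genes <- as.character(hit_genes)
  if (length(effect_sizes) == 1L && is.null(names(effect_sizes))) {
    effect_sizes <- stats::setNames(rep(effect_sizes, length(hit_genes)), hit_genes)
  }
  if (length(hit_genes) && !setequal(names(effect_sizes), hit_genes)) {
    stop("`effect_sizes` must be named by `hit_genes`", call. = FALSE)
  }
  if (length(effect_sizes) && !all(is.finite(effect_sizes))) {
    stop("effect sizes must be finite", call. = FALSE)
  }
  if (!is.null(plate_effects)) {
    stopifnot(is.data.frame(plate_effects),
              all(c("plate", "location_shift", "scale_factor") %in% names(plate_effects)))
    if (any(plate_effects$scale_factor <= 0)) {
      stop("plate scale factors must be > 0", call. = FALSE)
    }
  }
  structure(list(hit_genes = hit_genes, effect_sizes = effect_sizes,
                 plate_effects = plate_effects, seed = as.integer(seed)),
            class = "screen_truth")
}

#' Default planted truth emulating the kinome screen
#'
#' 31 hit genes among `n_genes` kinases, planted effects drawn uniformly
#' from `effect_range` control-MAD units.
#'
#' @param n_genes library size (default 704).
#' @param n_hits number of planted hits (default 31).
#' @param effect_range range of planted effects in control-MAD units.
#' @param seed integer seed.
#' @return `screen_truth` object.
#' @export
default_screen_truth <- function(n_genes = 704, n_hits = 31,
                                 effect_range = c(5, 8), seed = 1L) {
  genes <- kinome_gene_ids(n_genes)
  with_seed(seed, {
    hits <- sort(sample(genes, n_hits))
    eff <- stats::setNames(stats::runif(n_hits, effect_range[1], effect_range[2]), hits)
    screen_truth(hit_genes = hits, effect_sizes = eff, seed = seed)
  })
}

#' @rdname default_screen_truth
#' @export
kinome_gene_ids <- function(n_genes = 704) sprintf("KIN%03d", seq_len(n_genes))

#' Simulate an arrayed siRNA screen with planted hits
#'
#' Lays out `n_genes` pooled-siRNA test wells plus `n_controls_per_plate`
#' non-targeting controls per plate (controls in fixed leading positions,
#' genes filled row-major across as many plates as needed), for each of
#' `replicates` replicate screens. Null readouts are Gaussian with per-plate
#' location/scale effects; planted hit wells are shifted by
#' `effect_size x true control MAD` of their plate.
#'
#' @param n_genes number of library genes (default 704).
#' @param n_controls_per_plate control wells per plate (default 48).
#' @param plate_capacity wells per plate (default 384).
#' @param replicates replicate screens (default 2).
#' @param truth a [screen_truth()]; defaults to [default_screen_truth()].
#' @return list with `wells` (the well table) and the completed `truth`
#'   (plate effects filled in).
#' @export
simulate_screen <- function(n_genes = 704, n_controls_per_plate = 48,
                            plate_capacity = 384, replicates = 2,
                            truth = default_screen_truth(n_genes = n_genes)) {
  stopifnot(inherits(truth, "screen_truth"))
  stop_if_not_scalar_number(n_genes, "n_genes", min = 1)
  stop_if_not_scalar_number(n_controls_per_plate, "n_controls_per_plate", min = 2)
  n_test <- plate_capacity - n_controls_per_plate
  if (n_test < 1) {
    stop(sprintf("plate capacity %d cannot hold %d controls plus a test well",
                 plate_capacity, n_controls_per_plate), call. = FALSE)
  }
  genes <- kinome_gene_ids(n_genes)
  if (!all(truth$hit_genes %in% genes)) {
    stop("some planted hit genes are not in the simulated library", call. = FALSE)
  }
  n_plates <- ceiling(n_genes / n_test)
  plate_ids <- as.vector(outer(sprintf("p%02d", seq_len(n_plates)),
                               sprintf("r%d", seq_len(replicates)),
                               function(p, r) paste(r, p, sep = "_")))
  with_seed(truth$seed, {
    pe <- truth$plate_effects
    if (is.null(pe)) {
      pe <- data.frame(plate = plate_ids,
                       location_shift = stats::rnorm(length(plate_ids), 0, 10),
                       scale_factor = stats::runif(length(plate_ids), 0.7, 1.3),
                       stringsAsFactors = FALSE)
    } else if (!all(plate_ids %in% pe$plate)) {
      stop("truth$plate_effects does not cover all generated plates", call. = FALSE)
    }
    rows <- vector("list", replicates * n_plates)
    k <- 0L
    for (r in seq_len(replicates)) {
      gene_split <- split(genes, ceiling(seq_along(genes) / n_test))
      for (p in seq_len(n_plates)) {
        pid <- sprintf("r%d_p%02d", r, p)
        eff <- pe[pe$plate == pid, ]
        mu <- BASELINE_LOCATION + eff$location_shift
        sdv <- BASELINE_SCALE * eff$scale_factor
        true_mad <- stats::qnorm(0.75) * sdv
        pg <- gene_split[[p]]
        n_wells <- n_controls_per_plate + length(pg)
        readout <- stats::rnorm(n_wells, mu, sdv)
        gene_col <- c(rep(NA_character_, n_controls_per_plate), pg)
        is_hit <- !is.na(gene_col) & gene_col %in% truth$hit_genes
        readout[is_hit] <- readout[is_hit] +
          truth$effect_sizes[gene_col[is_hit]] * true_mad
        k <- k + 1L
        rows[[k]] <- data.frame(
          plate = pid,
          well = well_labels(n_wells, plate_capacity),
          gene = gene_col,
          sirna = c(sprintf("ctrl_%02d", seq_len(n_controls_per_plate)),
                    paste0(pg, "_pool")),
          replicate = r,
          readout = readout,
          is_control = is.na(gene_col),
          stringsAsFactors = FALSE
        )
      }
    }
    wells <- do.call(rbind, rows)
    rownames(wells) <- NULL
    truth$plate_effects <- pe
    list(wells = wells, truth = truth)
  })
}

# Row-major 384-well style labels (A01..P24); falls back to w#### for
# non-standard capacities.
well_labels <- function(n, capacity) {
  if (capacity <= 384) {
    i <- seq_len(n) - 1L
    sprintf("%s%02d", LETTERS[i %/% 24 + 1L], i %% 24 + 1L)
  } else {
    sprintf("w%04d", seq_len(n))
  }
}

#' Ground truth for a simulated interactome
#'
#' @param hub_node id of the planted hub (default `"AR"`).
#' @param hub_attachment_bias preferential-attachment multiplier for the hub
#'   (must be >= 1).
#' @param planted_hit_neighbors node ids to be wired directly to the hub
#'   with confident edges.
#' @param planted_weight confidence weight of the planted hub edges.
#' @param seed integer seed.
#' @return object of class `interactome_truth`.
#' @export
interactome_truth <- function(hub_node = "AR", hub_attachment_bias = 4,
                              planted_hit_neighbors = character(),
                              planted_weight = 0.9, seed = 1L) {
  if (hub_attachment_bias < 1) {
    stop("`hub_attachment_bias` must be >= 1", call. = FALSE)
  }
  stopifnot(planted_weight > 0, planted_weight <= 1)
  structure(list(hub_node = as.character(hub_node),
                 hub_attachment_bias = hub_attachment_bias,
                 planted_hit_neighbors = as.character(planted_hit_neighbors),
                 planted_weight = planted_weight, seed = as.integer(seed)),
            class = "interactome_truth")
}

#' Simulate a scale-free weighted interactome with a planted hub
#'
#' Preferential-attachment growth: each new node attaches to
#' `attachment_parameter` existing nodes with probability proportional to
#' degree, the hub's degree weighted by `hub_attachment_bias`. Edge
#' confidences are uniform on `weight_range`; planted hub-neighbor edges are
#' added with weight `truth$planted_weight`. Node ids are the hub plus the
#' kinome gene ids, so screen hits map onto the graph.
#'
#' @param n_nodes number of nodes (>= 3; default 705: the hub plus the full
#'   704-gene kinome, so every screen hit can map onto the graph).
#' @param attachment_parameter edges added per new node (default 2).
#' @param weight_range range of uniform edge confidences in (0, 1].
#' @param truth an [interactome_truth()].
#' @return list with `edges` (data frame `node_a, node_b, weight`) and `truth`.
#' @export
simulate_interactome <- function(n_nodes = 705, attachment_parameter = 2,
                                 weight_range = c(0.2, 0.95),
                                 truth = interactome_truth()) {
  stopifnot(inherits(truth, "interactome_truth"))
  stop_if_not_scalar_number(n_nodes, "n_nodes", min = 3)
  stopifnot(weight_range[1] > 0, weight_range[2] <= 1)
  m <- max(1L, as.integer(attachment_parameter))
  nodes <- c(truth$hub_node, kinome_gene_ids(n_nodes - 1L))
  if (anyDuplicated(nodes)) stop("node ids must be unique", call. = FALSE)
  with_seed(truth$seed, {
    m0 <- min(n_nodes, m + 1L)
    a <- integer(0); b <- integer(0)
    for (i in seq_len(m0)) for (j in seq_len(m0)) if (i < j) {
      a <- c(a, i); b <- c(b, j)
    }
    deg <- tabulate(c(a, b), nbins = n_nodes)
    for (i in seq(m0 + 1L, length.out = n_nodes - m0)) {
      w <- deg[seq_len(i - 1L)]
      w[1L] <- w[1L] * truth$hub_attachment_bias # hub is node 1
      targets <- sample(seq_len(i - 1L), size = min(m, i - 1L), prob = w)
      a <- c(a, rep(i, length(targets))); b <- c(b, targets)
      deg[i] <- deg[i] + length(targets)
      deg[targets] <- deg[targets] + 1L
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(cbind(lo, hi))
    lo <- lo[keep]; hi <- hi[keep]
    weight <- stats::runif(length(lo), weight_range[1], weight_range[2])
    edges <- data.frame(node_a = nodes[lo], node_b = nodes[hi],
                        weight = weight, stringsAsFactors = FALSE)
    planted <- intersect(truth$planted_hit_neighbors, nodes)
    if (!setequal(planted, truth$planted_hit_neighbors)) {
      stop("planted hit neighbors must be graph nodes", call. = FALSE)
    }
    if (length(planted)) {
      pe <- data.frame(node_a = truth$hub_node, node_b = planted,
                       weight = truth$planted_weight, stringsAsFactors = FALSE)
      edges <- rbind(edges, pe)
      key <- paste(pmin(edges$node_a, edges$node_b),
                   pmax(edges$node_a, edges$node_b))
      # keep the last (planted) copy of duplicated hub edges
      edges <- edges[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    }
    rownames(edges) <- NULL
    list(edges = edges, truth = truth)
  })
}

#' Simulate a per-siRNA confirmation screen
#'
#' Each gene's siRNAs are assayed individually in `assays` independent
#' readouts (e.g. MTS proliferation and cell counts), on plates carrying
#' their own non-targeting controls. Per-siRNA effects emulate variable
#' knockdown efficiency.
#'
#' @param genes character vector of genes to deconvolve.
#' @param sirnas_per_gene siRNAs per gene (default 8: 4 from the original
#'   pool plus 4 additional distinct siRNAs).
#' @param per_sirna_effect named list gene -> numeric effect vector in
#'   control-MAD units (recycled to `sirnas_per_gene`); genes absent from
#'   the list get zero effects.
#' @param assays number of independent readouts (default 2).
#' @param n_controls control wells per assay plate (default 48).
#' @param seed integer seed.
#' @return well-style data frame (`plate` = assay id, `replicate` = assay
#'   index) suitable for [score_confirmation()].
#' @export
simulate_confirmation <- function(genes, sirnas_per_gene = 8,
                                  per_sirna_effect = list(), assays = 2,
                                  n_controls = 48, seed = 1L) {
  stop_if_not_scalar_number(sirnas_per_gene, "sirnas_per_gene", min = 1)
  stop_if_not_scalar_number(assays, "assays", min = 1)
  genes <- as.character(genes)
  with_seed(seed, {
    rows <- vector("list", assays)
    for (a in seq_len(assays)) {
      mu <- BASELINE_LOCATION + stats::rnorm(1, 0, 10)
      sdv <- BASELINE_SCALE * stats::runif(1, 0.7, 1.3)
      true_mad <- stats::qnorm(0.75) * sdv
      gene_col <- rep(genes, each = sirnas_per_gene)
      sirna <- paste0(gene_col, "_si", rep(seq_len(sirnas_per_gene), length(genes)))
      eff <- unlist(lapply(genes, function(g) {
        e <- per_sirna_effect[[g]] %||% 0
        rep_len(e, sirnas_per_gene)
      }))
      n_wells <- n_controls + length(gene_col)
      readout <- stats::rnorm(n_wells, mu, sdv)
      readout[-seq_len(n_controls)] <- readout[-seq_len(n_controls)] + eff * true_mad
      rows[[a]] <- data.frame(
        plate = sprintf("assay%d", a),
        well = well_labels(n_wells, 384),
        gene = c(rep(NA_character_, n_controls), gene_col),
        sirna = c(sprintf("ctrl_%02d", seq_len(n_controls)), sirna),
        replicate = a,
        readout = readout,
        is_control = c(rep(TRUE, n_controls), rep(FALSE, length(gene_col))),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Per-siRNA Z-scores from a confirmation-screen well table
#'
#' Normalizes each assay plate against its own controls and returns one Z
#' per (gene, siRNA, assay), the input expected by [call_confirmed_hits()].
#'
#' @param wells well table from [simulate_confirmation()] (or same dialect).
#' @return data frame `gene, sirna, assay, z`.
#' @export
score_confirmation <- function(wells) {
  stopifnot(is.data.frame(wells))
  out <- NULL
  for (p in unique(wells$plate)) {
    sub <- wells[wells$plate == p, , drop = FALSE]
    cs <- control_stats(sub)
    test <- !sub$is_control
    out <- rbind(out, data.frame(gene = sub$gene[test], sirna = sub$sirna[test],
                                 assay = sub$replicate[test],
                                 z = z_score(sub$readout[test], cs),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Ground truth for a simulated TMA
#'
#' Latent per-(class, marker) means on the 0-3 staining scale, plus a planted
#' two-subclass structure among CRPC cores (a low-CSK subclass with elevated
#' SRC-family phospho-markers versus a normal-CSK subclass).
#'
#' @param class_marker_means numeric matrix, rows = tumor classes, columns =
#'   markers, entries in \[0, 3\]. Row names are class labels.
#' @param crpc_subclass_means 2-row matrix (`low-CSK`, `normal-CSK`) of
#'   latent means for CRPC cores, same columns.
#' @param crpc_low_fraction fraction of CRPC cores in the low-CSK subclass.
#' @param noise_sd latent Gaussian SD around the means before discretization.
#' @param crpc_subclass_assignment optional named vector core id -> subclass;
#'   filled by [simulate_tma()] when `NULL`.
#' @param seed integer seed.
#' @return object of class `tma_truth`.
#' @export
tma_truth <- function(class_marker_means = default_tma_means(),
                      crpc_subclass_means = default_crpc_subclass_means(),
                      crpc_low_fraction = 0.5, noise_sd = 0.35,
                      crpc_subclass_assignment = NULL, seed = 1L) {
  if (any(class_marker_means < 0 | class_marker_means > 3) ||
      any(crpc_subclass_means < 0 | crpc_subclass_means > 3)) {
    stop("latent staining means must lie within [0, 3]", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, crpc_low_fraction >= 0, crpc_low_fraction <= 1)
  structure(list(class_marker_means = class_marker_means,
                 crpc_subclass_means = crpc_subclass_means,
                 crpc_low_fraction = crpc_low_fraction, noise_sd = noise_sd,
                 crpc_subclass_assignment = crpc_subclass_assignment,
                 seed = as.integer(seed)),
            class = "tma_truth")
}

#' @rdname tma_truth
#' @export
tma_markers <- function() {
  c("CSK", "SRC", "pSRC-Y419", "FAK", "pFAK-Y925", "AR", "pAR-Y534")
}

#' @rdname tma_truth
#' @export
default_tma_means <- function() {
  m <- rbind(
    PPCa = c(1.8, 1.5, 1.0, 1.2, 0.8, 2.0, 1.0),
    mets = c(1.6, 1.8, 1.4, 1.5, 1.2, 2.4, 1.4)
  )
  colnames(m) <- tma_markers()
  m
}

#' @rdname tma_truth
#' @export
default_crpc_subclass_means <- function() {
  m <- rbind(
    `low-CSK` = c(0.2, 2.0, 2.8, 1.6, 2.6, 2.6, 2.4),
    `normal-CSK` = c(2.6, 1.8, 0.4, 1.5, 0.8, 2.6, 1.0)
  )
  colnames(m) <- tma_markers()
  m
}

#' Simulate a TMA score table
#'
#' Draws latent Gaussian staining intensities around the class (or planted
#' CRPC subclass) means and discretizes to the ordinal 0-3 scale by rounding
#' and clipping.
#'
#' @param classes tumor classes to simulate; `"CRPC"` cores are drawn from
#'   the planted subclass profiles.
#' @param cores_per_class integer vector (recycled) of cores per class;
#'   defaults emulate group sizes of 25-52 cores with 42 CRPC cores.
#' @param markers marker panel (default [tma_markers()]).
#' @param truth a [tma_truth()].
#' @return list with `scores` (long data frame `core, tumor_class, marker,
#'   score`) and the completed `truth` (CRPC subclass assignment filled in).
#' @export
simulate_tma <- function(classes = c("PPCa", "mets", "CRPC"),
                         cores_per_class = c(30, 30, 42),
                         markers = tma_markers(), truth = tma_truth()) {
  stopifnot(inherits(truth, "tma_truth"), length(markers) >= 1)
  cores_per_class <- rep_len(cores_per_class, length(classes))
  if (any(cores_per_class < 1)) stop("cores_per_class must be >= 1", call. = FALSE)
  with_seed(truth$seed, {
    rows <- list()
    assignment <- truth$crpc_subclass_assignment
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      n <- cores_per_class[ci]
      ids <- sprintf("%s_core%02d", cl, seq_len(n))
      if (cl == "CRPC") {
        if (is.null(assignment)) {
          n_low <- round(truth$crpc_low_fraction * n)
          sub <- c(rep("low-CSK", n_low), rep("normal-CSK", n - n_low))
          assignment <- stats::setNames(sub, ids)
        }
        mu <- truth$crpc_subclass_means[assignment[ids], markers, drop = FALSE]
      } else {
        if (!cl %in% rownames(truth$class_marker_means)) {
          stop(sprintf("no latent means configured for class '%s'", cl),
               call. = FALSE)
        }
        mu <- truth$class_marker_means[rep(cl, n), markers, drop = FALSE]
      }
      latent <- mu + stats::rnorm(length(mu), 0, truth$noise_sd)
      score <- pmin(3L, pmax(0L, as.integer(round(latent))))
      rows[[cl]] <- data.frame(core = rep(ids, times = length(markers)),
                               tumor_class = cl,
                               marker = rep(markers, each = n),
                               score = as.integer(score),
                               stringsAsFactors = FALSE)
    }
    scores <- do.call(rbind, rows)
    rownames(scores) <- NULL
    truth$crpc_subclass_assignment <- assignment
    list(scores = scores, truth = truth)
  })
}
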