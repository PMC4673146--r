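# Seeded end-to-end pipeline: simulate -> normalize -> hits -> network ->
# enrichment -> confirmation -> IHC, with one validated config and a
# consolidated JSON report.

default_config <- function() {
  list(
    seed = 1L,
    screen = list(n_genes = 704L, n_controls_per_plate = 48L,
                  plate_capacity = 384L, replicates = 2L, n_hits = 31L,
                  effect_min = 5, effect_max = 8,
                  policy = "mean", z_min = 1.8),
    interactome = list(n_nodes = 705L, attachment = 2L, hub_node = "AR",
                       hub_bias = 4, weight_min = 0.2, weight_max = 0.95,
                       planted_weight = 0.9),
    pcsf = list(cost_mode = "one_minus_weight", beta = 1, omega = NA_real_),
    enrichment = list(n_iterations = 1000L, criterion = "betweenness"),
    confirmation = list(sirnas_per_gene = 8L, active_sirnas = 5L,
                        effect = 5, assays = 2L, min_sirnas = 3L,
                        assay_rule = "mean"),
    tma = list(cores_ppca = 30L, cores_mets = 30L, cores_crpc = 42L,
               noise_sd = 0.35, crpc_low_fraction = 0.5, n_clusters = 2L)
  )
}

check_scalar <- function(value, template, key) {
  if (length(value) != 1L) stop(sprintf("config key '%s' must be scalar", key), call. = FALSE)
  if (is.numeric(template)) {
    if (!is.numeric(value)) stop(sprintf("config key '%s' must be numeric, got '%s'", key, value), call. = FALSE)
    if (is.integer(template)) value <- as.integer(value)
  } else if (is.character(template) && !is.character(value)) {
    stop(sprintf("config key '%s' must be a string", key), call. = FALSE)
  }
  value
}

#' Validate a pipeline configuration
#'
#' Merges a raw key-value list (or YAML file) over the full default
#' configuration. Unknown keys are rejected; every value is type-checked
#' against its default.
#'
#' @param raw named list, path to a YAML file, or `NULL` (all defaults).
#' @return fully-defaulted config list of class `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw)) raw <- yaml::read_yaml(raw)
  raw <- raw %||% list()
  if (!is.list(raw)) stop("config must be a named list", call. = FALSE)
  cfg <- default_config()
  for (section in names(raw)) {
    if (!section %in% names(cfg)) {
      stop(sprintf("unknown config key '%s'", section), call. = FALSE)
    }
    if (is.list(cfg[[section]])) {
      if (!is.list(raw[[section]])) {
        stop(sprintf("config section '%s' must be a mapping", section), call. = FALSE)
      }
      for (key in names(raw[[section]])) {
        if (!key %in% names(cfg[[section]])) {
          stop(sprintf("unknown config key '%s.%s'", section, key), call. = FALSE)
        }
        cfg[[section]][[key]] <- check_scalar(raw[[section]][[key]],
                                              cfg[[section]][[key]],
                                              paste(section, key, sep = "."))
      }
    } else {
      cfg[[section]] <- check_scalar(raw[[section]], cfg[[section]], section)
    }
  }
  if (cfg$screen$z_min <= 0 && !is.finite(cfg$screen$z_min)) {
    # -Inf allowed (vacuous threshold); NaN rejected
    if (is.nan(cfg$screen$z_min)) stop("screen.z_min must be a number", call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full simulated pipeline
#'
#' Executes, in order: screen simulation, plate normalization and gene
#' scoring, primary hit calling, interactome simulation (hub wired to the
#' planted hits present in the graph), PCSF inference with hit Z-scores as
#' prizes, betweenness reporting, randomization enrichment of the hub,
#' per-siRNA confirmation of the primary hits, and TMA simulation with
#' class aggregation plus CRPC core clustering. Every intermediate artifact
#' is written under `out_dir`, and a consolidated JSON report is returned.
#'
#' @param config a [validate_config()] config (or raw list/path accepted by
#'   it).
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return the run report (list), invisibly written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = tempfile("run"),
                         seed = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  stage_seed <- function(i) derive_seed(config$seed, i)
  log_stage <- function(name, ...) {
    message(sprintf("[%s] %s", name, sprintf(...)))
  }

  # 1. screen simulation + scoring ------------------------------------
  sc <- config$screen
  truth <- with_seed(stage_seed(1L), default_screen_truth(
    n_genes = sc$n_genes, n_hits = sc$n_hits,
    effect_range = c(sc$effect_min, sc$effect_max), seed = stage_seed(1L)))
  sim <- simulate_screen(n_genes = sc$n_genes,
                         n_controls_per_plate = sc$n_controls_per_plate,
                         plate_capacity = sc$plate_capacity,
                         replicates = sc$replicates, truth = truth)
  write_wells(sim$wells, file.path(out_dir, "wells.csv"))
  scores <- score_genes(sim$wells, policy = sc$policy)
  hits <- call_primary_hits(scores, z_min = sc$z_min)
  gs <- merge(scores, hits[c("gene", "is_hit")], by = "gene")
  utils::write.table(gs, file.path(out_dir, "gene_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hit_genes <- hits$gene[hits$is_hit]
  log_stage("screen", "%d genes scored, %d primary hits at Z >= %g",
            nrow(scores), length(hit_genes), sc$z_min)

  # 2. interactome ------------------------------------------------------
  ic <- config$interactome
  itruth <- interactome_truth(
    hub_node = ic$hub_node, hub_attachment_bias = ic$hub_bias,
    planted_hit_neighbors = intersect(truth$hit_genes,
                                      kinome_gene_ids(ic$n_nodes - 1L)),
    planted_weight = ic$planted_weight, seed = stage_seed(2L))
  isim <- simulate_interactome(n_nodes = ic$n_nodes,
                               attachment_parameter = ic$attachment,
                               weight_range = c(ic$weight_min, ic$weight_max),
                               truth = itruth)
  net <- as_interactome(isim$edges)
  write_interactome(net, file.path(out_dir, "interactome.tsv"))
  log_stage("interactome", "%d nodes, %d edges, hub '%s'",
            length(net$nodes), nrow(net$edges), ic$hub_node)

  # 3. PCSF --------------------------------------------------------------
  pc <- config$pcsf
  costed <- make_costed(net, cost_mode = pc$cost_mode)
  prizes <- stats::setNames(hits$z_summary[hits$is_hit], hit_genes)
  prizes <- prizes[prizes > 0]
  omega <- if (is.na(pc$omega)) NULL else pc$omega
  forest <- solve_pcsf(costed, prizes, beta = pc$beta, omega = omega)
  write_forest_sif(forest, file.path(out_dir, "forest.sif"))
  forest_report(forest, file.path(out_dir, "forest.json"))
  btw <- betweenness_report(forest)
  log_stage("pcsf", "forest with %d nodes / %d trees, objective %.4g, %d unmapped hits",
            length(forest$nodes), forest$components, forest$objective_total,
            length(forest$unmapped))

  # 4. enrichment --------------------------------------------------------
  en <- config$enrichment
  background <- intersect(kinome_gene_ids(sc$n_genes), net$nodes)
  enr <- randomization_test(costed, prizes, background,
                            query_node = ic$hub_node,
                            n_iterations = en$n_iterations,
                            criterion = en$criterion, beta = pc$beta,
                            omega = omega, seed = stage_seed(3L))
  utils::write.table(
    data.frame(iteration = seq_along(enr$null_statistics),
               statistic = enr$null_statistics,
               included = enr$null_included),
    file.path(out_dir, "null_stats.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(query = enr$query_node, criterion = enr$criterion,
         observed = enr$observed_statistic, empirical_p = enr$empirical_p,
         null = as.list(null_summary(enr)[1, ])),
    file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  log_stage("enrichment", "p = %.4g (%s criterion, N = %d)",
            enr$empirical_p, en$criterion, en$n_iterations)

  # 5. confirmation ------------------------------------------------------
  cf <- config$confirmation
  eff <- lapply(stats::setNames(hit_genes, hit_genes), function(g) {
    if (g %in% truth$hit_genes) {
      c(rep(cf$effect, cf$active_sirnas),
        rep(0, max(0L, cf$sirnas_per_gene - cf$active_sirnas)))
    } else rep(0, cf$sirnas_per_gene)
  })
  conf_wells <- simulate_confirmation(hit_genes,
                                      sirnas_per_gene = cf$sirnas_per_gene,
                                      per_sirna_effect = eff,
                                      assays = cf$assays,
                                      seed = stage_seed(4L))
  conf_z <- score_confirmation(conf_wells)
  confirmed <- call_confirmed_hits(conf_z, min_sirnas = cf$min_sirnas,
                                   z_min = sc$z_min,
                                   assay_rule = cf$assay_rule)
  utils::write.table(confirmed, file.path(out_dir, "confirmation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("confirmation", "%d of %d hits confirmed (>= %d siRNAs)",
            sum(confirmed$is_hit), length(hit_genes), cf$min_sirnas)

  # 6. TMA ---------------------------------------------------------------
  tm <- config$tma
  ttruth <- tma_truth(noise_sd = tm$noise_sd,
                      crpc_low_fraction = tm$crpc_low_fraction,
                      seed = stage_seed(5L))
  tsim <- simulate_tma(cores_per_class = c(tm$cores_ppca, tm$cores_mets,
                                           tm$cores_crpc),
                       truth = ttruth)
  write_tma(tsim$scores, file.path(out_dir, "tma.csv"))
  summ <- aggregate_by_class(tsim$scores)
  utils::write.table(summ, file.path(out_dir, "class_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pw <- compare_classes(summ, "PPCa", "CRPC")
  utils::write.table(pw, file.path(out_dir, "pairwise_p.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dend <- cluster_cores(tsim$scores, "CRPC")
  write_intensity_map(dend, file.path(out_dir, "intensity_map.tsv"))
  write_dendrogram_newick(dend, file.path(out_dir, "dendrogram.nwk"))
  clusters <- cut_cores(dend, k = tm$n_clusters)
  planted <- tsim$truth$crpc_subclass_assignment[names(clusters)]
  ri <- rand_index(clusters, planted)
  log_stage("tma", "%d CRPC cores clustered, Rand index vs planted subclasses %.3f",
            length(clusters), ri)

  report <- list(
    provenance = list(config_hash = cfg_hash, seed = config$seed,
                      package_version = tryCatch(
                        as.character(utils::packageVersion("crpcnet")),
                        error = function(e) NA_character_),
                      r_version = paste(R.version$major, R.version$minor, sep = ".")),
    screen = list(n_genes = nrow(scores), n_primary_hits = length(hit_genes),
                  hit_genes = hit_genes),
    pcsf = list(n_forest_nodes = length(forest$nodes),
                n_forest_edges = nrow(forest$edges),
                components = forest$components,
                objective_total = forest$objective_total,
                hub_included = ic$hub_node %in% forest$nodes,
                hub_betweenness = if (ic$hub_node %in% forest$nodes)
                  unname(btw[ic$hub_node]) else 0,
                unmapped_hits = forest$unmapped),
    enrichment = list(criterion = en$criterion,
                      observed = enr$observed_statistic,
                      empirical_p = enr$empirical_p),
    confirmation = list(n_confirmed = sum(confirmed$is_hit),
                        confirmed_genes = confirmed$gene[confirmed$is_hit]),
    tma = list(n_crpc_cores_clustered = length(clusters),
               rand_index_vs_planted = ri)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
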