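#' Default pipeline configuration
#'
#' Flat list of run parameters with the study cut-offs as defaults:
#' `alpha = 0.001` and `lfc_cut = 0.5` (differential expression),
#' `p_cut = 0.001` and `dpsi_cut = 0.4` (differential splicing),
#' `fdr_cut = 0.05` (enrichment), `r_threshold = 0.9` (TF screen).
#'
#' @return named list of defaults (stages all enabled, simulation on).
#' @export
default_run_config <- function() {
  list(seed = 1L,
       outdir = "results/pipeline",
       simulate = TRUE,
       run_de = TRUE,
       run_enrich = TRUE,
       run_splice = TRUE,
       run_consequence = TRUE,
       run_tfscreen = TRUE,
       alpha = 0.001,
       lfc_cut = 0.5,
       p_cut = 0.001,
       dpsi_cut = 0.4,
       fdr_cut = 0.05,
       r_threshold = 0.9,
       group_a = "PC",
       group_b = "MBC",
       n_genes = 1000L,
       n_events = 200L,
       counts_path = NULL,
       metadata_path = NULL,
       junctions_path = NULL,
       events_path = NULL,
       genesets_path = NULL,
       tissue_counts_path = NULL,
       tissue_metadata_path = NULL)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, range-checks every parameter and rejects unknown keys;
#' all problems are collected and reported at once.
#'
#' @param config named list (possibly partial); may also be a path to a
#'   YAML or JSON file.
#' @return the normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  defaults <- default_run_config()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))],
                           keep.null = TRUE)
  chk_frac <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1)
      errors <<- c(errors, sprintf("%s must lie in (0,1): got %s", key,
                                   paste(v, collapse = ",")))
  }
  for (key in c("alpha", "p_cut", "fdr_cut", "r_threshold")) chk_frac(key)
  for (key in c("lfc_cut", "dpsi_cut")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      errors <- c(errors, sprintf("%s must be non-negative", key))
  }
  if (!is.null(cfg$dpsi_cut) && is.numeric(cfg$dpsi_cut) &&
      length(cfg$dpsi_cut) == 1 && !is.na(cfg$dpsi_cut) && cfg$dpsi_cut > 1)
    errors <- c(errors, "dpsi_cut cannot exceed 1")
  for (key in c("n_genes", "n_events", "seed")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      errors <- c(errors, sprintf("%s must be a non-negative number", key))
    else cfg[[key]] <- as.integer(v)
  }
  for (key in grep("^(simulate|run_)", names(defaults), value = TRUE)) {
    v <- cfg[[key]]
    if (!is.logical(v) || length(v) != 1 || is.na(v))
      errors <- c(errors, sprintf("%s must be TRUE or FALSE", key))
  }
  if (!isTRUE(cfg$simulate)) {
    needed <- c("counts_path", "metadata_path")
    miss <- needed[vapply(cfg[needed], is.null, logical(1))]
    if (length(miss))
      errors <- c(errors,
                  sprintf("simulation disabled but missing input path(s): %s",
                          paste(miss, collapse = ", ")))
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  cfg
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages (simulate, differential expression,
#' enrichment, differential splicing, consequence calling, TF screen) on
#' synthetic or provided inputs, writes per-stage TSVs and a
#' machine-readable `summary.json` under `outdir`, and logs parameters and
#' seed to `run.log`. Re-running with the same configuration reproduces the
#' summary byte for byte.
#'
#' @param config list or YAML/JSON path accepted by [validate_config()].
#' @return the run summary, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$outdir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  log_line(logf, sprintf("pipeline start (package version %s, seed %d)",
                         as.character(utils::packageVersion("bcellsplice")),
                         cfg$seed))
  log_line(logf, "parameters: ",
           sprintf("alpha=%g lfc_cut=%g p_cut=%g dpsi_cut=%g fdr_cut=%g r_threshold=%g",
                   cfg$alpha, cfg$lfc_cut, cfg$p_cut, cfg$dpsi_cut,
                   cfg$fdr_cut, cfg$r_threshold))
  summary <- list(seed = cfg$seed)

  ## inputs
  if (isTRUE(cfg$simulate)) {
    log_line(logf, "stage simulate")
    scfg <- sim_config(n_genes = cfg$n_genes, seed = cfg$seed)
    sim <- generate_counts(scfg)
    cm <- sim$counts
    truth <- sim$truth
    tissue <- generate_tissue_panel(scfg, truth)
    ev_truth <- simulate_event_truth(scfg, n_events = cfg$n_events)
    events <- ev_truth$events
    junctions <- generate_junction_counts(scfg, events, ev_truth$true_psi)
    genesets <- c(toy_gene_sets(truth), toy_tf_genesets(truth))
    write_counts_tsv(cm, file.path(cfg$outdir, "counts.tsv"),
                     file.path(cfg$outdir, "samples.tsv"))
    write_counts_tsv(tissue, file.path(cfg$outdir, "tissue_counts.tsv"),
                     file.path(cfg$outdir, "tissue_samples.tsv"))
    write_events_tsv(events, file.path(cfg$outdir, "events.tsv"))
    write_junctions_tsv(junctions, file.path(cfg$outdir, "junctions.tsv"))
    write_gene_sets_tsv(genesets, file.path(cfg$outdir, "gene_sets.tsv"))
    truth_out <- truth[c("de", "de_condition", "planted_tf",
                         "planted_targets")]
    truth_out$differential_events <- ev_truth$differential
    jsonlite::write_json(truth_out, file.path(cfg$outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    log_line(logf, "stage load inputs")
    if (is.null(cfg$counts_path) || !file.exists(cfg$counts_path))
      stop("stage load: counts input missing")
    cm <- read_counts_tsv(cfg$counts_path, cfg$metadata_path)
    tissue <- if (!is.null(cfg$tissue_counts_path))
      read_counts_tsv(cfg$tissue_counts_path, cfg$tissue_metadata_path)
    else NULL
    events <- if (!is.null(cfg$events_path)) read_events_tsv(cfg$events_path)
    else NULL
    junctions <- if (!is.null(cfg$junctions_path))
      read_junctions_tsv(cfg$junctions_path)
    else NULL
    genesets <- if (!is.null(cfg$genesets_path))
      read_gene_sets(cfg$genesets_path)
    else NULL
  }

  de <- NULL
  if (isTRUE(cfg$run_de)) {
    log_line(logf, sprintf("stage de: %s vs %s", cfg$group_b, cfg$group_a))
    de <- de_test(cm, cfg$group_a, cfg$group_b,
                  alpha = cfg$alpha, lfc_cut = cfg$lfc_cut)
    write_tsv_plain(de, file.path(cfg$outdir, "de_results.tsv"))
    summary$n_de <- sum(de$status != "ns")
    summary$n_up <- sum(de$status == "up")
    summary$n_down <- sum(de$status == "down")
    log_line(logf, sprintf("  %d differential genes (%d up, %d down)",
                           summary$n_de, summary$n_up, summary$n_down))
  }

  if (isTRUE(cfg$run_enrich)) {
    if (is.null(de) || is.null(genesets))
      stop("stage enrich: needs DE results and gene sets")
    log_line(logf, "stage enrich")
    hits <- de$gene_id[de$status != "ns"]
    enr <- go_enrichment(hits, de$gene_id, genesets, fdr_cut = cfg$fdr_cut)
    write_tsv_plain(enr, file.path(cfg$outdir, "enrichment.tsv"))
    summary$n_enriched_sets <- sum(enr$reportable)
  }

  if (isTRUE(cfg$run_splice)) {
    if (is.null(events) || is.null(junctions))
      stop("stage splice: needs events and junction counts")
    log_line(logf, "stage splice")
    psi <- psi_matrix(junctions, events)
    cond <- stats::setNames(junctions$condition, junctions$sample)
    cond <- cond[!duplicated(names(cond))]
    ds <- differential_psi(psi, cond, cfg$group_a, cfg$group_b,
                           p_cut = cfg$p_cut, dpsi_cut = cfg$dpsi_cut)
    write_tsv_plain(ds, file.path(cfg$outdir, "diff_splice.tsv"))
    bd <- event_breakdown(ds, events)
    write_tsv_plain(bd, file.path(cfg$outdir, "event_breakdown.tsv"))
    summary$n_significant_events <- sum(ds$significant)
    summary$events_by_type <- stats::setNames(as.list(bd$n), bd$etype)
    summary$frac_lower_in_focal <- direction_summary(ds, cfg$group_b)
    log_line(logf, sprintf("  %d significant events",
                           summary$n_significant_events))
  }

  if (isTRUE(cfg$run_consequence)) {
    log_line(logf, "stage consequence")
    ann <- build_toy_annotation()
    cons <- consequence_table(ann)
    write_tsv_plain(cons, file.path(cfg$outdir, "consequences.tsv"))
    summary$consequence_categories <-
      as.list(table(cons$category))
  }

  if (isTRUE(cfg$run_tfscreen)) {
    if (is.null(tissue) || is.null(genesets))
      stop("stage tfscreen: needs a tissue panel and gene sets")
    log_line(logf, "stage tfscreen")
    scr_cfg <- screen_config(r_threshold = cfg$r_threshold)
    scr <- run_tf_screen(cm, tissue, genesets, scr_cfg)
    write_tsv_plain(scr$discovery$records,
                    file.path(cfg$outdir, "tf_correlations.tsv"))
    write_tsv_plain(scr$validated, file.path(cfg$outdir, "tf_ranking.tsv"))
    summary$n_any_pass <- length(scr$discovery$any_pass)
    summary$n_all_pass <- length(scr$discovery$all_pass)
    summary$top_tf <- scr$top_tf
    log_line(logf, sprintf("  %d TFs pass for >=1 target, %d for all; top hit %s",
                           summary$n_any_pass, summary$n_all_pass,
                           summary$top_tf))
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(logf, "pipeline done")
  invisible(summary)
}
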