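#' Simulation configuration
#'
#' Defines the synthetic study design: a 4-condition x 3-replicate B-cell
#' differentiation panel (prePB, PB, PC, MBC) with negative-binomial gene
#' counts, a planted set of differentially expressed genes, a planted
#' TF -> target co-regulation structure, a 17-sample tissue panel for
#' cross-tissue validation, and Poisson/binomial junction counts for splice
#' events at configurable true PSI.
#'
#' Defaults not fixed by the emulated design (dispersion, library sizes,
#' latent-activity scale) are simulation choices; see the methods vignette.
#'
#' @param conditions condition labels; the differential-expression effect is
#'   planted in the *last* condition versus the rest (MBC by default).
#' @param replicates_per_condition replicates per condition (>= 2 when a
#'   differential test will be run).
#' @param n_genes number of genes.
#' @param nb_dispersion common negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts. The default (2e-4) is
#'   deliberately near the technical/Poisson limit: a Welch t-test at
#'   triplicate scale only has power for the planted effect when replicate
#'   noise is this low (see the power analysis in the methods vignette);
#'   real biological replicates are far more dispersed.
#' @param library_size_range pair of positive numbers; per-sample library
#'   sizes are drawn uniformly in this range.
#' @param de_fraction fraction of genes with a planted expression effect.
#' @param de_log2fc absolute planted log2 fold change (sign randomized).
#' @param n_decoy_tfs number of decoy transcription factors (independent of
#'   the targets).
#' @param n_targets number of planted TF targets.
#' @param coregulation_noise_sd log2-scale noise around the shared latent
#'   activity of the planted TF and its targets.
#' @param tf_activity_sd log2-scale standard deviation of the shared latent
#'   activity across samples.
#' @param tissue_panel_size number of samples in the validation tissue panel.
#' @param junction_depth expected junction reads per event and sample.
#' @param seed integer master seed; per-stage substreams are derived from it
#'   by fixed offsets so each stage is reproducible in isolation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(conditions = c("prePB", "PB", "PC", "MBC"),
                       replicates_per_condition = 3L,
                       n_genes = 1000L,
                       nb_dispersion = 2e-4,
                       library_size_range = c(1e7, 2e7),
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       n_decoy_tfs = 200L,
                       n_targets = 3L,
                       coregulation_noise_sd = 0.1,
                       tf_activity_sd = 1,
                       tissue_panel_size = 17L,
                       junction_depth = 1000L,
                       seed = 1L) {
  cfg <- list(conditions = as.character(conditions),
              replicates_per_condition = as.integer(replicates_per_condition),
              n_genes = as.integer(n_genes),
              nb_dispersion = nb_dispersion,
              library_size_range = as.numeric(library_size_range),
              de_fraction = de_fraction,
              de_log2fc = de_log2fc,
              n_decoy_tfs = as.integer(n_decoy_tfs),
              n_targets = as.integer(n_targets),
              coregulation_noise_sd = coregulation_noise_sd,
              tf_activity_sd = tf_activity_sd,
              tissue_panel_size = as.integer(tissue_panel_size),
              junction_depth = as.integer(junction_depth),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$conditions) < 1) stop("sizing error: need >= 1 condition")
  if (cfg$replicates_per_condition < 1)
    stop("sizing error: replicates_per_condition must be positive")
  if (cfg$n_genes < 0) stop("sizing error: n_genes must be non-negative")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  if (length(cfg$library_size_range) != 2 ||
      any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    stop("library_size_range must be an increasing pair of positives")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must lie in [0,1]")
  if (cfg$de_log2fc < 0) stop("de_log2fc must be non-negative")
  if (cfg$n_decoy_tfs < 0 || cfg$n_targets < 0)
    stop("sizing error: negative TF network sizes")
  if (cfg$coregulation_noise_sd < 0)
    stop("coregulation_noise_sd must be non-negative")
  if (cfg$tissue_panel_size < 0)
    stop("sizing error: tissue_panel_size must be non-negative")
  if (cfg$junction_depth < 1)
    stop("sizing error: junction_depth must be positive")
  invisible(cfg)
}

# Named ids for the planted regulator and its targets: stand-ins for the
# NERF/ELF2 -> SEC24B/CUL3/CSNK1D structure the panel emulates.
planted_gene_ids <- function(cfg) {
  target_names <- c("SEC24B", "CUL3", "CSNK1D")
  if (cfg$n_targets > 3)
    target_names <- c(target_names,
                      sprintf("TGT%02d", seq_len(cfg$n_targets - 3)))
  list(tf = "ELF2",
       targets = target_names[seq_len(cfg$n_targets)],
       decoys = if (cfg$n_decoy_tfs > 0)
         sprintf("TF%03d", seq_len(cfg$n_decoy_tfs)) else character(0))
}

#' Generate the B-cell differentiation count panel
#'
#' Negative-binomial counts per gene x sample. Gene baseline abundances are
#' log-normal and scaled so each sample's expected column sum equals its
#' drawn library size. A planted fraction of genes carries a signed log2
#' fold change in the last condition (MBC by default) versus the rest. The
#' planted TF and its targets additionally share a per-sample log-normal
#' latent activity (plus independent noise), giving a tunable Pearson
#' correlation on the log scale.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth`, the planted
#'   ground truth: `de` (tibble of gene_id, log2fc signed, MBC-vs-rest),
#'   `de_condition`, `planted_tf`, `planted_targets`, `decoy_tfs`, and the
#'   reusable `gene_ids` / `base_weight` for the tissue panel.
#' @export
generate_counts <- function(config) {
  cfg <- validate_sim_config(config)
  n_samples <- length(cfg$conditions) * cfg$replicates_per_condition
  condition <- rep(cfg$conditions, each = cfg$replicates_per_condition)
  sample_ids <- paste(condition,
                      rep(seq_len(cfg$replicates_per_condition),
                          times = length(cfg$conditions)), sep = "_")
  names(condition) <- sample_ids

  if (cfg$n_genes == 0) {
    counts <- matrix(integer(0), nrow = 0, ncol = n_samples,
                     dimnames = list(character(0), sample_ids))
    truth <- list(de = tibble::tibble(gene_id = character(0),
                                      log2fc = numeric(0)),
                  de_condition = cfg$conditions[length(cfg$conditions)],
                  planted_tf = character(0),
                  planted_targets = character(0),
                  decoy_tfs = character(0),
                  gene_ids = character(0), base_weight = numeric(0))
    return(list(counts = count_matrix(counts, condition), truth = truth))
  }

  ids <- planted_gene_ids(cfg)
  n_special <- 1L + cfg$n_targets + cfg$n_decoy_tfs
  if (cfg$n_genes < n_special + 1L)
    stop("sizing error: n_genes too small for the planted TF network")
  gene_ids <- c(ids$tf, ids$targets, ids$decoys,
                sprintf("g%05d", seq_len(cfg$n_genes - n_special)))

  withr::with_seed(cfg$seed + 101L, {
    w <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 0.5)
    w <- w / sum(w)
    names(w) <- gene_ids

    lib <- stats::runif(n_samples, cfg$library_size_range[1],
                        cfg$library_size_range[2])

    de_condition <- cfg$conditions[length(cfg$conditions)]
    n_de <- round(cfg$de_fraction * cfg$n_genes)
    plain <- setdiff(gene_ids, c(ids$tf, ids$targets))
    n_de <- min(n_de, length(plain))
    de_genes <- sample(plain, n_de)
    de_sign <- sample(c(-1, 1), n_de, replace = TRUE)

    mu <- outer(w, lib)
    if (n_de > 0) {
      in_de_cond <- condition == de_condition
      mu[de_genes, in_de_cond] <-
        mu[de_genes, in_de_cond] * 2^(de_sign * cfg$de_log2fc)
    }

    coreg <- c(ids$tf, ids$targets)
    activity <- stats::rnorm(n_samples, 0, cfg$tf_activity_sd)
    eps <- matrix(stats::rnorm(length(coreg) * n_samples, 0,
                               cfg$coregulation_noise_sd),
                  nrow = length(coreg))
    mu[coreg, ] <- mu[coreg, , drop = FALSE] *
      2^(rep(activity, each = length(coreg)) + eps)

    counts <- draw_nb(mu, cfg$nb_dispersion)
  })
  dimnames(counts) <- list(gene_ids, sample_ids)

  truth <- list(de = tibble::tibble(gene_id = de_genes,
                                    log2fc = de_sign * cfg$de_log2fc),
                de_condition = de_condition,
                planted_tf = ids$tf,
                planted_targets = ids$targets,
                decoy_tfs = ids$decoys,
                gene_ids = gene_ids,
                base_weight = w)
  list(counts = count_matrix(counts, condition), truth = truth)
}

draw_nb <- function(mu, dispersion) {
  n <- length(mu)
  x <- if (dispersion > 0)
    stats::rnbinom(n, mu = as.vector(mu), size = 1 / dispersion)
  else
    stats::rpois(n, as.vector(mu))
  matrix(x, nrow = nrow(mu))
}

#' Generate the multi-tissue validation panel
#'
#' One count matrix with `tissue_panel_size` samples (one per tissue). The
#' planted TF and its targets co-vary across tissues through a shared latent
#' activity; every other gene (including the decoy TFs) receives independent
#' tissue-to-tissue variation.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [generate_counts()].
#' @param tissue_noise_sd log2-scale independent tissue variation applied to
#'   non-coregulated genes.
#' @return a [count_matrix()] whose condition labels are the tissue names.
#' @export
generate_tissue_panel <- function(config, truth, tissue_noise_sd = 0.5) {
  cfg <- validate_sim_config(config)
  if (length(truth$planted_tf) == 0 && cfg$n_genes > 0)
    stop("truth must contain a planted TF (run generate_counts first)")
  n_genes <- length(truth$gene_ids)
  tissues <- sprintf("tissue%02d", seq_len(cfg$tissue_panel_size))

  withr::with_seed(cfg$seed + 303L, {
    lib <- stats::runif(cfg$tissue_panel_size, cfg$library_size_range[1],
                        cfg$library_size_range[2])
    mu <- outer(truth$base_weight, lib)
    offset <- matrix(stats::rnorm(n_genes * cfg$tissue_panel_size, 0,
                                  tissue_noise_sd),
                     nrow = n_genes, dimnames = list(truth$gene_ids, NULL))
    coreg <- c(truth$planted_tf, truth$planted_targets)
    activity <- stats::rnorm(cfg$tissue_panel_size, 0, cfg$tf_activity_sd)
    offset[coreg, ] <- rep(activity, each = length(coreg)) +
      stats::rnorm(length(coreg) * cfg$tissue_panel_size, 0,
                   cfg$coregulation_noise_sd)
    mu <- mu * 2^offset
    counts <- draw_nb(mu, cfg$nb_dispersion)
  })
  dimnames(counts) <- list(truth$gene_ids, tissues)
  condition <- stats::setNames(tissues, tissues)
  count_matrix(counts, condition)
}

#' Splice event definition
#'
#' One alternative-splicing event: an exon-skipping cassette (SE), retained
#' intron (RI), or alternative 5'/3' splice-site segment (A5SS/A3SS). The
#' `segment` is the differential region in 0-based half-open genomic
#' coordinates: the cassette exon, the retained intron, or the alternative
#' extension. Effective junction counts follow the junction-support model:
#' the SE inclusion form is supported by 2 junctions and the skipping form
#' by 1; all other types have one junction (or boundary) per form.
#'
#' @param event_id,gene_id identifiers.
#' @param etype one of "SE", "RI", "A5SS", "A3SS".
#' @param segment integer pair (start, end), 0-based half-open.
#' @param chrom,strand location (plus strand by default).
#' @return one-row tibble with len_inc / len_skip filled per event type.
#' @export
splice_event <- function(event_id, gene_id, etype,
                         segment = c(0L, 1L), chrom = gene_id,
                         strand = "+") {
  etype <- match.arg(etype, c("SE", "RI", "A5SS", "A3SS"))
  if (length(segment) != 2 || segment[2] <= segment[1])
    stop("segment must be a (start, end) pair with end > start")
  tibble::tibble(event_id = event_id, gene_id = gene_id, etype = etype,
                 chrom = chrom, strand = strand,
                 seg_start = as.integer(segment[1]),
                 seg_end = as.integer(segment[2]),
                 len_inc = if (etype == "SE") 2L else 1L,
                 len_skip = 1L)
}

#' Generate junction counts at configured true PSI
#'
#' For each event x sample the total junction reads are
#' Poisson(`junction_depth`); inclusion reads are binomial with success
#' probability chosen so that the length-normalized PSI estimator applied to
#' the *expected* counts returns the true PSI exactly:
#' `q = psi * len_inc / (psi * len_inc + (1 - psi) * len_skip)`.
#'
#' @param config a [sim_config()].
#' @param events tibble of events as returned by [splice_event()] (rows may
#'   be concatenated).
#' @param true_psi numeric matrix events x conditions of true PSI in
#'   `[0, 1]` (rownames = event ids, colnames = condition labels).
#' @return tibble (event_id, sample, condition, inc_reads, skip_reads).
#' @export
generate_junction_counts <- function(config, events, true_psi) {
  cfg <- validate_sim_config(config)
  if (any(is.na(true_psi)) || any(true_psi < 0) || any(true_psi > 1))
    stop("true PSI values must lie in [0,1]")
  true_psi <- as.matrix(true_psi)
  if (is.null(rownames(true_psi))) rownames(true_psi) <- events$event_id
  if (is.null(colnames(true_psi))) colnames(true_psi) <- cfg$conditions
  if (!all(events$event_id %in% rownames(true_psi)))
    stop("every event needs a true PSI row")

  condition <- rep(cfg$conditions, each = cfg$replicates_per_condition)
  sample_ids <- paste(condition,
                      rep(seq_len(cfg$replicates_per_condition),
                          times = length(cfg$conditions)), sep = "_")
  n_ev <- nrow(events)
  n_s <- length(sample_ids)

  withr::with_seed(cfg$seed + 202L, {
    psi <- true_psi[events$event_id, , drop = FALSE][, condition, drop = FALSE]
    q <- psi * events$len_inc /
      (psi * events$len_inc + (1 - psi) * events$len_skip)
    total <- matrix(stats::rpois(n_ev * n_s, cfg$junction_depth),
                    nrow = n_ev)
    inc <- matrix(stats::rbinom(n_ev * n_s, as.vector(total), as.vector(q)),
                  nrow = n_ev)
  })
  tibble::tibble(event_id = rep(events$event_id, times = n_s),
                 sample = rep(sample_ids, each = n_ev),
                 condition = rep(condition, each = n_ev),
                 inc_reads = as.integer(inc),
                 skip_reads = as.integer(total - inc))
}

#' Random splice-event panel with planted differential events
#'
#' Draws a panel of events over the four types (weighted towards exon
#' skipping, as in bulk AS surveys) and a true-PSI matrix in which a
#' fraction of events changes by at least `dpsi` in the last condition.
#'
#' @param config a [sim_config()].
#' @param n_events number of events.
#' @param diff_fraction fraction of events with a planted PSI change.
#' @param dpsi planted PSI difference (last condition vs the rest).
#' @return list with `events`, `true_psi`, and `differential` (event ids).
#' @export
simulate_event_truth <- function(config, n_events = 200L,
                                 diff_fraction = 0.1, dpsi = 0.5) {
  cfg <- validate_sim_config(config)
  withr::with_seed(cfg$seed + 404L, {
    etypes <- sample(c("SE", "RI", "A5SS", "A3SS"), n_events, replace = TRUE,
                     prob = c(0.8, 0.02, 0.08, 0.1))
    events <- do.call(rbind, lapply(seq_len(n_events), function(i) {
      splice_event(sprintf("ev%04d", i), sprintf("g%05d", i), etypes[i],
                   segment = c(100L, 200L))
    }))
    base <- stats::runif(n_events, 0.05, 0.95)
    true_psi <- matrix(base, nrow = n_events,
                       ncol = length(cfg$conditions),
                       dimnames = list(events$event_id, cfg$conditions))
    n_diff <- round(diff_fraction * n_events)
    diff_ev <- sample(events$event_id, n_diff)
    last <- cfg$conditions[length(cfg$conditions)]
    shifted <- true_psi[diff_ev, last] + dpsi
    # reflect into [0,1] by flipping direction where the shift overflows
    over <- shifted > 1
    shifted[over] <- true_psi[diff_ev, last][over] - dpsi
    true_psi[diff_ev, last] <- pmin(pmax(shifted, 0), 1)
  })
  list(events = events, true_psi = true_psi, differential = diff_ev)
}

#' Toy transcription-factor gene sets
#'
#' Builds the two GO-style candidate sets used by the screen
#' ("GO:0008134" and "GO:0000981") from the planted TF and decoys, with an
#' overlapping split so the union/deduplication path is exercised.
#'
#' @param truth the `truth` element from [generate_counts()].
#' @return named list of character vectors.
#' @export
toy_tf_genesets <- function(truth) {
  tfs <- c(truth$planted_tf, truth$decoy_tfs)
  n <- length(tfs)
  half <- ceiling(n * 0.6)
  list("GO:0008134" = tfs[seq_len(half)],
       "GO:0000981" = tfs[seq(max(1, n - half + 1), n)])
}

#' Toy functional gene sets with one planted enriched set
#'
#' Returns gene sets over the simulated universe: one "secretory-pathway"
#' style set seeded with planted DE genes (so enrichment of the DE list is
#' expected) plus random background sets.
#'
#' @param truth the `truth` element from [generate_counts()].
#' @param n_sets total number of sets.
#' @param set_size genes per set.
#' @param planted_fraction fraction of the planted set drawn from true DE
#'   genes.
#' @param seed integer seed.
#' @return named list of character vectors; the planted set is named
#'   "planted_secretory".
#' @export
toy_gene_sets <- function(truth, n_sets = 10L, set_size = 50L,
                          planted_fraction = 0.6, seed = 7L) {
  universe <- truth$gene_ids
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets - 1L), function(i)
      sample(universe, min(set_size, length(universe))))
    names(sets) <- sprintf("random_set_%02d", seq_len(n_sets - 1L))
    n_planted <- min(round(planted_fraction * set_size), nrow(truth$de))
    planted <- c(sample(truth$de$gene_id, n_planted),
                 sample(setdiff(universe, truth$de$gene_id),
                        set_size - n_planted))
    c(list(planted_secretory = planted), sets)
  })
}
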