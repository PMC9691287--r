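#' Screen configuration
#'
#' Parameters of the two-stage TF-target co-expression screen: candidate TFs
#' are drawn from two GO-style gene sets, correlations against the target
#' genes must exceed `r_threshold` (strictly) to pass, and the
#' discovery-stage intersection is validated on a multi-tissue panel.
#'
#' @param r_threshold pass threshold on the Pearson correlation coefficient
#'   (default 0.9, strict inequality).
#' @param candidate_set_ids gene-set ids naming the TF candidate universe.
#' @param targets target gene ids (default the three COPII genes
#'   upregulated in MBC: SEC24B, CUL3, CSNK1D).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(r_threshold = 0.9,
                          candidate_set_ids = c("GO:0008134", "GO:0000981"),
                          targets = c("SEC24B", "CUL3", "CSNK1D")) {
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("r_threshold must lie in (0,1)")
  if (length(targets) < 1) stop("need at least one target gene")
  structure(list(r_threshold = r_threshold,
                 candidate_set_ids = candidate_set_ids,
                 targets = targets),
            class = "screen_config")
}

#' Pearson correlation with a t-transform p-value
#'
#' Sample Pearson r with the two-sided p-value from
#' `t = r * sqrt((n-2) / (1-r^2))` on n-2 degrees of freedom; |r| = 1 gives
#' p = 0.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors with n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined-correlation error: zero-variance vector")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Candidate TF list from gene sets
#'
#' Union of the configured candidate sets, restricted to expressed genes,
#' with the target genes excluded (self-correlation guard).
#'
#' @param genesets named list of character vectors.
#' @param expressed character vector of expressed gene ids.
#' @param config a [screen_config()].
#' @return character vector of candidate TF ids.
#' @export
candidate_tfs <- function(genesets, expressed, config = screen_config()) {
  missing <- setdiff(config$candidate_set_ids, names(genesets))
  if (length(missing))
    stop(sprintf("lookup error: missing gene set(s): %s",
                 paste(missing, collapse = ", ")))
  cands <- unique(unlist(genesets[config$candidate_set_ids],
                         use.names = FALSE))
  setdiff(intersect(cands, expressed), config$targets)
}

#' Discovery-stage correlation screen
#'
#' Computes the Pearson correlation (with t-transform p) between every
#' candidate TF and every target gene on log2(normalized + 1) expression
#' across all samples of the discovery panel. A TF passes for a target iff
#' `r > r_threshold`; the any-pass and all-pass (intersection) sets and the
#' per-target Venn counts are returned.
#'
#' @param panel a [count_matrix()] (the B-cell discovery panel).
#' @param candidates character vector of candidate TF ids.
#' @param config a [screen_config()].
#' @return list with `records` (tibble tf, target, r, p, n, pass),
#'   `pass_sets` (per-target character vectors), `any_pass`, `all_pass`,
#'   and `venn` (tibble of counts).
#' @export
discovery_screen <- function(panel, candidates, config = screen_config()) {
  missing_t <- setdiff(config$targets, rownames(panel$counts))
  if (length(missing_t))
    stop(sprintf("lookup error: target(s) absent from panel: %s",
                 paste(missing_t, collapse = ", ")))
  candidates <- intersect(candidates, rownames(panel$counts))
  if (length(candidates) == 0) {
    records <- tibble::tibble(tf = character(0), target = character(0),
                              r = numeric(0), p = numeric(0),
                              n = integer(0), pass = logical(0))
    return(list(records = records,
                pass_sets = stats::setNames(
                  rep(list(character(0)), length(config$targets)),
                  config$targets),
                any_pass = character(0), all_pass = character(0),
                venn = tibble::tibble(target = config$targets, n_pass = 0L)))
  }
  x <- log_expr(panel)
  n <- ncol(x)
  tx <- t(x[candidates, , drop = FALSE])
  records <- do.call(rbind, lapply(config$targets, function(tg) {
    r <- suppressWarnings(as.vector(stats::cor(tx, x[tg, ])))
    r[is.na(r)] <- 0  # zero-variance candidate: no co-expression signal
    rr <- pmin(pmax(r, -1), 1)
    p <- ifelse(abs(rr) >= 1, 0,
                2 * stats::pt(-abs(rr * sqrt((n - 2) / (1 - rr^2))), n - 2))
    tibble::tibble(tf = candidates, target = tg, r = r, p = p, n = n,
                   pass = r > config$r_threshold)
  }))
  pass_sets <- lapply(config$targets, function(tg)
    records$tf[records$target == tg & records$pass])
  names(pass_sets) <- config$targets
  any_pass <- sort(unique(unlist(pass_sets, use.names = FALSE)))
  all_pass <- sort(Reduce(intersect, pass_sets))
  venn <- tibble::tibble(target = config$targets,
                         n_pass = vapply(pass_sets, length, integer(1)))
  list(records = records, pass_sets = pass_sets,
       any_pass = any_pass, all_pass = all_pass, venn = venn)
}

#' Validate screened TFs on the tissue panel
#'
#' For each TF, one Pearson correlation per target across the tissue panel
#' samples (one sample per tissue), then the arithmetic mean of the r values
#' and of the p values over targets. A BH-adjusted mean-p column is emitted
#' alongside the descriptive p values.
#'
#' @param tissue_panel a [count_matrix()] (tissue validation panel).
#' @param tfs character vector of TFs to validate (the discovery
#'   intersection).
#' @param config a [screen_config()].
#' @return tibble (tf, mean_r, mean_p, mean_p_adj).
#' @export
validate_in_tissues <- function(tissue_panel, tfs, config = screen_config()) {
  if (length(tfs) == 0)
    return(tibble::tibble(tf = character(0), mean_r = numeric(0),
                          mean_p = numeric(0), mean_p_adj = numeric(0)))
  res <- discovery_screen(tissue_panel, tfs, config)
  rec <- res$records
  rec$p_adj <- bh_adjust(rec$p)
  agg <- lapply(split(rec, rec$tf), function(d)
    tibble::tibble(tf = d$tf[1], mean_r = mean(d$r), mean_p = mean(d$p),
                   mean_p_adj = mean(d$p_adj)))
  out <- do.call(rbind, agg)
  out[match(intersect(tfs, out$tf), out$tf), ]
}

#' Rank validated TFs
#'
#' Orders TFs by mean validation correlation (descending), breaking ties by
#' mean p (ascending) then lexicographic id; rank 1 is the reported top hit.
#'
#' @param validated tibble from [validate_in_tissues()].
#' @return the same tibble with a `rank` column, sorted by rank.
#' @export
rank_tfs <- function(validated) {
  if (nrow(validated) == 0) {
    validated$rank <- integer(0)
    return(validated)
  }
  o <- order(-validated$mean_r, validated$mean_p, validated$tf)
  out <- validated[o, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Run the full two-stage TF screen
#'
#' Candidate selection, discovery screen on the B-cell panel, tissue-panel
#' validation of the all-pass intersection, and ranking.
#'
#' @param panel discovery [count_matrix()].
#' @param tissue_panel validation [count_matrix()].
#' @param genesets named list of candidate gene sets.
#' @param config a [screen_config()].
#' @return list with `candidates`, `discovery` (see [discovery_screen()]),
#'   `validated` (ranked tibble), and `top_tf`.
#' @export
run_tf_screen <- function(panel, tissue_panel, genesets,
                          config = screen_config()) {
  cands <- candidate_tfs(genesets, rownames(panel$counts), config)
  disc <- discovery_screen(panel, cands, config)
  val <- rank_tfs(validate_in_tissues(tissue_panel, disc$all_pass, config))
  list(candidates = cands, discovery = disc, validated = val,
       top_tf = if (nrow(val)) val$tf[val$rank == 1] else NA_character_)
}
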