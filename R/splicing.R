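#' Length-normalized percent spliced in (PSI)
#'
#' PSI from junction read counts with effective-length normalization:
#' `PSI = (inc/len_inc) / (inc/len_inc + skip/len_skip)`. For exon-skipping
#' events the inclusion form is supported by two junctions (len_inc = 2)
#' and the skipping form by one (len_skip = 1); the other event types use
#' 1/1. When both counts are zero the event has no coverage and PSI is
#' missing (NA). Vectorized over counts.
#'
#' @param inc_reads,skip_reads non-negative junction read counts.
#' @param len_inc,len_skip positive effective junction counts per form.
#' @return numeric PSI in `[0, 1]`, NA where coverage is zero.
#' @export
compute_psi <- function(inc_reads, skip_reads, len_inc = 1, len_skip = 1) {
  if (any(inc_reads < 0, na.rm = TRUE) || any(skip_reads < 0, na.rm = TRUE))
    stop("junction read counts must be non-negative")
  if (any(len_inc <= 0) || any(len_skip <= 0))
    stop("effective lengths must be positive")
  inc_n <- inc_reads / len_inc
  skip_n <- skip_reads / len_skip
  psi <- inc_n / (inc_n + skip_n)
  psi[inc_reads + skip_reads == 0] <- NA_real_
  psi
}

#' PSI matrix from a junction count table
#'
#' @param junctions long tibble (event_id, sample, inc_reads, skip_reads) as
#'   written by [generate_junction_counts()] or read from a junction TSV.
#' @param events event tibble carrying len_inc / len_skip per event_id.
#' @return numeric matrix events x samples of PSI (NA = no coverage).
#' @export
psi_matrix <- function(junctions, events) {
  ev_ids <- unique(junctions$event_id)
  samples <- unique(junctions$sample)
  if (!all(ev_ids %in% events$event_id))
    stop("junction table references unknown events")
  li <- stats::setNames(events$len_inc, events$event_id)[ev_ids]
  ls <- stats::setNames(events$len_skip, events$event_id)[ev_ids]
  i <- match(junctions$event_id, ev_ids)
  j <- match(junctions$sample, samples)
  psi <- matrix(NA_real_, length(ev_ids), length(samples),
                dimnames = list(ev_ids, samples))
  psi[cbind(i, j)] <- compute_psi(junctions$inc_reads, junctions$skip_reads,
                                  li[i], ls[i])
  psi
}

#' Differential splicing between two groups
#'
#' Welch's t-test on replicate PSI values per event, with
#' `dpsi = mean(PSI in group_b) - mean(PSI in group_a)`. An event is
#' significant iff `pvalue < p_cut` and `|dpsi| > dpsi_cut` (defaults
#' 0.001 and 0.4). Events with fewer than two covered replicates in either
#' group are reported as untested (absence of evidence, not p = 1). Missing
#' PSI values propagate: group means use available replicates only. When
#' both groups have zero variance the test degenerates: p = 1 if the means
#' agree, p = 0 if the groups are perfectly separated (e.g. PSI exactly 1 in
#' every replicate of one group).
#'
#' @param psi PSI matrix from [psi_matrix()].
#' @param condition_of named vector mapping sample id -> condition.
#' @param group_a,group_b condition labels (dpsi is B minus A).
#' @param p_cut,dpsi_cut significance cut-offs.
#' @return tibble (event_id, n_a, n_b, psi_a, psi_b, dpsi, pvalue, tested,
#'   significant) with attributes `group_a` / `group_b`.
#' @export
differential_psi <- function(psi, condition_of, group_a, group_b,
                             p_cut = 0.001, dpsi_cut = 0.4) {
  for (g in c(group_a, group_b))
    if (!g %in% condition_of) stop(sprintf("unknown condition label: %s", g))
  a_cols <- intersect(colnames(psi), names(condition_of)[condition_of == group_a])
  b_cols <- intersect(colnames(psi), names(condition_of)[condition_of == group_b])
  xa <- psi[, a_cols, drop = FALSE]
  xb <- psi[, b_cols, drop = FALSE]

  n_a <- rowSums(!is.na(xa))
  n_b <- rowSums(!is.na(xb))
  m_a <- rowMeans(xa, na.rm = TRUE)
  m_b <- rowMeans(xb, na.rm = TRUE)
  v_a <- apply(xa, 1, stats::var, na.rm = TRUE)
  v_b <- apply(xb, 1, stats::var, na.rm = TRUE)
  tested <- n_a >= 2 & n_b >= 2

  dpsi <- m_b - m_a
  se2 <- v_a / n_a + v_b / n_b
  pvalue <- rep(NA_real_, nrow(psi))
  ok <- tested & !is.na(se2) & se2 > 0
  tstat <- (m_b[ok] - m_a[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v_a[ok] / n_a[ok])^2 / (n_a[ok] - 1) +
                       (v_b[ok] / n_b[ok])^2 / (n_b[ok] - 1))
  pvalue[ok] <- 2 * stats::pt(-abs(tstat), df)
  degen <- tested & !is.na(se2) & se2 == 0
  pvalue[degen] <- ifelse(dpsi[degen] == 0, 1, 0)

  significant <- tested & !is.na(pvalue) &
    pvalue < p_cut & abs(dpsi) > dpsi_cut
  out <- tibble::tibble(event_id = rownames(psi),
                        n_a = unname(n_a), n_b = unname(n_b),
                        psi_a = unname(ifelse(n_a > 0, m_a, NA_real_)),
                        psi_b = unname(ifelse(n_b > 0, m_b, NA_real_)),
                        dpsi = unname(ifelse(tested, dpsi, NA_real_)),
                        pvalue = unname(pvalue),
                        tested = unname(tested),
                        significant = unname(significant))
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  out
}

#' Event-type breakdown of significant events
#'
#' Counts and percentages of significant events per category (SE, RI, A5SS,
#' A3SS); percentages are over the total number of significant events.
#'
#' @param results tibble from [differential_psi()].
#' @param events event tibble with event_id and etype.
#' @return tibble (etype, n, pct); counts sum to the number of significant
#'   events.
#' @export
event_breakdown <- function(results, events) {
  etypes <- c("SE", "RI", "A5SS", "A3SS")
  sig <- results$event_id[results$significant]
  et <- stats::setNames(events$etype, events$event_id)[sig]
  n <- unname(vapply(etypes, function(t) sum(et == t), integer(1)))
  tibble::tibble(etype = etypes, n = n,
                 pct = if (sum(n) > 0) 100 * n / sum(n) else rep(0, 4))
}

#' Fraction of significant events with lower inclusion in a focal group
#'
#' Mirrors the "3/4 of significant events are less included in MBC" style
#' summary: among significant events, the fraction whose mean PSI is lower
#' in the focal condition than in the other tested condition.
#'
#' @param results tibble from [differential_psi()] (carries the group
#'   orientation as attributes).
#' @param focal_group one of the two tested condition labels.
#' @return fraction in `[0, 1]`, or NA when no event is significant.
#' @export
direction_summary <- function(results, focal_group) {
  ga <- attr(results, "group_a")
  gb <- attr(results, "group_b")
  if (!focal_group %in% c(ga, gb))
    stop("focal_group must be one of the tested conditions")
  d <- results$dpsi[results$significant]
  if (length(d) == 0) return(NA_real_)
  delta_focal <- if (focal_group == gb) d else -d
  mean(delta_focal < 0)
}

#' Isoform fractions from two independent junction choices
#'
#' For a transcript with two alternative starts and one alternative 3'SS
#' (the NERF/ELF2 pattern: isoforms 1a/1b/2a/2b), estimates the four isoform
#' fractions under independence of the two choices:
#' `fraction(isoform) = P(start choice) * P(3'SS choice)`.
#'
#' @param start_inc reads supporting the short-N-terminus start (exon 5).
#' @param start_alt reads supporting the long-N-terminus start (exon 1).
#' @param ss3_proximal,ss3_distal reads supporting the two 3'SS choices.
#' @param labels names for the four fractions, in the order
#'   (short x proximal, short x distal, long x proximal, long x distal).
#' @return named numeric vector of four fractions summing to 1.
#' @export
isoform_fractions_from_junctions <- function(start_inc, start_alt,
                                             ss3_proximal, ss3_distal,
                                             labels = c("NERF-1a", "NERF-1b",
                                                        "NERF-2a", "NERF-2b")) {
  if (any(c(start_inc, start_alt, ss3_proximal, ss3_distal) < 0))
    stop("junction read counts must be non-negative")
  if (start_inc + start_alt == 0 || ss3_proximal + ss3_distal == 0)
    stop("estimation error: zero total reads in a junction pair")
  p_short <- start_inc / (start_inc + start_alt)
  p_prox <- ss3_proximal / (ss3_proximal + ss3_distal)
  stats::setNames(c(p_short * p_prox, p_short * (1 - p_prox),
                    (1 - p_short) * p_prox, (1 - p_short) * (1 - p_prox)),
                  labels)
}
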