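STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Frame status of a length change
#'
#' A splice event preserves the reading frame iff the induced length change
#' is a multiple of 3 (e.g. skipping a 99-nt exon is frame-preserving,
#' skipping a 116-, 187- or 296-nt exon shifts the frame).
#'
#' @param delta_length signed length change in nucleotides.
#' @return TRUE if frame-preserving.
#' @export
frame_status <- function(delta_length) {
  delta_length %% 3 == 0
}

# First in-frame stop codon at or after `start` (0-based), NA if none.
find_stop <- function(seq, start) {
  n <- nchar(seq)
  if (start + 3 > n) return(NA_integer_)
  starts <- seq.int(start, n - 3, by = 3)
  codons <- substring(seq, starts + 1, starts + 3)
  hit <- which(codons %in% STOP_CODONS)
  if (!length(hit)) NA_integer_ else as.integer(starts[hit[1]])
}

# First variant transcript coordinate at which the variant's exonic
# positions diverge from the reference's (0-based).
divergence_point <- function(g_ref, g_var) {
  m <- min(length(g_ref), length(g_var))
  if (m == 0) return(0L)
  diff <- which(g_ref[seq_len(m)] != g_var[seq_len(m)])
  if (length(diff)) diff[1] - 1L else m
}

#' Scan an isoform variant for its ORF and first stop codon
#'
#' Translation starts at the annotated start codon mapped into the variant.
#' If the mapped start is intact, codons are walked until the first stop
#' (TAA/TAG/TGA, standard nuclear code). If the start is destroyed, or no
#' stop is reached before the transcript end (as happens when an insertion
#' shifts the frame past all annotated stops), the scanner falls back to the
#' first AUG downstream of the event's disruption point whose open frame
#' runs for at least `min_alt_codons` codons before a stop; such calls are
#' flagged `alt_start` (low confidence).
#'
#' @param variant an `isoform_variant` from [apply_event()] or
#'   [reference_variant()].
#' @param min_alt_codons minimum ORF length (codons) for an alternative
#'   start to be accepted.
#' @return list with `start_pos`, `stop_pos` (0-based variant coordinates of
#'   the start codon and of the first base of the stop codon; `stop_pos` is
#'   NA when no ORF is found), `alt_start` flag and `status` ("ok" or
#'   "no-ORF").
#' @export
scan_orf <- function(variant, min_alt_codons = 30L) {
  stopifnot(inherits(variant, "isoform_variant"))
  tx <- variant$base
  g_ref <- genomic_positions(tx$exons, tx$strand)
  g_var <- genomic_positions(variant$exons, tx$strand)
  seq <- variant$seq

  start_g <- g_ref[tx$cds_start + 1L]
  s <- match(start_g, g_var) - 1L
  if (!is.na(s) && substr(seq, s + 1L, s + 3L) == "ATG") {
    stop_pos <- find_stop(seq, s)
    if (!is.na(stop_pos))
      return(list(start_pos = s, stop_pos = stop_pos,
                  alt_start = FALSE, status = "ok"))
  }

  # alternative-start fallback: first AUG downstream of the disruption
  d <- divergence_point(g_ref, g_var)
  hits <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (hits[1] != -1) {
    for (a in as.integer(hits) - 1L) {
      if (a < d) next
      stop_pos <- find_stop(seq, a + 3L)
      if (!is.na(stop_pos) && (stop_pos - a) / 3 >= min_alt_codons)
        return(list(start_pos = a, stop_pos = stop_pos,
                    alt_start = TRUE, status = "ok"))
    }
  }
  list(start_pos = NA_integer_, stop_pos = NA_integer_,
       alt_start = FALSE, status = "no-ORF")
}

#' Predict nonsense-mediated decay by the 50-nt last-junction rule
#'
#' NMD is predicted iff the stop codon lies at least 50 nt upstream of the
#' last exon-exon junction of the variant; a stop in the last exon escapes,
#' and a single-exon variant escapes by definition.
#'
#' @param variant an `isoform_variant`.
#' @param stop_pos 0-based variant coordinate of the first stop-codon base
#'   (from [scan_orf()]).
#' @param rule_nt distance threshold in nucleotides (canonical 50).
#' @return list with `nmd_predicted` and `stop_in_last_exon` flags.
#' @export
nmd_predict <- function(variant, stop_pos, rule_nt = 50L) {
  stopifnot(inherits(variant, "isoform_variant"))
  if (is.na(stop_pos)) stop("stop_pos must be a valid variant coordinate")
  exon_lens <- variant$exons[, 2] - variant$exons[, 1]
  if (variant$base$strand == "-") exon_lens <- rev(exon_lens)
  if (length(exon_lens) == 1)
    return(list(nmd_predicted = FALSE, stop_in_last_exon = TRUE))
  tlen <- sum(exon_lens)
  if (stop_pos < 0 || stop_pos > tlen - 3)
    stop("stop_pos must be a valid variant coordinate")
  last_junction <- tlen - exon_lens[length(exon_lens)]
  stop_in_last <- stop_pos >= last_junction
  list(nmd_predicted = !stop_in_last &&
         (last_junction - stop_pos) >= rule_nt,
       stop_in_last_exon = stop_in_last)
}

#' Domain truncation calls for an isoform variant
#'
#' A domain (given in reference transcript coordinates within the CDS) is
#' *lost* when none of it is translated in the reference reading frame of
#' the variant: its sequence is deleted, frameshifted, or downstream of the
#' variant's stop. Each reference coding position counts as translated iff
#' it is present in the variant, in frame relative to the variant's
#' translation start, and upstream of the variant's stop codon — so a
#' frame-preserving deletion leaves downstream domains intact, while a
#' frameshift or premature stop removes everything it garbles. Domains with
#' only part of their positions translated are *truncated*; the rest are
#' *retained*.
#'
#' @param variant an `isoform_variant`.
#' @param domains tibble with columns domain_id, start, end (0-based
#'   half-open reference transcript coordinates, inside the CDS).
#' @param orf optional precomputed [scan_orf()] result.
#' @return tibble (domain_id, status) with status in
#'   retained / truncated / lost.
#' @export
domain_truncation <- function(variant, domains, orf = NULL) {
  stopifnot(inherits(variant, "isoform_variant"))
  tx <- variant$base
  if (nrow(domains) > 0 &&
      (any(domains$start < tx$cds_start) || any(domains$end > tx$cds_end)))
    stop("domain interval outside the reference CDS")
  if (is.null(orf)) orf <- scan_orf(variant)

  idx <- seq.int(tx$cds_start, length.out = tx$cds_end - tx$cds_start)
  if (is.na(orf$stop_pos)) {
    ok <- rep(FALSE, length(idx))
  } else {
    g_ref <- genomic_positions(tx$exons, tx$strand)
    g_var <- genomic_positions(variant$exons, tx$strand)
    m <- match(g_ref[idx + 1L], g_var) - 1L
    ok <- !is.na(m) & m >= orf$start_pos & m < orf$stop_pos &
      ((m - orf$start_pos) %% 3L) == ((idx - tx$cds_start) %% 3L)
    ok[is.na(ok)] <- FALSE
  }

  status <- vapply(seq_len(nrow(domains)), function(i) {
    sel <- idx >= domains$start[i] & idx < domains$end[i]
    n_ok <- sum(ok[sel])
    if (n_ok == sum(sel)) "retained" else if (n_ok == 0) "lost"
    else "truncated"
  }, character(1))
  tibble::tibble(domain_id = domains$domain_id, status = status)
}

#' Classify the protein-level consequence of a splice variant
#'
#' Combines the component calls into one of four categories:
#' `frame-preserving` (length change divisible by 3), `frameshift-NMD`
#' (frameshift with a premature stop predicted to trigger NMD),
#' `frameshift-escape-alt-terminus` (frameshift whose stop escapes NMD,
#' e.g. an alternative stop in the last exon producing a shortened
#' C-terminus), and `no-ORF` (no stop codon reachable, even from an
#' alternative start).
#'
#' @param variant an `isoform_variant`.
#' @param domains optional domain tibble (see [domain_truncation()]).
#' @return one-row tibble: transcript_id, event_id, inclusion,
#'   delta_length, frame_preserving, stop_pos, stop_in_last_exon,
#'   nmd_predicted, alt_start, category, n_lost_domains, lost_domains.
#' @export
classify_consequence <- function(variant, domains = NULL) {
  orf <- scan_orf(variant)
  fp <- frame_status(variant$delta_length)
  if (is.na(orf$stop_pos)) {
    nmd <- list(nmd_predicted = FALSE, stop_in_last_exon = FALSE)
    category <- "no-ORF"
  } else {
    nmd <- nmd_predict(variant, orf$stop_pos)
    category <- if (fp) "frame-preserving"
    else if (nmd$nmd_predicted) "frameshift-NMD"
    else "frameshift-escape-alt-terminus"
  }
  lost <- character(0)
  n_lost <- NA_integer_
  if (!is.null(domains)) {
    dom <- domain_truncation(variant, domains, orf = orf)
    lost <- dom$domain_id[dom$status == "lost"]
    n_lost <- length(lost)
  }
  tibble::tibble(
    transcript_id = variant$base$transcript_id,
    event_id = if (is.null(variant$event)) NA_character_
               else variant$event$event_id,
    inclusion = variant$inclusion,
    delta_length = variant$delta_length,
    frame_preserving = fp,
    stop_pos = orf$stop_pos,
    stop_in_last_exon = nmd$stop_in_last_exon,
    nmd_predicted = nmd$nmd_predicted,
    alt_start = orf$alt_start,
    category = category,
    n_lost_domains = n_lost,
    lost_domains = paste(lost, collapse = ","))
}

#' Consequence calls for every fixture event
#'
#' Runs [apply_event()] + [classify_consequence()] over the event/transcript
#' pairs of a toy annotation (see [build_toy_annotation()]), using the
#' non-reference form of each event (the form whose consequence the event is
#' about: skipping for annotated cassettes, inclusion for poison exons,
#' distal splice-site choice for A3SS).
#'
#' @param annotation list from [build_toy_annotation()].
#' @return tibble of consequence calls, one row per event.
#' @export
consequence_table <- function(annotation) {
  rows <- lapply(seq_len(nrow(annotation$events)), function(i) {
    ev <- annotation$events[i, ]
    tx <- annotation$transcripts[[ev$transcript_id]]
    dom <- annotation$domains[annotation$domains$transcript_id ==
                                tx$transcript_id, ]
    var <- apply_event(tx, ev, inclusion = ev$variant_inclusion)
    classify_consequence(var, domains = if (nrow(dom)) dom else NULL)
  })
  do.call(rbind, rows)
}
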