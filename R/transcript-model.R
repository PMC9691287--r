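#' Transcript model
#'
#' Ordered exons plus an annotated ORF on a strand, carrying the genomic
#' sequence of its locus so that event application (exon skipping, intron
#' retention, alternative splice sites) can recompute the spliced sequence.
#' All genomic coordinates are 0-based half-open; transcript-relative
#' coordinates (cds_start/cds_end) are 0-based on the spliced sequence, and
#' the CDS excludes the stop codon (so `cds_end` is the coordinate of the
#' first base of the annotated stop).
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome / locus name.
#' @param strand "+" or "-" (fixtures are plus strand).
#' @param exons integer matrix with columns start, end (0-based half-open),
#'   sorted, disjoint.
#' @param cds_start,cds_end transcript-relative ORF bounds (stop excluded).
#' @param genome_seq character scalar: the locus sequence from coordinate 0.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds_start, cds_end, genome_seq) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0) stop("transcript needs at least one exon")
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon")
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons")
  tlen <- sum(exons[, 2] - exons[, 1])
  if (cds_start < 0 || cds_end > tlen || cds_end < cds_start)
    stop("CDS outside transcript")
  if ((cds_end - cds_start) %% 3 != 0)
    stop("reference CDS length must be divisible by 3")
  if (max(exons[, 2]) > nchar(genome_seq))
    stop("exons extend past the genome sequence")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 genome_seq = genome_seq),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s, %s strand): %d exons, %d nt, CDS [%d, %d)\n",
              x$transcript_id, x$gene_id, x$strand, nrow(x$exons),
              transcript_length(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

transcript_length <- function(exons) sum(exons[, 2] - exons[, 1])

# Genomic position (0-based) of every transcript position, 5'->3'.
genomic_positions <- function(exons, strand = "+") {
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons[i, 1], exons[i, 2] - 1L)), use.names = FALSE)
  if (strand == "-") rev(pos) else pos
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Spliced transcript sequence from genome + exon set.
spliced_seq <- function(genome_seq, exons, strand = "+") {
  parts <- substring(genome_seq, exons[, 1] + 1L, exons[, 2])
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

transcript_seq <- function(tx) spliced_seq(tx$genome_seq, tx$exons, tx$strand)

#' Apply a splice event to a transcript model
#'
#' Builds the isoform variant: cassette exon in/out (SE; the cassette may be
#' a poison exon absent from the reference), intron retained/spliced (RI),
#' or proximal/distal splice-site choice (A5SS/A3SS, where the event segment
#' is the alternative extension adjoining the affected exon). If the
#' requested state equals the reference structure the variant is the
#' identity (delta_length 0).
#'
#' @param transcript a [transcript_model()], or an `isoform_variant` to
#'   compose several events on one transcript (e.g. the joint skipping of a
#'   cassette pair); `delta_length` is always relative to the reference.
#' @param event one-row event tibble from [splice_event()].
#' @param inclusion logical: produce the inclusion form (segment spliced in)?
#' @return object of class `isoform_variant` with the modified exon set,
#'   recomputed spliced sequence and `delta_length` (modified minus
#'   reference spliced length, nucleotides).
#' @export
apply_event <- function(transcript, event, inclusion) {
  if (inherits(transcript, "isoform_variant")) {
    current <- transcript$exons
    transcript <- transcript$base
  } else {
    stopifnot(inherits(transcript, "transcript_model"))
    current <- transcript$exons
  }
  if (nrow(event) != 1) stop("apply_event takes a single event")
  seg <- c(event$seg_start, event$seg_end)
  exons <- current
  span <- c(min(exons[, 1]), max(exons[, 2]))
  if (seg[1] < span[1] - 1e6 || seg[2] > nchar(transcript$genome_seq))
    stop("structural mismatch: event segment outside the locus")

  new_exons <- switch(event$etype,
    SE = apply_se(exons, seg, inclusion),
    RI = apply_ri(exons, seg, inclusion),
    A5SS = apply_alt_ss(exons, seg, inclusion,
                        side = if (transcript$strand == "+") "end" else "start"),
    A3SS = apply_alt_ss(exons, seg, inclusion,
                        side = if (transcript$strand == "+") "start" else "end"))

  seq <- spliced_seq(transcript$genome_seq, new_exons, transcript$strand)
  delta <- transcript_length(new_exons) - transcript_length(transcript$exons)
  structure(list(base = transcript, event = event, inclusion = inclusion,
                 exons = new_exons, seq = seq,
                 ref_seq = transcript_seq(transcript),
                 delta_length = as.integer(delta)),
            class = "isoform_variant")
}

apply_se <- function(exons, seg, inclusion) {
  hit <- which(exons[, 1] == seg[1] & exons[, 2] == seg[2])
  if (inclusion) {
    if (length(hit)) return(exons)  # cassette already present
    # must fall strictly inside an intron
    inside_exon <- any(seg[1] < exons[, 2] & seg[2] > exons[, 1])
    before <- any(exons[, 2] <= seg[1])
    after <- any(exons[, 1] >= seg[2])
    if (inside_exon || !before || !after)
      stop("structural mismatch: cassette must lie between two exons")
    out <- rbind(exons, seg)
    out[order(out[, 1]), , drop = FALSE]
  } else {
    if (!length(hit)) {
      overlaps <- any(seg[1] < exons[, 2] & seg[2] > exons[, 1])
      if (overlaps)
        stop("structural mismatch: cassette does not match an exon exactly")
      return(exons)  # already skipped
    }
    if (hit == 1 || hit == nrow(exons))
      stop("structural mismatch: cannot skip a terminal exon")
    exons[-hit, , drop = FALSE]
  }
}

apply_ri <- function(exons, seg, inclusion) {
  up <- which(exons[, 2] == seg[1])
  down <- which(exons[, 1] == seg[2])
  if (inclusion) {
    if (length(up) == 1 && length(down) == 1 && down == up + 1) {
      merged <- exons
      merged[up, 2] <- merged[down, 2]
      return(merged[-down, , drop = FALSE])
    }
    # already retained?
    if (any(exons[, 1] <= seg[1] & exons[, 2] >= seg[2])) return(exons)
    stop("structural mismatch: segment is not an intron of this transcript")
  } else {
    host <- which(exons[, 1] < seg[1] & exons[, 2] > seg[2])
    if (length(host) == 1) {
      left <- c(exons[host, 1], seg[1])
      right <- c(seg[2], exons[host, 2])
      out <- rbind(exons[-host, , drop = FALSE], left, right)
      return(out[order(out[, 1]), , drop = FALSE])
    }
    if (length(up) == 1 && length(down) == 1) return(exons)  # already spliced
    stop("structural mismatch: segment is not retained in this transcript")
  }
}

# side = "end": segment extends an exon's 3'-genomic end (A5SS on plus).
# side = "start": segment extends an exon's 5'-genomic start (A3SS on plus).
apply_alt_ss <- function(exons, seg, inclusion, side) {
  out <- exons
  if (side == "end") {
    if (inclusion) {
      i <- which(exons[, 2] == seg[1])
      if (length(i) != 1) {
        if (any(exons[, 2] == seg[2])) return(exons)  # already long form
        stop("structural mismatch: no exon ends at the alternative segment")
      }
      out[i, 2] <- seg[2]
    } else {
      i <- which(exons[, 2] == seg[2])
      if (length(i) != 1) {
        if (any(exons[, 2] == seg[1])) return(exons)  # already short form
        stop("structural mismatch: no exon carries the alternative segment")
      }
      if (seg[1] <= exons[i, 1])
        stop("structural mismatch: trimming would empty the exon")
      out[i, 2] <- seg[1]
    }
  } else {
    if (inclusion) {
      i <- which(exons[, 1] == seg[2])
      if (length(i) != 1) {
        if (any(exons[, 1] == seg[1])) return(exons)
        stop("structural mismatch: no exon starts at the alternative segment")
      }
      out[i, 1] <- seg[1]
    } else {
      i <- which(exons[, 1] == seg[1])
      if (length(i) != 1) {
        if (any(exons[, 1] == seg[2])) return(exons)
        stop("structural mismatch: no exon carries the alternative segment")
      }
      if (seg[2] >= exons[i, 2])
        stop("structural mismatch: trimming would empty the exon")
      out[i, 1] <- seg[2]
    }
  }
  out
}

#' Reference isoform as a variant
#'
#' Wraps a transcript model as an identity `isoform_variant` (no event
#' applied), convenient for running the consequence callers on the
#' annotated isoform.
#' @param transcript a [transcript_model()].
#' @return an `isoform_variant` with delta_length 0.
#' @export
reference_variant <- function(transcript) {
  structure(list(base = transcript, event = NULL, inclusion = NA,
                 exons = transcript$exons, seq = transcript_seq(transcript),
                 ref_seq = transcript_seq(transcript), delta_length = 0L),
            class = "isoform_variant")
}

#' @export
print.isoform_variant <- function(x, ...) {
  ev <- if (is.null(x$event)) "reference" else
    sprintf("%s (%s, inclusion=%s)", x$event$event_id, x$event$etype,
            x$inclusion)
  cat(sprintf("isoform_variant of %s: %s, delta_length = %+d nt\n",
              x$base$transcript_id, ev, x$delta_length))
  invisible(x)
}
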