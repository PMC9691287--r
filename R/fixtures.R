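# Toy annotation fixtures.
#
# Each fixture emulates one exemplar locus: a SEC24C-like transcript with a
# 116-nt cassette exon whose skipping frameshifts into an NMD-triggering
# PTC; a SEC24D-like transcript with a 296-nt frameshifting poison exon; a
# KLHL12-like transcript whose 99+187-nt cassette pair, when jointly
# skipped, frameshifts into an alternative stop in the last exon (NMD
# escape) and removes three of six kelch repeats; a SEC31A-like transcript
# with a 50-nt alternative exon coupled to an alternative downstream start;
# a PICALM-like transcript with frame-preserving exon 13 / exon 17 cassettes;
# and a NERF/ELF2-like gene with two alternative starts and an alternative
# 3'SS in exon 7.
#
# Sequence construction: filler bases are drawn from {A, C, G} only, so the
# genome contains no stop codon in any frame except where one is planted
# explicitly (a planted TAA stops exactly one frame; planted ATG starts are
# followed by C so they cannot create a TGA). This makes every reading-frame
# outcome of every variant fully determined by construction.

new_locus <- function(exon_lens, intron_len = 100L, tail = 200L) {
  n <- length(exon_lens)
  starts <- cumsum(c(0L, utils::head(exon_lens, -1) + intron_len))
  exons <- cbind(start = starts, end = starts + exon_lens)
  list(exons = exons,
       glen = max(exons[, 2]) + tail,
       tstarts = cumsum(c(0L, utils::head(exon_lens, -1))))
}

# smallest p >= p_min with (p - anchor) %% 3 == frame
first_inframe <- function(p_min, anchor, frame = 0L) {
  p_min + ((frame - (p_min - anchor)) %% 3L)
}

plant <- function(genome, gstart, motif) {
  bases <- strsplit(motif, "")[[1]]
  genome[gstart + seq_along(bases)] <- bases
  genome
}

filler_genome <- function(glen) {
  sample(c("A", "C", "G"), glen, replace = TRUE)
}

finish_genome <- function(genome) paste(genome, collapse = "")

#' Build the toy annotation fixture set
#'
#' Deterministically constructs six exemplar transcript models with
#' internally consistent exon/CDS coordinates and explicit sequences, the
#' splice events acting on them, and a domain table (six kelch-repeat
#' intervals on the KLHL12-like transcript, three of them downstream of the
#' 99/187-nt cassette pair, plus a WD40 repeat on the SEC31A-like one).
#' Coordinates are 0-based half-open, plus strand.
#'
#' @return list with `transcripts` (named list of [transcript_model()]),
#'   `events` (tibble of [splice_event()] rows plus `transcript_id` and
#'   `variant_inclusion`, the non-reference form each event is about), and
#'   `domains` (tibble: transcript_id, domain_id, start, end in reference
#'   transcript coordinates).
#' @export
build_toy_annotation <- function() {
  withr::with_seed(20221110L, {
    transcripts <- list()
    events <- list()
    domains <- list()

    ## SEC24C-like: 13 exons, exon 11 = 116 nt; skipping frameshifts into a
    ## PTC in exon 12, >= 50 nt upstream of the last junction -> NMD.
    lens <- c(150L, rep(120L, 9), 116L, 200L, 250L)
    loc <- new_locus(lens)
    g <- filler_genome(loc$glen)
    gp <- genomic_positions(loc$exons)
    cds_start <- 30L
    g <- plant(g, gp[cds_start + 1L] - 1L + 1L, "ATGC")
    p0 <- first_inframe(loc$tstarts[13] + 60L, cds_start)
    g <- plant(g, gp[p0 + 1L] - 1L + 1L, "TAA")
    q <- first_inframe(loc$tstarts[12] + 12L, cds_start + 116L)
    g <- plant(g, gp[q + 1L] - 1L + 1L, "TAA")
    transcripts$SEC24C_like <- transcript_model(
      "SEC24C_like", "SEC24C_like", "chr_SEC24C", "+",
      loc$exons, cds_start, p0, finish_genome(g))
    events$SEC24C <- cbind(
      splice_event("SE_SEC24C_E11", "SEC24C_like", "SE",
                   segment = loc$exons[11, ], chrom = "chr_SEC24C"),
      tibble::tibble(transcript_id = "SEC24C_like",
                     variant_inclusion = FALSE))

    ## SEC24D-like: 12 exons; a 296-nt poison exon in the intron after exon
    ## 9 whose inclusion frameshifts into a PTC inside the poison exon.
    lens <- c(150L, rep(120L, 8), 150L, 150L, 250L)
    loc <- new_locus(lens, intron_len = 450L)
    g <- filler_genome(loc$glen)
    gp <- genomic_positions(loc$exons)
    cds_start <- 30L
    g <- plant(g, gp[cds_start + 1L], "ATGC")
    p0 <- first_inframe(loc$tstarts[12] + 60L, cds_start)
    g <- plant(g, gp[p0 + 1L], "TAA")
    poison_start <- loc$exons[9, 2] + 60L
    P <- loc$tstarts[10]  # inclusion-variant coordinate of the poison start
    k <- first_inframe(36L, 0L, frame = (cds_start - P) %% 3L)
    g <- plant(g, poison_start + k, "TAA")
    transcripts$SEC24D_like <- transcript_model(
      "SEC24D_like", "SEC24D_like", "chr_SEC24D", "+",
      loc$exons, cds_start, p0, finish_genome(g))
    events$SEC24D <- cbind(
      splice_event("SE_SEC24D_poison", "SEC24D_like", "SE",
                   segment = c(poison_start, poison_start + 296L),
                   chrom = "chr_SEC24D"),
      tibble::tibble(transcript_id = "SEC24D_like",
                     variant_inclusion = TRUE))

    ## KLHL12-like: 14 exons, exon 10 = 99 nt and exon 11 = 187 nt; joint
    ## skipping (-286) frameshifts into an alternative stop in the last
    ## exon (NMD escape); six kelch repeats, three downstream of the pair.
    lens <- c(150L, rep(120L, 8), 99L, 187L, 150L, 150L, 300L)
    loc <- new_locus(lens)
    g <- filler_genome(loc$glen)
    gp <- genomic_positions(loc$exons)
    cds_start <- 30L
    g <- plant(g, gp[cds_start + 1L], "ATGC")
    q <- first_inframe(loc$tstarts[14] + 15L, cds_start + 286L)
    g <- plant(g, gp[q + 1L], "TAA")
    p0 <- first_inframe(loc$tstarts[14] + 150L, cds_start)
    g <- plant(g, gp[p0 + 1L], "TAA")
    transcripts$KLHL12_like <- transcript_model(
      "KLHL12_like", "KLHL12_like", "chr_KLHL12", "+",
      loc$exons, cds_start, p0, finish_genome(g))
    events$KLHL12_E10 <- cbind(
      splice_event("SE_KLHL12_E10", "KLHL12_like", "SE",
                   segment = loc$exons[10, ], chrom = "chr_KLHL12"),
      tibble::tibble(transcript_id = "KLHL12_like",
                     variant_inclusion = FALSE))
    events$KLHL12_E11 <- cbind(
      splice_event("SE_KLHL12_E11", "KLHL12_like", "SE",
                   segment = loc$exons[11, ], chrom = "chr_KLHL12"),
      tibble::tibble(transcript_id = "KLHL12_like",
                     variant_inclusion = FALSE))
    kelch_starts <- c(400L, 500L, 600L, 1400L, 1470L, 1540L)
    domains$KLHL12 <- tibble::tibble(
      transcript_id = "KLHL12_like",
      domain_id = sprintf("kelch%d", 1:6),
      start = kelch_starts, end = kelch_starts + 60L)

    ## SEC31A-like: 8 exons; a 50-nt alternative exon after exon 3 whose
    ## inclusion shifts the frame past every stop, forcing the alternative
    ## downstream start planted in exon 5 (shorter N-terminus, first WD40
    ## repeat lost).
    lens <- c(150L, 120L, 120L, 120L, 150L, 120L, 120L, 250L)
    loc <- new_locus(lens, intron_len = 200L)
    g <- filler_genome(loc$glen)
    gp <- genomic_positions(loc$exons)
    cds_start <- 30L
    g <- plant(g, gp[cds_start + 1L], "ATGC")
    p0 <- first_inframe(loc$tstarts[8] + 60L, cds_start)
    g <- plant(g, gp[p0 + 1L], "TAA")
    a <- first_inframe(loc$tstarts[5] + 12L, cds_start)
    g <- plant(g, gp[a + 1L], "ATGC")
    alt_start <- loc$exons[3, 2] + 60L
    transcripts$SEC31A_like <- transcript_model(
      "SEC31A_like", "SEC31A_like", "chr_SEC31A", "+",
      loc$exons, cds_start, p0, finish_genome(g))
    events$SEC31A <- cbind(
      splice_event("SE_SEC31A_E3b", "SEC31A_like", "SE",
                   segment = c(alt_start, alt_start + 50L),
                   chrom = "chr_SEC31A"),
      tibble::tibble(transcript_id = "SEC31A_like",
                     variant_inclusion = TRUE))
    domains$SEC31A <- tibble::tibble(
      transcript_id = "SEC31A_like", domain_id = "WD40_1",
      start = 60L, end = 180L)

    ## PICALM-like: 20 exons; exon 13 (102 nt) and exon 17 (96 nt) cassettes
    ## are both frame-preserving, giving the Delta13 / Delta17 isoforms with
    ## distinct C-terminal segments.
    lens <- c(150L, rep(120L, 11), 102L, 120L, 120L, 120L, 96L, 120L, 120L,
              250L)
    loc <- new_locus(lens)
    g <- filler_genome(loc$glen)
    gp <- genomic_positions(loc$exons)
    cds_start <- 30L
    g <- plant(g, gp[cds_start + 1L], "ATGC")
    p0 <- first_inframe(loc$tstarts[20] + 60L, cds_start)
    g <- plant(g, gp[p0 + 1L], "TAA")
    transcripts$PICALM_like <- transcript_model(
      "PICALM_like", "PICALM_like", "chr_PICALM", "+",
      loc$exons, cds_start, p0, finish_genome(g))
    events$PICALM_E13 <- cbind(
      splice_event("SE_PICALM_E13", "PICALM_like", "SE",
                   segment = loc$exons[13, ], chrom = "chr_PICALM"),
      tibble::tibble(transcript_id = "PICALM_like",
                     variant_inclusion = FALSE))
    events$PICALM_E17 <- cbind(
      splice_event("SE_PICALM_E17", "PICALM_like", "SE",
                   segment = loc$exons[17, ], chrom = "chr_PICALM"),
      tibble::tibble(transcript_id = "PICALM_like",
                     variant_inclusion = FALSE))

    ## NERF/ELF2-like: 10 exons; a long isoform starting in exon 1 and a
    ## short one starting at an AUG in exon 5, plus an alternative 3'SS
    ## (21 nt) at the start of exon 7.
    lens <- c(180L, 120L, 120L, 120L, 150L, 120L, 160L, 120L, 120L, 250L)
    loc <- new_locus(lens)
    g <- filler_genome(loc$glen)
    gp <- genomic_positions(loc$exons)
    cds_start <- 30L
    g <- plant(g, gp[cds_start + 1L], "ATGC")
    p0 <- first_inframe(loc$tstarts[10] + 60L, cds_start)
    g <- plant(g, gp[p0 + 1L], "TAA")
    a <- first_inframe(loc$tstarts[5] + 12L, cds_start)
    g <- plant(g, gp[a + 1L], "ATGC")
    genome <- finish_genome(g)
    transcripts$NERF_like <- transcript_model(
      "NERF_like", "NERF_like", "chr_NERF", "+",
      loc$exons, cds_start, p0, genome)
    short_exons <- loc$exons[5:10, , drop = FALSE]
    transcripts$NERF_like_short <- transcript_model(
      "NERF_like_short", "NERF_like", "chr_NERF", "+",
      short_exons, a - loc$tstarts[5], p0 - loc$tstarts[5], genome)
    events$NERF_A3SS <- cbind(
      splice_event("A3SS_NERF_E7", "NERF_like", "A3SS",
                   segment = c(loc$exons[7, 1], loc$exons[7, 1] + 21L),
                   chrom = "chr_NERF"),
      tibble::tibble(transcript_id = "NERF_like",
                     variant_inclusion = FALSE))

    list(transcripts = transcripts,
         events = do.call(rbind, unname(events)),
         domains = do.call(rbind, unname(domains)))
  })
}
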