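# Plain-text readers/writers for the pipeline's tabular formats, plus
# GTF/BED/FASTA round-trips for the fixture annotation.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' Write / read a count matrix as TSV
#'
#' Counts go to one TSV (gene_id + one column per sample), sample metadata
#' (sample, condition) to a second.
#'
#' @param cm a [count_matrix()].
#' @param counts_path,metadata_path file paths.
#' @return (read) a [count_matrix()]; (write) invisibly, the paths.
#' @export
write_counts_tsv <- function(cm, counts_path, metadata_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv_plain(df, counts_path)
  write_tsv_plain(data.frame(sample = names(cm$condition),
                             condition = unname(cm$condition)),
                  metadata_path)
  invisible(c(counts_path, metadata_path))
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_path, metadata_path) {
  df <- utils::read.delim(counts_path, sep = "\t", check.names = FALSE)
  meta <- utils::read.delim(metadata_path, sep = "\t", check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  count_matrix(counts, stats::setNames(as.character(meta$condition),
                                       meta$sample))
}

#' Write / read a junction count table as TSV
#' @param junctions tibble (event_id, sample, condition, inc_reads,
#'   skip_reads).
#' @param path file path.
#' @return (read) the tibble.
#' @export
write_junctions_tsv <- function(junctions, path) {
  write_tsv_plain(junctions, path)
  invisible(path)
}

#' @rdname write_junctions_tsv
#' @export
read_junctions_tsv <- function(path) read_tsv_plain(path)

#' Write / read splice-event definitions as TSV
#' @param events tibble of [splice_event()] rows.
#' @param path file path.
#' @return (read) the tibble.
#' @export
write_events_tsv <- function(events, path) {
  write_tsv_plain(events, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) read_tsv_plain(path)

#' Read gene sets (two-column TSV or GMT)
#'
#' TSV format: columns set_id, gene_id. GMT format: one set per line,
#' `set_id <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path file path; format chosen by extension (".gmt" = GMT).
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[`, character(1), 1)
    sets
  } else {
    df <- read_tsv_plain(path)
    split(as.character(df$gene_id), df$set_id)
  }
}

#' Write gene sets as two-column TSV
#' @param genesets named list of character vectors.
#' @param path file path.
#' @export
write_gene_sets_tsv <- function(genesets, path) {
  df <- data.frame(
    set_id = rep(names(genesets), lengths(genesets)),
    gene_id = unlist(genesets, use.names = FALSE))
  write_tsv_plain(df, path)
  invisible(path)
}

#' Write / read simulation truth as JSON
#' @param truth the `truth` element from [generate_counts()].
#' @param path file path.
#' @return (read) the truth list (tibbles restored).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$de <- tibble::as_tibble(truth$de)
  truth$base_weight <- stats::setNames(as.numeric(truth$base_weight),
                                       truth$gene_ids)
  truth
}

#' Write a toy annotation to GTF + FASTA + BED
#'
#' GTF uses 1-based closed coordinates (converted from the internal 0-based
#' half-open convention); the genome FASTA carries one record per
#' chromosome; domains go to a transcript-space BED (chrom = transcript id).
#'
#' @param annotation list from [build_toy_annotation()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_annotation <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- file.path(dir, "transcripts.gtf")
  fa <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "domains.bed")

  grl <- lapply(annotation$transcripts, function(tx) {
    n <- nrow(tx$exons)
    GenomicRanges::GRanges(
      seqnames = tx$chrom,
      ranges = IRanges::IRanges(start = tx$exons[, 1] + 1L,
                                end = tx$exons[, 2]),
      strand = tx$strand,
      type = "exon",
      gene_id = tx$gene_id,
      transcript_id = tx$transcript_id,
      exon_number = seq_len(n))
  })
  gr <- suppressWarnings(do.call(c, unname(grl)))
  rtracklayer::export(gr, gtf, format = "gtf")

  chroms <- unique(vapply(annotation$transcripts,
                          function(tx) tx$chrom, character(1)))
  seqs <- vapply(chroms, function(ch) {
    tx <- Filter(function(t) t$chrom == ch, annotation$transcripts)[[1]]
    tx$genome_seq
  }, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)

  dom <- annotation$domains
  utils::write.table(
    data.frame(dom$transcript_id, dom$start, dom$end, dom$domain_id),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(gtf = gtf, fasta = fa, bed = bed))
}

#' Read a toy annotation back from GTF + FASTA + BED
#'
#' Reconstructs [transcript_model()] objects from the exon records; CDS
#' bounds are recovered by locating the annotated start codon (first ATG of
#' the spliced sequence) and its first in-frame stop.
#'
#' @param dir directory written by [write_annotation()].
#' @return list with `transcripts` and `domains` (no events; event tables
#'   travel as TSV).
#' @export
read_annotation <- function(dir) {
  gr <- rtracklayer::import(file.path(dir, "transcripts.gtf"))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(fa) <- sub("\\s.*", "", names(fa))
  gr <- gr[gr$type == "exon"]
  txs <- split(seq_along(gr), gr$transcript_id)
  transcripts <- lapply(names(txs), function(tid) {
    idx <- txs[[tid]]
    chrom <- as.character(GenomicRanges::seqnames(gr)[idx][1])
    strand <- as.character(BiocGenerics::strand(gr)[idx][1])
    exons <- cbind(BiocGenerics::start(gr)[idx] - 1L,
                   BiocGenerics::end(gr)[idx])
    exons <- exons[order(exons[, 1]), , drop = FALSE]
    genome_seq <- as.character(fa[[chrom]])
    seq <- spliced_seq(genome_seq, exons, strand)
    cds_start <- as.integer(regexpr("ATG", seq, fixed = TRUE)) - 1L
    if (cds_start < 0) stop("no start codon found for ", tid)
    cds_end <- find_stop(seq, cds_start)
    transcript_model(tid, gr$gene_id[idx][1], chrom, strand, exons,
                     cds_start, cds_end, genome_seq)
  })
  names(transcripts) <- names(txs)
  bed <- utils::read.delim(file.path(dir, "domains.bed"), header = FALSE)
  domains <- tibble::tibble(transcript_id = bed[[1]], domain_id = bed[[4]],
                            start = as.integer(bed[[2]]),
                            end = as.integer(bed[[3]]))
  list(transcripts = transcripts, domains = domains)
}
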