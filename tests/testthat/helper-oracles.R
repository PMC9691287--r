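# Independent brute-force oracles and small fixture builders.

# BH step-up computed from the definition (sort, scale by m/i, enforce
# monotonicity from the largest p down, clip, restore input order).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric probability by exhaustive summation over the
# overlap distribution: P(X >= k) for X ~ Hyper(N, K, n).
brute_hyper_tail <- function(k, K, N, n) {
  kmax <- min(K, n)
  if (k > kmax) return(0)
  ks <- seq.int(max(k, max(0, n - (N - K))), kmax)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Pearson r and t-transform p from the definitional sums.
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# First stop position (0-based, first base of the stop codon) from `start`,
# found by translating with Biostrings (independent of the codon walk in
# the package).
oracle_first_stop <- function(seq, start) {
  sub <- substr(seq, start + 1, nchar(seq))
  k <- nchar(sub) %/% 3
  if (k == 0) return(NA_integer_)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(sub, 1, 3 * k)),
    if.fuzzy.codon = "solve"))
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit == -1) NA_integer_ else start + 3L * (as.integer(hit) - 1L)
}

# Random toy transcript with a guaranteed ATG in exon 1 and at least four
# exons, over the full ACGT alphabet (stops arise by chance), for
# ORF-scanner oracle comparisons.
random_toy_transcript <- function(id) {
  n_ex <- sample(4:8, 1)
  lens <- sample(30:150, n_ex, replace = TRUE)
  starts <- cumsum(c(0L, head(lens, -1) + 50L))
  exons <- cbind(starts, starts + lens)
  glen <- max(exons[, 2]) + 50L
  genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
  seq <- bcellsplice:::spliced_seq(genome, exons)
  cds_start <- sample(0:min(20, lens[1] - 3), 1)
  substr(genome, exons[1, 1] + cds_start + 1,
         exons[1, 1] + cds_start + 3) <- "ATG"
  seq <- bcellsplice:::spliced_seq(genome, exons)
  cds_end <- oracle_first_stop(seq, cds_start)
  if (is.na(cds_end)) cds_end <- cds_start + 3 * ((nchar(seq) - cds_start) %/% 3)
  transcript_model(id, id, paste0("chr_", id), "+", exons,
                   cds_start, cds_end, genome)
}

# Tiny count matrix from a plain matrix.
make_cm <- function(mat, condition = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  if (is.null(condition))
    condition <- stats::setNames(rep("A", ncol(mat)), colnames(mat))
  count_matrix(mat, condition)
}

# Small simulation shared across tests (cached per session).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_counts(sim_config(seed = 42L))
    cache
  }
})
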