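#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median ratio of each
#' sample's counts to the per-gene geometric mean, over genes with positive
#' counts in every sample, then rescaled so the factors have geometric
#' mean 1 (a documented stand-in for a full NB-GLM normalization).
#'
#' @param cm a [count_matrix()].
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(cm) {
  x <- cm$counts
  if (ncol(x) == 1) return(stats::setNames(1, colnames(x)))
  all_pos <- rowSums(x > 0) == ncol(x)
  if (!any(all_pos))
    stop("normalization error: no gene with all-positive counts")
  lx <- log(x[all_pos, , drop = FALSE])
  loggeo <- rowMeans(lx)
  f <- exp(apply(lx - loggeo, 2, stats::median))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(x))
}

#' Normalized log2 expression
#'
#' `log2(count / size_factor + 1)`; the pseudo-count of 1 bounds fold
#' changes at low counts.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix, genes x samples.
#' @export
log_expr <- function(cm) {
  f <- size_factors(cm)
  log2(sweep(cm$counts, 2, f, "/") + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' BH step-up adjusted p-values (clipped to 1, order-preserving with the
#' input indexing); rejects out-of-range inputs.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential expression between two conditions
#'
#' A deliberately simple substitute for an NB-GLM fit: Welch's t-test per
#' gene on `log2(normalized count + 1)`, with the log2 fold change taken as
#' the difference of group means on that scale, BH adjustment across all
#' genes, and the study cut-offs `padj < alpha` and `|log2fc| > lfc_cut`
#' (defaults 0.001 and 0.5). Genes with zero variance in both groups get
#' p = 1 (avoids undefined t statistics; all-zero genes land here).
#'
#' @param cm a [count_matrix()].
#' @param group_a,group_b condition labels (log2fc is B over A).
#' @param alpha adjusted-p cut-off.
#' @param lfc_cut absolute log2 fold-change cut-off.
#' @return tibble (gene_id, base_mean, log2fc, pvalue, padj, status) where
#'   status is "up"/"down"/"ns"; group labels stored as attributes.
#' @export
de_test <- function(cm, group_a, group_b, alpha = 0.001, lfc_cut = 0.5) {
  a_samp <- samples_of(cm, group_a)
  b_samp <- samples_of(cm, group_b)
  if (length(a_samp) < 2 || length(b_samp) < 2)
    stop("need >= 2 replicates per group")
  x <- log_expr(cm)
  xa <- x[, a_samp, drop = FALSE]
  xb <- x[, b_samp, drop = FALSE]
  n1 <- ncol(xa); n2 <- ncol(xb)
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- rowSums((xa - m1)^2) / (n1 - 1)
  v2 <- rowSums((xb - m2)^2) / (n2 - 1)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  pvalue <- rep(1, nrow(x))
  ok <- se2 > 0
  tstat <- lfc[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  pvalue[ok] <- 2 * stats::pt(-abs(tstat), df)
  padj <- bh_adjust(pvalue)
  status <- rep("ns", nrow(x))
  status[padj < alpha & lfc > lfc_cut] <- "up"
  status[padj < alpha & lfc < -lfc_cut] <- "down"
  out <- tibble::tibble(gene_id = rownames(x),
                        base_mean = unname(rowMeans(2^x - 1)),
                        log2fc = unname(lfc), pvalue = unname(pvalue),
                        padj = unname(padj), status = status)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "alpha") <- alpha
  attr(out, "lfc_cut") <- lfc_cut
  out
}

#' Directional summary of a gene set in a DE result
#'
#' Counts how many members of a gene set are up- or down-regulated in the
#' tested contrast (the "88 of 410 mRNA-processing genes up in MBC" style
#' summary).
#'
#' @param de tibble from [de_test()].
#' @param geneset character vector of gene ids.
#' @return named integer vector (n_up, n_down, n_in_set) where n_in_set is
#'   the number of set members present in the tested universe.
#' @export
geneset_direction_summary <- function(de, geneset) {
  in_set <- de$gene_id %in% geneset
  c(n_up = sum(in_set & de$status == "up"),
    n_down = sum(in_set & de$status == "down"),
    n_in_set = sum(in_set))
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided (upper tail) hypergeometric test of the overlap between a hit
#' list and each gene set, restricted to the tested universe, with BH
#' adjustment across sets. Rows with `fdr < fdr_cut` are flagged reportable.
#'
#' @param hits character vector of hit gene ids (must be contained in the
#'   universe).
#' @param universe character vector of tested gene ids.
#' @param genesets named list of character vectors.
#' @param fdr_cut reporting threshold (default 0.05).
#' @return tibble (geneset_id, overlap, set_size, universe_size, hits,
#'   pvalue, fdr, reportable), ordered by p-value.
#' @export
go_enrichment <- function(hits, universe, genesets, fdr_cut = 0.05) {
  hits <- unique(hits); universe <- unique(universe)
  if (!all(hits %in% universe))
    stop("containment error: hits must be a subset of the universe")
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(genesets), function(id) {
    set <- intersect(unique(genesets[[id]]), universe)
    K <- length(set)
    k <- length(intersect(set, hits))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(geneset_id = id, overlap = k, set_size = K,
                   universe_size = N, hits = n, pvalue = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out$reportable <- out$fdr < fdr_cut
  out[order(out$pvalue), ]
}

#' PCA of samples on log expression
#'
#' Principal-component scores of the samples on log2(normalized + 1)
#' expression, gene-centered, no gene scaling.
#'
#' @param cm a [count_matrix()].
#' @param n_components number of components to return.
#' @return tibble (sample, condition, PC1..PCk) with attribute
#'   `variance` (per-component variances, non-increasing).
#' @export
pca_projection <- function(cm, n_components = 2L) {
  if (ncol(cm$counts) < 2) stop("dimension error: need >= 2 samples")
  if (n_components > ncol(cm$counts))
    stop("dimension error: more components than samples")
  x <- log_expr(cm)
  x <- x - rowMeans(x)
  pc <- stats::prcomp(t(x), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  out <- tibble::tibble(sample = colnames(cm$counts),
                        condition = unname(cm$condition))
  for (i in seq_len(k)) out[[paste0("PC", i)]] <- scores[, i]
  attr(out, "variance") <- pc$sdev[seq_len(k)]^2
  out
}

#' Pairwise Pearson correlation of samples
#'
#' Helper for correlation heatmaps: Pearson correlation between sample
#' columns of the log expression matrix.
#'
#' @param cm a [count_matrix()].
#' @return samples x samples correlation matrix.
#' @export
sample_correlation <- function(cm) {
  stats::cor(log_expr(cm), method = "pearson")
}
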