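#' Count matrix with sample conditions
#'
#' Lightweight container for a genes x samples matrix of non-negative
#' integer read counts together with a condition label per sample
#' (B-cell subtype, or tissue for the validation panel).
#'
#' @param counts integer matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param condition named character vector mapping every sample id to a
#'   condition label.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `condition`.
#' @export
count_matrix <- function(counts, condition) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids")
  if (length(counts) > 0 && (any(is.na(counts)) || any(counts < 0)))
    stop("counts must be non-negative")
  condition <- condition[colnames(counts)]
  if (ncol(counts) > 0 && any(is.na(condition)))
    stop("every sample needs a condition label")
  if (!is.null(condition)) names(condition) <- colnames(counts)
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (ncol(x$counts) > 0) {
    tab <- table(x$condition)
    cat("conditions:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Samples belonging to a condition
#' @param cm a [count_matrix()].
#' @param condition condition label.
#' @return character vector of sample ids.
#' @export
samples_of <- function(cm, condition) {
  if (!condition %in% cm$condition)
    stop(sprintf("unknown condition label: %s", condition))
  names(cm$condition)[cm$condition == condition]
}
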