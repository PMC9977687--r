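#' Median-of-ratios size-factor normalization
#'
#' Scales each sample column by its size factor: the median, over genes
#' positive in every column, of the ratio of the gene's count to its
#' geometric mean across columns. This is the classic pseudo-reference
#' normalization used for bulk RNA-seq counts; it is provided as plumbing
#' so the downstream clustering can consume normalized matrices.
#'
#' @param counts an `ExpressionMatrix` on layer `"counts"`.
#' @return an `ExpressionMatrix` on layer `"normalized_counts"` with the
#'   size factors attached as attribute `"size_factors"`.
#' @export
size_factor_normalize <- function(counts) {
  assert_that(inherits(counts, "ExpressionMatrix"), "not an ExpressionMatrix")
  assert_that(counts$layer == "counts",
              "size_factor_normalize expects layer 'counts'")
  x <- counts$values
  pos <- rowSums(x > 0) == ncol(x)
  if (!any(pos)) {
    stop("no gene has positive counts in every column; cannot build a ",
         "pseudo-reference", call. = FALSE)
  }
  # geometric mean in log space for numerical stability
  log_ref <- rowMeans(log(x[pos, , drop = FALSE]))
  sf <- apply(x[pos, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(col) - log_ref))
  })
  out <- sweep(x, 2, sf, "/")
  res <- expression_matrix(out, counts$species_id, counts$stage_info,
                           "normalized_counts",
                           replicate_map = counts$replicate_map)
  attr(res, "size_factors") <- sf
  res
}

#' Expressed genes by the strict TPM threshold rule
#'
#' A gene is expressed when its abundance is strictly above `threshold`
#' TPM in at least one stage. Replicates, when present, are averaged per
#' stage before thresholding.
#'
#' @param m an `ExpressionMatrix` on layer `"tpm"`.
#' @param threshold TPM threshold, default 2.
#' @return character vector of expressed gene identifiers.
#' @export
expressed_genes <- function(m, threshold = 2) {
  assert_that(inherits(m, "ExpressionMatrix"), "not an ExpressionMatrix")
  assert_that(m$layer == "tpm", "expressed_genes expects layer 'tpm'")
  mm <- average_replicates(m)
  keep <- apply(mm$values, 1, max) > threshold
  genes(mm)[keep]
}

#' Per-column quantile transformation to uniform [0, 1]
#'
#' Maps each stage column onto the uniform reference by empirical rank:
#' value with rank r (mean rank on ties) among n becomes (r - 1)/(n - 1).
#' After the transform all stage columns share the same marginal
#' distribution, which makes them comparable as transcriptome
#' distributions for divergence analyses.
#'
#' @param m an `ExpressionMatrix` on layer `"tpm"`.
#' @return an `ExpressionMatrix` on layer `"quantile_uniform"`.
#' @export
quantile_transform <- function(m) {
  assert_that(inherits(m, "ExpressionMatrix"), "not an ExpressionMatrix")
  assert_that(m$layer == "tpm", "quantile_transform expects layer 'tpm'")
  x <- m$values
  assert_that(nrow(x) > 0, "empty column: no genes to transform")
  n <- nrow(x)
  out <- apply(x, 2, function(col) {
    if (n == 1) return(0.5)
    (rank(col, ties.method = "average") - 1) / (n - 1)
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(x))
  expression_matrix(out, m$species_id, m$stage_info, "quantile_uniform",
                    replicate_map = m$replicate_map)
}

#' Across-sample quantile normalization
#'
#' Classic quantile normalization: each column's sorted values are
#' replaced by the row-wise mean of all sorted columns, then restored to
#' the original order, so that afterwards every column carries an
#' identical multiset of values.
#'
#' @param m an `ExpressionMatrix` with at least two columns.
#' @return an `ExpressionMatrix` on the same layer.
#' @export
quantile_normalize <- function(m) {
  assert_that(inherits(m, "ExpressionMatrix"), "not an ExpressionMatrix")
  x <- m$values
  assert_that(ncol(x) >= 2, "quantile normalization needs >= 2 columns")
  ord <- apply(x, 2, order)
  sorted <- vapply(seq_len(ncol(x)), function(j) x[ord[, j], j],
                   numeric(nrow(x)))
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) out[ord[, j], j] <- ref
  res <- m
  res$values <- out
  res
}
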