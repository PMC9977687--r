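#' Gene annotation bundle
#'
#' Holds the per-gene labels the enrichment analytics consume:
#' transcription factor classes (a gene may carry several classes from a
#' fixed catalogue) and an ordered phylostratum (evolutionary node of
#' origin) per annotated gene.
#'
#' @param tf_classes named list: gene -> character vector of TF classes.
#' @param phylostratum named character vector: gene -> stratum label.
#' @param strata_levels ordered character vector of stratum labels, old
#'   to young.
#' @param catalogue optional character vector of valid TF class labels.
#' @return an object of class `GeneAnnotation`.
#' @export
gene_annotation <- function(tf_classes = list(), phylostratum = character(0),
                            strata_levels = NULL, catalogue = NULL) {
  if (!is.null(catalogue) && length(tf_classes)) {
    bad <- setdiff(unique(unlist(tf_classes)), catalogue)
    assert_that(length(bad) == 0,
                paste0("TF classes outside the catalogue: ",
                       paste(utils::head(bad, 3), collapse = ", ")))
  }
  if (is.null(strata_levels)) strata_levels <- unique(phylostratum)
  structure(list(tf_classes = tf_classes, phylostratum = phylostratum,
                 strata_levels = strata_levels, catalogue = catalogue),
            class = "GeneAnnotation")
}

#' Classify genes into transcription factor classes
#'
#' A gene is assigned every class whose identifier list intersects the
#' gene's identifiers (e.g. protein-family identifiers); genes with no
#' match receive no class and are not transcription factors.
#'
#' @param gene_ids named list: gene -> character vector of identifiers,
#'   or a long data.frame with columns `gene`, `identifier`.
#' @param catalogue named list: TF class -> character vector of
#'   identifiers, or a long data.frame with columns `class`, `identifier`.
#' @return named list: gene -> character vector of matched classes (only
#'   genes with >= 1 match appear).
#' @export
classify_tf <- function(gene_ids, catalogue) {
  if (is.data.frame(gene_ids)) {
    gene_ids <- split(gene_ids$identifier, gene_ids$gene)
  }
  if (is.data.frame(catalogue)) {
    catalogue <- split(catalogue$identifier, catalogue$class)
  }
  assert_that(length(catalogue) > 0, "empty TF class catalogue")
  ok <- vapply(gene_ids, function(ids) is.character(ids) || is.factor(ids),
               logical(1))
  if (any(!ok)) {
    message(sum(!ok), " malformed identifier entries skipped")
    gene_ids <- gene_ids[ok]
  }
  res <- lapply(gene_ids, function(ids) {
    names(catalogue)[vapply(catalogue, function(cid) {
      any(as.character(ids) %in% cid)
    }, logical(1))]
  })
  res[vapply(res, length, integer(1)) > 0]
}

#' Load a TF class catalogue from a TSV file
#'
#' Reads a two-column table (`class`, `identifiers` with comma-separated
#' identifier lists) into the named-list form [classify_tf()] consumes.
#' The package ships a synthetic 36-class example catalogue at
#' `system.file("extdata", "tf_class_catalogue_synthetic.tsv",
#' package = "devocomp")`; its identifiers are placeholders, to be
#' replaced by a curated protein-family mapping for real analyses.
#'
#' @param path path to the catalogue TSV.
#' @return named list: class -> character vector of identifiers.
#' @export
load_tf_catalogue <- function(path = system.file(
    "extdata", "tf_class_catalogue_synthetic.tsv", package = "devocomp")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("class", "identifiers") %in% names(df)),
              "catalogue needs columns class, identifiers")
  stats::setNames(strsplit(df$identifiers, ",\\s*"), df$class)
}

#' Label enrichment across clusters (Fisher's exact test)
#'
#' For every (cluster, label) pair builds the 2x2 membership-by-label
#' contingency table over the clustered gene universe, applies a
#' two-tailed Fisher's exact test, and corrects across the full table
#' family. Direction is over- or under-representation by the sample odds
#' ratio against 1.
#'
#' @param assignments data.frame (`gene`, `cluster`) or named vector.
#' @param ann a `GeneAnnotation`.
#' @param label_kind `"tf"` or `"phylostratum"`.
#' @param correction `"BH"` or `"bonferroni"`.
#' @return data.frame of class `EnrichmentTable` with columns `cluster`,
#'   `label`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_raw`, `p_adj`,
#'   `direction`.
#' @export
label_enrichment <- function(assignments, ann,
                             label_kind = c("tf", "phylostratum"),
                             correction = c("BH", "bonferroni")) {
  label_kind <- match.arg(label_kind)
  correction <- match.arg(correction)
  assert_that(inherits(ann, "GeneAnnotation"), "not a GeneAnnotation")
  cl <- if (is.data.frame(assignments)) {
    stats::setNames(assignments$cluster, assignments$gene)
  } else assignments
  universe <- names(cl)
  label_of <- switch(label_kind,
    tf = {
      labs <- unique(unlist(ann$tf_classes))
      lapply(stats::setNames(labs, labs), function(lb) {
        universe %in% names(ann$tf_classes)[vapply(ann$tf_classes,
          function(cs) lb %in% cs, logical(1))]
      })
    },
    phylostratum = {
      labs <- ann$strata_levels
      lapply(stats::setNames(labs, labs), function(lb) {
        universe %in% names(ann$phylostratum)[ann$phylostratum == lb]
      })
    })
  clusters <- sort(unique(cl))
  rows <- list()
  for (cc in clusters) {
    inc <- cl == cc
    if (!any(inc)) {
      message("empty cluster ", cc, " skipped")
      next
    }
    for (lb in names(label_of)) {
      hit <- label_of[[lb]]
      a <- sum(inc & hit); b <- sum(inc & !hit)
      c2 <- sum(!inc & hit); d <- sum(!inc & !hit)
      # fisher.test can exceed 1 by an ulp when summing table probabilities
      p <- min(1, stats::fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE),
                                     alternative = "two.sided")$p.value)
      or <- (a * d) / (b * c2)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cc, label = lb, a = a, b = b, c = c2, d = d,
        odds_ratio = or, p_raw = p,
        direction = if (is.nan(or) || or == 1) "none" else
          if (or > 1) "over" else "under",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p_raw, method = correction)
  out <- out[c("cluster", "label", "a", "b", "c", "d", "odds_ratio",
               "p_raw", "p_adj", "direction")]
  class(out) <- c("EnrichmentTable", class(out))
  out
}

#' Phylostratum expression profile
#'
#' Summarizes, for each phylostratum and stage, the 75th percentile
#' (linear interpolation between order statistics) of the member genes'
#' expression in a quantile-normalized matrix.
#'
#' @param m an `ExpressionMatrix` (quantile-normalized recommended;
#'   replicates are averaged first).
#' @param ann a `GeneAnnotation` with phylostrata.
#' @param probs quantile to summarize with, default 0.75.
#' @return data.frame: one row per (stratum, stage) with the summary
#'   `value`; strata with no genes in the matrix are dropped with a log.
#' @export
phylostratum_profile <- function(m, ann, probs = 0.75) {
  assert_that(inherits(ann, "GeneAnnotation"), "not a GeneAnnotation")
  mm <- average_replicates(m)
  rows <- list()
  for (st in ann$strata_levels) {
    gs <- intersect(names(ann$phylostratum)[ann$phylostratum == st],
                    genes(mm))
    if (!length(gs)) {
      message("phylostratum '", st, "' has no genes in the matrix")
      next
    }
    v <- apply(mm$values[gs, , drop = FALSE], 2, stats::quantile,
               probs = probs, type = 7, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = st, stage = mm$stage_info$stage, value = v,
      n_genes = length(gs), stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Adult tissue panel
#'
#' TPM expression over a set of adult tissues with two designated tissue
#' groups: the anterior pair and the posterior pair used by the
#' tissue-restricted gene set rule.
#'
#' @param values numeric genes x tissues TPM matrix.
#' @param anterior,posterior character vectors (length 2 each) of tissue
#'   column names.
#' @return an object of class `TissuePanel`.
#' @export
tissue_panel <- function(values, anterior, posterior) {
  missing <- setdiff(c(anterior, posterior), colnames(values))
  assert_that(length(missing) == 0,
              paste0("designated tissue absent from the panel: ",
                     paste(missing, collapse = ", ")))
  structure(list(values = values, anterior = anterior,
                 posterior = posterior),
            class = "TissuePanel")
}

#' Tissue-restricted anterior and posterior/trunk gene sets
#'
#' A gene is anterior-restricted when it is expressed (strictly above
#' `threshold` TPM) in BOTH designated anterior tissues and at or below
#' the threshold in every other panel tissue; the posterior/trunk rule is
#' symmetric for the posterior pair. The two sets are disjoint by
#' construction.
#'
#' @param panel a `TissuePanel`.
#' @param threshold TPM threshold, default 2.
#' @return list with character vectors `anterior` and `posterior_trunk`.
#' @export
tissue_restricted_sets <- function(panel, threshold = 2) {
  assert_that(inherits(panel, "TissuePanel"), "not a TissuePanel")
  x <- panel$values
  restricted <- function(pair) {
    others <- setdiff(colnames(x), pair)
    inside <- rowSums(x[, pair, drop = FALSE] > threshold) == length(pair)
    outside <- rowSums(x[, others, drop = FALSE] > threshold) == 0
    rownames(x)[inside & outside]
  }
  list(anterior = restricted(panel$anterior),
       posterior_trunk = restricted(panel$posterior))
}

#' Per-stage contrast of two gene sets
#'
#' Z-scores each gene's stage profile, then per stage runs a two-sample
#' two-tailed Student's t-test (pooled variance by default) of set A
#' against set B, Bonferroni-corrected across stages.
#'
#' @param set_a,set_b disjoint character vectors of genes (each >= 2).
#' @param m an `ExpressionMatrix`.
#' @param var_equal pooled-variance Student test (`TRUE`, default) or
#'   Welch (`FALSE`).
#' @return data.frame with columns `stage`, `mean_a`, `mean_b`, `t`,
#'   `df`, `p_raw`, `p_adj`.
#' @export
compare_dynamics <- function(set_a, set_b, m, var_equal = TRUE) {
  assert_that(length(set_a) >= 2 && length(set_b) >= 2,
              "both gene sets need >= 2 genes")
  assert_that(length(intersect(set_a, set_b)) == 0,
              "gene sets must be disjoint")
  mm <- average_replicates(m)
  zscore <- function(gs) {
    x <- mm$values[gs, , drop = FALSE]
    sdv <- apply(x, 1, stats::sd)
    keep <- sdv > 0 & is.finite(sdv)
    (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) /
      sdv[keep]
  }
  za <- zscore(set_a)
  zb <- zscore(set_b)
  assert_that(nrow(za) >= 2 && nrow(zb) >= 2,
              "fewer than 2 usable (non-constant) genes in a set")
  res <- lapply(seq_len(ncol(za)), function(j) {
    tt <- stats::t.test(za[, j], zb[, j], var.equal = var_equal)
    data.frame(stage = mm$stage_info$stage[j],
               mean_a = mean(za[, j]), mean_b = mean(zb[, j]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- adjust_pvalues(out$p_raw, method = "bonferroni")
  out
}
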