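#' Translate cluster assignments into orthogroup sets
#'
#' Maps each cluster's genes to the set of distinct orthogroups they
#' belong to; genes without an orthogroup are dropped with a logged count.
#'
#' @param assignments data.frame from [harden_assignments()] (columns
#'   `gene`, `cluster`) or a named gene -> cluster vector.
#' @param map an `OrthologyMap`.
#' @param species the species identifier of `assignments`.
#' @param gene_subset optional character vector restricting the analysis
#'   to a gene subset (e.g. transcription factors only).
#' @return named list: cluster label -> character vector of orthogroups.
#' @export
to_orthogroup_sets <- function(assignments, map, species,
                               gene_subset = NULL) {
  assert_that(inherits(map, "OrthologyMap"), "not an OrthologyMap")
  assert_that(species %in% map$species,
              paste0("species '", species, "' absent from the orthology map"))
  if (is.data.frame(assignments)) {
    cl <- stats::setNames(assignments$cluster, assignments$gene)
  } else {
    cl <- assignments
  }
  if (!is.null(gene_subset)) cl <- cl[names(cl) %in% gene_subset]
  g2o <- map$gene2og[[species]]
  mapped <- names(cl) %in% names(g2o)
  if (sum(!mapped) > 0) {
    message(sum(!mapped), " genes without an orthogroup dropped")
  }
  cl <- cl[mapped]
  sets <- lapply(split(names(cl), cl), function(gs) unique(unname(g2o[gs])))
  names(sets) <- paste0("cluster_", names(sets))
  assert_that(any(vapply(sets, length, integer(1)) > 0),
              "every cluster translated to an empty orthogroup set")
  sets
}

#' Upper-tail hypergeometric overlap tests between two cluster families
#'
#' For every pair of clusters (one from each species) tests whether their
#' orthogroup overlap exceeds the chance expectation:
#' p = P(X >= n_overlap) with X ~ Hypergeometric(N = universe, K = nA,
#' n = nB). P values are adjusted across all pairs of the comparison.
#'
#' @param sets_a,sets_b named lists of orthogroup sets (from
#'   [to_orthogroup_sets()]).
#' @param universe number of orthogroups testable between the species
#'   pair; by default the orthogroups represented in either family
#'   are counted (union), but the recommended pipeline value is the
#'   intersection-universe computed by the caller.
#' @param method multiple-testing correction, `"BH"` or `"bonferroni"`.
#' @return data.frame of class `OverlapTable` with columns `cluster_a`,
#'   `cluster_b`, `n_a`, `n_b`, `n_overlap`, `n_universe`, `p_raw`,
#'   `p_adj`.
#' @export
pairwise_overlap_tests <- function(sets_a, sets_b, universe = NULL,
                                   method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (is.null(universe)) {
    universe <- length(union(unlist(sets_a), unlist(sets_b)))
  }
  sizes <- c(vapply(sets_a, length, integer(1)),
             vapply(sets_b, length, integer(1)))
  assert_that(universe >= max(sizes),
              "universe smaller than the largest cluster set")
  grid <- expand.grid(cluster_a = names(sets_a), cluster_b = names(sets_b),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    A <- sets_a[[grid$cluster_a[i]]]
    B <- sets_b[[grid$cluster_b[i]]]
    ov <- length(intersect(A, B))
    if (ov > min(length(A), length(B))) {
      stop("inconsistent sets: overlap exceeds the smaller set",
           call. = FALSE)
    }
    p <- stats::phyper(ov - 1, length(A), universe - length(A), length(B),
                       lower.tail = FALSE)
    c(n_a = length(A), n_b = length(B), n_overlap = ov, p_raw = p)
  })
  res <- as.data.frame(do.call(rbind, res))
  out <- cbind(grid, res[c("n_a", "n_b", "n_overlap")],
               n_universe = universe, p_raw = res$p_raw)
  out$p_adj <- adjust_pvalues(out$p_raw, method = method)
  class(out) <- c("OverlapTable", class(out))
  out
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up or Bonferroni, order-preserving with the
#' input vector.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method `"BH"` or `"bonferroni"`.
#' @return numeric vector of adjusted p-values, same order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "BH") "BH" else "bonferroni")
}

#' Quadrant specification for overlap analyses
#'
#' Classifies each species' clusters as early (pre-larval) or late
#' (post-larval); excluded clusters (e.g. adult-tissue driven ones) are
#' removed from the analysis.
#'
#' @param species_a,species_b lists with elements `early`, `late` and
#'   optionally `excluded`, each a character vector of cluster labels.
#' @return an object of class `QuadrantSpec`.
#' @export
quadrant_spec <- function(species_a, species_b) {
  chk <- function(q, who) {
    assert_that(length(intersect(q$early, q$late)) == 0,
                paste0("early and late cluster sets overlap for ", who))
    q$excluded <- q$excluded %||% character(0)
    q
  }
  structure(list(species_a = chk(species_a, "species_a"),
                 species_b = chk(species_b, "species_b")),
            class = "QuadrantSpec")
}

#' Derive a quadrant spec from fitted cluster models
#'
#' Classifies each cluster by the life-cycle phase of the stage where its
#' centroid peaks: pre-larval/larval peaks are "early", post-larval peaks
#' are "late", adult-tissue peaks are excluded.
#'
#' @param model_a,model_b `ClusterModel` objects.
#' @param stage_info_a,stage_info_b stage metadata of each species
#'   (`stage_info` of the clustered matrices).
#' @return a `QuadrantSpec`.
#' @export
quadrant_spec_from_models <- function(model_a, model_b,
                                      stage_info_a, stage_info_b) {
  classify <- function(model, info) {
    peak <- apply(model$centroids, 1, which.max)
    phase <- info$phase[peak]
    list(early = rownames(model$centroids)[phase %in% c("pre-larval", "larval")],
         late = rownames(model$centroids)[phase == "post-larval"],
         excluded = rownames(model$centroids)[phase == "adult-tissue"])
  }
  quadrant_spec(classify(model_a, stage_info_a),
                classify(model_b, stage_info_b))
}

#' @keywords internal
#' @noRd
classify_cluster <- function(cluster, q_side) {
  ifelse(cluster %in% q_side$early, "early",
         ifelse(cluster %in% q_side$late, "late",
                ifelse(cluster %in% q_side$excluded, "excluded", NA)))
}

#' Quadrant relative similarity
#'
#' Partitions all classified cluster pairs of an overlap table into the
#' four quadrants (early-early, early-late, late-early, late-late) and
#' computes, per quadrant,
#' RS = mean(-log10 p_adj within the quadrant) / mean(-log10 p_adj over
#' all classified pairs). Values above 1 mark quadrants with
#' higher-than-average orthogroup overlap.
#'
#' @param table an `OverlapTable`.
#' @param q a `QuadrantSpec`.
#' @param p_floor floor applied to adjusted p-values before taking logs.
#' @return data.frame with columns `quadrant`, `n_pairs`, `mean_nlp`,
#'   `rs`; quadrants with no pairs carry `NA`.
#' @export
quadrant_relative_similarity <- function(table, q, p_floor = 1e-300) {
  assert_that(inherits(q, "QuadrantSpec"), "q must be a QuadrantSpec")
  pa <- classify_cluster(table$cluster_a, q$species_a)
  pb <- classify_cluster(table$cluster_b, q$species_b)
  keep <- !(pa %in% "excluded") & !(pb %in% "excluded")
  pa <- pa[keep]; pb <- pb[keep]
  if (anyNA(pa) || anyNA(pb)) {
    stop("non-excluded cluster without an early/late class", call. = FALSE)
  }
  nlp <- -log10(pmax(table$p_adj[keep], p_floor))
  total <- mean(nlp)
  quadrants <- c("early-early", "early-late", "late-early", "late-late")
  lab <- paste(pa, pb, sep = "-")
  out <- data.frame(quadrant = quadrants,
                    n_pairs = vapply(quadrants, function(qq) sum(lab == qq),
                                     integer(1)),
                    mean_nlp = vapply(quadrants, function(qq) {
                      if (any(lab == qq)) mean(nlp[lab == qq]) else NA_real_
                    }, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$rs <- out$mean_nlp / total
  if (any(out$n_pairs == 0)) {
    message("empty quadrant(s): ",
            paste(out$quadrant[out$n_pairs == 0], collapse = ", "))
  }
  out
}

#' Heterochronically shifted orthologue pairs
#'
#' Returns the one-to-one orthologue pairs whose cluster memberships fall
#' in the requested quadrant, e.g. early in species A and late in species
#' B. Pairs touching an excluded cluster or an unassigned gene are
#' dropped.
#'
#' @param assign_a,assign_b assignments per species (data.frame from
#'   [harden_assignments()] or named vectors).
#' @param map an `OrthologyMap`.
#' @param species_a,species_b species identifiers.
#' @param q a `QuadrantSpec`.
#' @param direction `"early_a_late_b"`, `"late_a_early_b"`, or a list
#'   `list(a = <phase>, b = <phase>)` for custom rules.
#' @return data.frame with columns `orthogroup`, `gene_a`, `gene_b`,
#'   `cluster_a`, `cluster_b`; may be empty.
#' @export
shifted_gene_sets <- function(assign_a, assign_b, map, species_a, species_b,
                              q, direction = "early_a_late_b") {
  assert_that(inherits(q, "QuadrantSpec"), "q must be a QuadrantSpec")
  if (is.character(direction)) {
    direction <- switch(direction,
      early_a_late_b = list(a = "early", b = "late"),
      late_a_early_b = list(a = "late", b = "early"),
      stop("unknown direction '", direction, "'", call. = FALSE))
  }
  as_vec <- function(a) {
    if (is.data.frame(a)) stats::setNames(a$cluster, a$gene) else a
  }
  va <- as_vec(assign_a); vb <- as_vec(assign_b)
  pairs <- one_to_one(map, species_a, species_b)
  pairs <- pairs[pairs$gene_a %in% names(va) & pairs$gene_b %in% names(vb), ]
  pairs$cluster_a <- paste0("cluster_", va[pairs$gene_a])
  pairs$cluster_b <- paste0("cluster_", vb[pairs$gene_b])
  ca <- classify_cluster(pairs$cluster_a, q$species_a)
  cb <- classify_cluster(pairs$cluster_b, q$species_b)
  keep <- !is.na(ca) & !is.na(cb) & ca == direction$a & cb == direction$b
  pairs[keep, , drop = FALSE]
}

#' Average expression dynamics of a gene set
#'
#' Z-scores each gene's stage profile, averages per stage, and reports
#' mean and standard error; optionally adds a locally weighted regression
#' over stage ordinals for presentation.
#'
#' @param gene_set character vector of genes (subset of the matrix).
#' @param m an `ExpressionMatrix` (replicates are averaged first).
#' @param smooth add a loess curve.
#' @param span loess span over stage ordinals.
#' @return data.frame with columns `stage`, `ordinal`, `mean`, `se`, and
#'   `smoothed` when requested.
#' @export
average_dynamics <- function(gene_set, m, smooth = FALSE, span = 0.75) {
  assert_that(length(gene_set) > 0, "empty gene set")
  mm <- average_replicates(m)
  missing <- setdiff(gene_set, genes(mm))
  assert_that(length(missing) == 0,
              paste0("genes absent from the matrix: ",
                     paste(utils::head(missing, 3), collapse = ", ")))
  x <- mm$values[gene_set, , drop = FALSE]
  sdv <- apply(x, 1, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    message(sum(flat), " constant-profile genes excluded from the average")
    x <- x[!flat, , drop = FALSE]
    sdv <- sdv[!flat]
  }
  assert_that(nrow(x) > 0, "no genes left after removing flat profiles")
  z <- (x - rowMeans(x)) / sdv
  out <- data.frame(stage = mm$stage_info$stage,
                    ordinal = mm$stage_info$ordinal,
                    mean = colMeans(z),
                    se = apply(z, 2, stats::sd) / sqrt(nrow(z)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (smooth) {
    # short stage series cannot support a narrow quadratic window
    n_st <- nrow(out)
    fit <- stats::loess(mean ~ ordinal, data = out,
                        span = max(span, min(1, 6 / n_st)),
                        degree = if (n_st < 8) 1 else 2)
    out$smoothed <- stats::predict(fit, out$ordinal)
  }
  out
}
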