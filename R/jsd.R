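#' Stage transcriptome as a probability distribution
#'
#' Converts one stage column, restricted to an orthologue set, into a
#' probability vector on the simplex (divided by its sum).
#'
#' @param m an `ExpressionMatrix` on layer `"quantile_uniform"`, or a
#'   non-negative numeric vector.
#' @param orthologues character vector of gene identifiers to restrict to
#'   (ignored when `m` is already a vector).
#' @param stage stage label (ignored when `m` is a vector).
#' @return an object of class `StageDistribution` with elements
#'   `species_id`, `stage`, `orthologues`, `p`.
#' @export
stage_distribution <- function(m, orthologues = NULL, stage = NULL) {
  if (inherits(m, "ExpressionMatrix")) {
    assert_that(m$layer == "quantile_uniform",
                "stage_distribution expects layer 'quantile_uniform'")
    assert_that(stage %in% stages(m), paste0("unknown stage: ", stage))
    mm <- average_replicates(m)
    v <- mm$values[orthologues %||% genes(mm), stage]
    sp <- m$species_id
  } else {
    v <- as.numeric(m)
    names(v) <- names(m)
    sp <- NA_character_
  }
  assert_that(all(v >= 0), "negative abundances cannot form a distribution")
  s <- sum(v)
  if (s == 0) {
    stop("all-zero stage", if (!is.null(stage)) paste0(": ", stage),
         call. = FALSE)
  }
  structure(list(species_id = sp, stage = stage,
                 orthologues = names(v), p = v / s),
            class = "StageDistribution")
}

#' @keywords internal
#' @noRd
as_prob <- function(x) {
  if (inherits(x, "StageDistribution")) x$p else as.numeric(x)
}

# Shared kernel: per-element JSD terms, with the 0 * log(0/x) = 0
# convention. Sum of the terms is the raw JSD in bits.
#' @keywords internal
#' @noRd
jsd_terms <- function(p, q) {
  assert_that(length(p) == length(q), "distributions of unequal length")
  m2 <- (p + q) / 2
  tp <- tq <- numeric(length(p))
  ip <- p > 0
  iq <- q > 0
  tp[ip] <- p[ip] * log2(p[ip] / m2[ip])
  tq[iq] <- q[iq] * log2(q[iq] / m2[iq])
  (tp + tq) / 2
}

#' Jensen-Shannon divergence between two stage distributions
#'
#' JSD(P || Q) = 1/2 sum p_i log2(p_i / m_i) + 1/2 sum q_i log2(q_i / m_i)
#' with m_i = (p_i + q_i)/2; terms with a zero numerator contribute 0.
#' Symmetric, bounded in [0, 1] bits, and zero iff P = Q.
#'
#' @param p,q `StageDistribution` objects or probability vectors of equal
#'   length.
#' @return the divergence in bits.
#' @export
jsd_raw <- function(p, q) {
  sum(jsd_terms(as_prob(p), as_prob(q)))
}

#' Gene-wise Jensen-Shannon divergence
#'
#' The per-orthologue additive term of the JSD sum; the terms add up
#' exactly to [jsd_raw()] and rank genes by how much they separate (high
#' gwJSD) or unite (low gwJSD) the two stage transcriptomes.
#'
#' @inheritParams jsd_raw
#' @param label optional label for the stage pair.
#' @return an object of class `GeneWiseJSD` with elements `values` (named
#'   per-orthologue terms) and `pair_label`.
#' @export
gene_wise_jsd <- function(p, q, label = NULL) {
  pv <- as_prob(p); qv <- as_prob(q)
  v <- jsd_terms(pv, qv)
  nm <- if (inherits(p, "StageDistribution")) p$orthologues else names(pv)
  names(v) <- nm
  structure(list(values = v, pair_label = label), class = "GeneWiseJSD")
}

# Column-normalize a non-negative matrix to per-column distributions.
#' @keywords internal
#' @noRd
simplex_columns <- function(x) {
  s <- colSums(x)
  if (any(s == 0)) {
    stop("all-zero stage: ", colnames(x)[which(s == 0)[1]], call. = FALSE)
  }
  sweep(x, 2, s, "/")
}

# JSD grid between all column pairs of two column-stochastic matrices.
#' @keywords internal
#' @noRd
jsd_grid <- function(pa, pb) {
  out <- matrix(NA_real_, ncol(pa), ncol(pb),
                dimnames = list(colnames(pa), colnames(pb)))
  for (i in seq_len(ncol(pa))) {
    for (j in seq_len(ncol(pb))) {
      out[i, j] <- sum(jsd_terms(pa[, i], pb[, j]))
    }
  }
  out
}

#' Stage-pair JSD matrix between two species
#'
#' Computes the raw JSD for every stage pair over the shared one-to-one
#' orthologue set. Both matrices must be quantile-transformed; replicates
#' are averaged first and each stage column is simplex-normalized.
#'
#' @param m_a,m_b `ExpressionMatrix` objects on layer
#'   `"quantile_uniform"`.
#' @param orthologues data.frame with columns `gene_a`, `gene_b` (from
#'   [one_to_one()]).
#' @return an object of class `JSDMatrix` with the `raw` grid (stages of
#'   A x stages of B), `n_orthologues` and `comparison` label.
#' @export
stage_pair_matrix <- function(m_a, m_b, orthologues) {
  assert_that(nrow(orthologues) > 0, "empty orthologue list")
  assert_that(m_a$layer == "quantile_uniform" &&
                m_b$layer == "quantile_uniform",
              "both matrices must be on layer 'quantile_uniform'")
  ma <- average_replicates(m_a)
  mb <- average_replicates(m_b)
  pa <- simplex_columns(ma$values[orthologues$gene_a, , drop = FALSE])
  pb <- simplex_columns(mb$values[orthologues$gene_b, , drop = FALSE])
  structure(list(raw = jsd_grid(pa, pb),
                 n_orthologues = nrow(orthologues),
                 comparison = paste(m_a$species_id, m_b$species_id,
                                    sep = "_vs_")),
            class = "JSDMatrix")
}

#' @export
print.JSDMatrix <- function(x, ...) {
  cat(sprintf("JSDMatrix %s: %d x %d stages, %d orthologues%s\n",
              x$comparison, nrow(x$raw), ncol(x$raw), x$n_orthologues,
              if (!is.null(x$boot_mean)) ", bootstrapped" else ""))
  invisible(x)
}

#' Bootstrap the stage-pair JSD matrix
#'
#' Resamples the orthologue pair list with replacement (`B` replicates,
#' same size as the original set) and records the per-cell mean and
#' standard deviation of the raw JSD grid across replicates.
#' Deterministic given `seed`.
#'
#' @inheritParams stage_pair_matrix
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @return a `JSDMatrix` with `raw`, `boot_mean`, `boot_sd`, `B`.
#' @export
bootstrap_jsd <- function(m_a, m_b, orthologues, B = 250L, seed = 1L) {
  assert_that(B >= 2, "bootstrap needs B >= 2")
  base <- stage_pair_matrix(m_a, m_b, orthologues)
  ma <- average_replicates(m_a)
  mb <- average_replicates(m_b)
  xa <- ma$values[orthologues$gene_a, , drop = FALSE]
  xb <- mb$values[orthologues$gene_b, , drop = FALSE]
  n <- nrow(orthologues)
  acc <- matrix(0, nrow(base$raw), ncol(base$raw))
  acc2 <- acc
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      g <- jsd_grid(simplex_columns(xa[idx, , drop = FALSE]),
                    simplex_columns(xb[idx, , drop = FALSE]))
      acc <- acc + g
      acc2 <- acc2 + g^2
    }
  })
  mean_g <- acc / B
  var_g <- pmax(acc2 / B - mean_g^2, 0) * B / (B - 1)
  dimnames(mean_g) <- dimnames(base$raw)
  sd_g <- sqrt(var_g)
  dimnames(sd_g) <- dimnames(base$raw)
  base$boot_mean <- mean_g
  base$boot_sd <- sd_g
  base$B <- B
  base$seed <- seed
  base
}

#' Adjusted JSD grid of one comparison
#'
#' Divides the (bootstrap mean, when available, else raw) grid by the
#' number of one-to-one orthologues of the comparison, making grids of
#' comparisons with different orthologue counts commensurable.
#'
#' @param x a `JSDMatrix`.
#' @return numeric matrix of adjusted values.
#' @export
adjusted_jsd <- function(x) {
  assert_that(inherits(x, "JSDMatrix"), "not a JSDMatrix")
  (x$boot_mean %||% x$raw) / x$n_orthologues
}

#' Min-max normalization of adjusted JSD grids
#'
#' Rescales adjusted grids to [0, 1] as (x - min)/(max - min), pooling
#' the minimum and maximum either over all cells of all comparisons
#' (`scope = "global"`, the normalized JSD) or within each comparison
#' (`scope = "per_comparison"`, the relative JSD).
#'
#' @param grids a `JSDMatrix` or a list of them.
#' @param scope `"global"` or `"per_comparison"`.
#' @return the input objects with a `normalized` (global) or `relative`
#'   (per comparison) grid added; a single input comes back unwrapped.
#' @export
normalize_jsd <- function(grids, scope = c("global", "per_comparison")) {
  scope <- match.arg(scope)
  single <- inherits(grids, "JSDMatrix")
  if (single) grids <- list(grids)
  adj <- lapply(grids, adjusted_jsd)
  rescale <- function(x, lo, hi) {
    if (hi == lo) {
      stop("degenerate collection: max adjusted JSD equals min",
           call. = FALSE)
    }
    (x - lo) / (hi - lo)
  }
  if (scope == "global") {
    lo <- min(unlist(adj)); hi <- max(unlist(adj))
    for (i in seq_along(grids)) {
      grids[[i]]$adjusted <- adj[[i]]
      grids[[i]]$normalized <- rescale(adj[[i]], lo, hi)
    }
  } else {
    for (i in seq_along(grids)) {
      grids[[i]]$adjusted <- adj[[i]]
      grids[[i]]$relative <- rescale(adj[[i]], min(adj[[i]]), max(adj[[i]]))
    }
  }
  if (single) grids[[1]] else grids
}

#' Similarity-driving genes from the gene-wise JSD distribution
#'
#' Estimates a Gaussian kernel density of the gwJSD values (Silverman's
#' rule bandwidth, 512-point grid from 0 to the maximum), locates the
#' density mode, and returns the genes with gwJSD strictly below 25% of
#' the mode location — the genes driving the similarity of the two
#' stages.
#'
#' @param g a `GeneWiseJSD` (>= 30 values).
#' @param mode_fraction threshold as a fraction of the mode location.
#' @param bw bandwidth selector passed to [stats::density()].
#' @param n_grid number of density evaluation points.
#' @return an object of class `SimilarityDrivers` with elements `mode`,
#'   `threshold`, `drivers` (character vector), `density`.
#' @export
similarity_drivers <- function(g, mode_fraction = 0.25, bw = "nrd0",
                               n_grid = 512L) {
  x <- if (inherits(g, "GeneWiseJSD")) g$values else g
  assert_that(length(x) >= 30, "need >= 30 gwJSD values")
  if (max(x) == min(x)) {
    stop("degenerate density: all gwJSD values are equal", call. = FALSE)
  }
  d <- stats::density(x, bw = bw, n = n_grid, from = 0, to = max(x))
  mode <- d$x[which.max(d$y)]
  threshold <- mode_fraction * mode
  structure(list(mode = mode, threshold = threshold,
                 drivers = names(x)[x < threshold], density = d),
            class = "SimilarityDrivers")
}

#' @export
print.SimilarityDrivers <- function(x, ...) {
  cat(sprintf("SimilarityDrivers: mode=%.4g, threshold=%.4g, %d drivers\n",
              x$mode, x$threshold, length(x$drivers)))
  invisible(x)
}
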