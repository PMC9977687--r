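#' Standardize gene profiles for clustering
#'
#' Averages replicates, optionally drops genes never expressed above
#' `threshold`, z-scores every remaining gene profile across stages
#' (mean 0, SD 1 with the n - 1 denominator), and removes zero-variance
#' profiles with a logged count.
#'
#' @param m an `ExpressionMatrix` on layer `"normalized_counts"` or
#'   `"tpm"`.
#' @param drop_unexpressed drop genes with no value strictly above
#'   `threshold` at any stage.
#' @param threshold expression threshold used by the drop rule; default 0
#'   (any expression). Use 2 on a TPM layer for the canonical rule.
#' @return an `ExpressionMatrix` on layer `"zscore"`.
#' @export
standardize_profiles <- function(m, drop_unexpressed = TRUE, threshold = 0) {
  assert_that(inherits(m, "ExpressionMatrix"), "not an ExpressionMatrix")
  assert_that(m$layer %in% c("normalized_counts", "tpm"),
              "standardize_profiles expects layer 'normalized_counts' or 'tpm'")
  mm <- average_replicates(m)
  x <- mm$values
  if (drop_unexpressed) {
    keep <- apply(x, 1, max) > threshold
    if (sum(!keep) > 0) {
      message(sum(!keep), " of ", nrow(x),
              " genes discarded as unexpressed")
    }
    x <- x[keep, , drop = FALSE]
  }
  assert_that(nrow(x) > 0, "all genes removed: nothing to standardize")
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    message(sum(flat), " zero-variance gene profiles removed")
    x <- x[!flat, , drop = FALSE]
    mu <- mu[!flat]
    sdv <- sdv[!flat]
  }
  assert_that(nrow(x) > 0, "all genes removed: nothing to standardize")
  z <- (x - mu) / sdv
  expression_matrix(z, mm$species_id, mm$stage_info, "zscore")
}

#' Estimate the fuzzy c-means fuzzifier from data dimensionality
#'
#' Empirical relation between the fuzzifier m and the dataset shape
#' (Schwammle & Jensen 2010), the common default in soft clustering of
#' expression time courses.
#'
#' @param z an `ExpressionMatrix` on layer `"zscore"`, or a numeric matrix.
#' @return fuzzifier m > 1.
#' @export
estimate_fuzzifier <- function(z) {
  x <- if (inherits(z, "ExpressionMatrix")) z$values else z
  N <- nrow(x)
  D <- ncol(x)
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means clustering of standardized stage profiles
#'
#' Standard fuzzy c-means: memberships updated proportionally to
#' distance^(-2/(m-1)), centroids as membership^m-weighted means, iterated
#' until the maximum centroid shift falls below `tol` or `max_iter` is
#' reached. The best of `restarts` random initializations (by final
#' objective) is returned; the result is deterministic given `seed`.
#'
#' @param z an `ExpressionMatrix` on layer `"zscore"` (genes x stages).
#' @param k number of clusters, `1 <= k <= n_genes`.
#' @param m fuzzifier > 1; `NULL` uses [estimate_fuzzifier()].
#' @param seed integer seed.
#' @param restarts number of random initializations.
#' @param tol convergence tolerance on the centroid shift.
#' @param max_iter iteration cap per restart.
#' @return an object of class `ClusterModel` with elements `k`, `m`,
#'   `centroids` (k x stages), `membership` (genes x k), `assignments`
#'   (named integer, argmax with lowest-index tie-break), `objective`,
#'   `seed`, `iterations`, `converged`.
#' @export
fuzzy_cmeans <- function(z, k, m = NULL, seed = 1L, restarts = 5L,
                         tol = 1e-6, max_iter = 1000L) {
  x <- if (inherits(z, "ExpressionMatrix")) z$values else as.matrix(z)
  n <- nrow(x)
  assert_that(k >= 1, "k must be >= 1")
  assert_that(k <= n, paste0("k = ", k, " exceeds the number of genes (",
                             n, ")"))
  if (is.null(m)) m <- estimate_fuzzifier(x)
  assert_that(m > 1, "fuzzifier m must be > 1")

  fit_one <- function() {
    C <- x[sample.int(n, k), , drop = FALSE]
    u <- NULL
    conv <- FALSE
    it <- 0L
    trace <- numeric(0)
    expo <- -1 / (m - 1)
    for (it in seq_len(max_iter)) {
      d2 <- pmax(outer(rowSums(x^2), rep(1, k)) +
                   matrix(rowSums(C^2), n, k, byrow = TRUE) -
                   2 * x %*% t(C), 0)
      w <- d2^expo
      zero <- d2 < .Machine$double.eps
      hit <- rowSums(zero) > 0
      u <- w / rowSums(w)
      if (any(hit)) {
        u[hit, ] <- zero[hit, , drop = FALSE] /
          rowSums(zero[hit, , drop = FALSE])
      }
      um <- u^m
      trace <- c(trace, sum(um * d2))
      Cnew <- (t(um) %*% x) / colSums(um)
      shift <- max(abs(Cnew - C))
      C <- Cnew
      if (shift < tol) {
        conv <- TRUE
        break
      }
    }
    d2 <- pmax(outer(rowSums(x^2), rep(1, k)) +
                 matrix(rowSums(C^2), n, k, byrow = TRUE) -
                 2 * x %*% t(C), 0)
    list(centroids = C, membership = u, objective = sum((u^m) * d2),
         iterations = it, converged = conv, objective_trace = trace)
  }

  best <- with_seed(seed, {
    fits <- lapply(seq_len(max(1L, restarts)), function(i) fit_one())
    fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  })
  if (!best$converged) {
    warning("fuzzy c-means did not converge within ", max_iter,
            " iterations; returning best state", call. = FALSE)
  }
  rownames(best$centroids) <- paste0("cluster_", seq_len(k))
  colnames(best$centroids) <- colnames(x)
  dimnames(best$membership) <- list(rownames(x), rownames(best$centroids))
  assign <- max.col(best$membership, ties.method = "first")
  names(assign) <- rownames(x)
  structure(list(k = k, m = m, centroids = best$centroids,
                 membership = best$membership, assignments = assign,
                 objective = best$objective, seed = seed,
                 iterations = best$iterations, converged = best$converged,
                 objective_trace = best$objective_trace),
            class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("ClusterModel: k=%d, m=%.3f, %d genes, objective=%.4g%s\n",
              x$k, x$m, nrow(x$membership), x$objective,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Minimum centroid distance across a range of cluster numbers
#'
#' For each k in `k_range`, fits a fuzzy c-means model and records the
#' minimum pairwise Euclidean distance among its centroids — the summary
#' curve the elbow rule for choosing k is applied to.
#'
#' @inheritParams fuzzy_cmeans
#' @param k_range integer vector of candidate cluster numbers (all >= 2).
#' @return data.frame with columns `k` and `d_min`.
#' @export
min_centroid_distance <- function(z, k_range, m = NULL, seed = 1L,
                                  restarts = 5L) {
  assert_that(all(k_range >= 2), "k_range must lie in [2, n_genes]")
  d_min <- vapply(seq_along(k_range), function(i) {
    fit <- fuzzy_cmeans(z, k_range[i], m = m,
                        seed = derive_seed(seed, i), restarts = restarts)
    min(stats::dist(fit$centroids))
  }, numeric(1))
  data.frame(k = as.integer(k_range), d_min = d_min)
}

#' Elbow selection of the cluster number
#'
#' Picks the knee of the minimum centroid distance curve: the interior k
#' at which the following drop most exceeds the preceding one (the
#' largest downward kink, i.e. the maximal negative discrete second
#' difference). A preceding rise of d_min — fit stochasticity, not a
#' real improvement — is clamped to a zero preceding drop so it cannot
#' masquerade as a kink. Ties go to the smallest k; on a perfectly
#' linear decay every interior point ties, so the smallest interior k
#' is returned.
#'
#' @param series data.frame with strictly increasing `k` and `d_min`
#'   (from [min_centroid_distance()]); at least 3 points.
#' @return the selected k (integer).
#' @export
select_k_elbow <- function(series) {
  assert_that(is.data.frame(series) && all(c("k", "d_min") %in% names(series)),
              "series must have columns k and d_min")
  assert_that(nrow(series) >= 3, "elbow selection needs >= 3 points")
  assert_that(all(diff(series$k) > 0), "k must be strictly increasing")
  d <- series$d_min
  i <- 2:(length(d) - 1)
  kink <- (d[i] - d[i + 1]) - pmax(0, d[i - 1] - d[i])
  as.integer(series$k[i[which.max(kink)]])
}

#' Harden a fuzzy clustering into discrete assignments
#'
#' Argmax of the membership matrix with ties broken by the lowest cluster
#' index; genes whose best membership falls below `min_membership` are
#' excluded with a logged count.
#'
#' @param model a `ClusterModel`.
#' @param min_membership minimum best-membership required to keep a gene.
#' @return data.frame with columns `gene`, `cluster` (integer),
#'   `membership`.
#' @export
harden_assignments <- function(model, min_membership = 0) {
  assert_that(inherits(model, "ClusterModel"), "not a ClusterModel")
  u <- model$membership
  cl <- max.col(u, ties.method = "first")
  best <- u[cbind(seq_len(nrow(u)), cl)]
  out <- data.frame(gene = rownames(u), cluster = cl, membership = best,
                    stringsAsFactors = FALSE)
  if (min_membership > 0) {
    drop <- out$membership < min_membership
    if (any(drop)) {
      message(sum(drop), " genes below the membership cutoff excluded")
    }
    out <- out[!drop, , drop = FALSE]
  }
  out
}
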