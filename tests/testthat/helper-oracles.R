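# Independent oracles used to check the package implementations. These
# deliberately avoid the code paths they verify (brute-force enumeration,
# naive loops, hand-rolled formulas).

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  si <- s(tab)
  sr <- s(rowSums(tab))
  sc <- s(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expct <- sr * sc / n2
  (si - expct) / ((sr + sc) / 2 - expct)
}

# Upper-tail hypergeometric p by exhaustive enumeration of all C(N, n)
# draws of n elements from a universe of N, of which the first K form
# set A: P(overlap >= ov).
oracle_hyper_enum <- function(ov, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= ov)
}

# Two-tailed Fisher p by enumeration of all 2x2 tables with the observed
# margins, summing probabilities of tables at most as probable.
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  as <- max(0, c1 - (N - r1)):min(r1, c1)
  pr <- vapply(as, function(x) {
    choose(r1, x) * choose(N - r1, c1 - x) / choose(N, c1)
  }, numeric(1))
  p_obs <- pr[as == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Per-term JSD oracle: scalar loop, independent of the vectorized kernel.
oracle_jsd_terms <- function(p, q) {
  vapply(seq_along(p), function(i) {
    m2 <- (p[i] + q[i]) / 2
    tp <- if (p[i] > 0) p[i] * log2(p[i] / m2) else 0
    tq <- if (q[i] > 0) q[i] * log2(q[i] / m2) else 0
    (tp + tq) / 2
  }, numeric(1))
}

# Small two-species ExpressionMatrix fixture on a given layer.
make_toy_matrix <- function(values, layer = "tpm", species = "toy",
                            phases = NULL, replicate_map = NULL) {
  n_st <- if (is.null(replicate_map)) ncol(values) else length(replicate_map)
  st <- if (is.null(replicate_map)) colnames(values) else names(replicate_map)
  info <- data.frame(stage = st, ordinal = seq_len(n_st),
                     phase = phases %||% rep("larval", n_st),
                     stringsAsFactors = FALSE)
  expression_matrix(values, species, info, layer,
                    replicate_map = replicate_map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
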