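test_that("read_expression_table round-trips and validates input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  vals <- matrix(c(1.5, 0, 3, 2, 4.25, 6), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  writeLines(c("gene\ts1\ts2",
               "g1\t1.5\t2",
               "g2\t0\t4.25",
               "g3\t3\t6"), tmp)
  m <- read_expression_table(tmp, list(species_id = "sp", layer = "tpm"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m$values), unname(vals))
  expect_equal(m$layer, "tpm")

  # write/read round trip on a synthetic fixture
  b <- simulate_dataset(simulation_config(
    n_orthologues = 40L, n_specific = 5L, seed = 3L))
  em <- b$expression$species_a$tpm
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, f2)
  back <- read_expression_table(f2, list(
    species_id = "species_a", layer = "tpm",
    stage_info = em$stage_info, replicate_map = em$replicate_map))
  expect_equal(back$values, em$values, tolerance = 1e-12)

  # duplicate gene row names the first duplicate
  writeLines(c("gene\ts1", "g1\t1", "g1\t2"), tmp)
  expect_error(read_expression_table(tmp, list(species_id = "sp",
                                               layer = "tpm")), "g1")
  # non-numeric cell names row and column
  writeLines(c("gene\ts1\ts2", "g1\t1\tx"), tmp)
  expect_error(read_expression_table(tmp, list(species_id = "sp",
                                               layer = "tpm")),
               "row 1.*s2")
})

test_that("average_replicates averages per stage and matches a loop", {
  vals <- matrix(c(2, 4, 1, 3), nrow = 1,
                 dimnames = list("g1", c("a_r1", "a_r2", "b_r1", "b_r2")))
  m <- make_toy_matrix(vals, layer = "counts",
                       replicate_map = list(a = c("a_r1", "a_r2"),
                                            b = c("b_r1", "b_r2")))
  avg <- average_replicates(m)
  expect_equal(unname(avg$values["g1", ]), c(3, 2))
  expect_null(avg$replicate_map)

  # single replicate leaves values unchanged
  m1 <- make_toy_matrix(matrix(c(5, 7), 1, dimnames = list("g", c("a", "b"))),
                        layer = "tpm",
                        replicate_map = list(a = "a", b = "b"))
  expect_equal(unname(average_replicates(m1)$values[1, ]), c(5, 7))

  # random 5x6, 2 reps/stage, against an independent loop
  set.seed(42)
  x <- matrix(runif(30), 5, 6,
              dimnames = list(paste0("g", 1:5),
                              paste0(rep(c("s1", "s2", "s3"), each = 2),
                                     "_r", 1:2)))
  rmap <- list(s1 = c("s1_r1", "s1_r2"), s2 = c("s2_r1", "s2_r2"),
               s3 = c("s3_r1", "s3_r2"))
  got <- average_replicates(make_toy_matrix(x, "tpm",
                                            replicate_map = rmap))$values
  for (s in names(rmap)) {
    for (g in rownames(x)) {
      expect_equal(got[g, s], mean(x[g, rmap[[s]]]))
    }
  }
})

test_that("size_factor_normalize implements median-of-ratios", {
  # columns that are scalar multiples of one vector equalize
  base <- c(10, 20, 5, 40)
  x <- cbind(s1 = base, s2 = 2 * base, s3 = 0.5 * base)
  rownames(x) <- paste0("g", 1:4)
  m <- make_toy_matrix(x, "counts")
  norm <- size_factor_normalize(m)
  expect_equal(norm$values[, "s1"], norm$values[, "s2"])
  expect_equal(norm$values[, "s1"], norm$values[, "s3"])
  expect_equal(norm$layer, "normalized_counts")

  # equal columns give unit size factors and an unchanged matrix
  y <- cbind(s1 = base, s2 = base)
  rownames(y) <- paste0("g", 1:4)
  m2 <- size_factor_normalize(make_toy_matrix(y, "counts"))
  expect_equal(unname(attr(m2, "size_factors")), c(1, 1))
  expect_equal(m2$values, y)

  # random count matrix against a direct reimplementation
  set.seed(7)
  z <- matrix(rpois(200, 50) + 1, 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  sf_got <- attr(size_factor_normalize(make_toy_matrix(z, "counts")),
                 "size_factors")
  ref <- exp(rowMeans(log(z)))
  sf_exp <- apply(z, 2, function(col) median(col / ref))
  expect_equal(unname(sf_got), unname(sf_exp), tolerance = 1e-12)

  # no all-positive gene -> error
  z0 <- cbind(s1 = c(0, 1), s2 = c(1, 0))
  rownames(z0) <- c("g1", "g2")
  expect_error(size_factor_normalize(make_toy_matrix(z0, "counts")),
               "pseudo-reference")
})

test_that("expressed_genes applies the strict >2 TPM rule", {
  x <- rbind(low = c(1.9, 1.2), boundary = c(2.0, 1.0),
             hit = c(2.1, 0), zero = c(0, 0))
  colnames(x) <- c("s1", "s2")
  m <- make_toy_matrix(x, "tpm")
  expect_equal(expressed_genes(m), "hit")
  expect_error(expressed_genes(make_toy_matrix(x, "counts")), "tpm")

  # monotone in the threshold: raising it never adds genes
  set.seed(1)
  y <- matrix(rexp(300, 1 / 3), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  my <- make_toy_matrix(y, "tpm")
  prev <- expressed_genes(my, threshold = 0)
  for (thr in c(1, 2, 4, 8)) {
    cur <- expressed_genes(my, threshold = thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("quantile_transform maps ranks onto the uniform grid", {
  x <- cbind(s1 = c(3, 1, 4, 1.5, 9), s2 = rep(2, 5))
  rownames(x) <- paste0("g", 1:5)
  q <- quantile_transform(make_toy_matrix(x, "tpm"))
  # strictly increasing column of length 5 hits (0, .25, .5, .75, 1)
  expect_equal(unname(q$values[order(x[, 1]), "s1"]),
               c(0, 0.25, 0.5, 0.75, 1))
  # constant column collapses to a single value
  expect_equal(unname(q$values[, "s2"]), rep(0.5, 5))
  expect_equal(q$layer, "quantile_uniform")

  # rank order preserved, output in [0, 1], ties share the mean rank
  set.seed(5)
  y <- matrix(sample(1:20, 60, replace = TRUE), 20, 3,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  qy <- quantile_transform(make_toy_matrix(y, "tpm"))$values
  expect_true(all(qy >= 0 & qy <= 1))
  for (j in 1:3) {
    expect_equal(order(qy[, j]), order(y[, j]))
    expect_equal(unname(qy[, j]),
                 unname(rank(y[, j], ties.method = "average") - 1) / 19)
  }
})

test_that("quantile_normalize equalizes column distributions", {
  # hand example: (1,2,3) and (4,5,6) both become (2.5, 3.5, 4.5)
  x <- cbind(s1 = c(1, 2, 3), s2 = c(6, 4, 5))
  rownames(x) <- paste0("g", 1:3)
  qn <- quantile_normalize(make_toy_matrix(x, "tpm"))$values
  expect_equal(unname(qn[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "s2"]), c(4.5, 2.5, 3.5))

  # permutation columns become identical; idempotent; shared multiset
  set.seed(9)
  v <- exp(rnorm(30))
  y <- cbind(s1 = v, s2 = sample(v), s3 = sample(v))
  rownames(y) <- paste0("g", 1:30)
  my <- make_toy_matrix(y, "tpm")
  q1 <- quantile_normalize(my)
  # permutation columns carry identical value multisets afterwards
  expect_equal(unname(sort(q1$values[, 1])), unname(sort(q1$values[, 2])))
  expect_equal(unname(sort(q1$values[, 1])), unname(sort(q1$values[, 3])))
  # and the ranks within each column are untouched
  expect_equal(order(q1$values[, 2]), order(y[, 2]))
  q2 <- quantile_normalize(q1)
  expect_equal(q2$values, q1$values, tolerance = 1e-12)

  # agrees with the limma reference implementation on tie-free data
  skip_if_not_installed("limma")
  z <- matrix(exp(rnorm(200)), 40, 5,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  got <- quantile_normalize(make_toy_matrix(z, "tpm"))$values
  expect_equal(unname(got), unname(limma::normalizeQuantiles(z)),
               tolerance = 1e-12)
})
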