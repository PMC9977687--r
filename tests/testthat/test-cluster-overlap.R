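toy_map <- function() {
  orthology_map(list(
    OG1 = list(A = "a1", B = "b1"),
    OG2 = list(A = "a2", B = "b2"),
    OG3 = list(A = c("a3", "a3b"), B = "b3"),   # paralogues in A
    OG4 = list(A = "a4", B = "b4"),
    OG5 = list(B = "b5")))                       # absent from A
}

test_that("orthology map parses, validates and round-trips", {
  map <- toy_map()
  o2o <- one_to_one(map, "A", "B")
  expect_equal(o2o$orthogroup, c("OG1", "OG2", "OG4"))
  expect_equal(o2o$gene_a, c("a1", "a2", "a4"))
  # a gene in two orthogroups is rejected
  expect_error(orthology_map(list(OG1 = list(A = "a1"),
                                  OG2 = list(A = "a1"))),
               "more than one orthogroup")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroups(map, f)
  back <- read_orthogroups(f)
  expect_equal(one_to_one(back, "A", "B"), o2o)
  expect_equal(sort(names(back$memberships)), sort(names(map$memberships)))
})

test_that("to_orthogroup_sets translates, dedupes and drops unmapped", {
  map <- toy_map()
  asg <- c(a1 = 1, a2 = 1, a3 = 2, a3b = 2, a4 = 2, orphan = 1)
  expect_message(sets <- to_orthogroup_sets(asg, map, "A"),
                 "1 genes without an orthogroup")
  expect_equal(sort(sets$cluster_1), c("OG1", "OG2"))
  # both paralogues collapse onto one orthogroup
  expect_equal(sort(sets$cluster_2), c("OG3", "OG4"))

  # random fixture recounted with an independent dictionary loop
  set.seed(11)
  n <- 60
  og <- paste0("OG", formatC(1:n, width = 3, flag = "0"))
  mem <- lapply(seq_len(n), function(i) list(A = paste0("ga", i)))
  names(mem) <- og
  big <- orthology_map(mem)
  cl <- sample(1:4, n, replace = TRUE)
  names(cl) <- paste0("ga", 1:n)
  sets <- to_orthogroup_sets(cl, big, "A")
  recount <- new.env()
  for (g in names(cl)) {
    key <- paste0("cluster_", cl[[g]])
    assign(key, union(get0(key, recount, ifnotfound = character(0)),
                      big$gene2og$A[[g]]), recount)
  }
  for (k in names(sets)) {
    expect_setequal(sets[[k]], get(k, recount))
  }
})

test_that("hypergeometric overlap p matches exact enumeration", {
  sets_a <- list(cluster_1 = paste0("OG", 1:5))
  sets_b <- list(cluster_1 = paste0("OG", c(1:4)))
  tab <- pairwise_overlap_tests(sets_a, sets_b, universe = 10)
  # N=10, nA=5, nB=4, overlap=4: p = 5/210 by enumeration
  expect_equal(tab$p_raw, 5 / 210, tolerance = 1e-12)
  expect_equal(tab$p_raw, oracle_hyper_enum(4, 5, 10, 4), tolerance = 1e-12)

  # zero overlap is certain: P(X >= 0) = 1
  t0 <- pairwise_overlap_tests(list(c1 = c("OG1", "OG2")),
                               list(c1 = c("OG3", "OG4")), universe = 10)
  expect_equal(t0$p_raw, 1)
  # a cluster spanning the universe forces the overlap
  tu <- pairwise_overlap_tests(list(c1 = paste0("OG", 1:6)),
                               list(c1 = paste0("OG", 1:3)), universe = 6)
  expect_equal(tu$p_raw, 1)
  expect_true(all(tab$p_adj >= tab$p_raw))
})

test_that("adjust_pvalues reproduces BH and Bonferroni", {
  expect_equal(adjust_pvalues(0.2, "BH"), 0.2)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(0.04, 3), "bonferroni"), rep(0.12, 3))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  # BH agrees with the step-up reference and is monotone in raw p
  set.seed(21)
  p <- runif(500)
  adj <- adjust_pvalues(p, "BH")
  expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("quadrant RS follows the stated ratio and its algebra", {
  q <- quadrant_spec(list(early = "cluster_e", late = "cluster_l"),
                     list(early = "cluster_e", late = "cluster_l"))
  # two singleton quadrants with mean -log10 p of 2 and 1
  tab <- data.frame(cluster_a = c("cluster_e", "cluster_l"),
                    cluster_b = c("cluster_e", "cluster_l"),
                    p_adj = c(1e-2, 1e-1))
  rs <- quadrant_relative_similarity(tab, q)
  expect_equal(rs$rs[rs$quadrant == "early-early"], 2 / 1.5)
  expect_equal(rs$rs[rs$quadrant == "late-late"], 1 / 1.5)
  expect_true(all(is.na(rs$rs[rs$quadrant %in% c("early-late",
                                                 "late-early")])))

  # all-equal adjusted p gives RS = 1 everywhere populated
  tab2 <- expand.grid(cluster_a = c("cluster_e", "cluster_l"),
                      cluster_b = c("cluster_e", "cluster_l"),
                      stringsAsFactors = FALSE)
  tab2$p_adj <- 0.05
  rs2 <- quadrant_relative_similarity(tab2, q)
  expect_equal(rs2$rs, rep(1, 4))

  # weighted identity sum(n_q RS_q) = N on random tables
  set.seed(31)
  for (rep in 1:20) {
    ea <- paste0("cluster_", 1:3)
    la <- paste0("cluster_", 4:6)
    qq <- quadrant_spec(list(early = ea, late = la),
                        list(early = ea, late = la))
    tt <- expand.grid(cluster_a = c(ea, la), cluster_b = c(ea, la),
                      stringsAsFactors = FALSE)
    tt$p_adj <- runif(nrow(tt))
    rr <- quadrant_relative_similarity(tt, qq)
    expect_equal(sum(rr$n_pairs * rr$rs), nrow(tt), tolerance = 1e-9)
  }
})

test_that("shifted_gene_sets selects the requested quadrant", {
  map <- orthology_map(list(OG1 = list(A = "a1", B = "b1"),
                            OG2 = list(A = "a2", B = "b2"),
                            OG3 = list(A = "a3", B = "b3")))
  q <- quadrant_spec(list(early = "cluster_1", late = "cluster_2",
                          excluded = "cluster_9"),
                     list(early = "cluster_1", late = "cluster_2",
                          excluded = "cluster_9"))
  asg_a <- c(a1 = 2, a2 = 1, a3 = 2)
  asg_b <- c(b1 = 1, b2 = 1, b3 = 9)
  hit <- shifted_gene_sets(asg_a, asg_b, map, "A", "B", q,
                           direction = "late_a_early_b")
  expect_equal(hit$orthogroup, "OG1")   # a1 late, b1 early
  # pair with one gene in an excluded cluster is dropped
  expect_false("OG3" %in% hit$orthogroup)
  # opposite direction finds nothing here
  none <- shifted_gene_sets(asg_a, asg_b, map, "A", "B", q,
                            direction = "early_a_late_b")
  expect_equal(nrow(none), 0L)
})

test_that("average_dynamics matches a brute-force loop", {
  set.seed(41)
  x <- matrix(rexp(40, 0.2), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  m <- make_toy_matrix(x, "tpm")
  got <- average_dynamics(paste0("g", 1:8), m)
  z <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  for (j in 1:5) expect_equal(got$mean[j], mean(z[, j]))

  # a single gene returns its own z-profile
  one <- average_dynamics("g1", m)
  expect_equal(one$mean, unname(z[1, ]))

  # smoothing adds a finite curve; empty set errors
  sm <- average_dynamics(paste0("g", 1:8), m, smooth = TRUE)
  expect_true(all(is.finite(sm$smoothed)))
  expect_error(average_dynamics(character(0), m), "empty gene set")
})
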