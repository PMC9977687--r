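test_that("classify_tf joins identifier lists against the catalogue", {
  catalogue <- list(homeodomain = c("PTHR1", "PTHR2"),
                    zinc_finger = c("PTHR3"),
                    bzip = c("PTHR4"))
  ids <- list(g1 = c("PTHR1", "PTHR3"),   # two classes
              g2 = "PTHR9",               # no match
              g3 = "PTHR4")
  got <- classify_tf(ids, catalogue)
  expect_setequal(got$g1, c("homeodomain", "zinc_finger"))
  expect_false("g2" %in% names(got))
  expect_equal(got$g3, "bzip")

  # random fixture against a brute-force join
  set.seed(13)
  cat2 <- split(paste0("ID", 1:40), rep(paste0("class", 1:8), each = 5))
  ids2 <- lapply(1:30, function(i) sample(paste0("ID", 1:60), 3))
  names(ids2) <- paste0("g", 1:30)
  got2 <- classify_tf(ids2, cat2)
  for (g in names(ids2)) {
    expected <- names(cat2)[vapply(cat2, function(v)
      length(intersect(v, ids2[[g]])) > 0, logical(1))]
    if (length(expected)) {
      expect_setequal(got2[[g]], expected)
    } else {
      expect_false(g %in% names(got2))
    }
  }
})

test_that("the shipped synthetic catalogue loads into classify_tf form", {
  cat36 <- load_tf_catalogue()
  expect_length(cat36, 36)
  expect_true(all(vapply(cat36, length, integer(1)) >= 2))
  hit <- classify_tf(list(gX = cat36[[3]][1]), cat36)
  expect_equal(hit$gX, names(cat36)[3])
})

test_that("label_enrichment computes two-tailed Fisher tests", {
  # 8 genes, 2 clusters; TF split 3:1 vs 1:3 -> (3,1;1,3), p ~ 0.4857
  asg <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 1, g5 = 2, g6 = 2, g7 = 2, g8 = 2)
  ann <- gene_annotation(
    tf_classes = list(g1 = "hd", g2 = "hd", g3 = "hd", g5 = "hd"))
  tab <- label_enrichment(asg, ann, label_kind = "tf")
  row1 <- tab[tab$cluster == 1 & tab$label == "hd", ]
  expect_equal(c(row1$a, row1$b, row1$c, row1$d), c(3, 1, 1, 3))
  expect_equal(row1$p_raw, 34 / 70, tolerance = 1e-12)
  expect_equal(row1$p_raw, oracle_fisher_enum(3, 1, 1, 3),
               tolerance = 1e-12)
  expect_equal(row1$direction, "over")

  # enrichment direction flips when the label is complemented
  ann_c <- gene_annotation(tf_classes = list(g4 = "hd", g6 = "hd",
                                             g7 = "hd", g8 = "hd"))
  tab_c <- label_enrichment(asg, ann_c, label_kind = "tf")
  row1c <- tab_c[tab_c$cluster == 1 & tab_c$label == "hd", ]
  expect_equal(row1c$direction, "under")
  expect_equal(row1c$p_raw, row1$p_raw, tolerance = 1e-12)

  # a label carried by every gene of a single cluster universe: p = 1
  asg1 <- c(g1 = 1, g2 = 1)
  annu <- gene_annotation(tf_classes = list(g1 = "hd", g2 = "hd"))
  tabu <- label_enrichment(asg1, annu, label_kind = "tf")
  expect_equal(tabu$p_raw, 1)

  # phylostratum labels route through the same machinery
  ann_ps <- gene_annotation(
    phylostratum = c(g1 = "old", g2 = "old", g3 = "young", g4 = "young",
                     g5 = "old", g6 = "young", g7 = "young", g8 = "young"),
    strata_levels = c("old", "young"))
  tab_ps <- label_enrichment(asg, ann_ps, label_kind = "phylostratum",
                             correction = "bonferroni")
  expect_true(all(tab_ps$p_adj >= tab_ps$p_raw))
  expect_setequal(unique(tab_ps$label), c("old", "young"))
})

test_that("phylostratum_profile summarizes by interpolated quantile", {
  x <- rbind(g1 = c(1, 5), g2 = c(2, 5), g3 = c(3, 5), g4 = c(4, 5),
             g5 = c(9, 9))
  colnames(x) <- c("s1", "s2")
  m <- make_toy_matrix(x, "tpm")
  ann <- gene_annotation(
    phylostratum = c(g1 = "old", g2 = "old", g3 = "old", g4 = "old",
                     g5 = "young"),
    strata_levels = c("old", "young", "missing"))
  expect_message(prof <- phylostratum_profile(m, ann), "missing")
  # (1,2,3,4) at stage s1: type-7 75th percentile is 3.25
  expect_equal(prof$value[prof$stratum == "old" & prof$stage == "s1"], 3.25)
  # constant values summarize to the constant
  expect_equal(prof$value[prof$stratum == "old" & prof$stage == "s2"], 5)
  # single-gene stratum returns the gene's value
  expect_equal(prof$value[prof$stratum == "young" & prof$stage == "s1"], 9)

  # monotone under adding a constant
  m2 <- m
  m2$values <- m$values + 10
  prof2 <- suppressMessages(phylostratum_profile(m2, ann))
  expect_equal(prof2$value, prof$value + 10)
})

test_that("tissue_restricted_sets applies the exclusivity rule", {
  x <- rbind(ant = c(5, 6, 0, 0, 0),
             both_ends = c(5, 6, 0, 7, 8),
             post = c(0, 0, 0, 7, 8),
             half_ant = c(5, 1, 0, 0, 0),
             everywhere = c(5, 5, 5, 5, 5))
  colnames(x) <- c("head", "anterior_segments", "midgut", "tail",
                   "body_wall")
  panel <- tissue_panel(x, anterior = c("head", "anterior_segments"),
                        posterior = c("tail", "body_wall"))
  sets <- tissue_restricted_sets(panel)
  expect_equal(sets$anterior, "ant")
  expect_equal(sets$posterior_trunk, "post")
  # the sets are disjoint by construction
  expect_length(intersect(sets$anterior, sets$posterior_trunk), 0)

  # lowering the threshold keeps designated expression but can evict via
  # the exclusivity clause (half_ant becomes expressed in one anterior
  # tissue only at threshold 0.5 yet everywhere-gene stays out)
  sets_low <- tissue_restricted_sets(panel, threshold = 0.5)
  expect_true("half_ant" %in% sets_low$anterior)
  expect_false("everywhere" %in% sets_low$anterior)
  # raising the threshold above the anterior levels empties the set
  sets_high <- tissue_restricted_sets(panel, threshold = 6)
  expect_length(sets_high$anterior, 0)

  expect_error(tissue_panel(x, anterior = c("head", "nope"),
                            posterior = c("tail", "body_wall")), "nope")
})

test_that("compare_dynamics matches the pooled-variance formula", {
  # 3 + 3 toy, hand-computed Student t at the first stage
  x <- rbind(a1 = c(1, 5, 3), a2 = c(2, 6, 3), a3 = c(3, 4, 2),
             b1 = c(4, 1, 2), b2 = c(6, 2, 3), b3 = c(5, 3, 1))
  colnames(x) <- c("s1", "s2", "s3")
  m <- make_toy_matrix(x, "tpm")
  res <- compare_dynamics(c("a1", "a2", "a3"), c("b1", "b2", "b3"), m)
  z <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  za <- z[1:3, 1]; zb <- z[4:6, 1]
  sp2 <- ((3 - 1) * var(za) + (3 - 1) * var(zb)) / (3 + 3 - 2)
  t_hand <- (mean(za) - mean(zb)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t[1], t_hand, tolerance = 1e-12)
  expect_equal(res$df[1], 4)
  expect_equal(res$p_adj, pmin(1, res$p_raw * 3))

  # planted 3-SD separation is detected with Bonferroni room to spare
  set.seed(17)
  up <- matrix(rnorm(40 * 4, rep(c(0, 0, 3, 3), each = 40)), 40, 4,
               dimnames = list(paste0("u", 1:40), paste0("s", 1:4)))
  dn <- matrix(rnorm(40 * 4, rep(c(3, 3, 0, 0), each = 40)), 40, 4,
               dimnames = list(paste0("d", 1:40), paste0("s", 1:4)))
  mm <- make_toy_matrix(rbind(up, dn) + 5, "tpm")
  res2 <- compare_dynamics(rownames(up), rownames(dn), mm)
  expect_true(all(res2$p_adj < 1e-3))

  expect_error(compare_dynamics("a1", c("b1", "b2"), m), ">= 2 genes")
  expect_error(compare_dynamics(c("a1", "b1"), c("b1", "b2"), m),
               "disjoint")
})
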