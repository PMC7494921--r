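test_that("pairwise_correlations recovers planted pair structure and handles degenerate features", {
  set.seed(40)
  m <- 50
  z <- rnorm(m)
  # 3 mRNA x 2 miRNA: a1~b1 and a2~b1 strongly +, a3~b1 strongly -, the
  # three b2 pairs null
  a <- rbind(a1 = z + rnorm(m, 0, 0.1),
             a2 = z + rnorm(m, 0, 0.1),
             a3 = -z + rnorm(m, 0, 0.1))
  b <- rbind(b1 = z + rnorm(m, 0, 0.1),
             b2 = rnorm(m))
  colnames(a) <- colnames(b) <- paste0("s", 1:m)
  tab <- suppressMessages(pairwise_correlations(a, b, alpha = 0.01))
  expect_identical(nrow(tab), 6L)
  expect_identical(attr(tab, "n_significant_positive"), 2L)
  expect_identical(attr(tab, "n_significant_negative"), 1L)
  # agreement with cor.test on every pair
  for (r in seq_len(nrow(tab))) {
    ct <- cor.test(a[tab$id_a[r], ], b[tab$id_b[r], ])
    expect_equal(tab$pcc[r], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(tab$p_raw[r], ct$p.value, tolerance = 1e-12)
  }

  # identical and negated features give pcc exactly +-1
  self <- suppressMessages(pairwise_correlations(
    a[1, , drop = FALSE],
    rbind(b1 = a[1, ], b2 = -a[1, ])))
  expect_equal(self$pcc, c(1, -1), tolerance = 1e-12)

  # affine rescaling leaves pcc untouched
  a_resc <- a; a_resc[1, ] <- 100 * a_resc[1, ] - 7
  tab2 <- suppressMessages(pairwise_correlations(a_resc, b))
  expect_equal(tab2$pcc, tab$pcc, tolerance = 1e-12)

  # zero-variance feature: flagged undefined, excluded from BH
  a_const <- a; a_const[3, ] <- 2
  tab3 <- suppressMessages(pairwise_correlations(a_const, b))
  expect_identical(tab3$sign[tab3$id_a == "a3"], c("undefined", "undefined"))
  expect_true(all(is.na(tab3$p_adj[tab3$id_a == "a3"])))

  expect_error(pairwise_correlations(a[, 1:2], b[, 1:2]), "at least 3")
})

test_that("welch_t_baseline matches t.test per feature and supports top-n truncation", {
  set.seed(41)
  x <- rand_layer(40, 20, seed = 41, layer = "mRNA")
  ann <- factor(rep(c("control", "case"), each = 10),
                levels = c("control", "case"))
  names(ann) <- colnames(x)
  x[1:5, ann == "case"] <- x[1:5, ann == "case"] + 3

  tab <- welch_t_baseline(x, ann)
  for (i in c(1, 3, 17, 40)) {
    tt <- t.test(x[i, ann == "case"], x[i, ann == "control"])
    expect_equal(tab$p_raw[i], tt$p.value, tolerance = 1e-12)
    expect_equal(tab$t[i], unname(tt$statistic), tolerance = 1e-12)
  }
  expect_true(all(paste0("f", 1:5) %in% selected_ids(tab)))

  top <- welch_t_baseline(x, ann, top_n = 3)
  expect_identical(sum(top$selected), 3L)
  expect_identical(sort(top$p_raw[top$selected]), sort(tab$p_raw)[1:3])

  # equal class means with common variance: P essentially 1
  x2 <- x
  x2[7, ] <- rep(c(-1, 1), 10)
  tab2 <- welch_t_baseline(x2, ann)
  expect_equal(tab2$p_raw[7], 1, tolerance = 1e-12)

  expect_error(welch_t_baseline(x[, 1:11], ann[1:11]), "per class")
})

test_that("welch_t_baseline recovers planted features on synthetic defaults", {
  ds <- default_dataset()
  tab <- welch_t_baseline(ds$layer_a, ds$annotation)
  expect_gte(recovery_metrics(selected_ids(tab), ds$truth_a)$recall, 0.9)
  # all planted features sit in the top ranks
  top <- welch_t_baseline(ds$layer_a, ds$annotation,
                          top_n = length(ds$truth_a))
  expect_gte(recovery_metrics(selected_ids(top), ds$truth_a)$recall, 0.9)
})

test_that("cross_dataset_confusion counts the 2x2 overlap over the universe", {
  universe <- paste0("g", 1:10)
  ct <- cross_dataset_confusion(c("g1", "g2"), c("g3", "g4"), universe)
  expect_identical(unlist(ct[c("a", "b", "c", "d")]),
                   c(a = 6, b = 2, c = 2, d = 0))

  ct2 <- cross_dataset_confusion(universe, universe, universe)
  expect_identical(unlist(ct2[c("a", "b", "c", "d")]),
                   c(a = 0, b = 0, c = 0, d = 10))

  expect_error(cross_dataset_confusion(c("g1", "zzz"), "g2", universe), "zzz")
})

test_that("fisher_exact: probability-mass P, odds ratios, and invariances", {
  # no-association table
  fe <- fisher_exact(confusion_table(10, 10, 10, 10))
  expect_equal(fe$odds_ratio_sample, 1)
  expect_equal(fe$p_two_sided, 1, tolerance = 1e-12)

  # agreement with stats::fisher.test on random tables
  set.seed(42)
  for (i in 1:25) {
    cts <- rpois(4, sample(c(2, 8, 30), 1)) + 1
    ft <- fisher.test(matrix(cts, 2))
    fe <- fisher_exact(matrix(cts, 2))
    expect_equal(fe$p_two_sided, ft$p.value, tolerance = 1e-10)
    expect_equal(fe$odds_ratio_cmle, unname(ft$estimate), tolerance = 1e-8)
  }

  # transpose invariance of P
  fe1 <- fisher_exact(confusion_table(12, 3, 7, 9))
  fe2 <- fisher_exact(confusion_table(12, 7, 3, 9))
  expect_equal(fe1$p_two_sided, fe2$p_two_sided, tolerance = 1e-12)

  # infinite sample odds ratio when an off-diagonal count is 0
  expect_identical(fisher_exact(confusion_table(5, 0, 4, 3))$odds_ratio_sample,
                   Inf)

  # degenerate margin
  fe0 <- fisher_exact(confusion_table(0, 0, 5, 5))
  expect_true(fe0$degenerate)
  expect_identical(fe0$p_two_sided, 1)
  expect_true(is.na(fe0$odds_ratio_sample))

  expect_error(fisher_exact(confusion_table(1, 2, 3, 4.5)), "integer")
})
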