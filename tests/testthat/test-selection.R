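test_that("chi2_pvalues matches the chi-squared(1) survival function and its contract", {
  set.seed(20)
  u <- rnorm(200)
  p <- chi2_pvalues(u)
  expect_equal(p, chi2_sf_oracle((u / sd(u))^2), tolerance = 1e-12)

  # monotone decreasing in |u|
  o <- order(abs(u))
  expect_true(all(diff(p[o]) <= 1e-15))

  # u = 0 maps to P = 1
  expect_equal(chi2_pvalues(c(0, 3, -3))[1], 1)

  expect_error(chi2_pvalues(rep(1, 5)), "degenerate component")
  expect_error(chi2_pvalues(1), "at least 2")

  # population-sd mode uses the n denominator
  up <- c(-2, 0, 2)
  sig_pop <- sqrt(mean((up - mean(up))^2))
  expect_equal(chi2_pvalues(up, "population"),
               chi2_sf_oracle((up / sig_pop)^2), tolerance = 1e-12)
})

test_that("chi-squared threshold values land on their textbook probabilities", {
  # (u/sigma)^2 = 3.841459 -> 0.05 ; = 1 -> 0.3173
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05, tolerance = 1e-6)
  expect_equal(chi2_sf_oracle(3.841459), 0.05, tolerance = 1e-6)
  expect_equal(chi2_sf_oracle(1), 0.3173105, tolerance = 1e-7)
  # and the implementation reproduces them through a crafted vector:
  # sd of u is irrelevant to the check because we compare on (u/sd)^2 via
  # the oracle identity above
  set.seed(21)
  u <- rnorm(50)
  expect_equal(chi2_pvalues(u), chi2_sf_oracle((u / sd(u))^2),
               tolerance = 1e-12)
})

test_that("bh_adjust agrees with the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(22)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("select_features applies a strict threshold and score_features is sign-invariant", {
  tab <- data.frame(id = letters[1:3], p_adj = c(0.005, 0.01, 0.5))
  sel <- select_features(tab, alpha = 0.01)
  expect_identical(sel$selected, c(TRUE, FALSE, FALSE))  # strict: 0.01 is out
  expect_error(select_features(tab, alpha = 0), "alpha")

  set.seed(23)
  u <- rnorm(100); names(u) <- paste0("g", 1:100)
  s1 <- score_features(u, component = 2L, layer = "mRNA")
  s2 <- score_features(-u, component = 2L, layer = "mRNA")
  expect_identical(s1$selected, s2$selected)
  expect_equal(s1$p_raw, s2$p_raw, tolerance = 1e-14)
  expect_true(all(s1$p_adj >= s1$p_raw - 1e-15))

  # inverting the chi2/BH chain: 3 far-out features among 97 nulls. The
  # spike fraction must be small because sigma is computed from the vector
  # itself: k equal spikes among m features cap (u/sigma)^2 near m/k.
  u3 <- c(rep(10, 3), rnorm(97, 0, 0.3))
  names(u3) <- paste0("g", 1:100)
  s3 <- score_features(u3, alpha = 0.01)
  expect_identical(sum(s3$selected), 3L)
  expect_identical(selected_ids(s3), paste0("g", 1:3))
})

test_that("diagnose_components reports Welch and correlation diagnostics per component", {
  a <- rand_layer(30, 12, seed = 24, prefix = "g")
  b <- rand_layer(20, 12, seed = 25, prefix = "m")
  f <- project_samples(a, b, td_factorize(collapse_over_samples(a, b), L = 4))
  ann <- factor(rep(c("control", "case"), each = 6),
                levels = c("control", "case"))
  names(ann) <- colnames(a)
  d <- diagnose_components(f, ann)
  expect_identical(d$l, 1:4)
  expect_true(all(d$t_p_rows >= 0 & d$t_p_rows <= 1))
  expect_true(all(abs(d$pcc) <= 1))
  # against the textbook routes
  expect_equal(d$t_p_rows[2],
               t.test(f$proj_rows[ann == "case", 2],
                      f$proj_rows[ann == "control", 2])$p.value,
               tolerance = 1e-12)
  expect_equal(d$pcc[3], cor(f$proj_rows[, 3], f$proj_cols[, 3]),
               tolerance = 1e-12)

  # symmetric projections with equal class means give t = 0, P = 1
  f0 <- f
  f0$proj_rows[, 1] <- rep(c(-1, 1), 6)
  f0$proj_cols[, 1] <- f0$proj_rows[, 1]
  d0 <- diagnose_components(f0, ann)
  expect_equal(d0$t_p_rows[1], 1, tolerance = 1e-12)
  expect_equal(d0$pcc[1], 1, tolerance = 1e-12)

  names(ann)[1] <- "missing_sample"
  expect_error(diagnose_components(f, ann), "s1")
})

test_that("choose_component minimizes the worse-layer P with deterministic ties", {
  d <- data.frame(l = 1:3,
                  t_p_rows = c(0.5, 1e-8, 1e-8),
                  t_p_cols = c(0.9, 1e-6, 1e-6),
                  pcc = 0, pcc_p = 1)
  expect_identical(choose_component(d), 2L)          # tie on 2 and 3 -> smaller l
  expect_identical(choose_component(d, "manual", manual_l = 2), 2L)
  expect_error(choose_component(d, "manual", manual_l = 9), "out of range")
  expect_identical(choose_component(d[1, ]), 1L)     # single component
})

test_that("the planted signal component wins the diagnostics on synthetic data", {
  ds <- default_dataset()
  r <- quiet_tdfe(ds$layer_a, ds$layer_b, ds$annotation)
  expect_identical(which.min(r$diagnostics$t_p_rows), 2L)
  expect_identical(which.min(r$diagnostics$t_p_cols), 2L)
  expect_identical(r$component, 2L)
})
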