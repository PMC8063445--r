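test_that("identical groups give logFC 0 and p 1", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE)
  fx <- make_expr(list(A = vals, B = vals))
  d <- study_design(fx$samples, baseline = "B", disease = "A")
  for (mode in c("ordinary", "moderated")) {
    ct <- compute_contrast(fx$expression, d, "A", "B", moderation = mode)
    expect_equal(ct$logFC, c(0, 0))
    expect_equal(ct$p, c(1, 1))
    expect_equal(ct$adj_p, c(1, 1))
  }
})

test_that("ordinary mode reproduces the pooled two-sample t", {
  fx <- make_expr(list(A = matrix(c(2, 4, 6), 1), B = matrix(c(1, 3, 5), 1)))
  d <- study_design(fx$samples, baseline = "B", disease = "A")
  ct <- compute_contrast(fx$expression, d, "A", "B", moderation = "ordinary")
  # independent oracle: base R pooled-variance t-test
  tt <- t.test(c(2, 4, 6), c(1, 3, 5), var.equal = TRUE)
  expect_equal(ct$logFC, 1.0)
  expect_equal(ct$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ct$df, unname(tt$parameter))
  expect_equal(ct$p, tt$p.value, tolerance = 1e-12)
  expect_equal(ct$t, 1 / 1.6329932, tolerance = 1e-6)

  # and across 50 random genes
  set.seed(21)
  a <- matrix(rnorm(150), 50)
  b <- matrix(rnorm(200, sd = 2), 50)
  fx2 <- make_expr(list(A = a, B = b))
  d2 <- study_design(fx2$samples, baseline = "B", disease = "A")
  ct2 <- compute_contrast(fx2$expression, d2, "A", "B", moderation = "ordinary")
  for (g in seq_len(50)) {
    tt <- t.test(a[g, ], b[g, ], var.equal = TRUE)
    expect_equal(ct2$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(ct2$p[g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t agrees with the limma empirical-Bayes cross-check", {
  skip_if_not_installed("limma")
  sim <- simulate_expression(sim_config(n_genes = 800, n_treatments = 1,
                                        restoration_fractions = c(T1 = 0.5),
                                        noise_sd = 0.4, noise_df = 4, seed = 8))
  ct <- compute_contrast(sim$expression, sim$design, "TG", "WT",
                         moderation = "moderated")
  m <- as.matrix(sim$expression[-1])
  rownames(m) <- sim$expression$gene_id
  keep <- grepl("^(TG|WT)_", colnames(m))
  groups <- factor(sub("_[0-9]+$", "", colnames(m)[keep]), levels = c("WT", "TG"))
  fit <- limma::eBayes(limma::lmFit(m[, keep], model.matrix(~groups)))
  expect_equal(ct$logFC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(ct, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(ct, "s2_prior"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(ct$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(ct$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("contrasts are antisymmetric and converge across modes at large n", {
  sim <- simulate_expression(sim_config(n_genes = 300, n_treatments = 1,
                                        restoration_fractions = c(T1 = 0.5),
                                        seed = 13))
  ab <- compute_contrast(sim$expression, sim$design, "TG", "WT")
  ba <- compute_contrast(sim$expression, sim$design, "WT", "TG")
  expect_equal(ab$logFC, -ba$logFC, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  # with heteroscedastic noise (finite prior df) the shrinkage washes out as
  # replicates accumulate: the moderated t approaches the ordinary t
  rel_diff <- function(n) {
    s <- simulate_expression(sim_config(n_genes = 300, n_per_group = n,
                                        n_treatments = 1,
                                        restoration_fractions = c(T1 = 0.5),
                                        frac_disease_genes = 0,
                                        noise_df = 6, seed = 14))
    mod <- compute_contrast(s$expression, s$design, "TG", "WT", "moderated")
    ord <- compute_contrast(s$expression, s$design, "TG", "WT", "ordinary")
    max(abs(mod$t - ord$t) / (1 + abs(ord$t)))
  }
  d <- vapply(c(4, 12, 50), rel_diff, numeric(1))
  expect_true(all(diff(d) < 0))
  expect_lt(d[3], 0.25)
})

test_that("zero-variance genes fall back to the moderated statistic", {
  a <- rbind(c(5, 5, 5), matrix(rnorm(30), 10))
  b <- rbind(c(3, 3, 3), matrix(rnorm(30), 10))
  fx <- make_expr(list(A = a, B = b))
  d <- study_design(fx$samples, baseline = "B", disease = "A")
  expect_warning(
    ct <- compute_contrast(fx$expression, d, "A", "B", moderation = "ordinary"),
    class = "txr_zero_variance_warning")
  expect_equal(ct$logFC[1], 2)
  expect_true(is.finite(ct$t[1]) && ct$t[1] > 0)
  expect_true(ct$p[1] < 1)
})

test_that("unknown groups and missing samples are design errors", {
  sim <- simulate_expression(sim_config(n_genes = 20, seed = 2))
  expect_error(compute_contrast(sim$expression, sim$design, "NOPE", "WT"),
               class = "txr_design_error")
  expr2 <- sim$expression[, -2]
  expect_error(compute_contrast(expr2, sim$design, "TG", "WT"),
               class = "txr_design_error")
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(1.0), 1.0)
  expect_error(adjust_bh(c(0.5, 1.2)), class = "txr_value_error")

  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), brute_bh(p), tolerance = 1e-12)
  }

  # monotonicity: raising one p never lowers any adjusted value
  set.seed(100)
  for (i in 1:50) {
    p <- runif(20)
    adj <- adjust_bh(p)
    j <- sample(20, 1)
    p2 <- p
    p2[j] <- min(1, p2[j] + runif(1) * (1 - p2[j]))
    expect_true(all(adjust_bh(p2) >= adj - 1e-12))
  }
})

test_that("adjusted p-values respect their invariants on real contrasts", {
  sim <- simulate_expression(sim_config(n_genes = 400, seed = 6))
  ct <- compute_contrast(sim$expression, sim$design, "TG", "WT")
  expect_true(all(ct$adj_p >= ct$p - 1e-15))
  expect_true(all(ct$adj_p <= 1))
  o <- order(ct$p)
  expect_true(all(diff(ct$adj_p[o]) >= -1e-15))
  expect_true(all(ct$p > 0 & ct$p <= 1))
  expect_true(all(is.finite(ct$logFC)))
})
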