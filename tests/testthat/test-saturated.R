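test_that("with complete data FIML equals the closed-form ML solution", {
  sp <- ae_truth(n_per_group = 60)
  d <- simulate_dataset(sp, seed = 31)
  fit <- fit_saturated(d, "none")
  gs <- split_groups(d)
  for (g in names(gs)) {
    y <- as.matrix(gs[[g]]$pairs[, c("t1_trait1", "t1_trait2",
                                     "t2_trait1", "t2_trait2")])
    n <- nrow(y)
    expect_equal(fit$groups[[g]]$mean, colMeans(y), ignore_attr = TRUE)
    expect_equal(fit$groups[[g]]$cov, cov(y) * (n - 1) / n,
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
  expect_identical(fit$n_free, 56L)
  # and the deviance agrees with the row-by-row oracle to 1e-8 relative
  mu <- lapply(fit$groups, `[[`, "mean")
  sg <- lapply(fit$groups, `[[`, "cov")
  expect_equal(fit$minus2LL, oracle_m2ll(d, mu, sg),
               tolerance = 1e-8)
})

test_that("FIML with missing data matches the row-by-row oracle", {
  d <- rand_dataset(n_per_group = 40, missing_rate = 0.25, seed = 77)
  fit <- fit_saturated(d, "twin_order")
  mu <- lapply(fit$groups, `[[`, "mean")
  sg <- lapply(fit$groups, `[[`, "cov")
  expect_equal(fit$minus2LL, oracle_m2ll(d, mu, sg), tolerance = 1e-8)
  expect_identical(fit$n_free, 32L)
})

test_that("constraints never improve the optimum and df bookkeeping holds", {
  d <- rand_dataset(n_per_group = 50, missing_rate = 0.1, seed = 13)
  free <- fit_saturated(d, "none")
  to <- fit_saturated(d, "twin_order")
  eq <- fit_saturated(d, c("twin_order", "zyg_means_equal"))
  sx <- fit_saturated(d, c("twin_order", "zyg_means_equal",
                           "sex_means_equal"))
  expect_gte(to$minus2LL, free$minus2LL - 1e-6)
  expect_gte(eq$minus2LL, to$minus2LL - 1e-6)
  expect_gte(sx$minus2LL, eq$minus2LL - 1e-6)
  expect_identical(eq$n_free - sx$n_free, 2L)
  expect_identical(free$df, observed_count(d) - 56L)
})

test_that("all-missing pairs do not change the likelihood", {
  d <- rand_dataset(n_per_group = 25, missing_rate = 0.2, seed = 5)
  aug <- d$pairs[1, ]
  aug[, c("t1_trait1", "t1_trait2", "t2_trait1", "t2_trait2")] <- NA
  d2 <- twin_dataset(rbind(d$pairs, aug))
  expect_identical(n_pairs(d2), n_pairs(d))  # dropped at construction
  f1 <- fit_saturated(d, "twin_order")
  f2 <- fit_saturated(d2, "twin_order")
  expect_equal(f1$minus2LL, f2$minus2LL, tolerance = 1e-9)
})

test_that("correlations_from_fit does the hand arithmetic", {
  W <- matrix(c(1, 0.5, 0.5, 1), 2)
  X <- matrix(c(0.4, 0.2, 0.2, 0.4), 2)
  cv <- rbind(cbind(W, X), cbind(X, W))
  fit <- fake_sat_fit(list(MZf = cv, DZf = cv, MZm = cv, DZm = cv))
  corr <- correlations_from_fit(fit)
  expect_equal(unname(corr$r_ph), c(0.5, 0.5))
  expect_equal(corr$twin$r, rep(0.4, 8))
  expect_equal(unname(corr$ctct), rep(0.2, 4))
  # identity covariance: everything zero
  corr0 <- correlations_from_fit(
    fake_sat_fit(list(MZf = diag(4), DZf = diag(4), MZm = diag(4),
                      DZm = diag(4))))
  expect_equal(unname(corr0$r_ph), c(0, 0))
  expect_equal(corr0$twin$r, rep(0, 8))
})

test_that("correlations are invariant to rescaling a trait", {
  d <- rand_dataset(n_per_group = 60, missing_rate = 0.1, seed = 23)
  fit <- fit_saturated(d, "twin_order")
  d2 <- d
  for (cl in c("t1_trait2", "t2_trait2")) {
    d2$pairs[[cl]] <- 10 * d2$pairs[[cl]]
  }
  fit2 <- fit_saturated(d2, "twin_order")
  c1 <- correlations_from_fit(fit)
  c2 <- correlations_from_fit(fit2)
  expect_equal(c1$r_ph, c2$r_ph, tolerance = 1e-3)
  expect_equal(c1$twin$r, c2$twin$r, tolerance = 1e-3)
  expect_equal(c1$ctct, c2$ctct, tolerance = 1e-3)
})

test_that("saturated recovery: female phenotypic correlation near truth", {
  sp <- ae_truth(n_per_group = 1500, missing_rate = 0.05)
  d <- simulate_dataset(sp, seed = 202)
  corr <- correlations_from_fit(fit_saturated(d, "twin_order"))
  # generating value 0.403; 3 SE with ~3000 female pairs is about 0.05
  expect_lt(abs(corr$r_ph[["F"]] - 0.403), 0.05)
})

test_that("sex mean difference test: power and calibration (scaled down)", {
  # strong mean difference: decisive rejection
  sp <- ae_truth(n_per_group = 500)
  sp$params_by_sex$M$mu <- c(0.5, 0.5)
  d <- simulate_dataset(sp, seed = 404)
  res <- test_sex_mean_difference(d)
  expect_identical(res$delta_df, 2L)
  expect_lt(res$p, 1e-3)

  # no difference: p behaves like a null p-value (rough check, 24 reps)
  sp0 <- homogeneous_truth(n_per_group = 150)
  sp0$params_by_sex$M$mu <- c(0, 0)
  set.seed(606)
  ps <- vapply(1:24, function(i) {
    di <- simulate_dataset(sp0, seed = sample.int(1e7, 1))
    test_sex_mean_difference(di)$p
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 5)   # ~1.2 expected under the null
  expect_gt(mean(ps), 0.25)       # uniform null has mean 0.5
})
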