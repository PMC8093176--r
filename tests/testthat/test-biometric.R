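test_that("deviance matches a brute-force MVN density, incl. marginals", {
  p <- group_params(A = matrix(c(0.5, 0.2, 0.2, 0.6), 2),
                    CorD = matrix(c(0.2, 0.05, 0.05, 0.15), 2),
                    E = matrix(c(0.4, 0.1, 0.1, 0.3), 2),
                    mu = c(1, -0.5))
  params <- list(F = p, M = p)
  spec <- biometric_spec("ACE", "none")
  one <- data.frame(zygosity = "DZ", sex = "F",
                    t1_trait1 = 0.3, t1_trait2 = -0.2,
                    t2_trait1 = 1.4, t2_trait2 = 0.1)
  pad <- do.call(rbind, list(   # one complete pair in each other group
    data.frame(zygosity = "MZ", sex = "F", t1_trait1 = 0, t1_trait2 = 0,
               t2_trait1 = 0, t2_trait2 = 0),
    data.frame(zygosity = "MZ", sex = "M", t1_trait1 = 0, t1_trait2 = 0,
               t2_trait1 = 0, t2_trait2 = 0),
    data.frame(zygosity = "DZ", sex = "M", t1_trait1 = 0, t1_trait2 = 0,
               t2_trait1 = 0, t2_trait2 = 0)))
  d <- twin_dataset(rbind(one, pad))
  sig <- implied_pair_covariance(p, "ACE", "DZ")
  mu4 <- rep(p$mu, 2)
  dev <- biometric_deviance(params, spec, d)
  mu_l <- list(MZf = mu4, DZf = mu4, MZm = mu4, DZm = mu4)
  sg_l <- list(MZf = implied_pair_covariance(p, "ACE", "MZ"), DZf = sig,
               MZm = implied_pair_covariance(p, "ACE", "MZ"), DZm = sig)
  expect_equal(dev, oracle_m2ll(d, mu_l, sg_l), tolerance = 1e-10)
  # masking twin 2 leaves exactly the 2-d marginal term
  one_masked <- one
  one_masked[, c("t2_trait1", "t2_trait2")] <- NA
  dm <- twin_dataset(rbind(one_masked, pad))
  y <- c(0.3, -0.2)
  S <- sig[1:2, 1:2]
  dvec <- y - p$mu
  marg <- 2 * log(2 * pi) + log(det(S)) + drop(t(dvec) %*% solve(S, dvec))
  expect_equal(biometric_deviance(params, spec, dm) -
                 biometric_deviance(params, spec,
                                    twin_dataset(pad)),
               marg, tolerance = 1e-10)
})

test_that("non-PD implied covariance gives infinite deviance", {
  p_bad <- group_params(A = matrix(c(1, 0, 0, 1), 2),
                        CorD = matrix(0, 2, 2),
                        E = -2 * diag(2))   # indefinite total
  d <- simulate_dataset(ae_truth(5), seed = 1)
  expect_identical(
    biometric_deviance(list(F = p_bad, M = p_bad),
                       biometric_spec("ACE", "none"), d),
    Inf)
})

test_that("analytic gradient agrees with finite differences", {
  d <- simulate_dataset(ae_truth(40, missing_rate = 0.2), seed = 88)
  stats <- bivtwin:::pattern_stats(d)
  for (mode in c("none", "full")) {
    spec <- biometric_spec("ACE", mode)
    th <- bivtwin:::pack_params(bivtwin:::start_params(d, spec), spec)
    th <- th * 1.07 + 0.01
    g <- bivtwin:::grad_theta(th, spec, stats)
    gn <- vapply(seq_along(th), function(i) {
      e <- numeric(length(th)); e[i] <- 1e-6
      (bivtwin:::deviance_theta(th + e, spec, stats) -
         bivtwin:::deviance_theta(th - e, spec, stats)) / 2e-6
    }, numeric(1))
    expect_equal(g, gn, tolerance = 1e-4)
  }
})

test_that("AE recovery at n = 2000 pairs/group is within 0.05", {
  sp <- ae_truth(2000, missing_rate = 0.05)
  d <- simulate_dataset(sp, seed = 314)
  fit <- fit_biometric(d, biometric_spec("ACE", "none", drop = "C"),
                       n_starts = 2)
  est <- standardize(fit)
  expect_lt(abs(est$by_sex$F$h2[1] - 0.444), 0.05)
  expect_lt(abs(est$by_sex$F$h2[2] - 0.311), 0.05)
  expect_lt(abs(est$by_sex$M$h2[1] - 0.344), 0.05)
  expect_lt(abs(est$by_sex$F$rg - 0.719), 0.1)

  # fixed point: restarting from the optimum reproduces the deviance
  refit <- fit_biometric(d, fit$spec, starts = fit$params, n_starts = 1)
  expect_equal(refit$minus2LL, fit$minus2LL, tolerance = 1e-6)

  # nesting: the AE submodel can never beat the full ACE model
  full <- fit_biometric(d, biometric_spec("ACE", "none"), n_starts = 2,
                        extra_starts = list(fit$params))
  expect_gte(fit$minus2LL, full$minus2LL - 1e-6)
  expect_identical(full$n_free, 22L)
  expect_identical(fit$n_free, 16L)
  expect_identical(fit$df, observed_count(d) - 16L)
})

test_that("scale equivariance of the fitted model", {
  sp <- ae_truth(400)
  d <- simulate_dataset(sp, seed = 59)
  spec <- biometric_spec("ACE", "none", drop = "C")
  f1 <- fit_biometric(d, spec, n_starts = 1)
  d2 <- d
  for (cl in c("t1_trait1", "t2_trait1")) d2$pairs[[cl]] <- 3 * d2$pairs[[cl]]
  f2 <- fit_biometric(d2, spec, n_starts = 1)
  expect_equal(f2$params$F$A[1, 1], 9 * f1$params$F$A[1, 1],
               tolerance = 1e-3)
  expect_equal(f2$params$F$A[1, 2], 3 * f1$params$F$A[1, 2],
               tolerance = 1e-3)
  e1 <- as.data.frame(standardize(f1))
  e2 <- as.data.frame(standardize(f2))
  expect_equal(e1$value, e2$value, tolerance = 1e-3)
})

test_that("scalar sex limitation: shares equal across sexes, k recovers", {
  # scalar truth: male components scaled by k = (1.5, 2) gives females
  base <- demo_sim_spec()
  pm <- base$params_by_sex$M
  K <- diag(sqrt(c(1.5, 2)))
  pf <- group_params(A = K %*% pm$A %*% K, CorD = matrix(0, 2, 2),
                     E = K %*% pm$E %*% K, mu = c(0, 0))
  sp <- sim_spec("ACE", pf, pm, n_pairs = stats::setNames(rep(1000L, 4),
                                                          c("MZf", "DZf", "MZm", "DZm")))
  d <- simulate_dataset(sp, seed = 1001)
  fit <- fit_biometric(d, biometric_spec("ACE", "scalar", drop = "C"),
                       n_starts = 3)
  expect_true(fit$converged)
  expect_identical(fit$n_free, 12L)
  expect_lt(abs(fit$params$k[1] - 1.5), 0.25)
  expect_lt(abs(fit$params$k[2] - 2.0), 0.3)
  est <- standardize(fit)
  expect_equal(est$by_sex$F$h2, est$by_sex$M$h2, tolerance = 1e-9)
  # female total variance is k times the male total variance
  WF <- fit$params$F$A + fit$params$F$E
  WM <- fit$params$M$A + fit$params$M$E
  expect_equal(unname(diag(WF) / diag(WM)), unname(fit$params$k),
               tolerance = 1e-8)
})

test_that("genetic/environmental correlation formula and guards", {
  expect_equal(genetic_correlation(matrix(c(4, 2, 2, 1), 2)), 1.0)
  expect_equal(genetic_correlation(matrix(c(3, 0, 0, 5), 2)), 0)
  expect_error(genetic_correlation(matrix(c(-1, 0, 0, 1), 2)),
               "undefined")
  expect_warning(r <- genetic_correlation(matrix(c(1, 1.2, 1.2, 1), 2)),
                 "outside")
  expect_equal(r, 1.2)
  set.seed(3)
  for (i in 1:10) {
    E <- rand_psd2()
    expect_equal(environmental_correlation(E), cov2cor(E)[1, 2],
                 tolerance = 1e-12)
  }
})

test_that("standardized shares: symmetry case and algebraic identities", {
  m <- matrix(c(0.5, 0.2, 0.2, 0.4), 2)
  p <- group_params(A = m, CorD = m, E = m)
  d <- simulate_dataset(ae_truth(30), seed = 2)
  fit <- fit_biometric(d, biometric_spec("ACE", "none"), n_starts = 1)
  fit$params$F <- p; fit$params$M <- p
  est <- standardize(fit)
  for (sx in c("F", "M")) {
    s <- est$by_sex[[sx]]
    expect_equal(s$h2, c(1, 1) / 3, tolerance = 1e-12)
    expect_equal(s$c2_or_d2, c(1, 1) / 3, tolerance = 1e-12)
    expect_equal(unname(c(s$bivA, s$bivC_or_D, s$bivE)), rep(1, 3) / 3,
                 tolerance = 1e-12)
  }
  # identities on random indefinite-allowed parameter structures
  set.seed(42)
  for (i in 1:15) {
    pf <- list(A = rand_psd2(), CorD = rand_psd2(0.3),
               E = rand_psd2(), mu = c(0, 0))
    fit$params$F <- pf
    fit$params$M <- pf
    s <- standardize(fit)$by_sex$F
    expect_equal(s$h2 + s$c2_or_d2 + s$e2, c(1, 1), tolerance = 1e-10)
    expect_equal(s$bivA + s$bivC_or_D + s$bivE, 1, tolerance = 1e-10)
    rhs <- s$rg * sqrt(s$h2[1] * s$h2[2]) +
      s$rc_or_rd * sqrt(s$c2_or_d2[1] * s$c2_or_d2[2]) +
      s$re * sqrt(s$e2[1] * s$e2[2])
    expect_equal(s$r_ph_implied, rhs, tolerance = 1e-10)
  }
})

test_that("profile CI: ordering, quadratic limit for a mean parameter", {
  sp <- ae_truth(800)
  d <- simulate_dataset(sp, seed = 71)
  fit <- fit_biometric(d, biometric_spec("ACE", "none", drop = "C"),
                       n_starts = 1)
  ci <- profile_ci(fit, "h2_1_F")
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)
  expect_false(ci$open_lower || ci$open_upper)

  # the deviance is exactly quadratic in a mean parameter given the rest,
  # so the profile interval must match estimate +/- 1.96 SE from the
  # observed information (numerical Hessian over the full parameter set)
  ci_mu <- profile_ci(fit, "mu1_F")
  th <- fit$theta
  stats <- attr(fit, "stats")
  n <- length(th)
  h <- 1e-4
  H <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    ei <- numeric(n); ei[i] <- h
    ej <- numeric(n); ej[j] <- h
    H[i, j] <- H[j, i] <-
      (bivtwin:::deviance_theta(th + ei + ej, fit$spec, stats) -
       bivtwin:::deviance_theta(th + ei - ej, fit$spec, stats) -
       bivtwin:::deviance_theta(th - ei + ej, fit$spec, stats) +
       bivtwin:::deviance_theta(th - ei - ej, fit$spec, stats)) / (4 * h^2)
  }
  idx <- bivtwin:::theta_index(fit$spec)$F$mu[1]
  se <- sqrt(2 * solve(H)[idx, idx])
  wald <- qnorm(0.975) * se
  expect_equal(ci_mu$upper - ci_mu$estimate, wald, tolerance = 0.02)
  expect_equal(ci_mu$estimate - ci_mu$lower, wald, tolerance = 0.02)
})
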