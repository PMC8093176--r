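test_that("family heuristic: rMZ vs 2 rDZ per sex and trait", {
  mk_corr <- function(rmz_f, rdz_f, rmz_m, rdz_m) {
    structure(list(
      r_ph = c(F = 0.4, M = 0.3),
      twin = data.frame(
        group = rep(c("MZf", "DZf", "MZm", "DZm"), each = 2),
        trait = rep(1:2, 4),
        r = c(rmz_f, rdz_f, rmz_m, rdz_m)),
      ctct = c(MZf = 0.2, DZf = 0.1, MZm = 0.2, DZm = 0.1)),
      class = "correlation_summary")
  }
  # published female well-being correlations: 0.409 < 2 x 0.286 -> ACE;
  # the male optimism pair 0.261 > 2 x 0.111 fires under the any-trait rule
  c1 <- mk_corr(c(0.409, 0.274), c(0.286, 0.247),
                c(0.374, 0.261), c(0.198, 0.111))
  expect_identical(unname(choose_family(c1)), c("ACE", "ADE"))
  expect_identical(unname(choose_family(c1, rule = "all")),
                   c("ACE", "ACE"))
  # clear dominance signal on one trait
  c2 <- mk_corr(c(0.6, 0.3), c(0.2, 0.2), c(0.4, 0.4), c(0.2, 0.2))
  expect_identical(unname(choose_family(c2)), c("ADE", "ACE"))
  expect_identical(unname(choose_family(c2, rule = "all")),
                   c("ACE", "ACE"))
  # exact tie goes to ACE
  c3 <- mk_corr(c(0.4, 0.4), c(0.2, 0.2), c(0.4, 0.4), c(0.2, 0.2))
  expect_identical(unname(choose_family(c3)), c("ACE", "ACE"))
})

test_that("chi-square upper tail against the even-df series oracle", {
  for (df in c(2L, 4L, 6L, 8L)) {
    for (x in c(0.3, 1, 5, 9.2, 16.7, 30)) {
      expect_equal(chi2_upper_tail(x, df), chi2_sf_series(x, df),
                   tolerance = 1e-12)
    }
  }
  expect_equal(chi2_upper_tail(0, 3), 1)
  expect_equal(chi2_upper_tail(9.2, 6), chi2_sf_series(9.2, 6),
               tolerance = 1e-12)
  expect_error(chi2_upper_tail(-1, 2), "non-negative")
})

test_that("lrt bookkeeping, guards, and the 6-parameter C drop", {
  mk <- function(m2ll, n_free, n_obs = 1000) {
    list(minus2LL = m2ll, n_free = n_free, n_obs = n_obs,
         df = n_obs - n_free)
  }
  same <- lrt(mk(100, 10), mk(100, 8), labels = c("b", "n"))
  expect_equal(same$delta_minus2LL, 0)
  expect_equal(same$p, 1)
  expect_identical(same$decision, "retain nested")
  expect_error(lrt(mk(100, 8), mk(100, 10)), "fewer free parameters")
  expect_error(lrt(mk(100, 10), mk(100, 8, n_obs = 999)),
               "different data")
  expect_error(lrt(mk(100, 10), mk(99, 8)), "optimum")
  # dropping C for both sexes removes 2 x 3 = 6 parameters
  sACE <- biometric_spec("ACE", "none")
  sAE <- biometric_spec("ACE", "none", drop = "C")
  expect_identical(bivtwin:::n_free_params(sACE) -
                     bivtwin:::n_free_params(sAE), 6L)
  r <- lrt(mk(100, 22), mk(110, 16), alpha = 0.01)
  expect_identical(r$delta_df, 6L)
  expect_equal(r$p, chi2_upper_tail(10, 6))
})

test_that("AIC table arithmetic convention", {
  expect_equal(aic(list(minus2LL = 0, df = 0)), 0)
  expect_equal(aic(list(minus2LL = 500, df = 100)), 300)
})

test_that("C-drop test is conservative under an AE truth (type I)", {
  set.seed(801)
  rej <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    d <- simulate_dataset(ae_truth(400), seed = sample.int(1e7, 1))
    full <- fit_biometric(d, biometric_spec("ACE", "none"), n_starts = 1)
    ae <- fit_biometric(d, biometric_spec("ACE", "none", drop = "C"),
                        n_starts = 1,
                        extra_starts = list(
                          bivtwin:::project_drop(full$params,
                                                 biometric_spec("ACE", "none",
                                                                drop = "C"))))
    cmp <- lrt(full, ae, alpha = 0.01)
    rej <- rej + (cmp$decision == "retain base")
  }
  # boundary truth (C = 0): naive chi-square test rejects at or below alpha
  expect_lte(rej, 3L)
})

test_that("the ladder reproduces the expected sequence on AE truth", {
  d <- simulate_dataset(ae_truth(1200, missing_rate = 0.05), seed = 505)
  lad <- run_ladder(d, ladder_config(family = "ACE", scalar = TRUE,
                                     include_saturated = FALSE))
  expect_identical(lad$family, "ACE")
  expect_identical(lad$best, "AE with sex diff")
  tab <- lad$table
  # arithmetic identity on every row
  expect_equal(tab$AIC, tab$minus2LL - 2 * tab$df, tolerance = 1e-12)
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
  expect_true(all(tab$deltaLL >= 0, na.rm = TRUE))
  # monotone nesting along the main path ACE -> AE -> no sex diff
  main <- tab[match(c("ACE with sex diff", "AE with sex diff",
                      "AE no sex diff"), tab$model), ]
  expect_true(all(diff(main$minus2LL) >= -1e-6))
  # the scalar model sits between "AE with sex diff" and "AE no sex diff"
  scal <- tab$minus2LL[tab$model == "AE scalar sex limitation"]
  expect_gte(scal, main$minus2LL[2] - 1e-6)
  expect_lte(scal, main$minus2LL[3] + 1e-6)
  expect_identical(tab$ep[tab$model == "AE scalar sex limitation"], 12L)
})
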