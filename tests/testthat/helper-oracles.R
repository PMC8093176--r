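# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's pattern-compressed likelihood
# path: densities are computed pair by pair with solve()/determinant().

# row-by-row -2 log-likelihood of a twin_dataset under per-group MVN
oracle_m2ll <- function(dataset, mu_list, sigma_list) {
  y <- as.matrix(dataset$pairs[, c("t1_trait1", "t1_trait2",
                                   "t2_trait1", "t2_trait2")])
  g <- paste0(dataset$pairs$zygosity,
              ifelse(dataset$pairs$sex == "F", "f", "m"))
  tot <- 0
  for (i in seq_len(nrow(y))) {
    o <- which(!is.na(y[i, ]))
    mu <- mu_list[[g[i]]][o]
    S <- sigma_list[[g[i]]][o, o, drop = FALSE]
    d <- y[i, o] - mu
    tot <- tot + length(o) * log(2 * pi) +
      as.numeric(determinant(S, logarithm = TRUE)$modulus) +
      drop(t(d) %*% solve(S, d))
  }
  tot
}

# closed-form even-df chi-square survival function
chi2_sf_series <- function(x, df) {
  stopifnot(df %% 2 == 0)
  j <- 0:(df / 2 - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# random PSD 2x2 matrix
rand_psd2 <- function(scale = 1) {
  L <- matrix(rnorm(4, sd = scale), 2, 2)
  crossprod(L) + 1e-3 * diag(2)
}

# small random twin_dataset with the given missingness rate
rand_dataset <- function(n_per_group = 20, missing_rate = 0.2,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- sim_spec(
    family = "ACE",
    params_f = group_params(A = rand_psd2(), CorD = rand_psd2(0.5),
                            E = rand_psd2(), mu = rnorm(2)),
    params_m = group_params(A = rand_psd2(), CorD = rand_psd2(0.5),
                            E = rand_psd2(), mu = rnorm(2)),
    n_pairs = c(MZf = n_per_group, DZf = n_per_group,
                MZm = n_per_group, DZm = n_per_group),
    missing_rate = missing_rate,
    seed = sample.int(.Machine$integer.max / 2, 1))
  simulate_dataset(sp)
}

# AE world with quantitative sex differences (the demo truth, adjustable)
ae_truth <- function(n_per_group, missing_rate = 0) {
  demo_sim_spec(n_per_group = n_per_group, missing_rate = missing_rate)
}

# ACE world with quantitative sex differences
ace_truth <- function(n_per_group, missing_rate = 0) {
  sim_spec(
    family = "ACE",
    params_f = group_params(A = matrix(c(0.40, 0.20, 0.20, 0.40), 2),
                            CorD = matrix(c(0.20, 0.10, 0.10, 0.20), 2),
                            E = matrix(c(0.40, 0.10, 0.10, 0.40), 2),
                            mu = c(0, 0)),
    params_m = group_params(A = matrix(c(0.30, 0.15, 0.15, 0.30), 2),
                            CorD = matrix(c(0.25, 0.10, 0.10, 0.25), 2),
                            E = matrix(c(0.45, 0.10, 0.10, 0.45), 2),
                            mu = c(0.12, 0.31)),
    n_pairs = stats::setNames(rep(as.integer(n_per_group), 4),
                              c("MZf", "DZf", "MZm", "DZm")),
    missing_rate = missing_rate)
}

# sex-homogeneous AE world (no quantitative sex differences)
homogeneous_truth <- function(n_per_group, missing_rate = 0) {
  a <- matrix(c(0.4, 0.25, 0.25, 0.35), 2)
  e <- matrix(c(0.6, 0.15, 0.15, 0.65), 2)
  zero <- matrix(0, 2, 2)
  sim_spec(
    family = "ACE",
    params_f = group_params(A = a, CorD = zero, E = e, mu = c(0, 0)),
    params_m = group_params(A = a, CorD = zero, E = e, mu = c(0.1, 0.2)),
    n_pairs = stats::setNames(rep(as.integer(n_per_group), 4),
                              c("MZf", "DZf", "MZm", "DZm")),
    missing_rate = missing_rate)
}

# hand-built saturated_fit for correlation arithmetic tests
fake_sat_fit <- function(cov_by_group, n_pairs = 100) {
  structure(list(
    groups = lapply(cov_by_group, function(cv) list(mean = rep(0, 4),
                                                    cov = cv)),
    minus2LL = 0, n_free = 32L, n_obs = 1600L, df = 1568L,
    n_pairs = stats::setNames(rep(n_pairs, 4), names(cov_by_group)),
    constraints = "twin_order", converged = TRUE),
    class = "saturated_fit")
}
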