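# Full-information maximum likelihood for the 4-variate pair vector.
#
# The whole likelihood machinery runs on per-missingness-pattern sufficient
# statistics: within each zygosity-by-sex group, pairs sharing the same
# pattern of observed entries contribute through (n, mean, ML scatter) only.
# Every deviance evaluation is then O(#patterns), independent of the number
# of pairs, which is what makes the profile-CI and simulation suites cheap.

LOG2PI <- log(2 * pi)

# Compress one group's phenotype matrix (n x 4, NAs allowed) into pattern
# statistics: list of (obs = observed column indices, n, mean, scatter)
# with scatter the ML (1/n) cross-product about the pattern mean.
compress_group <- function(y) {
  if (nrow(y) == 0L) return(list())
  obs <- !is.na(y)
  key <- obs %*% c(1L, 2L, 4L, 8L)
  out <- list()
  for (k in sort(unique(as.integer(key)))) {
    rows <- which(key == k)
    o <- which(obs[rows[1L], ])
    yy <- y[rows, o, drop = FALSE]
    n <- nrow(yy)
    m <- colMeans(yy)
    d <- sweep(yy, 2L, m)
    out[[length(out) + 1L]] <- list(obs = o, n = n, mean = m,
                                    scatter = crossprod(d) / n)
  }
  out
}

# Pattern statistics for all four groups of a twin_dataset.
pattern_stats <- function(dataset) {
  groups <- split_groups(dataset)
  out <- lapply(groups, function(g) {
    compress_group(as.matrix(g$pairs[PHENO_COLS]))
  })
  attr(out, "n_obs") <- observed_count(dataset)
  attr(out, "n_pairs") <- vapply(groups, n_pairs, integer(1))
  out
}

# -2 log likelihood of one group under MVN(mu, sigma), mu length 4,
# sigma 4x4. Returns +Inf if any observed submatrix is not PD.
fiml_m2ll_group <- function(stats, mu, sigma) {
  tot <- 0
  for (p in stats) {
    o <- p$obs
    R <- chol_or_null(sigma[o, o, drop = FALSE])
    if (is.null(R)) return(Inf)
    logdet <- 2 * sum(log(diag(R)))
    d <- p$mean - mu[o]
    z <- backsolve(R, d, transpose = TRUE)
    tr <- sum(chol2inv(R) * p$scatter)
    tot <- tot + p$n * (length(o) * LOG2PI + logdet + tr + sum(z * z))
  }
  tot
}

# Total -2LL over the four groups; mu_list/sigma_list named by group.
fiml_m2ll <- function(stats, mu_list, sigma_list) {
  tot <- 0
  for (g in names(stats)) {
    if (!length(stats[[g]])) next
    tot <- tot + fiml_m2ll_group(stats[[g]], mu_list[[g]], sigma_list[[g]])
    if (!is.finite(tot)) return(Inf)
  }
  tot
}

# Gradient of the group -2LL with respect to sigma (4x4, treating all 16
# entries as independent) and mu (length 4). Standard MVN derivative per
# pattern: d/dSigma_o = n (Sigma_o^-1 - Sigma_o^-1 T Sigma_o^-1) with
# T = scatter + d d', and d/dmu_o = -2 n Sigma_o^-1 d.
fiml_grad_group <- function(stats, mu, sigma) {
  g_sigma <- matrix(0, 4L, 4L)
  g_mu <- numeric(4L)
  for (p in stats) {
    o <- p$obs
    R <- chol_or_null(sigma[o, o, drop = FALSE])
    if (is.null(R)) return(NULL)
    inv <- chol2inv(R)
    d <- p$mean - mu[o]
    Tm <- p$scatter + tcrossprod(d)
    g_sigma[o, o] <- g_sigma[o, o] + p$n * (inv - inv %*% Tm %*% inv)
    g_mu[o] <- g_mu[o] - 2 * p$n * drop(inv %*% d)
  }
  list(sigma = g_sigma, mu = g_mu)
}
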