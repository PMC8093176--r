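# Saturated (unstructured) means-and-covariances model for the four-group
# design: the descriptive layer (phenotypic, twin, and cross-twin
# cross-trait correlations) and the fit ceiling for the biometric models.

SAT_CONSTRAINTS <- c("none", "twin_order", "zyg_means_equal",
                     "sex_means_equal")

#' Fit the saturated model by FIML
#'
#' Estimates a mean vector and an unstructured 4x4 covariance matrix per
#' zygosity-by-sex group by maximizing the full-information likelihood of
#' each pair's observed sub-vector under multivariate normality.
#'
#' Supported constraint labels:
#' \describe{
#'   \item{`"none"`}{fully saturated: 4 means + 10 covariance parameters
#'     per group.}
#'   \item{`"twin_order"`}{means and covariance blocks equal across twin 1
#'     and twin 2 within a group (2 means, within-twin block `W`, symmetric
#'     cross-twin block `X`). This is the default, and makes the
#'     descriptive correlations well defined.}
#'   \item{`"zyg_means_equal"`}{means equal across zygosity within sex.}
#'   \item{`"sex_means_equal"`}{one common mean vector for all groups
#'     (implies equality across zygosity).}
#' }
#'
#' @param dataset a `twin_dataset` with all four groups non-empty.
#' @param constraints character vector of constraint labels (above).
#' @return object of class `saturated_fit` with per-group `mean` and `cov`,
#'   `minus2LL`, `n_free`, `n_obs`, `df` and convergence diagnostics.
#' @export
fit_saturated <- function(dataset, constraints = "twin_order") {
  constraints <- unique(constraints)
  bad <- setdiff(constraints, SAT_CONSTRAINTS)
  if (length(bad)) stop("unknown constraint label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  groups <- split_groups(dataset)
  npg <- vapply(groups, n_pairs, integer(1))
  if (any(npg == 0L)) {
    stop("all four groups must be non-empty; empty: ",
         paste(names(npg)[npg == 0L], collapse = ", "), call. = FALSE)
  }
  if (any(npg < 10L)) {
    warning("group(s) with fewer than 10 pairs: estimates may be unstable")
  }
  stats <- pattern_stats(dataset)
  twin_order <- "twin_order" %in% constraints
  mean_level <- if ("sex_means_equal" %in% constraints) "all"
                else if ("zyg_means_equal" %in% constraints) "sex"
                else "group"

  if (mean_level == "group") {
    # groups are likelihood-independent: fit each separately
    fits <- lapply(GROUPS, function(g) {
      fit_sat_group(stats[[g]], as.matrix(groups[[g]]$pairs[PHENO_COLS]),
                    twin_order)
    })
    names(fits) <- GROUPS
    out_groups <- lapply(fits, function(f) f[c("mean", "cov")])
    m2ll <- sum(vapply(fits, `[[`, numeric(1), "minus2LL"))
    n_free <- sum(vapply(fits, `[[`, numeric(1), "n_free"))
    converged <- all(vapply(fits, `[[`, logical(1), "converged"))
  } else {
    jf <- fit_sat_joint(stats, groups, twin_order, mean_level)
    out_groups <- jf$groups
    m2ll <- jf$minus2LL
    n_free <- jf$n_free
    converged <- jf$converged
  }
  if (!is.finite(m2ll)) stop("saturated fit did not converge", call. = FALSE)
  n_obs <- observed_count(dataset)
  structure(list(groups = out_groups, minus2LL = m2ll,
                 n_free = as.integer(n_free), n_obs = n_obs,
                 df = n_obs - as.integer(n_free),
                 n_pairs = npg, constraints = constraints,
                 converged = converged),
            class = "saturated_fit")
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat(sprintf("saturated_fit: -2LL = %.1f, %d free parameters, df = %d (constraints: %s)\n",
              x$minus2LL, x$n_free, x$df,
              paste(x$constraints, collapse = ", ")))
  invisible(x)
}

# --- internal machinery ------------------------------------------------

# moment starts for one group from its raw phenotype matrix
sat_moments <- function(y) {
  mu <- colMeans(y, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  cv <- suppressWarnings(stats::cov(y, use = "pairwise.complete.obs"))
  cv[!is.finite(cv)] <- 0
  diag(cv)[diag(cv) <= 0] <- 1
  # shrink toward the diagonal until PD
  lam <- 0
  while (is.null(chol_or_null((1 - lam) * cv + lam * diag(diag(cv)))) &&
         lam < 1) lam <- lam + 0.1
  (1 - lam) * cv + lam * diag(diag(cv))
  }

# covariance parameter vector <-> matrix, per group
sat_cov_par0 <- function(cv, twin_order) {
  if (twin_order) {
    W <- (cv[1:2, 1:2] + cv[3:4, 3:4]) / 2
    X <- (cv[1:2, 3:4] + t(cv[1:2, 3:4])) / 2
    L <- t(chol(W))
    c(log(L[1, 1]), L[2, 1], log(L[2, 2]), X[1, 1], (X[1, 2] + X[2, 1]) / 2,
      X[2, 2])
  } else {
    L <- t(chol(cv))
    th <- numeric(10L)
    k <- 1L
    for (j in 1:4) for (i in j:4) {
      th[k] <- if (i == j) log(L[i, i]) else L[i, j]
      k <- k + 1L
    }
    th
  }
}

sat_cov_build <- function(th, twin_order) {
  if (twin_order) {
    L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2L, 2L)
    W <- tcrossprod(L)
    X <- sym2(th[4], th[5], th[6])
    rbind(cbind(W, X), cbind(X, W))
  } else {
    L <- matrix(0, 4L, 4L)
    k <- 1L
    for (j in 1:4) for (i in j:4) {
      L[i, j] <- if (i == j) exp(th[k]) else th[k]
      k <- k + 1L
    }
    tcrossprod(L)
  }
}

n_cov_par <- function(twin_order) if (twin_order) 6L else 10L

fit_sat_group <- function(gstats, y, twin_order) {
  complete <- length(gstats) == 1L && length(gstats[[1L]]$obs) == 4L
  if (complete && !twin_order) {
    # FIML reduces to the closed-form ML solution with no missing data
    p <- gstats[[1L]]
    m2ll <- p$n * (4 * LOG2PI +
                     as.numeric(determinant(p$scatter)$modulus) + 4)
    return(list(mean = p$mean, cov = p$scatter, minus2LL = m2ll,
                n_free = 14L, converged = TRUE))
  }
  cv <- sat_moments(y)
  mu0 <- colMeans(y, na.rm = TRUE); mu0[!is.finite(mu0)] <- 0
  ncv <- n_cov_par(twin_order)
  nmu <- if (twin_order) 2L else 4L
  par0 <- c(if (twin_order) (mu0[1:2] + mu0[3:4]) / 2 else mu0,
            sat_cov_par0(cv, twin_order))
  fn <- function(th) {
    mu <- if (twin_order) rep(th[1:2], 2L) else th[1:4]
    fiml_m2ll_group(gstats, mu, sat_cov_build(th[(nmu + 1L):(nmu + ncv)],
                                              twin_order))
  }
  opt <- stats::nlminb(par0, fn, control = list(eval.max = 20000,
                                               iter.max = 5000))
  th <- opt$par
  mu <- if (twin_order) rep(th[1:2], 2L) else th[1:4]
  list(mean = mu, cov = sat_cov_build(th[(nmu + 1L):(nmu + ncv)], twin_order),
       minus2LL = opt$objective, n_free = nmu + ncv,
       converged = opt$convergence == 0L)
}

# joint fit across groups when means are tied across zygosity and/or sex
fit_sat_joint <- function(stats, groups, twin_order, mean_level) {
  ncv <- n_cov_par(twin_order)
  nmu_unit <- if (twin_order) 2L else 4L
  units <- switch(mean_level, sex = c("F", "M"), all = "common")
  unit_of <- function(g) {
    if (mean_level == "all") "common" else toupper(substr(g, 3, 3))
  }
  mu0s <- lapply(units, function(u) {
    ys <- do.call(rbind, lapply(GROUPS[vapply(GROUPS, unit_of, "") == u],
      function(g) as.matrix(groups[[g]]$pairs[PHENO_COLS])))
    m <- colMeans(ys, na.rm = TRUE); m[!is.finite(m)] <- 0
    if (twin_order) (m[1:2] + m[3:4]) / 2 else m
  })
  cov0s <- lapply(GROUPS, function(g) {
    sat_cov_par0(sat_moments(as.matrix(groups[[g]]$pairs[PHENO_COLS])),
                 twin_order)
  })
  par0 <- c(unlist(mu0s), unlist(cov0s))
  n_mu <- length(units) * nmu_unit
  fn <- function(th) {
    tot <- 0
    for (i in seq_along(GROUPS)) {
      g <- GROUPS[i]
      ui <- match(unit_of(g), units)
      m <- th[((ui - 1L) * nmu_unit + 1L):(ui * nmu_unit)]
      mu <- if (twin_order) rep(m, 2L) else m
      cth <- th[(n_mu + (i - 1L) * ncv + 1L):(n_mu + i * ncv)]
      tot <- tot + fiml_m2ll_group(stats[[g]], mu,
                                   sat_cov_build(cth, twin_order))
      if (!is.finite(tot)) return(Inf)
    }
    tot
  }
  opt <- stats::nlminb(par0, fn, control = list(eval.max = 50000,
                                               iter.max = 10000))
  th <- opt$par
  out <- list()
  for (i in seq_along(GROUPS)) {
    g <- GROUPS[i]
    ui <- match(unit_of(g), units)
    m <- th[((ui - 1L) * nmu_unit + 1L):(ui * nmu_unit)]
    cth <- th[(n_mu + (i - 1L) * ncv + 1L):(n_mu + i * ncv)]
    out[[g]] <- list(mean = if (twin_order) rep(m, 2L) else m,
                     cov = sat_cov_build(cth, twin_order))
  }
  list(groups = out, minus2LL = opt$objective,
       n_free = n_mu + 4L * ncv, converged = opt$convergence == 0L)
}

# --- descriptive correlations -----------------------------------------

#' Descriptive correlations from a saturated fit
#'
#' Converts the fitted per-group covariance matrices into the descriptive
#' statistics of the twin design: per sex, the within-person cross-trait
#' (phenotypic) correlation; per sex and zygosity, the within-trait twin
#' correlations and the cross-twin cross-trait correlation.
#'
#' @param fit a `saturated_fit`.
#' @param pool_twin_order average the two twin-order positions (and, for the
#'   phenotypic correlation, pool MZ and DZ groups weighted by pair counts).
#'   With the default `"twin_order"` constraint pooling is exact.
#' @return object of class `correlation_summary` with elements `r_ph`
#'   (named by sex), `twin` (data.frame: group, trait, r) and `ctct`
#'   (named by group).
#' @export
correlations_from_fit <- function(fit, pool_twin_order = TRUE) {
  stopifnot(inherits(fit, "saturated_fit"))
  corr_at <- function(cv, i, j) {
    v1 <- cv[i, i]; v2 <- cv[j, j]
    if (v1 <= 0 || v2 <= 0) stop("non-positive fitted variance",
                                 call. = FALSE)
    cv[i, j] / sqrt(v1 * v2)
  }
  r_ph_g <- vapply(GROUPS, function(g) {
    cv <- fit$groups[[g]]$cov
    if (pool_twin_order) (corr_at(cv, 1, 2) + corr_at(cv, 3, 4)) / 2
    else corr_at(cv, 1, 2)
  }, numeric(1))
  w <- fit$n_pairs
  r_ph <- c(F = sum(r_ph_g[c("MZf", "DZf")] * w[c("MZf", "DZf")]) /
                sum(w[c("MZf", "DZf")]),
            M = sum(r_ph_g[c("MZm", "DZm")] * w[c("MZm", "DZm")]) /
                sum(w[c("MZm", "DZm")]))
  twin <- do.call(rbind, lapply(GROUPS, function(g) {
    cv <- fit$groups[[g]]$cov
    data.frame(group = g, trait = 1:2,
               r = c(corr_at(cv, 1, 3), corr_at(cv, 2, 4)),
               stringsAsFactors = FALSE)
  }))
  ctct <- vapply(GROUPS, function(g) {
    cv <- fit$groups[[g]]$cov
    if (pool_twin_order) (corr_at(cv, 1, 4) + corr_at(cv, 2, 3)) / 2
    else corr_at(cv, 1, 4)
  }, numeric(1))
  structure(list(r_ph = r_ph, twin = twin, ctct = ctct),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("phenotypic r: F = %.3f, M = %.3f\n", x$r_ph[["F"]],
              x$r_ph[["M"]]))
  tw <- stats::reshape(x$twin, idvar = "group", timevar = "trait",
                       direction = "wide")
  for (i in seq_len(nrow(tw))) {
    cat(sprintf("%4s: twin r = %.3f / %.3f, cross-twin cross-trait = %.3f\n",
                tw$group[i], tw$r.1[i], tw$r.2[i], x$ctct[[tw$group[i]]]))
  }
  invisible(x)
}

#' Likelihood-ratio test for sex differences in trait means
#'
#' Compares a saturated model with sex-specific means (equal across
#' zygosity and twin order) against one with a single common mean vector.
#' The two mean parameters equated give the test 2 degrees of freedom.
#'
#' @param dataset a `twin_dataset`.
#' @param alpha significance threshold for the reported decision.
#' @return a `comparison_result` (see [lrt()]).
#' @export
test_sex_mean_difference <- function(dataset, alpha = 0.05) {
  base <- fit_saturated(dataset, c("twin_order", "zyg_means_equal"))
  nested <- fit_saturated(dataset, c("twin_order", "zyg_means_equal",
                                     "sex_means_equal"))
  lrt(base, nested, alpha = alpha,
      labels = c("sex-specific means", "equal means"))
}
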