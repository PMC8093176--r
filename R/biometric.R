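# Bivariate ACE/ADE variance-component model, fitted by FIML.
#
# Component covariance matrices are estimated directly (variance-component
# parameterization): they may be indefinite, and only the implied total
# per-group covariance is required to be positive definite — the evaluator
# returns an effectively infinite deviance elsewhere. This keeps
# likelihood-ratio tests of components unbiased near the zero boundary.

BIG_DEV <- 1e10

#' Specify a bivariate biometric twin model
#'
#' @param family `"ACE"` (shared environment) or `"ADE"` (non-additive
#'   genetic interpretation of the middle component).
#' @param sex_equality
#'   `"none"`: all components and means sex-specific (quantitative sex
#'   differences);
#'   `"full"`: component matrices equated across sexes (means stay
#'   sex-specific);
#'   `"scalar"`: scalar sex limitation — male components free, female total
#'   variance is `k_t` times the male total variance per trait (female
#'   components scaled by `sqrt(k)` on each trait's rows and columns), so
#'   all standardized shares are equal across sexes.
#' @param drop components to drop (fixed to zero): `NULL`, a character
#'   vector such as `"C"` / `"D"` / `"A"` applied to both sexes, or a named
#'   list like `list(F = "C")` for per-sex drops (only with
#'   `sex_equality = "none"`). `E` can never be dropped.
#' @return object of class `biometric_spec`.
#' @export
biometric_spec <- function(family = c("ACE", "ADE"),
                           sex_equality = c("none", "full", "scalar"),
                           drop = NULL) {
  family <- match.arg(family)
  sex_equality <- match.arg(sex_equality)
  full <- c("A", "CorD", "E")
  norm_drop <- function(d) {
    d <- vapply(d, function(x) {
      switch(x, C = , D = , CorD = "CorD", A = "A",
             stop("cannot drop component '", x, "'", call. = FALSE))
    }, "")
    unique(d)
  }
  comps <- list(F = full, M = full)
  if (!is.null(drop)) {
    if (is.list(drop)) {
      if (sex_equality != "none") {
        stop("per-sex drops require sex_equality = 'none'", call. = FALSE)
      }
      for (sx in names(drop)) {
        comps[[sx]] <- setdiff(comps[[sx]], norm_drop(drop[[sx]]))
      }
    } else {
      for (sx in c("F", "M")) comps[[sx]] <- setdiff(comps[[sx]],
                                                     norm_drop(drop))
    }
  }
  if (sex_equality != "none" && !identical(comps$F, comps$M)) {
    stop("sex-equated models need the same component set for both sexes",
         call. = FALSE)
  }
  structure(list(family = family, sex_equality = sex_equality,
                 components = comps),
            class = "biometric_spec")
}

#' @export
print.biometric_spec <- function(x, ...) {
  lab <- function(cs) paste(sub("CorD", if (x$family == "ACE") "C" else "D",
                                cs), collapse = "")
  cat(sprintf("biometric_spec: %s family, F: %s, M: %s, sex_equality = %s (%d free parameters)\n",
              x$family, lab(x$components$F), lab(x$components$M),
              x$sex_equality, n_free_params(x)))
  invisible(x)
}

n_free_params <- function(spec) {
  switch(spec$sex_equality,
         none = 3L * (length(spec$components$F) +
                      length(spec$components$M)) + 4L,
         full = 3L * length(spec$components$F) + 4L,
         scalar = 3L * length(spec$components$M) + 4L + 2L)
}

model_label <- function(spec) {
  comp <- paste(sub("CorD", if (spec$family == "ACE") "C" else "D",
                    spec$components$F), collapse = "")
  switch(spec$sex_equality,
         none = paste(comp, "with sex diff"),
         full = paste(comp, "no sex diff"),
         scalar = paste(comp, "scalar sex limitation"))
}

# --- parameter vector <-> structure ------------------------------------

pack_params <- function(params, spec) {
  tri <- function(m) c(m[1, 1], m[1, 2], m[2, 2])
  th <- numeric(0)
  if (spec$sex_equality == "none") {
    for (sx in c("F", "M")) {
      for (cm in spec$components[[sx]]) th <- c(th, tri(params[[sx]][[cm]]))
      th <- c(th, params[[sx]]$mu)
    }
  } else if (spec$sex_equality == "full") {
    for (cm in spec$components$F) th <- c(th, tri(params$F[[cm]]))
    th <- c(th, params$F$mu, params$M$mu)
  } else {
    for (cm in spec$components$M) th <- c(th, tri(params$M[[cm]]))
    th <- c(th, params$F$mu, params$M$mu, log(params$k))
  }
  th
}

unpack_params <- function(theta, spec) {
  zero <- matrix(0, 2L, 2L)
  take3 <- function(i) sym2(theta[i], theta[i + 1L], theta[i + 2L])
  i <- 1L
  out <- list(F = list(A = zero, CorD = zero, E = zero, mu = c(0, 0)),
              M = list(A = zero, CorD = zero, E = zero, mu = c(0, 0)),
              k = NULL)
  if (spec$sex_equality == "none") {
    for (sx in c("F", "M")) {
      for (cm in spec$components[[sx]]) {
        out[[sx]][[cm]] <- take3(i); i <- i + 3L
      }
      out[[sx]]$mu <- theta[i:(i + 1L)]; i <- i + 2L
    }
  } else if (spec$sex_equality == "full") {
    for (cm in spec$components$F) {
      m <- take3(i); i <- i + 3L
      out$F[[cm]] <- m; out$M[[cm]] <- m
    }
    out$F$mu <- theta[i:(i + 1L)]; out$M$mu <- theta[(i + 2L):(i + 3L)]
  } else {
    for (cm in spec$components$M) {
      out$M[[cm]] <- take3(i); i <- i + 3L
    }
    out$F$mu <- theta[i:(i + 1L)]; out$M$mu <- theta[(i + 2L):(i + 3L)]
    k <- exp(theta[(i + 4L):(i + 5L)])
    out$k <- k
    D <- diag(sqrt(k))
    for (cm in spec$components$M) out$F[[cm]] <- D %*% out$M[[cm]] %*% D
  }
  out
}

# per-group mean vectors and 4x4 covariances implied by a parameter
# structure under the spec's family
implied_moments <- function(params, family) {
  mu <- list(); sigma <- list()
  for (g in GROUPS) {
    sx <- toupper(substr(g, 3, 3))
    zyg <- substr(g, 1, 2)
    p <- params[[sx]]
    co <- cross_coef(family, zyg)
    W <- p$A + p$CorD + p$E
    X <- co[["a"]] * p$A + co[["c"]] * p$CorD
    mu[[g]] <- rep(p$mu, 2L)
    sigma[[g]] <- rbind(cbind(W, X), cbind(X, W))
  }
  list(mu = mu, sigma = sigma)
}

# --- deviance and gradient ---------------------------------------------

deviance_theta <- function(theta, spec, stats) {
  params <- unpack_params(theta, spec)
  mm <- implied_moments(params, spec$family)
  d <- fiml_m2ll(stats, mm$mu, mm$sigma)
  if (!is.finite(d)) BIG_DEV else d
}

# analytic gradient; valid for sex_equality "none" and "full"
grad_theta <- function(theta, spec, stats) {
  params <- unpack_params(theta, spec)
  mm <- implied_moments(params, spec$family)
  n <- length(theta)
  g <- numeric(n)
  by_sex <- list(F = list(A = matrix(0, 2, 2), CorD = matrix(0, 2, 2),
                          E = matrix(0, 2, 2), mu = numeric(2)),
                 M = list(A = matrix(0, 2, 2), CorD = matrix(0, 2, 2),
                          E = matrix(0, 2, 2), mu = numeric(2)))
  for (gp in GROUPS) {
    if (!length(stats[[gp]])) next
    gr <- fiml_grad_group(stats[[gp]], mm$mu[[gp]], mm$sigma[[gp]])
    if (is.null(gr)) return(numeric(n))  # non-PD region: flat, step rejected
    sx <- toupper(substr(gp, 3, 3))
    zyg <- substr(gp, 1, 2)
    co <- cross_coef(spec$family, zyg)
    GS <- gr$sigma
    within <- GS[1:2, 1:2] + GS[3:4, 3:4]
    cross <- GS[1:2, 3:4] + GS[3:4, 1:2]
    by_sex[[sx]]$A <- by_sex[[sx]]$A + within + co[["a"]] * cross
    by_sex[[sx]]$CorD <- by_sex[[sx]]$CorD + within + co[["c"]] * cross
    by_sex[[sx]]$E <- by_sex[[sx]]$E + within
    by_sex[[sx]]$mu <- by_sex[[sx]]$mu + gr$mu[1:2] + gr$mu[3:4]
  }
  tri_grad <- function(M) c(M[1, 1], M[1, 2] + M[2, 1], M[2, 2])
  i <- 1L
  if (spec$sex_equality == "none") {
    for (sx in c("F", "M")) {
      for (cm in spec$components[[sx]]) {
        g[i:(i + 2L)] <- tri_grad(by_sex[[sx]][[cm]]); i <- i + 3L
      }
      g[i:(i + 1L)] <- by_sex[[sx]]$mu; i <- i + 2L
    }
  } else if (spec$sex_equality == "full") {
    for (cm in spec$components$F) {
      g[i:(i + 2L)] <- tri_grad(by_sex$F[[cm]] + by_sex$M[[cm]])
      i <- i + 3L
    }
    g[i:(i + 1L)] <- by_sex$F$mu
    g[(i + 2L):(i + 3L)] <- by_sex$M$mu
  } else {
    stop("no analytic gradient for scalar mode")  # callers use numeric
  }
  g
}

#' Deviance (-2 log-likelihood) of a biometric parameter structure
#'
#' Evaluates the full-information -2 log-likelihood of a twin dataset
#' under the bivariate variance-component model: each group's pair vector
#' is multivariate normal with mean `rep(mu, 2)` and covariance
#' [implied_pair_covariance()] from the sex-appropriate components.
#' Returns `Inf` if any group's implied covariance is not positive
#' definite.
#'
#' @param params list with elements `F` and `M`, each a [group_params()]
#'   (or a plain list with `A`, `CorD`, `E`, `mu`).
#' @param spec a [biometric_spec()].
#' @param dataset a `twin_dataset`.
#' @return scalar deviance.
#' @export
biometric_deviance <- function(params, spec, dataset) {
  stopifnot(inherits(spec, "biometric_spec"),
            inherits(dataset, "twin_dataset"))
  for (sx in c("F", "M")) {
    for (nm in c("A", "CorD", "E")) {
      params[[sx]][[nm]] <- check_sym2(params[[sx]][[nm]],
                                       paste0(nm, "_", sx))
    }
    if (length(params[[sx]]$mu) != 2L) {
      stop("mu must have length 2", call. = FALSE)
    }
  }
  stats <- pattern_stats(dataset)
  mm <- implied_moments(params, spec$family)
  fiml_m2ll(stats, mm$mu, mm$sigma)
}

# --- fitting -----------------------------------------------------------

# per-sex moment starts: pooled within-twin mean and covariance
start_params <- function(dataset, spec) {
  groups <- split_groups(dataset)
  pooled <- function(sx) {
    gs <- groups[paste0(c("MZ", "DZ"), tolower(sx))]
    y <- do.call(rbind, lapply(gs, function(g) {
      m <- as.matrix(g$pairs[PHENO_COLS])
      rbind(m[, 1:2, drop = FALSE], m[, 3:4, drop = FALSE])
    }))
    mu <- colMeans(y, na.rm = TRUE); mu[!is.finite(mu)] <- 0
    cv <- suppressWarnings(stats::cov(y, use = "pairwise.complete.obs"))
    cv[!is.finite(cv)] <- 0
    diag(cv)[diag(cv) <= 0] <- 1
    if (is.null(chol_or_null(cv))) cv <- diag(diag(cv))
    list(mu = unname(mu), W = unname(cv))
  }
  pf <- pooled("F"); pm <- pooled("M")
  zero <- matrix(0, 2L, 2L)
  mk <- function(p, comps) {
    m <- length(comps)
    out <- list(A = zero, CorD = zero, E = zero, mu = p$mu)
    for (cm in comps) out[[cm]] <- p$W / m
    out
  }
  if (spec$sex_equality == "scalar") {
    k0 <- pmax(diag(pf$W) / diag(pm$W), 1e-3)
    pars <- list(F = mk(pf, spec$components$F),
                 M = mk(pm, spec$components$M), k = k0)
  } else if (spec$sex_equality == "full") {
    pav <- list(mu = (pf$mu + pm$mu) / 2, W = (pf$W + pm$W) / 2)
    pars <- list(F = mk(pav, spec$components$F),
                 M = mk(pav, spec$components$M))
    pars$F$mu <- pf$mu; pars$M$mu <- pm$mu
  } else {
    pars <- list(F = mk(pf, spec$components$F),
                 M = mk(pm, spec$components$M))
  }
  pars
}

# draw deterministic jitters without disturbing the caller's RNG stream
fixed_jitter <- function(n, seed = 20251231L) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' Fit a bivariate biometric twin model
#'
#' Minimizes the FIML deviance by quasi-Newton iteration (PORT routines,
#' analytic gradient where available) from data-driven starting values:
#' means from group averages, each present component initialized to an
#' equal share of the pooled within-twin covariance. A fixed number of
#' deterministically jittered restarts guards against local optima; the
#' best optimum is kept.
#'
#' @param dataset a `twin_dataset` with all four groups non-empty.
#' @param spec a [biometric_spec()].
#' @param starts optional parameter structure (as in
#'   [biometric_deviance()]) used as the first start.
#' @param n_starts number of starts including the first (default 3).
#' @param extra_starts optional list of additional parameter structures to
#'   try (used for warm starts along model ladders).
#' @return object of class `biometric_fit`: `spec`, `params` (per-sex
#'   effective component matrices, means, and `k` in scalar mode),
#'   `minus2LL`, `n_free`, `df = observed_count - n_free`,
#'   `AIC = minus2LL - 2 df`, `converged`, optimizer diagnostics.
#' @export
fit_biometric <- function(dataset, spec, starts = NULL, n_starts = 3L,
                          extra_starts = NULL) {
  stopifnot(inherits(spec, "biometric_spec"))
  stats <- pattern_stats(dataset)
  if (any(attr(stats, "n_pairs") == 0L)) {
    stop("all four groups must be non-empty", call. = FALSE)
  }
  th0 <- pack_params(if (is.null(starts)) start_params(dataset, spec)
                     else starts, spec)
  n <- length(th0)
  stopifnot(n == n_free_params(spec))
  starts_list <- list(th0)
  if (n_starts > 1L) {
    z <- fixed_jitter((n_starts - 1L) * n)
    for (j in seq_len(n_starts - 1L)) {
      zz <- z[((j - 1L) * n + 1L):(j * n)]
      starts_list[[j + 1L]] <- th0 * (1 + 0.15 * zz) + 0.02 * zz
    }
  }
  for (es in extra_starts) starts_list[[length(starts_list) + 1L]] <-
    pack_params(es, spec)

  fn <- function(th) deviance_theta(th, spec, stats)
  gr <- if (spec$sex_equality %in% c("none", "full")) {
    function(th) grad_theta(th, spec, stats)
  } else NULL
  best <- NULL
  for (th in starts_list) {
    opt <- tryCatch(
      stats::nlminb(th, fn, gradient = gr,
                    control = list(eval.max = 20000, iter.max = 5000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best) || best$objective >= BIG_DEV) {
    stop("fit_biometric: no start converged to a finite deviance",
         call. = FALSE)
  }
  params <- unpack_params(best$par, spec)
  n_obs <- attr(stats, "n_obs")
  fit <- structure(
    list(spec = spec, params = params, theta = best$par,
         minus2LL = best$objective, n_free = n,
         n_obs = n_obs, df = n_obs - n,
         AIC = best$objective - 2 * (n_obs - n),
         converged = best$convergence == 0L,
         iterations = best$iterations, message = best$message,
         n_pairs = attr(stats, "n_pairs")),
    class = "biometric_fit")
  attr(fit, "stats") <- stats
  fit
}

#' @export
print.biometric_fit <- function(x, ...) {
  cat(sprintf("biometric_fit: %s\n  -2LL = %.1f, ep = %d, df = %d, AIC = %.1f, converged: %s\n",
              model_label(x$spec), x$minus2LL, x$n_free, x$df, x$AIC,
              x$converged))
  invisible(x)
}
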