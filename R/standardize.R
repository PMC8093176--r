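# Standardized estimates: variance shares, bivariate covariance shares
# (bivariate heritability), genetic/environmental correlations, and
# profile-likelihood confidence intervals.

#' Genetic correlation from a component covariance matrix
#'
#' `rg = VA12 / sqrt(VA11 * VA22)`: the genetic covariance divided by the
#' square root of the product of the genetic variances. Under the
#' variance-component parameterization the matrix may be indefinite, in
#' which case the result can exceed 1 in magnitude; a warning is issued
#' rather than truncating, since truncation would hide the indefinite
#' estimate.
#'
#' @param A symmetric 2x2 additive-genetic covariance matrix with positive
#'   diagonal.
#' @return scalar correlation.
#' @export
#' @examples
#' genetic_correlation(matrix(c(4, 2, 2, 1), 2))  # 1.0: PSD boundary
genetic_correlation <- function(A) {
  A <- check_sym2(A, "A")
  if (A[1, 1] <= 0 || A[2, 2] <= 0) {
    stop("undefined correlation: component variances must be positive",
         call. = FALSE)
  }
  r <- A[1, 2] / sqrt(A[1, 1] * A[2, 2])
  if (abs(r) > 1) {
    warning(sprintf("correlation %.3f outside [-1, 1]: component matrix is indefinite", r))
  }
  r
}

#' Environmental correlation from a component covariance matrix
#'
#' `re = VE12 / sqrt(VE11 * VE22)`, the environmental analogue of
#' [genetic_correlation()] (also used for the shared-environment
#' correlation rc and the non-additive correlation rd).
#'
#' @param E symmetric 2x2 environmental covariance matrix with positive
#'   diagonal.
#' @return scalar correlation.
#' @export
environmental_correlation <- function(E) genetic_correlation(E)

#' Standardize a fitted biometric model
#'
#' Converts fitted component matrices into scale-free summaries, per sex:
#' univariate variance shares (`h2`, `c2`/`d2`, `e2` per trait), shares of
#' the phenotypic covariance (`bivA` is the bivariate heritability),
#' component correlations (`rg`, `rc`/`rd`, `re`), and the model-implied
#' phenotypic correlation. Shares of present components sum to one by
#' construction, and `r_ph = rg*sqrt(h2_1*h2_2) + rc*sqrt(c2_1*c2_2) +
#' re*sqrt(e2_1*e2_2)` holds as an algebraic identity.
#'
#' @param fit a `biometric_fit`.
#' @param ... unused.
#' @return object of class `standardized_estimates`; use
#'   [as.data.frame.standardized_estimates()] for a tabular view.
#' @export
standardize <- function(fit, ...) UseMethod("standardize")

#' @rdname standardize
#' @export
standardize.biometric_fit <- function(fit, ...) {
  spec <- fit$spec
  out <- list()
  for (sx in c("F", "M")) {
    p <- fit$params[[sx]]
    W <- p$A + p$CorD + p$E
    comps <- spec$components[[if (spec$sex_equality == "none") sx else "M"]]
    shares <- lapply(c(A = "A", CorD = "CorD", E = "E"), function(cm) {
      if (!cm %in% comps) return(c(NA_real_, NA_real_))
      c(p[[cm]][1, 1] / W[1, 1], p[[cm]][2, 2] / W[2, 2])
    })
    cov_ok <- abs(W[1, 2]) > 1e-12
    biv <- vapply(c(A = "A", CorD = "CorD", E = "E"), function(cm) {
      if (!cm %in% comps || !cov_ok) return(NA_real_)
      p[[cm]][1, 2] / W[1, 2]
    }, numeric(1))
    rcomp <- vapply(c(A = "A", CorD = "CorD", E = "E"), function(cm) {
      if (!cm %in% comps) return(NA_real_)
      m <- p[[cm]]
      if (m[1, 1] <= 0 || m[2, 2] <= 0) return(NA_real_)
      suppressWarnings(genetic_correlation(m))
    }, numeric(1))
    out[[sx]] <- list(
      h2 = shares$A, c2_or_d2 = shares$CorD, e2 = shares$E,
      bivA = biv[["A"]], bivC_or_D = biv[["CorD"]], bivE = biv[["E"]],
      rg = rcomp[["A"]], rc_or_rd = rcomp[["CorD"]], re = rcomp[["E"]],
      r_ph_implied = W[1, 2] / sqrt(W[1, 1] * W[2, 2]),
      total_var = diag(W), total_cov = W[1, 2],
      cov_defined = cov_ok)
  }
  structure(list(family = spec$family, sex_equality = spec$sex_equality,
                 by_sex = out),
            class = "standardized_estimates")
}

#' Tabular view of standardized estimates
#'
#' @param x a `standardized_estimates` object.
#' @param ... unused.
#' @return data.frame with one row per sex-by-quantity combination.
#' @export
as.data.frame.standardized_estimates <- function(x, ...) {
  mid <- if (x$family == "ACE") "C" else "D"
  rows <- list()
  for (sx in c("F", "M")) {
    s <- x$by_sex[[sx]]
    q <- c(h2_1 = s$h2[1], h2_2 = s$h2[2],
           stats::setNames(c(s$c2_or_d2[1], s$c2_or_d2[2]),
                           paste0(tolower(mid), "2_", 1:2)),
           e2_1 = s$e2[1], e2_2 = s$e2[2],
           bivA = s$bivA,
           stats::setNames(s$bivC_or_D, paste0("biv", mid)),
           bivE = s$bivE,
           rg = s$rg, stats::setNames(s$rc_or_rd, paste0("r",
                                                         tolower(mid))),
           re = s$re, r_ph = s$r_ph_implied)
    rows[[sx]] <- data.frame(sex = sx, quantity = names(q),
                             value = unname(q), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.standardized_estimates <- function(x, ...) {
  mid <- if (x$family == "ACE") "C" else "D"
  for (sx in c("F", "M")) {
    s <- x$by_sex[[sx]]
    cat(sprintf("%s: h2 = %.3f/%.3f", sx, s$h2[1], s$h2[2]))
    if (!all(is.na(s$c2_or_d2))) {
      cat(sprintf(", %s2 = %.3f/%.3f", tolower(mid), s$c2_or_d2[1],
                  s$c2_or_d2[2]))
    }
    cat(sprintf(", e2 = %.3f/%.3f\n   bivA = %s, bivE = %s, rg = %s, re = %.3f, r_ph = %.3f\n",
                s$e2[1], s$e2[2], fmt_num(s$bivA, 3), fmt_num(s$bivE, 3),
                fmt_num(s$rg, 3), s$re, s$r_ph_implied))
  }
  invisible(x)
}

# --- quantity extractors for profiling ---------------------------------

# returns function(params) -> scalar for a quantity label such as
# "h2_1_F", "e2_2_M", "bivA_F", "rg_F", "re_M", "rph_F", "VA12_F", "mu1_M"
quantity_fun <- function(quantity, spec) {
  if (is.function(quantity)) return(quantity)
  stopifnot(is.character(quantity), length(quantity) == 1L)
  parts <- strsplit(quantity, "_", fixed = TRUE)[[1L]]
  sx <- parts[length(parts)]
  if (!sx %in% c("F", "M")) {
    stop("quantity must end in _F or _M: ", quantity, call. = FALSE)
  }
  stat <- parts[1L]
  trait <- if (length(parts) == 3L) as.integer(parts[2L]) else NA_integer_
  comp_of <- c(h2 = "A", c2 = "CorD", d2 = "CorD", e2 = "E",
               bivA = "A", bivC = "CorD", bivD = "CorD", bivE = "E",
               rg = "A", rc = "CorD", rd = "CorD", re = "E")
  W_of <- function(p) p$A + p$CorD + p$E
  if (stat %in% c("h2", "c2", "d2", "e2")) {
    stopifnot(trait %in% 1:2)
    cm <- comp_of[[stat]]
    function(params) {
      p <- params[[sx]]
      p[[cm]][trait, trait] / W_of(p)[trait, trait]
    }
  } else if (stat %in% c("bivA", "bivC", "bivD", "bivE")) {
    cm <- comp_of[[stat]]
    function(params) {
      p <- params[[sx]]
      p[[cm]][1, 2] / W_of(p)[1, 2]
    }
  } else if (stat %in% c("rg", "rc", "rd", "re")) {
    cm <- comp_of[[stat]]
    function(params) {
      m <- params[[sx]][[cm]]
      m[1, 2] / sqrt(m[1, 1] * m[2, 2])
    }
  } else if (stat == "rph") {
    function(params) {
      W <- W_of(params[[sx]])
      W[1, 2] / sqrt(W[1, 1] * W[2, 2])
    }
  } else if (grepl("^V[ACDE][12][12]$", stat)) {
    cm <- switch(substr(stat, 2, 2), A = "A", C = "CorD", D = "CorD",
                 E = "E")
    i <- as.integer(substr(stat, 3, 3)); j <- as.integer(substr(stat, 4, 4))
    function(params) params[[sx]][[cm]][i, j]
  } else if (grepl("^mu[12]$", stat)) {
    t <- as.integer(substr(stat, 3, 3))
    function(params) params[[sx]]$mu[t]
  } else {
    stop("unknown quantity label: ", quantity, call. = FALSE)
  }
}

# index layout of the packed parameter vector: positions of each component
# triplet (11, 12, 22) and the means per sex, mirroring pack_params()
theta_index <- function(spec) {
  idx <- list(F = list(), M = list())
  i <- 1L
  if (spec$sex_equality == "none") {
    for (sx in c("F", "M")) {
      for (cm in spec$components[[sx]]) {
        idx[[sx]][[cm]] <- i:(i + 2L); i <- i + 3L
      }
      idx[[sx]]$mu <- i:(i + 1L); i <- i + 2L
    }
  } else if (spec$sex_equality == "full") {
    for (cm in spec$components$F) {
      idx$F[[cm]] <- idx$M[[cm]] <- i:(i + 2L); i <- i + 3L
    }
    idx$F$mu <- i:(i + 1L); idx$M$mu <- (i + 2L):(i + 3L)
  } else {
    stop("no theta index map for scalar mode")
  }
  idx
}

# For a preset quantity, express the constraint "quantity == target" by
# solving for one designated theta entry. Returns NULL when no exact
# substitution exists (custom function quantities, scalar mode).
# Otherwise: list(solved = index, fn(th, target) -> value,
#                 grad(th, target) -> named sparse derivative vector).
subst_rule <- function(quantity, spec) {
  if (!is.character(quantity) ||
      !spec$sex_equality %in% c("none", "full")) return(NULL)
  parts <- strsplit(quantity, "_", fixed = TRUE)[[1L]]
  sx <- parts[length(parts)]
  stat <- parts[1L]
  trait <- if (length(parts) == 3L) as.integer(parts[2L]) else NA_integer_
  idx <- theta_index(spec)
  comps <- spec$components[[sx]]
  has <- function(cm) cm %in% comps
  pos <- function(cm, ij) idx[[sx]][[cm]][ij]  # ij: 1 = 11, 2 = 12, 3 = 22
  share_of <- c(h2 = "A", c2 = "CorD", d2 = "CorD", e2 = "E",
                bivA = "A", bivC = "CorD", bivD = "CorD", bivE = "E")
  corr_of <- c(rg = "A", rc = "CorD", rd = "CorD", re = "E")

  if (stat %in% names(share_of)) {
    cm <- share_of[[stat]]
    if (!has(cm)) return(NULL)
    ij <- if (is.na(trait)) 2L else if (trait == 1L) 1L else 3L
    others <- setdiff(intersect(c("A", "CorD", "E"), comps), cm)
    oth_pos <- vapply(others, pos, integer(1), ij = ij)
    list(solved = pos(cm, ij),
         fn = function(th, t_) {
           if (abs(1 - t_) < 1e-9) return(NA_real_)
           t_ / (1 - t_) * sum(th[oth_pos])
         },
         grad = function(th, t_) {
           stats::setNames(rep(t_ / (1 - t_), length(oth_pos)), oth_pos)
         })
  } else if (stat %in% names(corr_of)) {
    cm <- corr_of[[stat]]
    if (!has(cm)) return(NULL)
    i11 <- pos(cm, 1L); i22 <- pos(cm, 3L)
    list(solved = pos(cm, 2L),
         fn = function(th, t_) {
           v <- th[i11] * th[i22]
           if (v <= 0) return(NA_real_)
           t_ * sqrt(v)
         },
         grad = function(th, t_) {
           s <- t_ * sqrt(th[i11] * th[i22])
           stats::setNames(c(s / (2 * th[i11]), s / (2 * th[i22])),
                           c(i11, i22))
         })
  } else if (stat == "rph") {
    if (!has("E")) return(NULL)
    diag_pos <- function(ij) vapply(comps, pos, integer(1), ij = ij)
    p1 <- diag_pos(1L); p2 <- diag_pos(3L)
    off_others <- vapply(setdiff(comps, "E"), pos, integer(1), ij = 2L)
    list(solved = pos("E", 2L),
         fn = function(th, t_) {
           W11 <- sum(th[p1]); W22 <- sum(th[p2])
           if (W11 <= 0 || W22 <= 0) return(NA_real_)
           t_ * sqrt(W11 * W22) - sum(th[off_others])
         },
         grad = function(th, t_) {
           W11 <- sum(th[p1]); W22 <- sum(th[p2])
           s <- t_ * sqrt(W11 * W22)
           g <- c(rep(s / (2 * W11), length(p1)),
                  rep(s / (2 * W22), length(p2)),
                  rep(-1, length(off_others)))
           stats::setNames(g, c(p1, p2, off_others))
         })
  } else if (grepl("^V[ACDE][12][12]$", stat)) {
    cm <- switch(substr(stat, 2, 2), A = "A", C = "CorD", D = "CorD",
                 E = "E")
    if (!has(cm)) return(NULL)
    i <- as.integer(substr(stat, 3, 3)); j <- as.integer(substr(stat, 4, 4))
    ij <- if (i == j) (if (i == 1L) 1L else 3L) else 2L
    list(solved = pos(cm, ij),
         fn = function(th, t_) t_,
         grad = function(th, t_) stats::setNames(numeric(0), integer(0)))
  } else if (grepl("^mu[12]$", stat)) {
    t <- as.integer(substr(stat, 3, 3))
    list(solved = idx[[sx]]$mu[t],
         fn = function(th, t_) t_,
         grad = function(th, t_) stats::setNames(numeric(0), integer(0)))
  } else NULL
}

#' Profile-likelihood confidence interval
#'
#' Likelihood-based interval for a free parameter or a derived standardized
#' quantity of a fitted biometric model: the set of target values whose
#' profiled deviance (all other parameters re-optimized) exceeds the
#' minimum by no more than the chi-square(1) quantile at `level` (3.841 for
#' 95%). For the preset quantity labels the constraint is imposed exactly
#' by solving one parameter from the target; custom function quantities
#' (and the scalar sex-limitation mode) fall back to penalized constrained
#' refits. Each bound is located by bracketing and root bisection.
#'
#' @param fit a `biometric_fit`.
#' @param quantity character label (e.g. `"h2_1_F"`, `"bivA_F"`, `"rg_F"`,
#'   `"re_M"`, `"VA12_F"`, `"mu1_M"`, `"rph_F"`) or a function
#'   `params -> scalar`.
#' @param level confidence level (default 0.95).
#' @param max_expand bracketing doublings before a bound is declared open.
#' @return list with `estimate`, `lower`, `upper`, `level`, and logical
#'   flags `open_lower`/`open_upper` set when a bound could not be
#'   bracketed within the search range.
#' @export
profile_ci <- function(fit, quantity, level = 0.95, max_expand = 14L) {
  stopifnot(inherits(fit, "biometric_fit"))
  spec <- fit$spec
  stats <- attr(fit, "stats")
  if (is.null(stats)) stop("fit carries no data summaries", call. = FALSE)
  qf_params <- quantity_fun(quantity, spec)
  qf <- function(th) qf_params(unpack_params(th, spec))
  crit <- stats::qchisq(level, df = 1L)
  q_hat <- qf(fit$theta)
  d_hat <- fit$minus2LL
  n <- length(fit$theta)
  eps <- 1e-6

  rule <- subst_rule(quantity, spec)
  have_grad <- spec$sex_equality %in% c("none", "full")

  if (!is.null(rule)) {
    free <- setdiff(seq_len(n), rule$solved)
    profile_dev <- local({
      warm_red <- fit$theta[free]
      function(target, reset = FALSE) {
        if (reset) warm_red <<- fit$theta[free]
        expand <- function(red) {
          th <- numeric(n)
          th[free] <- red
          th[rule$solved] <- rule$fn(th, target)
          th
        }
        fn <- function(red) {
          th <- expand(red)
          if (is.na(th[rule$solved])) return(BIG_DEV)
          deviance_theta(th, spec, stats)
        }
        gr <- if (have_grad) function(red) {
          th <- expand(red)
          if (is.na(th[rule$solved])) return(numeric(length(free)))
          g <- grad_theta(th, spec, stats)
          out <- g[free]
          dep <- rule$grad(th, target)
          if (length(dep)) {
            ii <- match(as.integer(names(dep)), free)
            out[ii] <- out[ii] + g[rule$solved] * unname(dep)
          }
          out
        } else NULL
        opt <- stats::nlminb(warm_red, fn, gradient = gr,
                             control = list(eval.max = 20000,
                                            iter.max = 3000))
        warm_red <<- opt$par
        opt$objective
      }
    })
  } else {
    # penalty fallback for custom quantities / scalar mode
    num_qgrad <- function(th) {
      g <- numeric(n)
      for (i in seq_len(n)) {
        e <- numeric(n); e[i] <- eps * max(1, abs(th[i]))
        g[i] <- (qf(th + e) - qf(th - e)) / (2 * e[i])
      }
      g
    }
    dev_gr <- if (have_grad) function(th) grad_theta(th, spec, stats)
              else NULL
    profile_dev <- local({
      warm <- fit$theta
      function(target, reset = FALSE) {
        if (reset) warm <<- fit$theta
        th <- warm
        for (lam in c(1e4, 1e7)) {
          pen_fn <- function(t_) {
            deviance_theta(t_, spec, stats) + lam * (qf(t_) - target)^2
          }
          pen_gr <- if (!is.null(dev_gr)) {
            function(t_) dev_gr(t_) +
              2 * lam * (qf(t_) - target) * num_qgrad(t_)
          } else NULL
          opt <- stats::nlminb(th, pen_fn, gradient = pen_gr,
                               control = list(eval.max = 20000,
                                              iter.max = 3000))
          th <- opt$par
        }
        warm <<- th
        deviance_theta(th, spec, stats)
      }
    })
  }

  find_bound <- function(dir) {
    profile_dev(q_hat, reset = TRUE)
    step <- max(0.1 * abs(q_hat), 0.05)
    t_in <- q_hat
    d_out <- NA_real_
    t_out <- NA_real_
    for (i in seq_len(max_expand)) {
      t_try <- q_hat + dir * step
      d_try <- profile_dev(t_try)
      if (d_try - d_hat > crit) {
        t_out <- t_try
        d_out <- d_try
        break
      }
      t_in <- t_try
      step <- step * 2
    }
    if (is.na(t_out)) return(list(bound = NA_real_, open = TRUE))
    root <- stats::uniroot(function(t_) profile_dev(t_) - d_hat - crit,
                           lower = min(t_in, t_out),
                           upper = max(t_in, t_out),
                           tol = 1e-4 * max(1, abs(q_hat)), maxiter = 60L)
    list(bound = root$root, open = FALSE)
  }
  lo <- find_bound(-1)
  hi <- find_bound(+1)
  list(estimate = q_hat, lower = lo$bound, upper = hi$bound, level = level,
       quantity = if (is.character(quantity)) quantity else "custom",
       open_lower = lo$open, open_upper = hi$open)
}
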