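# Nested-model comparison: family choice heuristic, likelihood-ratio
# tests, the table-arithmetic AIC convention, and the standard testing
# ladder (drop C/D, sex-difference test, optional scalar sex limitation).

#' Choose between the ACE and ADE family from twin correlations
#'
#' C and D are not jointly identified with twins reared together, so the
#' family is picked from the pattern of same-trait twin correlations: if
#' the MZ correlation exceeds twice the DZ correlation, dominance is
#' indicated and an ADE model is appropriate; otherwise (including ties)
#' ACE. The check runs per sex and trait; under the default `"any"` rule a
#' sex is assigned ADE if either trait indicates dominance.
#'
#' @param corr a `correlation_summary` from [correlations_from_fit()].
#' @param rule `"any"` (default) or `"all"`: how per-trait indications
#'   combine within a sex.
#' @return named character vector `c(F = ..., M = ...)` of families.
#' @export
choose_family <- function(corr, rule = c("any", "all")) {
  rule <- match.arg(rule)
  stopifnot(inherits(corr, "correlation_summary"))
  out <- c(F = "ACE", M = "ACE")
  for (sx in c("F", "M")) {
    mz <- corr$twin[corr$twin$group == paste0("MZ", tolower(sx)), ]
    dz <- corr$twin[corr$twin$group == paste0("DZ", tolower(sx)), ]
    ind <- mz$r[order(mz$trait)] > 2 * dz$r[order(dz$trait)]
    out[[sx]] <- if (if (rule == "any") any(ind) else all(ind)) "ADE"
                 else "ACE"
  }
  out
}

#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution, the reference for the
#' likelihood-ratio statistic between nested models.
#'
#' @param x non-negative test statistic.
#' @param df positive degrees of freedom.
#' @return upper-tail probability.
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(x < 0)) stop("test statistic must be non-negative", call. = FALSE)
  stopifnot(all(df > 0))
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test of two nested fits
#'
#' Works on any pair of fits carrying `minus2LL`, `n_free`, `n_obs` and
#' `df` (both `biometric_fit` and `saturated_fit`). The statistic is the
#' difference in -2 log-likelihood, referred to a chi-square with df equal
#' to the number of parameters constrained.
#'
#' @param base the less constrained model.
#' @param nested the constrained submodel, fitted to the same data.
#' @param alpha significance threshold for the reported decision (default
#'   0.01, the convention for genetic submodel tests).
#' @param labels optional character vector of length 2 naming base and
#'   nested models.
#' @return object of class `comparison_result` with `delta_minus2LL`,
#'   `delta_df`, `p` and `decision` (`"retain nested"` /
#'   `"retain base"`).
#' @export
lrt <- function(base, nested, alpha = 0.01, labels = NULL) {
  for (f in list(base, nested)) {
    stopifnot(is.numeric(f$minus2LL), is.numeric(f$n_free),
              is.numeric(f$n_obs), is.numeric(f$df))
  }
  if (nested$n_free >= base$n_free) {
    stop("nested model must have fewer free parameters than base",
         call. = FALSE)
  }
  if (base$n_obs != nested$n_obs) {
    stop("models were fitted to different data (observed counts differ)",
         call. = FALSE)
  }
  delta <- nested$minus2LL - base$minus2LL
  if (delta < 0) {
    if (delta >= -1e-6) delta <- 0
    else stop(sprintf("nested -2LL is %.3g below the base: base fit did not reach its optimum",
                      -delta), call. = FALSE)
  }
  ddf <- as.integer(round(nested$df - base$df))
  p <- chi2_upper_tail(delta, ddf)
  if (is.null(labels)) {
    lab <- function(f) if (inherits(f, "biometric_fit")) model_label(f$spec)
                       else "saturated"
    labels <- c(lab(base), lab(nested))
  }
  structure(list(base_label = labels[1L], nested_label = labels[2L],
                 delta_minus2LL = delta, delta_df = ddf, p = p,
                 alpha = alpha,
                 decision = if (p < alpha) "retain base"
                            else "retain nested"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: delta(-2LL) = %.2f, delta df = %d, p = %.4g -> %s (alpha = %g)\n",
              x$nested_label, x$base_label, x$delta_minus2LL, x$delta_df,
              x$p, x$decision, x$alpha))
  invisible(x)
}

#' AIC under the table-arithmetic convention
#'
#' `AIC = -2LL - 2 df` with `df = observed_count - free parameters`. Note
#' this differs from the common `-2LL + 2 * (free parameters)` by a
#' data-dependent constant, so it orders models identically on the same
#' data.
#'
#' @param fit a fit carrying `minus2LL` and `df`.
#' @return scalar AIC.
#' @export
aic <- function(fit) fit$minus2LL - 2 * fit$df

#' Options for the model-comparison ladder
#'
#' @param family `NULL` to pick ACE/ADE from the saturated twin
#'   correlations, or `"ACE"`/`"ADE"` to fix it (skipping the saturated
#'   step unless `include_saturated` is `TRUE`).
#' @param alpha significance level for the genetic submodel tests.
#' @param scalar also fit the scalar sex-limitation variant.
#' @param per_sex_drops additionally test dropping C (or D) for each sex
#'   separately.
#' @param n_starts multistarts per fit.
#' @param include_saturated force the saturated/descriptive step even when
#'   `family` is fixed.
#' @return list of class `ladder_config`.
#' @export
ladder_config <- function(family = NULL, alpha = 0.01, scalar = FALSE,
                          per_sex_drops = FALSE, n_starts = 2L,
                          include_saturated = is.null(family)) {
  if (!is.null(family)) family <- match.arg(family, c("ACE", "ADE"))
  structure(list(family = family, alpha = alpha, scalar = isTRUE(scalar),
                 per_sex_drops = isTRUE(per_sex_drops),
                 n_starts = as.integer(n_starts),
                 include_saturated = isTRUE(include_saturated)),
            class = "ladder_config")
}

# refit `base` with the nested optimum embedded as an extra start if the
# nested model came out below it (optimizer noise guard)
ensure_nesting <- function(base, nested, dataset, config) {
  if (nested$minus2LL < base$minus2LL - 1e-7) {
    refit <- fit_biometric(dataset, base$spec, starts = base$params,
                           n_starts = 1L,
                           extra_starts = list(nested$params))
    if (refit$minus2LL < base$minus2LL) return(refit)
  }
  base
}

#' Run the nested model-comparison ladder
#'
#' Executes the standard testing sequence for the four-group bivariate
#' design: (1) descriptive saturated model and ACE/ADE family choice;
#' (2) full family model with quantitative sex differences; (3) dropping
#' the C (or D) component for both sexes (optionally per sex); (4) the
#' no-sex-difference model equating all component matrices across sexes
#' (means remain sex-specific); (5) optionally the scalar sex-limitation
#' variant against the retained sex-difference model. Each step is tested
#' against its base by [lrt()] at `config$alpha`, and nested fits are
#' warm-started from their base so the -2LL ladder is monotone.
#'
#' @param dataset a `twin_dataset`.
#' @param config a [ladder_config()].
#' @return object of class `model_ladder`: `steps` (label, fit, comparison
#'   per step), `table` (ep, -2LL, df, AIC, delta LL, delta df, p per
#'   row), `best` (label of the retained model), `corr` (descriptives, if
#'   computed) and `alpha`.
#' @export
run_ladder <- function(dataset, config = ladder_config()) {
  stopifnot(inherits(config, "ladder_config"))
  corr <- NULL
  family <- config$family
  if (is.null(family) || config$include_saturated) {
    sat <- fit_saturated(dataset, "twin_order")
    corr <- correlations_from_fit(sat)
    if (is.null(family)) {
      fam_by_sex <- choose_family(corr)
      family <- if (any(fam_by_sex == "ADE")) "ADE" else "ACE"
    }
  }
  ns <- config$n_starts
  steps <- list()
  add_step <- function(fit, cmp) {
    steps[[length(steps) + 1L]] <<- list(label = model_label(fit$spec),
                                         fit = fit, comparison = cmp)
  }

  spec1 <- biometric_spec(family, "none")
  fit1 <- fit_biometric(dataset, spec1, n_starts = ns)

  spec2 <- biometric_spec(family, "none", drop = if (family == "ACE") "C"
                                                 else "D")
  fit2 <- fit_biometric(dataset, spec2, n_starts = ns,
                        extra_starts = list(project_drop(fit1$params,
                                                        spec2)))
  fit1 <- ensure_nesting(fit1, fit2, dataset, config)
  add_step(fit1, NULL)
  cmp2 <- lrt(fit1, fit2, alpha = config$alpha)
  add_step(fit2, cmp2)

  if (config$per_sex_drops) {
    for (sx in c("F", "M")) {
      sp <- biometric_spec(family, "none",
                           drop = stats::setNames(
                             list(if (family == "ACE") "C" else "D"), sx))
      ft <- fit_biometric(dataset, sp, n_starts = ns,
                          extra_starts = list(project_drop(fit1$params,
                                                          sp)))
      add_step(ft, lrt(fit1, ft, alpha = config$alpha))
    }
  }

  base3 <- if (cmp2$decision == "retain nested") fit2 else fit1
  spec3 <- biometric_spec(family, "full",
                          drop = if (identical(base3, fit2)) {
                            if (family == "ACE") "C" else "D"
                          } else NULL)
  fit3 <- fit_biometric(dataset, spec3, n_starts = ns,
                        extra_starts = list(average_sexes(base3$params)))
  base3 <- ensure_nesting(base3, fit3, dataset, config)
  cmp3 <- lrt(base3, fit3, alpha = config$alpha)
  add_step(fit3, cmp3)

  best <- if (cmp3$decision == "retain nested") fit3 else base3

  if (config$scalar) {
    spec_s <- biometric_spec(family, "scalar",
                             drop = if (identical(spec3$components$F,
                                                  c("A", "E")))
                               (if (family == "ACE") "C" else "D")
                             else NULL)
    fit_s <- fit_biometric(dataset, spec_s, n_starts = max(ns, 3L))
    add_step(fit_s, lrt(base3, fit_s, alpha = config$alpha))
  }

  tab <- do.call(rbind, lapply(steps, function(st) {
    cmp <- st$comparison
    data.frame(model = st$label, ep = st$fit$n_free,
               minus2LL = st$fit$minus2LL, df = st$fit$df,
               AIC = aic(st$fit),
               base = if (is.null(cmp)) NA_character_ else cmp$base_label,
               deltaLL = if (is.null(cmp)) NA_real_ else cmp$delta_minus2LL,
               delta_df = if (is.null(cmp)) NA_integer_ else cmp$delta_df,
               p = if (is.null(cmp)) NA_real_ else cmp$p,
               decision = if (is.null(cmp)) NA_character_ else cmp$decision,
               stringsAsFactors = FALSE)
  }))
  structure(list(steps = steps, table = tab, corr = corr,
                 family = family, best = model_label(best$spec),
                 best_fit = best, alpha = config$alpha),
            class = "model_ladder")
}

# drop components from a fitted parameter structure (warm start helper)
project_drop <- function(params, spec) {
  zero <- matrix(0, 2L, 2L)
  for (sx in c("F", "M")) {
    for (cm in c("A", "CorD")) {
      if (!cm %in% spec$components[[sx]]) {
        # fold the dropped block into E so the total stays close
        params[[sx]]$E <- params[[sx]]$E + params[[sx]][[cm]]
        params[[sx]][[cm]] <- zero
      }
    }
  }
  params$k <- NULL
  params
}

average_sexes <- function(params) {
  for (cm in c("A", "CorD", "E")) {
    avg <- (params$F[[cm]] + params$M[[cm]]) / 2
    params$F[[cm]] <- avg
    params$M[[cm]] <- avg
  }
  params$k <- NULL
  params
}

#' @export
print.model_ladder <- function(x, ...) {
  cat(sprintf("model ladder (%s family, alpha = %g), best: %s\n",
              x$family, x$alpha, x$best))
  tab <- x$table
  tab$minus2LL <- fmt_num(tab$minus2LL, 1)
  tab$AIC <- fmt_num(tab$AIC, 1)
  tab$deltaLL <- fmt_num(tab$deltaLL, 2)
  tab$p <- ifelse(is.na(tab$p), "NA", formatC(tab$p, format = "g",
                                              digits = 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
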