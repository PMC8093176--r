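# Descriptive tables, deterministic report rendering, and the end-to-end
# demonstration pipeline.

#' Per-sex descriptive statistics
#'
#' Counts, means, standard deviations (n-1 denominator) and ranges of the
#' observed phenotype values, per sex and trait, pooling twin 1 and twin 2.
#' With fewer than two observed values the SD is reported as `NA`.
#'
#' @param dataset a `twin_dataset`.
#' @return data.frame with columns sex, trait, n, mean, sd, min, max.
#' @export
descriptives <- function(dataset) {
  rows <- list()
  for (sx in c("F", "M")) {
    sub <- dataset$pairs[dataset$pairs$sex == sx, , drop = FALSE]
    for (t in 1:2) {
      v <- c(sub[[PHENO_COLS[t]]], sub[[PHENO_COLS[t + 2L]]])
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sx, trait = dataset$trait_names[t], n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Render an analysis report
#'
#' Deterministic, byte-stable rendering of an `analysis_report`:
#' correlations and shares to 3 decimals, -2LL and AIC to 1 decimal.
#'
#' @param report an `analysis_report` from [run_demo()] (or assembled by
#'   hand with the same elements).
#' @param format `"text"` (a character vector of lines) or `"tsv"` (a set
#'   of TSV files under `path`).
#' @param path output directory, required for `format = "tsv"`.
#' @return for `"text"`, the lines invisibly (also printed if
#'   `print = TRUE`); for `"tsv"`, the written file paths.
#' @param print print text output to the console.
#' @export
render_report <- function(report, format = c("text", "tsv"), path = NULL,
                          print = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(report, "analysis_report"))
  if (format == "tsv") {
    if (is.null(path)) stop("'path' (a directory) is required for tsv output",
                            call. = FALSE)
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    wr <- function(df, name) {
      fp <- file.path(path, paste0(name, ".tsv"))
      utils::write.table(df, fp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <<- c(files, fp)
    }
    wr(round_df(report$descriptives, 3), "descriptives")
    if (!is.null(report$correlations)) {
      wr(round_df(correlation_table(report$correlations), 3),
         "correlations")
    }
    if (!is.null(report$ladder_table) && nrow(report$ladder_table)) {
      lt <- report$ladder_table
      lt$minus2LL <- round(lt$minus2LL, 1)
      lt$AIC <- round(lt$AIC, 1)
      lt$deltaLL <- round(lt$deltaLL, 2)
      lt$p <- signif(lt$p, 4)
      wr(lt, "ladder")
    }
    if (!is.null(report$estimates)) {
      wr(round_df(report$estimates, 3), "estimates")
    }
    return(files)
  }
  lines <- c(sprintf("bivariate twin analysis report (seed %s)",
                     report$meta$seed),
             "", "== descriptives ==",
             df_lines(round_df(report$descriptives, 3)))
  if (!is.null(report$correlations)) {
    lines <- c(lines, "", "== correlations (saturated model) ==",
               df_lines(round_df(correlation_table(report$correlations),
                                 3)))
  }
  if (is.null(report$ladder_table) || !nrow(report$ladder_table)) {
    lines <- c(lines, "", "== model ladder ==",
               "no models were fitted (descriptives only)")
  } else {
    lt <- report$ladder_table
    lt$minus2LL <- fmt_num(lt$minus2LL, 1)
    lt$AIC <- fmt_num(lt$AIC, 1)
    lt$deltaLL <- fmt_num(lt$deltaLL, 2)
    lt$p <- ifelse(is.na(lt$p), "NA", formatC(lt$p, format = "g",
                                              digits = 4))
    lines <- c(lines, "",
               sprintf("== model ladder (best: %s) ==", report$best),
               df_lines(lt))
  }
  if (!is.null(report$estimates)) {
    lines <- c(lines, "", "== standardized estimates (best model) ==",
               df_lines(round_df(report$estimates, 3)))
  }
  if (print) writeLines(lines)
  invisible(lines)
}

round_df <- function(df, digits) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]]) && !is.integer(df[[cl]])) {
      df[[cl]] <- round(df[[cl]], digits)
    }
  }
  df
}

df_lines <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}

correlation_table <- function(corr) {
  tw <- stats::reshape(corr$twin, idvar = "group", timevar = "trait",
                       direction = "wide")
  names(tw) <- c("group", "twin_r_trait1", "twin_r_trait2")
  tw$cross_twin_cross_trait <- unname(corr$ctct[tw$group])
  tw$r_ph_sex <- unname(corr$r_ph[c("F", "F", "M", "M")])
  tw
}

#' Run the demonstration analysis end to end
#'
#' Simulates a dataset from [demo_sim_spec()] at the given seed, runs the
#' model-comparison ladder, standardizes the retained model, and (by
#' request) computes profile-likelihood confidence intervals for a small
#' set of headline quantities.
#'
#' @param seed integer seed for the simulation.
#' @param spec simulation specification (default [demo_sim_spec()]).
#' @param config ladder options (default: choose family from the data).
#' @param ci character vector of quantity labels for [profile_ci()]
#'   (default none, to keep the demo fast).
#' @return object of class `analysis_report`.
#' @export
run_demo <- function(seed = 1731L, spec = demo_sim_spec(),
                     config = ladder_config(), ci = character(0)) {
  dataset <- simulate_dataset(spec, seed = seed)
  ladder <- run_ladder(dataset, config)
  est <- standardize(ladder$best_fit)
  cis <- NULL
  if (length(ci)) {
    cis <- do.call(rbind, lapply(ci, function(q) {
      x <- profile_ci(ladder$best_fit, q)
      data.frame(quantity = q, estimate = x$estimate, lower = x$lower,
                 upper = x$upper, stringsAsFactors = FALSE)
    }))
  }
  structure(list(descriptives = descriptives(dataset),
                 correlations = ladder$corr,
                 ladder_table = ladder$table,
                 best = ladder$best,
                 estimates = as.data.frame(est),
                 ci = cis,
                 ladder = ladder,
                 meta = list(seed = seed,
                             n_pairs = unname(n_pairs(dataset)),
                             n_obs = observed_count(dataset),
                             package = as.character(
                               utils::packageVersion("bivtwin")))),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  writeLines(render_report(x, "text"))
  invisible(x)
}
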