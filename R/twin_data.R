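#' Construct a twin dataset
#'
#' A `twin_dataset` holds pair-level records for two continuous traits
#' measured on same-sex twin pairs in the classical four-group design
#' (MZ female, DZ female, MZ male, DZ male). Each pair contributes up to
#' four phenotype values, ordered (twin1 trait1, twin1 trait2, twin2 trait1,
#' twin2 trait2); any of the four may be missing, which the likelihood
#' machinery handles by full-information maximum likelihood.
#'
#' Pairs with all four phenotypes missing carry no information and are
#' dropped at construction; the number dropped is stored in the
#' `n_dropped` attribute.
#'
#' @param pairs data.frame with columns `zygosity` ("MZ"/"DZ"), `sex`
#'   ("F"/"M") and the four phenotype columns `t1_trait1`, `t1_trait2`,
#'   `t2_trait1`, `t2_trait2` (numeric, `NA` allowed).
#' @param trait_names character vector of length 2 labelling the traits.
#' @param provenance free-text note on where the data came from.
#' @return An object of class `twin_dataset`.
#' @export
#' @examples
#' d <- twin_dataset(data.frame(
#'   zygosity = c("MZ", "DZ"), sex = c("F", "F"),
#'   t1_trait1 = c(1, 2), t1_trait2 = c(0.5, NA),
#'   t2_trait1 = c(1.2, 2.1), t2_trait2 = c(0.4, 1.0)))
#' observed_count(d)
twin_dataset <- function(pairs, trait_names = c("trait1", "trait2"),
                         provenance = "") {
  stopifnot(is.data.frame(pairs))
  need <- c("zygosity", "sex", PHENO_COLS)
  miss <- setdiff(need, names(pairs))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  pairs <- as.data.frame(pairs)[need]
  pairs$zygosity <- as.character(pairs$zygosity)
  pairs$sex <- as.character(pairs$sex)
  if (anyNA(pairs$zygosity) || anyNA(pairs$sex)) {
    stop("zygosity and sex must not be missing", call. = FALSE)
  }
  bad_z <- !pairs$zygosity %in% c("MZ", "DZ")
  if (any(bad_z)) {
    stop(sprintf("unknown zygosity code '%s' at row %d",
                 pairs$zygosity[which(bad_z)[1L]], which(bad_z)[1L]),
         call. = FALSE)
  }
  bad_s <- !pairs$sex %in% c("F", "M")
  if (any(bad_s)) {
    stop(sprintf("unknown sex code '%s' at row %d",
                 pairs$sex[which(bad_s)[1L]], which(bad_s)[1L]),
         call. = FALSE)
  }
  for (cl in PHENO_COLS) pairs[[cl]] <- as.numeric(pairs[[cl]])
  y <- as.matrix(pairs[PHENO_COLS])
  empty <- rowSums(!is.na(y)) == 0L
  n_dropped <- sum(empty)
  pairs <- pairs[!empty, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs,
         trait_names = as.character(trait_names),
         provenance = provenance),
    n_dropped = n_dropped,
    class = "twin_dataset")
}

#' @export
print.twin_dataset <- function(x, ...) {
  ns <- vapply(split_groups(x), n_pairs, integer(1))
  cat(sprintf("twin_dataset: %d pairs (%s), traits: %s, %d observed values\n",
              n_pairs(x),
              paste(sprintf("%s=%d", names(ns), ns), collapse = ", "),
              paste(x$trait_names, collapse = " / "),
              observed_count(x)))
  invisible(x)
}

#' Number of twin pairs in a dataset
#' @param dataset a `twin_dataset`.
#' @return integer count of pairs.
#' @export
n_pairs <- function(dataset) nrow(dataset$pairs)

#' Count observed phenotype values
#'
#' Total number of non-missing phenotype entries over all pairs. This is the
#' "data points" quantity entering the degrees-of-freedom convention
#' `df = observed_count - free parameters` used throughout model comparison.
#'
#' @param dataset a `twin_dataset`.
#' @return non-negative integer.
#' @export
observed_count <- function(dataset) {
  sum(!is.na(as.matrix(dataset$pairs[PHENO_COLS])))
}

#' Split a dataset into the four zygosity-by-sex groups
#'
#' @param dataset a `twin_dataset`.
#' @return named list of four `twin_dataset` objects (`MZf`, `DZf`, `MZm`,
#'   `DZm`); groups may be empty. The four groups partition the input and
#'   preserve within-group pair order.
#' @export
split_groups <- function(dataset) {
  g <- group_label(dataset$pairs$zygosity, dataset$pairs$sex)
  out <- lapply(GROUPS, function(lab) {
    sub <- dataset$pairs[g == lab, , drop = FALSE]
    rownames(sub) <- NULL
    structure(list(pairs = sub, trait_names = dataset$trait_names,
                   provenance = dataset$provenance),
              n_dropped = 0L, class = "twin_dataset")
  })
  names(out) <- GROUPS
  out
}

#' Read pair-level twin data from CSV
#'
#' Expects a wide comma-delimited file with a header and one row per twin
#' pair. Logical roles can be remapped to arbitrary column names through
#' `column_map`. Unparseable phenotype cells become missing; rows in which
#' all four phenotypes are missing are dropped (a message reports the count).
#'
#' @param path path to a CSV file.
#' @param column_map named character vector mapping the logical roles
#'   `zygosity`, `sex`, `t1_trait1`, `t1_trait2`, `t2_trait1`, `t2_trait2`
#'   to column names in the file. Defaults to identity.
#' @param zygosity_codes named character vector translating file codes to
#'   "MZ"/"DZ" (default identity plus lower-case synonyms).
#' @param sex_codes named character vector translating file codes to
#'   "F"/"M".
#' @param na_codes strings read as missing (default empty, `"NA"`, `"NaN"`).
#' @param trait_names,provenance passed to [twin_dataset()].
#' @return a `twin_dataset`.
#' @export
read_twin_csv <- function(path, column_map = NULL,
                          zygosity_codes = c(MZ = "MZ", DZ = "DZ",
                                             mz = "MZ", dz = "DZ"),
                          sex_codes = c(F = "F", M = "M", f = "F", m = "M"),
                          na_codes = c("", "NA", "NaN"),
                          trait_names = c("trait1", "trait2"),
                          provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = na_codes, check.names = FALSE)
  roles <- c("zygosity", "sex", PHENO_COLS)
  map <- stats::setNames(roles, roles)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  absent <- map[!map %in% names(raw)]
  if (length(absent)) {
    stop("mapped column(s) not in file: ",
         paste(sprintf("%s (role %s)", absent, names(absent)),
               collapse = ", "), call. = FALSE)
  }
  df <- data.frame(zygosity = raw[[map[["zygosity"]]]],
                   sex = raw[[map[["sex"]]]],
                   stringsAsFactors = FALSE)
  decode <- function(x, codes, what) {
    known <- x %in% names(codes)
    if (any(!known & !is.na(x))) {
      i <- which(!known & !is.na(x))[1L]
      stop(sprintf("unknown %s code '%s' at row %d", what, x[i], i),
           call. = FALSE)
    }
    unname(codes[x])
  }
  df$zygosity <- decode(df$zygosity, zygosity_codes, "zygosity")
  df$sex <- decode(df$sex, sex_codes, "sex")
  for (cl in PHENO_COLS) {
    df[[cl]] <- suppressWarnings(as.numeric(raw[[map[[cl]]]]))
  }
  out <- twin_dataset(df, trait_names = trait_names, provenance = provenance)
  nd <- attr(out, "n_dropped")
  if (nd > 0) {
    message(sprintf("read_twin_csv: dropped %d row(s) with no observed phenotypes", nd))
  }
  out
}

#' Write a twin dataset to CSV
#'
#' Emits the wide format read by [read_twin_csv()]: header row, one row per
#' pair, missing entries as empty fields. The round trip
#' `read_twin_csv(write_twin_csv(d))` is lossless for observed values and
#' the missingness pattern.
#'
#' @param dataset a `twin_dataset`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_twin_csv <- function(dataset, path) {
  utils::write.csv(dataset$pairs, path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}
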