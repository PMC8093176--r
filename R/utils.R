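# internal helpers shared across modules

GROUPS <- c("MZf", "DZf", "MZm", "DZm")
PHENO_COLS <- c("t1_trait1", "t1_trait2", "t2_trait1", "t2_trait2")

group_label <- function(zygosity, sex) {
  paste0(as.character(zygosity), ifelse(as.character(sex) == "F", "f", "m"))
}

is_symmetric2 <- function(m, tol = 1e-10) {
  is.matrix(m) && all(dim(m) == c(2L, 2L)) && all(is.finite(m)) &&
    abs(m[1L, 2L] - m[2L, 1L]) <= tol * max(1, abs(m[1L, 2L]))
}

check_sym2 <- function(m, name) {
  if (!is_symmetric2(m)) {
    stop(sprintf("'%s' must be a finite symmetric 2x2 matrix", name),
         call. = FALSE)
  }
  # exact symmetrization so downstream algebra sees one off-diagonal value
  (m + t(m)) / 2
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1L])))
}

# Cholesky that returns NULL instead of erroring on non-PD input
chol_or_null <- function(m) {
  r <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(r) && any(diag(r) <= 0)) return(NULL)
  r
}

sym2 <- function(v11, v12, v22) matrix(c(v11, v12, v12, v22), 2L, 2L)

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}
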