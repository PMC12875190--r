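#' Assemble a regression testing problem
#'
#' Bundles the response `Y`, the covariate(s) of interest `X` and the control
#' covariates `Z` of the partial-correlation model
#' `Y = X beta + Z theta + eps`.  All downstream tests take one of these
#' objects.  `Z` usually contains an intercept column; none is added here
#' (see [read_problem()] for file input with automatic intercept handling).
#'
#' @param Y numeric response vector of length `n` (no missing values).
#' @param X numeric vector or `n x d` matrix: the covariate(s) whose effect
#'   is under test.
#' @param Z numeric vector or `n x p` matrix of control covariates.
#' @return An object of class `"palmrt_problem"`: a list with elements `Y`,
#'   `X`, `Z`, `n`, `d`, `p`.
#' @examples
#' set.seed(1)
#' pr <- palmrt_problem(rnorm(20), rnorm(20), cbind(1, rnorm(20)))
#' pr$n
#' @export
palmrt_problem <- function(Y, X, Z) {
  Y <- as.numeric(Y)
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  storage.mode(X) <- "double"
  storage.mode(Z) <- "double"
  n <- length(Y)
  if (n < 3L)
    stop_input("need at least 3 observations")
  if (nrow(X) != n || nrow(Z) != n)
    stop_input(sprintf(
      "row mismatch: length(Y)=%d, nrow(X)=%d, nrow(Z)=%d", n, nrow(X), nrow(Z)))
  if (ncol(X) < 1L || ncol(Z) < 1L)
    stop_input("X and Z must each have at least one column")
  if (anyNA(Y) || anyNA(X) || anyNA(Z) ||
      !all(is.finite(Y)) || !all(is.finite(X)) || !all(is.finite(Z)))
    stop_input("Y, X and Z must be finite with no missing values")
  structure(
    list(Y = Y, X = X, Z = Z, n = n, d = ncol(X), p = ncol(Z)),
    class = "palmrt_problem"
  )
}

#' @export
print.palmrt_problem <- function(x, ...) {
  cat(sprintf(
    "<palmrt_problem> n = %d observations, d = %d covariate(s) of interest, p = %d control(s)\n",
    x$n, x$d, x$p))
  invisible(x)
}

#' Read a regression problem from delimited text
#'
#' Reads one delimited table (CSV or TSV, header row required) and assigns
#' its columns to the roles of [palmrt_problem()].  Unless a constant column
#' is already present among the controls, an intercept column is appended to
#' `Z`.
#'
#' @param path path to a delimited text file.  The delimiter is taken from
#'   the extension (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is
#'   given.
#' @param y,x column name(s) for the response and the covariate(s) of
#'   interest.
#' @param z column names for the controls; `NULL` (default) uses every
#'   remaining column.
#' @param sep field separator; `NULL` to infer from the extension.
#' @param add_intercept append an all-ones column to `Z` when no constant
#'   column is present (default `TRUE`).
#' @return A `"palmrt_problem"`.
#' @export
read_problem <- function(path, y, x, z = NULL, sep = NULL,
                         add_intercept = TRUE) {
  if (!file.exists(path))
    stop_input(sprintf("file not found: %s", path))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L)
    stop_input(sprintf("no usable rows in %s", path))
  need <- c(y, x, z)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop_input(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (is.null(z))
    z <- setdiff(names(tab), c(y, x))
  used <- tab[, c(y, x, z), drop = FALSE]
  for (cn in names(used)) {
    v <- used[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop_input(sprintf("non-numeric cell in column '%s', row %d", cn, bad[1]))
      used[[cn]] <- vn
    }
  }
  na_rows <- which(rowSums(is.na(used)) > 0)
  if (length(na_rows))
    stop_input(sprintf("%d row(s) with missing values (first: row %d)",
                       length(na_rows), na_rows[1]))
  Z <- as.matrix(used[, z, drop = FALSE])
  if (ncol(Z) == 0L) {
    Z <- matrix(1, nrow(used), 1, dimnames = list(NULL, "(Intercept)"))
  } else if (add_intercept && !any(apply(Z, 2, function(col) diff(range(col)) == 0))) {
    Z <- cbind(`(Intercept)` = 1, Z)
  }
  palmrt_problem(used[[y]], as.matrix(used[, x, drop = FALSE]), Z)
}
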