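#' Serialize a test result or confidence interval to JSON
#'
#' `palmrt_test` objects carry `pvalue`, `B`, `alpha`, `n_ties`, `seed` and
#' `method`; `palmrt_ci` objects carry `lo`, `hi`, `alpha`,
#' `guaranteed_coverage`, `beta_grid` and `pvalues_on_grid`.  Paired scores
#' are omitted from the JSON (use [write_scores_tsv()] for those).
#'
#' @param x a `"palmrt_test"` or `"palmrt_ci"` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
result_to_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "palmrt_test")) {
    list(pvalue = x$pvalue, B = x$B, alpha = x$alpha, n_ties = x$n_ties,
         seed = x$seed, method = x$method)
  } else if (inherits(x, "palmrt_ci")) {
    list(lo = x$lo, hi = x$hi, alpha = x$alpha,
         guaranteed_coverage = x$guaranteed_coverage, empty = x$empty,
         beta_grid = x$beta_grid, pvalues_on_grid = x$pvalues_on_grid)
  } else {
    stop_input("`x` must be a palmrt_test or palmrt_ci object")
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write the paired permutation scores as TSV
#'
#' One row per sampled permutation: the original-covariate score and the
#' permuted-covariate score.
#'
#' @param x a `"palmrt_test"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(x, path) {
  stopifnot(inherits(x, "palmrt_test"))
  utils::write.table(
    data.frame(b = seq_len(x$B), omega_orig = x$omega_orig,
               omega_perm = x$omega_perm),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
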