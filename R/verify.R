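#' Certify that a fitter meets the framework's conditions
#'
#' The finite-sample guarantee requires two explicitly verifiable
#' properties of the fitting algorithm, checked here numerically on random
#' instances:
#' \describe{
#'   \item{Shift invariance}{the fit summary is unchanged when `Y` is
#'     shifted by any vector in the column span of the augmented controls
#'     `[Z, Z_pi]`.}
#'   \item{Row symmetry}{the fit summary is unchanged under a joint
#'     permutation of the rows of `(Y, X, [Z, Z_pi])`.}
#' }
#' Each draw generates a fresh problem, a random shift `gamma` (or row
#' permutation `sigma`), and compares scales, ordered residuals and the
#' evaluator's score.  Use this to certify custom fitters before trusting
#' their p-values.
#'
#' @param fitter a [palmrt_fitter()] or [palmrt_custom_fitter()].
#' @param evaluator evaluator whose score is compared as well (default L2).
#' @param n,d,p dimensions of the random test problems.
#' @param draws number of random draws per condition (default 20).
#' @param tol absolute tolerance (default 1e-6).
#' @param seed RNG seed for the draws.
#' @return Invisibly, a list with `pass` (logical), `max_shift_diff`,
#'   `max_symmetry_diff`.  Fails with an error when a condition is violated
#'   beyond `tol`.
#' @export
verify_fitter <- function(fitter, evaluator = palmrt_evaluator("l2"),
                          n = 20L, d = 1L, p = 2L, draws = 20L,
                          tol = 1e-6, seed = 1L) {
  stopifnot(inherits(fitter, "palmrt_fitter"))
  seeds <- derive_seeds(seed, draws)
  max_shift <- 0
  max_sym <- 0
  for (s in seeds) {
    inst <- with_seed(s, {
      Y <- rnorm(n)
      X <- matrix(rnorm(n * d), n, d)
      Z <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
      pi_b <- sample.int(n)
      gam <- rnorm(2 * p)
      sig <- sample.int(n)
      list(Y = Y, X = X, Zaug = cbind(Z, Z[pi_b, , drop = FALSE]),
           gam = gam, sig = sig)
    })
    base <- fit_with_prepare(fitter, inst$Y, inst$X, inst$Zaug)
    shifted <- fit_with_prepare(fitter, inst$Y + as.numeric(inst$Zaug %*% inst$gam),
                                inst$X, inst$Zaug)
    permuted <- fit_with_prepare(fitter, inst$Y[inst$sig],
                                 inst$X[inst$sig, , drop = FALSE],
                                 inst$Zaug[inst$sig, , drop = FALSE])
    max_shift <- max(max_shift, fit_diff(base, shifted, evaluator))
    max_sym <- max(max_sym, fit_diff(base, permuted, evaluator))
  }
  pass <- max_shift <= tol && max_sym <= tol
  if (!pass)
    stop_rpalmrt(sprintf(
      "fitter '%s' violates the framework's conditions (shift diff %.3g, symmetry diff %.3g, tol %.3g)",
      fitter$name, max_shift, max_sym, tol), "rpalmrt_verification_error")
  invisible(list(pass = pass, max_shift_diff = max_shift,
                 max_symmetry_diff = max_sym))
}

fit_with_prepare <- function(fitter, Y, X, Zaug) {
  ctx <- if (is.null(fitter$prepare)) NULL else fitter$prepare(Y, Zaug)
  fitter$fit(Y, X, Zaug, ctx)
}

fit_diff <- function(a, b, evaluator) {
  ds <- if (is.na(a$scale) && is.na(b$scale)) 0 else abs(a$scale - b$scale)
  dr <- max(abs(a$residuals - b$residuals))
  dw <- tryCatch(abs(evaluator$score(a) - evaluator$score(b)),
                 rpalmrt_error = function(e) 0)
  max(ds, dr, dw)
}
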