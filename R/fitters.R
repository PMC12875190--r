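#' Huber fitting specification
#'
#' Tuning constants for Huber M-estimation.  `delta` is the corner of the
#' Huber loss in units of the (normal-consistent) scale; the conventional
#' 1.345 gives 95% efficiency at the normal.  `mad_constant` multiplies the
#' raw median absolute deviation; 1.4826 makes the MAD consistent for the
#' standard deviation under normality (set it to 1 for the raw MAD).
#'
#' @param delta positive Huber corner (default 1.345).
#' @param max_iter cap on the IRLS phase of each fixed-scale fit
#'   (default 100).  The cap only bounds the cheap reweighting pre-phase:
#'   the Newton polish that follows always finishes on the exact minimiser
#'   of the convex objective, so hitting the cap changes the reported
#'   `converged` flag, not the fit.
#' @param tol convergence tolerance on the relative change of the residual
#'   vector between IRLS iterations (default 1e-9).  The criterion is
#'   deliberately expressed in residual (not raw coefficient) terms so that
#'   shifted and unshifted runs of the same problem stop at the same
#'   iteration, preserving the fitter's shift invariance; the tight default
#'   keeps the cost of a borderline extra iteration far below the 1e-6
#'   tolerance at which the framework's conditions are certified.
#' @param mad_constant MAD consistency constant (default 1.4826).
#' @return A list of class `"huber_spec"`.
#' @export
huber_spec <- function(delta = 1.345, max_iter = 100L, tol = 1e-9,
                       mad_constant = 1.4826) {
  check_scalar_number(delta, "delta", lower = .Machine$double.eps)
  check_scalar_number(max_iter, "max_iter", lower = 1)
  check_scalar_number(tol, "tol", lower = .Machine$double.xmin)
  check_scalar_number(mad_constant, "mad_constant", lower = .Machine$double.eps)
  structure(list(delta = delta, max_iter = as.integer(max_iter), tol = tol,
                 mad_constant = mad_constant),
            class = "huber_spec")
}

#' Fit summary: frozen scale plus ordered residuals
#'
#' The common currency between fitters and evaluators: an estimated scale
#' `s` (possibly `NA` for scale-free fitters) and the residual vector stored
#' as order statistics.  Sorting the residuals is what makes the summary
#' mechanically invariant to a joint row permutation of the data.
#'
#' @param scale positive scale estimate in the units of `Y`, or `NA` when
#'   the fitter does not estimate one.
#' @param residuals numeric residual vector (sorted ascending on storage).
#' @param converged logical; `FALSE` records that an iterative fitter hit
#'   its iteration cap (the fit is still usable and the test stays valid).
#' @return A list of class `"palmrt_fit"` with elements `scale`,
#'   `residuals` (nondecreasing), `converged`.
#' @export
fit_summary <- function(scale, residuals, converged = TRUE) {
  if (!is.na(scale) && !(is.numeric(scale) && scale > 0))
    stop_input("`scale` must be a positive number or NA")
  structure(list(scale = scale, residuals = sort(as.numeric(residuals)),
                 converged = isTRUE(converged)),
            class = "palmrt_fit")
}

#' Least-squares projection residuals
#'
#' Residuals of `Y` after orthogonal projection onto the column span of
#' `design`.  Rank-deficient designs use the pseudo-inverse, so the result
#' depends only on the span — which is exactly the shift-invariance the
#' permutation framework requires.
#'
#' @param Y numeric response vector.
#' @param design numeric `n x k` matrix.
#' @return Numeric residual vector of length `n` (unsorted).
#' @export
ols_residuals <- function(Y, design) {
  Y <- as.numeric(Y)
  design <- as.matrix(design)
  if (nrow(design) != length(Y))
    stop_input("row mismatch between Y and design")
  as.numeric(cpp_ols_resid(Y, design))
}

#' Median absolute deviation scale estimate
#'
#' `constant * median(|r - median(r)|)`.  A zero MAD signals that the
#' response is essentially inside the span of the controls; rather than
#' silently substituting a floor (which would change every downstream
#' score), this raises a degenerate-scale error carrying the residuals.
#'
#' @param r numeric vector, length at least 2.
#' @param constant consistency constant (default 1.4826; use 1 for the raw
#'   MAD).
#' @return Positive scale estimate.
#' @examples
#' mad_scale(c(1, 2, 4, 7))  # 1.5 * 1.4826
#' @export
mad_scale <- function(r, constant = 1.4826) {
  r <- as.numeric(r)
  if (length(r) < 2L)
    stop_input("need at least 2 residuals for a MAD")
  s <- cpp_mad(r, constant)
  if (!(s > 0))
    stop_degenerate_scale("MAD of residuals is zero (response is in the span of the controls?)",
                          residuals = r)
  s
}

#' Huber loss
#'
#' Quadratic (`t^2/2`) within `delta` of zero, linear
#' (`|t| delta - delta^2/2`) outside; continuously differentiable at the
#' corner.
#'
#' @param t numeric vector of standardised residuals.
#' @param delta positive corner (default 1.345).
#' @return `rho(t)`, elementwise.
#' @export
huber_rho <- function(t, delta = 1.345) {
  check_scalar_number(delta, "delta", lower = .Machine$double.xmin)
  a <- abs(t)
  ifelse(a <= delta, t^2 / 2, a * delta - delta^2 / 2)
}

#' Huber regression with a frozen scale
#'
#' Iteratively reweighted least squares for the Huber criterion with the
#' scale fixed at `s`: initialised at OLS, weights
#' `w_i = min(1, delta / (|r_i| / s))`, stopping when the relative change
#' of the residual vector drops below `spec$tol`, followed by a
#' semismooth-Newton polish with exact line search that lands on the true
#' minimiser of the (convex, piecewise quadratic) objective even in the
#' nearly flat valleys where plain IRLS stalls.  Rank-deficient designs
#' are reduced to a pivoted full-rank basis first; residuals depend only
#' on the column span.  Failure of the IRLS phase to meet `spec$tol`
#' within `spec$max_iter` is recorded on the result (attribute
#' `"converged"`), not raised: the polished estimate is still a valid
#' summary for the permutation test.
#'
#' @param Y numeric response.
#' @param design numeric `n x k` design matrix.
#' @param s positive scale (same units as `Y`).
#' @param spec a [huber_spec()].
#' @return Residual vector (unsorted) with attributes `"converged"` and
#'   `"iterations"`.
#' @export
huber_irls_fixed_scale <- function(Y, design, s, spec = huber_spec()) {
  check_scalar_number(s, "s", lower = .Machine$double.xmin)
  fit <- cpp_huber_fixed(as.numeric(Y), reduce_full_rank(as.matrix(design)), s,
                         spec$delta, spec$max_iter, spec$tol)
  structure(as.numeric(fit$residuals),
            converged = fit$converged, iterations = fit$iterations)
}

#' Huber fit with preliminary-regression scale estimation
#'
#' The composite fitting algorithm of the Huber-Huber test.  Step 1 runs a
#' robust regression of `Y` on the augmented controls `Zaug` alone — a
#' fixed number of MAD re-estimation stages, each followed by a fully
#' converged fixed-scale Huber fit (see the methods vignette for why the
#' stage count is fixed rather than iterated to a joint fixed point).
#' Step 2 freezes the scale `s` as the MAD of the final preliminary
#' residuals.  Step 3 refits `Y` on `[X, Zaug]` by fixed-scale Huber
#' regression at that frozen scale.  Because `s` depends only on
#' `(Y, Zaug)`, the original and permuted fits of one permutation pair
#' share the identical scale — which keeps their evaluation scores
#' comparable and, under the alternative, inflates `s` so that more
#' residuals sit in the quadratic core of the loss.
#'
#' @param Y numeric response.
#' @param X numeric `n x d` matrix (covariate of interest).
#' @param Zaug numeric matrix of augmented controls `[Z, Z_pi]`, already
#'   concatenated by the caller.
#' @param spec a [huber_spec()].
#' @return A [fit_summary()] carrying the frozen scale and the ordered
#'   residuals of the fixed-scale fit.
#' @export
huber_fit_with_preliminary_scale <- function(Y, X, Zaug, spec = huber_spec()) {
  ctx <- huber_prepare(as.numeric(Y), as.matrix(Zaug), spec)
  huber_fit_at_scale(as.numeric(Y), as.matrix(X), as.matrix(Zaug), ctx, spec)
}

# Reduce a design to a deterministic full-column-rank basis (pivoted QR).
# Every fit here depends on the design only through its column span, while
# the normal-equation solvers need full rank: an exactly collinear column
# (the permuted copy of an intercept, say) makes the downdated system
# near-singular, and a Cholesky that numerically "succeeds" on it returns
# huge null-direction coefficients whose cancellation pollutes the
# residuals at the 1e-3 level.
reduce_full_rank <- function(M) {
  qa <- qr(M)
  if (qa$rank < ncol(M))
    M <- M[, sort(qa$pivot[seq_len(qa$rank)]), drop = FALSE]
  M
}

huber_prepare <- function(Y, Zaug, spec) {
  Zaug <- reduce_full_rank(Zaug)
  pre <- cpp_huber_prelim(Y, Zaug, spec$delta, spec$max_iter, spec$tol,
                          spec$mad_constant)
  if (isTRUE(pre$degenerate))
    stop_degenerate_scale(
      "zero MAD in the preliminary regression of Y on the augmented controls",
      residuals = as.numeric(pre$residuals))
  list(scale = pre$scale)
}

huber_fit_at_scale <- function(Y, X, Zaug, ctx, spec) {
  design <- reduce_full_rank(cbind(X, Zaug))
  fit <- cpp_huber_fixed(Y, design, ctx$scale,
                         spec$delta, spec$max_iter, spec$tol)
  fit_summary(ctx$scale, fit$residuals, converged = fit$converged)
}

#' Quantile regression residuals
#'
#' Residuals `Y - design %*% b` where `b` minimises the check (pinball)
#' loss at quantile `q`, via the deterministic Barrodale-Roberts simplex of
#' \pkg{quantreg}.  The solver's fixed pivoting convention resolves
#' non-unique minimisers reproducibly while preserving shift invariance.
#' The design should include an intercept column (caller's responsibility).
#'
#' @param Y numeric response.
#' @param design numeric `n x k` design matrix.
#' @param q quantile level in (0, 1).
#' @return Residual vector of length `n` (unsorted).
#' @export
quantile_residuals <- function(Y, design, q) {
  check_scalar_number(q, "q", lower = 1e-12, upper = 1 - 1e-12)
  Y <- as.numeric(Y)
  design <- as.matrix(design)
  # The check-loss optimum depends on the design only through its column
  # span, but the simplex solver requires full column rank: augmented
  # controls [Z, Z_pi] always duplicate the intercept, so reduce to a
  # deterministic full-rank basis (pivoted QR) first.
  qa <- qr(design)
  if (qa$rank < ncol(design))
    design <- design[, sort(qa$pivot[seq_len(qa$rank)]), drop = FALSE]
  rq_resid(Y, design, q)
}

# Check-loss residuals without the rank-reduction preflight; the caller
# guarantees a full-column-rank design.  suppressWarnings: with even group
# sizes the solver flags non-unique solutions; its fixed pivoting convention
# already resolves them deterministically, which is all the framework needs.
rq_resid <- function(Y, design, q) {
  fit <- tryCatch(
    suppressWarnings(quantreg::rq.fit.br(design, Y, tau = q)),
    error = function(e) stop_rpalmrt(
      sprintf("quantile regression solver failed at q = %g: %s", q,
              conditionMessage(e)),
      "rpalmrt_fitter_failure")
  )
  as.numeric(Y - design %*% fit$coefficients)
}

# Fitter registry -------------------------------------------------------

#' Construct a registered model fitter
#'
#' A fitter is a pair of functions: an optional `prepare(Y, Zaug)` run once
#' per permutation (it may only look at the response and the augmented
#' controls — never at `X` — so anything it computes, such as a scale, is
#' shared by the original and permuted fits of that permutation), and
#' `fit(Y, X, Zaug, ctx)` returning a [fit_summary()].
#'
#' Registered names:
#' \describe{
#'   \item{`"ols"`}{least-squares projection residuals; the reported scale
#'     is the MAD of the preliminary OLS residuals of `Y` on `Zaug` (shared
#'     by the pair), or `NA` when that MAD is zero.}
#'   \item{`"huber"`}{[huber_fit_with_preliminary_scale()].}
#'   \item{`"quantile"`}{[quantile_residuals()] at quantile `q`
#'     (default 0.5); no scale.}
#' }
#'
#' @param name `"ols"`, `"huber"` or `"quantile"`.
#' @param spec a [huber_spec()] (used by `"ols"` for its MAD constant and by
#'   `"huber"` for everything).
#' @param q quantile level for `name = "quantile"`.
#' @return An object of class `"palmrt_fitter"`.
#' @seealso [palmrt_custom_fitter()] to wrap your own algorithm, and
#'   [verify_fitter()] to certify that it meets the framework's conditions.
#' @export
palmrt_fitter <- function(name = c("ols", "huber", "quantile"),
                          spec = huber_spec(), q = 0.5) {
  name <- match.arg(name)
  switch(name,
    ols = structure(list(
      name = "ols",
      prepare = function(Y, Zaug) {
        s <- tryCatch(mad_scale(cpp_ols_resid(Y, reduce_full_rank(Zaug)),
                                spec$mad_constant),
                      rpalmrt_degenerate_scale = function(e) NA_real_)
        list(scale = s)
      },
      fit = function(Y, X, Zaug, ctx) {
        fit_summary(ctx$scale,
                    cpp_ols_resid(Y, reduce_full_rank(cbind(X, Zaug))))
      },
      engine = list(code = 0L, spec = spec)), class = "palmrt_fitter"),
    huber = structure(list(
      name = "huber",
      prepare = function(Y, Zaug) huber_prepare(Y, Zaug, spec),
      fit = function(Y, X, Zaug, ctx) huber_fit_at_scale(Y, X, Zaug, ctx, spec),
      engine = list(code = 1L, spec = spec)), class = "palmrt_fitter"),
    quantile = structure(list(
      name = "quantile",
      prepare = NULL,
      fit = function(Y, X, Zaug, ctx) {
        fit_summary(NA_real_, quantile_residuals(Y, cbind(X, Zaug), q))
      }), class = "palmrt_fitter")
  )
}

#' Wrap a user-supplied fitting algorithm
#'
#' @param fit function `(Y, X, Zaug, ctx)` returning a [fit_summary()].
#' @param prepare optional function `(Y, Zaug)` returning a context list
#'   shared by the original and permuted fits of one permutation.
#' @param name label used in printed output.
#' @return An object of class `"palmrt_fitter"`.
#' @export
palmrt_custom_fitter <- function(fit, prepare = NULL, name = "custom") {
  stopifnot(is.function(fit), is.null(prepare) || is.function(prepare))
  structure(list(name = name, prepare = prepare, fit = fit),
            class = "palmrt_fitter")
}
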