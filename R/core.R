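#' Permutation p-value from paired scores
#'
#' `(1 + #\{b : omega_orig[b] >= omega_perm[b]\}) / (1 + B)`.  Ties count
#' toward the numerator (the original fit is "no better"), using exact
#' floating-point equality — the conservative direction.  The p-value can
#' never drop below `1/(B + 1)`.
#'
#' @param omega_orig,omega_perm numeric score vectors of equal length `B`;
#'   for each sampled permutation, the evaluation of the fit with the
#'   original and with the permuted covariate of interest.
#' @return A p-value in `(0, 1]`.
#' @examples
#' pvalue_from_scores(c(1, 1, 1, 1), c(2, 2, 2, 2))  # 1/5
#' pvalue_from_scores(c(2, 2), c(2, 3))              # 2/3
#' @export
pvalue_from_scores <- function(omega_orig, omega_perm) {
  omega_orig <- as.numeric(omega_orig)
  omega_perm <- as.numeric(omega_perm)
  B <- length(omega_orig)
  if (B < 1L || length(omega_perm) != B)
    stop_input("score vectors must have equal positive length")
  if (anyNA(omega_orig) || anyNA(omega_perm) ||
      any(is.nan(omega_orig)) || any(is.nan(omega_perm)))
    stop_input("scores must be non-missing")
  (1 + sum(omega_orig >= omega_perm)) / (1 + B)
}

#' Run a paired-permutation test for a covariate effect
#'
#' For each sampled permutation `pi`, forms the augmented control matrix
#' `[Z, Z_pi]`, fits the model once with the original covariate `X` and
#' once with the permuted covariate `X_pi` (sharing whatever the fitter's
#' `prepare` step computed from `(Y, [Z, Z_pi])`, e.g. a frozen scale),
#' scores both fits with the evaluator, and aggregates the `B` paired
#' comparisons into the permutation p-value.  Provided the fitter is
#' invariant to shifts of `Y` along the span of `[Z, Z_pi]` and treats rows
#' symmetrically (see [verify_fitter()]), the test's type I error is at
#' most `2 alpha` in finite samples for exchangeable errors, with no
#' further distributional assumptions; empirically the nominal level
#' `alpha` itself is respected for the shipped fitters.
#'
#' @param problem a [palmrt_problem()].
#' @param fitter a [palmrt_fitter()] (or [palmrt_custom_fitter()]).
#' @param evaluator a [palmrt_evaluator()].
#' @param perms a [sample_permutations()] set with `perms$n == problem$n`.
#' @param alpha nominal level recorded on the result (default 0.05).
#' @return An object of class `"palmrt_test"`: list with `pvalue`, `B`,
#'   `omega_orig`, `omega_perm`, `n_ties`, `alpha`, `seed`, `method`.
#' @examples
#' set.seed(1)
#' pr <- palmrt_problem(rnorm(30), rnorm(30), cbind(1, rnorm(30)))
#' run_test(pr, palmrt_fitter("ols"), palmrt_evaluator("l2"),
#'          sample_permutations(30, 99, seed = 2))$pvalue
#' @export
run_test <- function(problem, fitter, evaluator, perms, alpha = 0.05) {
  stopifnot(inherits(problem, "palmrt_problem"),
            inherits(fitter, "palmrt_fitter"),
            inherits(evaluator, "palmrt_evaluator"),
            inherits(perms, "palmrt_perms"))
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (perms$n != problem$n)
    stop_input(sprintf("permutation set is for n = %d but problem has n = %d",
                       perms$n, problem$n))
  sc <- pair_scores(problem, fitter, evaluator, perms)
  structure(list(
    pvalue = pvalue_from_scores(sc$omega_orig, sc$omega_perm),
    B = perms$B,
    omega_orig = sc$omega_orig,
    omega_perm = sc$omega_perm,
    n_ties = sum(sc$omega_orig == sc$omega_perm),
    alpha = alpha,
    seed = perms$seed,
    method = paste(fitter$name, evaluator$name, sep = "-")
  ), class = "palmrt_test")
}

# Permuted copies of constant control columns (intercepts) duplicate
# themselves, so the augmented block omits them: the span of [Z, Z_pi] is
# unchanged and the design stays full rank.
nonconstant_cols <- function(Z) {
  which(apply(Z, 2, function(col) diff(range(col)) > 0))
}

# Dispatch: registered OLS/Huber fitters with registered evaluators run the
# whole permutation loop in compiled code (numerically identical to the R
# path: same solvers, residuals sorted before summation); anything else —
# in particular custom fitters — takes the generic R loop.
pair_scores <- function(problem, fitter, evaluator, perms) {
  fe <- fitter$engine
  ee <- evaluator$engine
  if (!is.null(fe) && !is.null(ee)) {
    P <- do.call(rbind, perms$perms)
    storage.mode(P) <- "integer"
    sc <- tryCatch(
      cpp_location_scores(problem$Y, problem$X, problem$Z, P,
                          nonconstant_cols(problem$Z),
                          fe$code, ee$code, fe$spec$delta, fe$spec$max_iter,
                          fe$spec$tol, fe$spec$mad_constant, ee$delta),
      error = function(e) {
        msg <- conditionMessage(e)
        if (grepl("MAD|scale estimate", msg))
          stop_degenerate_scale(msg)
        stop_rpalmrt(msg, "rpalmrt_fitter_failure")
      })
    return(list(omega_orig = as.numeric(sc$omega_orig),
                omega_perm = as.numeric(sc$omega_perm)))
  }
  pair_scores_r(problem, fitter, evaluator, perms)
}

pair_scores_r <- function(problem, fitter, evaluator, perms) {
  B <- perms$B
  omega_orig <- numeric(B)
  omega_perm <- numeric(B)
  Y <- problem$Y; X <- problem$X; Z <- problem$Z
  keep <- nonconstant_cols(Z)
  for (b in seq_len(B)) {
    pi_b <- perms$perms[[b]]
    Zaug <- cbind(Z, Z[pi_b, keep, drop = FALSE])
    res <- tryCatch({
      ctx <- if (is.null(fitter$prepare)) NULL else fitter$prepare(Y, Zaug)
      fo <- fitter$fit(Y, X, Zaug, ctx)
      fp <- fitter$fit(Y, X[pi_b, , drop = FALSE], Zaug, ctx)
      c(evaluator$score(fo), evaluator$score(fp))
    }, rpalmrt_error = function(e) {
      e$message <- sprintf("%s (while processing permutation b = %d)",
                           conditionMessage(e), b)
      stop(e)
    })
    omega_orig[b] <- res[1]
    omega_perm[b] <- res[2]
  }
  list(omega_orig = omega_orig, omega_perm = omega_perm)
}

#' @export
print.palmrt_test <- function(x, ...) {
  cat(sprintf("Paired-permutation test (%s), B = %d\n", x$method, x$B))
  cat(sprintf("  p-value = %.4g  (floor 1/(B+1) = %.4g, ties = %d)\n",
              x$pvalue, 1 / (x$B + 1), x$n_ties))
  invisible(x)
}

#' Confidence interval by test inversion
#'
#' Inverts the family of level-`alpha` tests of a shifted null: a candidate
#' effect `beta*` is retained when the test applied to `Y - X beta*` fails
#' to reject.  The same permutation set is reused at every grid point, which
#' makes the p-value profile stable in `beta*`; the reported interval is the
#' convex hull of the retained grid points, with guaranteed coverage at
#' least `100 (1 - 2 alpha)%`.  The full p-value profile is returned so
#' disconnected acceptance regions can be detected.
#'
#' @inheritParams run_test
#' @param beta_grid ascending numeric grid of candidate effects; `NULL`
#'   (default) uses 401 equally spaced points spanning the OLS estimate of
#'   `beta` plus/minus 10 OLS standard errors.
#' @param alpha level of each inverted test; the interval's guaranteed
#'   coverage is `1 - 2 alpha`.
#' @return An object of class `"palmrt_ci"`: list with `lo`, `hi`, `alpha`,
#'   `guaranteed_coverage`, `beta_grid`, `pvalues_on_grid`, `empty`.  When
#'   every grid point is rejected, `lo`/`hi` are `NA` and `empty` is `TRUE`.
#' @export
invert_ci <- function(problem, fitter, evaluator, perms, alpha = 0.05,
                      beta_grid = NULL) {
  stopifnot(inherits(problem, "palmrt_problem"))
  if (problem$d != 1L)
    stop_input("test inversion needs a single covariate of interest (d = 1)")
  if (is.null(beta_grid)) {
    beta_grid <- default_beta_grid(problem)
  } else {
    beta_grid <- as.numeric(beta_grid)
    if (is.unsorted(beta_grid))
      stop_input("`beta_grid` must be sorted ascending")
  }
  x <- as.numeric(problem$X)
  pvals <- vapply(beta_grid, function(bstar) {
    shifted <- problem
    shifted$Y <- problem$Y - x * bstar
    run_test(shifted, fitter, evaluator, perms, alpha)$pvalue
  }, numeric(1))
  keep <- pvals > alpha
  structure(list(
    lo = if (any(keep)) min(beta_grid[keep]) else NA_real_,
    hi = if (any(keep)) max(beta_grid[keep]) else NA_real_,
    alpha = alpha,
    guaranteed_coverage = 1 - 2 * alpha,
    beta_grid = beta_grid,
    pvalues_on_grid = pvals,
    empty = !any(keep)
  ), class = "palmrt_ci")
}

# 401 points across the OLS estimate +/- 10 standard errors
default_beta_grid <- function(problem, n_points = 401L, half_width_se = 10) {
  A <- cbind(problem$X, problem$Z)
  qa <- qr(A)
  if (qa$rank < ncol(A))
    stop_input("design [X, Z] is rank deficient; supply `beta_grid` explicitly")
  est <- qr.coef(qa, problem$Y)[1]
  res <- qr.resid(qa, problem$Y)
  sigma2 <- sum(res^2) / (problem$n - qa$rank)
  XtXinv <- chol2inv(qr.R(qa))[1, 1]
  se <- sqrt(sigma2 * XtXinv)
  if (!is.finite(se) || se == 0)
    se <- max(abs(est), 1)
  seq(est - half_width_se * se, est + half_width_se * se,
      length.out = n_points)
}

#' @export
print.palmrt_ci <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("Test-inversion interval: empty (all %d grid points rejected at alpha = %g)\n",
                length(x$beta_grid), x$alpha))
  } else {
    cat(sprintf("Test-inversion interval: [%.6g, %.6g]  (alpha = %g, guaranteed coverage >= %g%%)\n",
                x$lo, x$hi, x$alpha, 100 * x$guaranteed_coverage))
  }
  invisible(x)
}
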