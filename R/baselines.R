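#' Partial F-test for a covariate effect
#'
#' The classical nested-model F-test comparing `Y ~ Z` against
#' `Y ~ X + Z`, with `(d, n - d - p)` degrees of freedom.  Exact under
#' i.i.d. normal errors; included as the reference method the permutation
#' tests are benchmarked against.
#'
#' @param problem a [palmrt_problem()].
#' @return The upper-tail p-value.
#' @export
partial_f_test <- function(problem) {
  stopifnot(inherits(problem, "palmrt_problem"))
  n <- problem$n; d <- problem$d; p <- problem$p
  if (n <= d + p)
    stop_input("need n > d + p for the F-test")
  qz <- qr(problem$Z)
  qa <- qr(cbind(problem$X, problem$Z))
  if (qa$rank < d + p)
    stop_input("design [X, Z] is rank deficient")
  rss0 <- sum(qr.resid(qz, problem$Y)^2)
  rss1 <- sum(qr.resid(qa, problem$Y)^2)
  # residual sums below projection round-off are treated as exact zeros
  tol <- 1e-24 * (1 + sum(problem$Y^2))
  if (rss1 <= tol) {
    # perfect fit: no evidence either way when the null model is also exact
    if (rss0 <= tol) return(1)
    return(0)
  }
  fstat <- ((rss0 - rss1) / d) / (rss1 / (n - d - p))
  pf(fstat, d, n - d - p, lower.tail = FALSE)
}

#' Koenker-studentized Breusch-Pagan heteroskedasticity test
#'
#' OLS fit of `Y` on `[X, Z]`, then an auxiliary OLS of the squared
#' residuals on the auxiliary regressors; Koenker's studentized statistic
#' `n R^2` from the auxiliary fit is referred to a chi-square distribution
#' with one degree of freedom per auxiliary slope.  By default the
#' auxiliary regressors are `X` only (plus an intercept), matching a
#' dispersion effect driven by the covariate of interest; set
#' `aux = "xz"` to use `[X, Z]`.
#'
#' @param problem a [palmrt_problem()].
#' @param aux `"x"` (default) or `"xz"`: the auxiliary regressor set.
#' @return The upper-tail p-value.
#' @export
koenker_bp_test <- function(problem, aux = c("x", "xz")) {
  stopifnot(inherits(problem, "palmrt_problem"))
  aux <- match.arg(aux)
  qa <- qr(cbind(problem$X, problem$Z))
  if (qa$rank < problem$d + problem$p)
    stop_input("design [X, Z] is rank deficient")
  e2 <- qr.resid(qa, problem$Y)^2
  # squared residuals constant up to round-off: nothing to explain
  if (diff(range(e2)) <= 1e-10 * (1 + max(e2))) return(1)
  W <- if (aux == "x") cbind(1, problem$X) else cbind(1, problem$X, problem$Z)
  qw <- qr(W)
  res_aux <- qr.resid(qw, e2)
  tss <- sum((e2 - mean(e2))^2)
  if (tss <= 0) return(1)
  r2 <- 1 - sum(res_aux^2) / tss
  df <- qw$rank - 1L
  if (df < 1L)
    stop_input("auxiliary regression has no slope degrees of freedom")
  stat <- problem$n * r2
  pchisq(stat, df, lower.tail = FALSE)
}
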