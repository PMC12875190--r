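test_that("least-squares residuals are projection residuals", {
  set.seed(1)
  A <- cbind(1, matrix(rnorm(60), 20, 3))
  # a response inside the span leaves nothing
  expect_equal(ols_residuals(A %*% c(1, -2, 3, 0.5), A), rep(0, 20),
               tolerance = 1e-10)
  # centering with an intercept-only design
  expect_equal(ols_residuals(c(1, 2, 3), matrix(1, 3, 1)), c(-1, 0, 1))
  # orthogonal to every design column (normal-equations oracle)
  y <- rnorm(20)
  r <- ols_residuals(y, A)
  expect_lt(max(abs(crossprod(A, r))), 1e-8)
  expect_equal(r, qr.resid(qr(A), y), tolerance = 1e-10)
  # rank-deficient designs: residual depends only on the span
  expect_equal(ols_residuals(y, cbind(A, A[, 2])), r, tolerance = 1e-8)
})

test_that("MAD scale matches hand evaluation and is scale equivariant", {
  expect_equal(mad_scale(c(1, 2, 4, 7), constant = 1), 1.5)
  expect_equal(mad_scale(c(1, 2, 4, 7)), 1.5 * 1.4826)
  expect_equal(mad_scale(c(1, 2, 4, 7)), stats::mad(c(1, 2, 4, 7)))
  set.seed(2)
  r <- rnorm(31)
  for (c0 in c(-3, 0.2, 10))
    expect_equal(mad_scale(c0 * r), abs(c0) * mad_scale(r))
  expect_error(mad_scale(rep(2, 10)), class = "rpalmrt_degenerate_scale")
})

test_that("Huber loss has the right branches and a smooth corner", {
  d <- 1.345
  expect_equal(huber_rho(0, d), 0)
  expect_equal(huber_rho(d, d), 0.9045125)
  expect_equal(huber_rho(10, d), 12.5454875)
  expect_equal(huber_rho(-10, d), huber_rho(10, d))
  # both branches agree at the corner, and so do their derivatives
  eps <- 1e-7
  expect_equal(huber_rho(d + eps, d), huber_rho(d - eps, d),
               tolerance = 1e-6)
  slope_in <- (huber_rho(d, d) - huber_rho(d - eps, d)) / eps
  slope_out <- (huber_rho(d + eps, d) - huber_rho(d, d)) / eps
  expect_equal(slope_in, slope_out, tolerance = 1e-5)
})

test_that("fixed-scale IRLS reduces to OLS when nothing is downweighted", {
  set.seed(3)
  A <- cbind(1, matrix(rnorm(40), 20, 2))
  y <- as.numeric(A %*% c(1, 2, -1)) + 0.01 * rnorm(20)
  # scale large enough that every standardised residual sits in the core
  r <- huber_irls_fixed_scale(y, A, s = 100)
  expect_equal(as.numeric(r), ols_residuals(y, A), tolerance = 1e-9)
  # delta -> Inf likewise recovers least squares
  r2 <- huber_irls_fixed_scale(y, A, s = 0.01, spec = huber_spec(delta = 1e12))
  expect_equal(as.numeric(r2), ols_residuals(y, A), tolerance = 1e-9)
})

test_that("fixed-scale IRLS minimises the Huber objective", {
  # direct-minimisation oracle: BFGS on the (smooth) objective
  set.seed(4)
  n <- 20
  A <- cbind(1, rnorm(n))
  y <- as.numeric(A %*% c(1, 2)) + rnorm(n)
  y[3] <- y[3] + 50  # one gross outlier
  s <- 1.3
  objective <- function(b) sum(huber_rho((y - A %*% b) / s))
  r_irls <- huber_irls_fixed_scale(y, A, s, huber_spec(tol = 1e-12))
  b_irls <- qr.solve(A, y - as.numeric(r_irls))
  opt <- optim(qr.solve(A, y), objective, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_lte(objective(b_irls), opt$value + 1e-8)
  # and in particular improves on the plain least-squares fit
  expect_lt(objective(b_irls), sum(huber_rho(ols_residuals(y, A) / s)))
})

test_that("the preliminary-scale composite shares one scale per pair and is invariant", {
  set.seed(5)
  n <- 30
  Z <- cbind(1, matrix(rnorm(n * 2), n, 2))
  Zaug <- make_zaug(Z, seed = 6)
  X <- matrix(rnorm(n), n, 1)
  Y <- rnorm(n) + as.numeric(X) * 0.5
  pi_b <- sample.int(n)
  f_orig <- huber_fit_with_preliminary_scale(Y, X, Zaug)
  f_perm <- huber_fit_with_preliminary_scale(Y, X[pi_b, , drop = FALSE], Zaug)
  expect_identical(f_orig$scale, f_perm$scale)  # scale is X-free
  expect_true(!is.unsorted(f_orig$residuals))
  # Condition 1: shift along the augmented-control span
  gam <- rnorm(ncol(Zaug))
  f_shift <- huber_fit_with_preliminary_scale(Y + Zaug %*% gam, X, Zaug)
  expect_equal(f_shift$scale, f_orig$scale, tolerance = 1e-8)
  expect_equal(f_shift$residuals, f_orig$residuals, tolerance = 1e-8)
  # Condition 2: joint row permutation
  sig <- sample.int(n)
  f_sig <- huber_fit_with_preliminary_scale(Y[sig], X[sig, , drop = FALSE],
                                            Zaug[sig, , drop = FALSE])
  expect_equal(f_sig$scale, f_orig$scale, tolerance = 1e-8)
  expect_equal(f_sig$residuals, f_orig$residuals, tolerance = 1e-8)
})

test_that("quantile residuals reproduce the median and minimise the check loss", {
  # intercept-only median
  r <- quantile_residuals(c(1, 2, 9), matrix(1, 3, 1), q = 0.5)
  expect_equal(r, c(-1, 0, 7))
  # brute-force oracle over all basic solutions of a 10 x 2 problem
  set.seed(7)
  n <- 10
  A <- cbind(1, rnorm(n))
  y <- rnorm(n)
  check_loss <- function(res, q) sum(pmax(q * res, (q - 1) * res))
  for (q in c(0.25, 0.5, 0.9)) {
    best <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      b <- tryCatch(solve(A[c(i, j), ], y[c(i, j)]), error = function(e) NULL)
      if (!is.null(b))
        best <- min(best, check_loss(y - A %*% b, q))
    }
    expect_equal(check_loss(quantile_residuals(y, A, q), q), best,
                 tolerance = 1e-6)
  }
  # Condition 1 for quantile regression
  gam <- rnorm(2)
  expect_equal(quantile_residuals(y + A %*% gam, A, 0.25),
               quantile_residuals(y, A, 0.25), tolerance = 1e-6)
  # a duplicated column must not change the fit
  expect_equal(quantile_residuals(y, cbind(A, A[, 1]), 0.9),
               quantile_residuals(y, A, 0.9), tolerance = 1e-8)
})

test_that("odd-sample medians are recovered exactly at q = 0.5", {
  for (seed in 1:5) {
    set.seed(seed)
    y <- rnorm(21)
    r <- quantile_residuals(y, matrix(1, 21, 1), 0.5)
    expect_equal(y - r, rep(median(y), 21))
  }
})
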