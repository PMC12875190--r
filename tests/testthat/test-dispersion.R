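test_that("the dispersion score is the negative log spread ratio", {
  f <- structure(list(iqr_case_mean = 2, iqr_control_mean = 2,
                      n_case = 10, n_control = 10),
                 class = "grouped_quantile_fit")
  expect_equal(dispersion_omega(f), 0)
  f$iqr_case_mean <- 4
  expect_equal(dispersion_omega(f), -log(2))
  # swapping the labels negates the score
  swapped <- f
  swapped$iqr_case_mean <- f$iqr_control_mean
  swapped$iqr_control_mean <- f$iqr_case_mean
  expect_equal(dispersion_omega(swapped), -dispersion_omega(f))
  # the two-sided variant is direction-blind
  expect_equal(dispersion_omega(f, two_sided = TRUE),
               dispersion_omega(swapped, two_sided = TRUE))
})

test_that("fitted spreads recover the inter-quantile ratio of the noise", {
  # case noise U(-2,2) vs control noise U(-1,1): population 80% IQR ratio 2
  set.seed(1)
  n <- 400
  x <- rep(0:1, n / 2)
  y <- ifelse(x == 1, runif(n, -2, 2), runif(n, -1, 1))
  fit <- fit_quantile_pair(y, x, matrix(1, n, 1))
  expect_equal(fit$n_case, 200)
  expect_equal(fit$iqr_case_mean / fit$iqr_control_mean, 2, tolerance = 0.15)
})

test_that("spreads are invariant to shifts along the augmented controls", {
  pr <- make_dispersion_problem(n = 50, p = 3, beta = 1, seed = 2)
  Zaug <- make_zaug(pr$Z, seed = 3)
  x <- as.numeric(pr$X)
  f0 <- fit_quantile_pair(pr$Y, x, Zaug)
  gam <- rnorm(ncol(Zaug))
  f1 <- fit_quantile_pair(pr$Y + as.numeric(Zaug %*% gam), x, Zaug)
  expect_equal(f0$iqr_case_mean, f1$iqr_case_mean, tolerance = 1e-8)
  expect_equal(f0$iqr_control_mean, f1$iqr_control_mean, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with informative conditions", {
  n <- 30
  Z1 <- matrix(1, n, 1)
  x <- rep(0:1, n / 2)
  # pure location shift, no noise: nothing to measure
  expect_error(fit_quantile_pair(2 + 3 * x, x, Z1),
               class = "rpalmrt_degenerate_dispersion")
  expect_error(fit_quantile_pair(rnorm(n), rep(1, n), Z1),
               class = "rpalmrt_input_error")
  expect_error(fit_quantile_pair(rnorm(n), x + 1, Z1),
               class = "rpalmrt_input_error")
  expect_error(dispersion_spec(0.9, 0.1), class = "rpalmrt_input_error")
})

test_that("the dispersion test is deterministic and permutation-symmetric", {
  # n chosen so n * q_low and n * q_high are non-integer: at integer
  # values the check-loss optimum can be non-unique and the solver's
  # vertex choice (not the fitted optimum) depends on row order
  pr <- make_dispersion_problem(n = 42, p = 3, beta = 1, seed = 4)
  ps <- sample_permutations(42, 29, seed = 5)
  t1 <- run_dispersion_test(pr, ps)
  expect_identical(t1, run_dispersion_test(pr, ps))
  # jointly permuting the data rows and conjugating the permutations
  # leaves every paired comparison, hence the p-value, unchanged
  sig <- rpalmrt:::with_seed(6, sample.int(42))
  sig_inv <- order(sig)
  pr2 <- pr
  pr2$Y <- pr$Y[sig]
  pr2$X <- pr$X[sig, , drop = FALSE]
  pr2$Z <- pr$Z[sig, , drop = FALSE]
  ps2 <- ps
  ps2$perms <- lapply(ps$perms, function(p) sig_inv[p[sig]])
  t2 <- run_dispersion_test(pr2, ps2)
  expect_equal(t2$pvalue, t1$pvalue)
  expect_equal(t2$omega_orig, t1$omega_orig, tolerance = 1e-8)
  expect_equal(t2$omega_perm, t1$omega_perm, tolerance = 1e-8)
})

test_that("a doubled case noise scale is detected at n = 200", {
  # beta = 1 doubles the case noise scale; rejection should be far more
  # frequent than the nominal level even in a small Monte-Carlo run
  rejections <- vapply(1:30, function(i) {
    pr <- make_dispersion_problem(n = 200, p = 6, beta = 1, seed = 900 + i,
                                  error_law = "cauchy")
    ps <- sample_permutations(200, 99, seed = 950 + i)
    run_dispersion_test(pr, ps)$pvalue <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.2)
})
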