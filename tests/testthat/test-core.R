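test_that("a response explained exactly by the controls gives p = 1", {
  # the zero response is the one perfect-fit case that stays exact in
  # floating point: every score is exactly zero, so all pairs tie
  set.seed(1)
  n <- 20
  Z <- cbind(1, rnorm(n))
  pr <- palmrt_problem(rep(0, n), rnorm(n), Z)
  tt <- run_test(pr, palmrt_fitter("ols"), palmrt_evaluator("l2"),
                 sample_permutations(n, 49, seed = 2))
  expect_equal(tt$pvalue, 1)
  expect_equal(tt$n_ties, 49)
  # a generic response inside the span leaves only projection round-off
  pr2 <- palmrt_problem(as.numeric(Z %*% c(2, -1)), pr$X, Z)
  sc <- rpalmrt:::pair_scores(pr2, palmrt_fitter("ols"),
                              palmrt_evaluator("l2"),
                              sample_permutations(n, 9, seed = 3))
  expect_lt(max(sc$omega_orig, sc$omega_perm), 1e-20)
})

test_that("results are deterministic given the permutation set", {
  pr <- make_problem(n = 30, p = 3, seed = 3)
  ps <- sample_permutations(30, 49, seed = 4)
  t1 <- run_test(pr, palmrt_fitter("huber"), palmrt_evaluator("huber"), ps)
  t2 <- run_test(pr, palmrt_fitter("huber"), palmrt_evaluator("huber"), ps)
  expect_identical(t1, t2)
})

test_that("the compiled score loop agrees with the generic R loop", {
  pr <- make_problem(n = 25, p = 3, seed = 5, error_law = "t3")
  ps <- sample_permutations(25, 29, seed = 6)
  for (combo in list(c("huber", "huber"), c("ols", "l2"),
                     c("ols", "huber"), c("ols", "l1"))) {
    f <- palmrt_fitter(combo[1])
    e <- palmrt_evaluator(combo[2])
    fast <- rpalmrt:::pair_scores(pr, f, e, ps)
    slow <- rpalmrt:::pair_scores_r(pr, f, e, ps)
    expect_equal(fast$omega_orig, slow$omega_orig, tolerance = 1e-12)
    expect_equal(fast$omega_perm, slow$omega_perm, tolerance = 1e-12)
  }
})

test_that("p-values are invariant to shifting Y along the controls", {
  pr <- make_problem(n = 40, p = 4, seed = 7, error_law = "lognormal")
  ps <- sample_permutations(40, 99, seed = 8)
  for (combo in list(c("huber", "huber"), c("ols", "l2"))) {
    f <- palmrt_fitter(combo[1])
    e <- palmrt_evaluator(combo[2])
    base <- run_test(pr, f, e, ps)
    shifted <- pr
    shifted$Y <- pr$Y + as.numeric(pr$Z %*% rnorm(pr$p, sd = 5))
    expect_equal(run_test(shifted, f, e, ps)$pvalue, base$pvalue)
  }
})

test_that("the comparison array has the exchangeability symmetry", {
  # T(pi1, pi2; eps) = omega(M(eps, X_pi2, [Z_pi1, Z_pi2])) must satisfy
  # T(pi1, pi2; eps_sigma) = T(pi1 o sigma^-1, pi2 o sigma^-1; eps)
  fitter <- palmrt_fitter("huber")
  evaluator <- palmrt_evaluator("huber")
  Tfun <- function(eps, X, Z, p1, p2) {
    Zaug <- cbind(Z[p1, , drop = FALSE], Z[p2, , drop = FALSE])
    evaluator$score(
      rpalmrt:::fit_with_prepare(fitter, eps, X[p2, , drop = FALSE], Zaug))
  }
  for (seed in 1:5) {
    set.seed(seed)
    n <- 18
    eps <- rnorm(n)
    X <- matrix(rnorm(n), n, 1)
    Z <- cbind(1, rnorm(n))
    p1 <- sample.int(n); p2 <- sample.int(n); sig <- sample.int(n)
    sig_inv <- order(sig)
    lhs <- Tfun(eps[sig], X, Z, p1, p2)
    rhs <- Tfun(eps, X, Z, p1[sig_inv], p2[sig_inv])
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("the type I error stays within the finite-sample bound", {
  # scaled-down Monte-Carlo check of the 2*alpha guarantee
  alpha <- 0.05
  n_reps <- 200
  for (m in c("huber-huber", "ols-l2")) {
    cfg <- scenario_config(n = 30, p = 3, error_law = "t3", beta = 0,
                           B = 99, alpha = alpha, n_reps = n_reps,
                           seed = 11, method = m)
    res <- run_study(cfg)
    bound <- 2 * alpha + 3 * sqrt(2 * alpha * (1 - 2 * alpha) / n_reps)
    expect_lte(res$rejection_rate, bound)
  }
})

test_that("errors inside the loop name the offending permutation", {
  set.seed(12)
  n <- 12
  Z <- cbind(1, rnorm(n))
  pr <- palmrt_problem(rep(0, n), rnorm(n), Z)  # exactly zero MAD
  ps <- sample_permutations(n, 5, seed = 13)
  err <- tryCatch(
    run_test(pr, palmrt_fitter("huber"), palmrt_evaluator("huber"), ps),
    error = function(e) e)
  expect_s3_class(err, "rpalmrt_degenerate_scale")
  expect_match(conditionMessage(err), "permutation b = 1")
})
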