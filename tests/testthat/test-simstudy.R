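test_that("generated designs have an intercept and the stated law", {
  d <- gen_design(10, 1, 1, "cauchy", seed = 1)
  expect_equal(d$Z, matrix(1, 10, 1))  # p = 1: intercept only
  expect_identical(gen_design(50, 4, 2, "t3", seed = 2),
                   gen_design(50, 4, 2, "t3", seed = 2))
  big <- gen_design(10000, 3, 1, "cauchy", seed = 3)
  draws <- c(big$X, big$Z[, -1])
  # Cauchy(0,1): median 0, quartiles at +-1
  expect_lt(abs(median(draws)), 0.05)
  expect_equal(unname(diff(quantile(draws, c(0.25, 0.75)))), 2,
               tolerance = 0.05)
  bal <- gen_design(20, 3, 1, "anova_balanced", seed = 4)
  expect_true(all(colSums(bal$Z[, -1, drop = FALSE]) == 0))
  expect_error(gen_design(20, 3, 1, "weibull", seed = 1))
})

test_that("error laws are seeded and match their definitions", {
  expect_identical(gen_errors(100, "lognormal", seed = 5),
                   gen_errors(100, "lognormal", seed = 5))
  expect_true(all(gen_errors(200, "lognormal", seed = 6) > 0))
  e <- gen_errors(100000, "normal", seed = 7)
  expect_equal(mean(e), 0, tolerance = 0.02)
  expect_equal(var(e), 1, tolerance = 0.02)
  # the outlier model plants exactly one extreme entry
  for (seed in 1:10) {
    e <- gen_errors(50, "multinomial_normal", seed = seed)
    expect_equal(sum(abs(e) > 5000), 1)
  }
  # both outlier signs occur across seeds
  signs <- vapply(1:40, function(s) {
    e <- gen_errors(50, "multinomial_normal", seed = s)
    sign(e[which.max(abs(e))])
  }, numeric(1))
  expect_setequal(unique(signs), c(-1, 1))
})

test_that("responses follow the location and dispersion models", {
  d <- gen_design(30, 3, 1, "normal", seed = 8)
  eps <- gen_errors(30, "normal", seed = 9)
  expect_equal(gen_location_response(d$X, d$Z, 0, eps), eps)
  y1 <- gen_location_response(d$X, d$Z, 1, eps)
  y3 <- gen_location_response(d$X, d$Z, 3, eps)
  expect_equal(y3 - y1, 2 * as.numeric(d$X))  # linear in beta
  x <- rep(0:1, 5000)
  eps_big <- gen_errors(10000, "normal", seed = 10)
  yd <- gen_dispersion_response(x, matrix(1, 10000, 1), 1.5, eps_big)
  expect_equal(sd(yd[x == 1]) / sd(yd[x == 0]), 2.5, tolerance = 0.1)
  expect_equal(gen_dispersion_response(x, matrix(1, 10000, 1), 0, eps_big),
               eps_big)
  expect_error(gen_dispersion_response(x, matrix(1, 10000, 1), -1, eps_big),
               class = "rpalmrt_input_error")
})

test_that("study runs are reproducible and scheduling independent", {
  cfg <- scenario_config(n = 25, p = 2, error_law = "normal", beta = 0,
                         B = 19, n_reps = 20, seed = 11, method = "ols-l2")
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(r1, r2)
  r_par <- run_study(cfg, cores = 2)
  expect_equal(r_par$rejection_rate, r1$rejection_rate)
  expect_equal(r1$mc_se,
               sqrt(r1$rejection_rate * (1 - r1$rejection_rate) / 20))
})

test_that("study rows echo the scenario and tolerate stray failures", {
  cfgs <- list(
    scenario_config(n = 25, p = 2, beta = 0, B = 19, n_reps = 10,
                    seed = 12, method = "ftest"),
    scenario_config(n = 30, p = 2, beta = 0, B = 19, n_reps = 10,
                    seed = 13, method = "bptest", model = "dispersion"))
  res <- run_study(cfgs)
  expect_equal(nrow(res), 2)
  expect_equal(res$method, c("ftest", "bptest"))
  expect_equal(res$n_failed, c(0L, 0L))
  expect_true(all(res$rejection_rate >= 0 & res$rejection_rate <= 1))
})

test_that("effect-size calibration hits its target and is monotone", {
  sc <- scenario_config(n = 100, p = 6, error_law = "normal", seed = 14)
  # the null power equals the level, so calibrating to it needs no effect
  expect_equal(calibrate_beta(0.05, sc, n_eval_reps = 500), 0,
               tolerance = 1e-12)
  targets <- c(0.2, 0.4, 0.6, 0.8, 0.95)
  betas <- vapply(targets, calibrate_beta, numeric(1), scenario = sc,
                  n_eval_reps = 1000)
  expect_true(all(diff(betas) > 0))
})
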