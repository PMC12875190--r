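#' Generate a simulated design matrix pair
#'
#' The first column of `Z` is an intercept; every remaining entry of `X`
#' and `Z` is drawn i.i.d. from `design_law`.  The heavy-tailed default
#' (`"cauchy"`) is the benchmark design for stress-testing partial
#' correlation tests; `"anova_balanced"` instead fills each non-intercept
#' column with a randomly ordered balanced set of -1/+1 contrasts.
#'
#' @param n,p,d sample size, number of control columns (including the
#'   intercept), number of covariate-of-interest columns.
#' @param design_law `"cauchy"`, `"normal"`, `"t3"` or `"anova_balanced"`.
#' @param seed integer seed.
#' @return List with matrices `X` (`n x d`) and `Z` (`n x p`).
#' @export
gen_design <- function(n, p, d = 1L, design_law = c("cauchy", "normal", "t3",
                                                    "anova_balanced"),
                       seed = 1L) {
  design_law <- match.arg(design_law)
  check_scalar_number(n, "n", lower = 3)
  check_scalar_number(p, "p", lower = 1)
  check_scalar_number(d, "d", lower = 1)
  n <- as.integer(n); p <- as.integer(p); d <- as.integer(d)
  rlaw <- switch(design_law,
    cauchy = function(k) rcauchy(k),
    normal = function(k) rnorm(k),
    t3 = function(k) rt(k, df = 3),
    anova_balanced = function(k) {
      m <- k / n
      as.vector(vapply(seq_len(m),
                       function(j) sample(rep(c(-1, 1), length.out = n)),
                       numeric(n)))
    })
  with_seed(seed, {
    X <- matrix(rlaw(n * d), n, d)
    Z <- if (p == 1L) matrix(1, n, 1)
         else cbind(1, matrix(rlaw(n * (p - 1L)), n, p - 1L))
    list(X = X, Z = Z)
  })
}

#' Generate simulated errors
#'
#' Error laws used in the benchmark scenarios: standard normal, Student t
#' with 3 df, standard Cauchy, log-normal (`exp` of a standard normal), and
#' the multinomial+normal outlier model: `n - 1` i.i.d. standard normals
#' with one uniformly chosen entry replaced by a draw from
#' `N(s * 1e4, 1)`, `s = +-1` equiprobable — a single severe outlier.
#'
#' @param n sample size.
#' @param error_law one of `"normal"`, `"t3"`, `"cauchy"`,
#'   `"multinomial_normal"`, `"lognormal"`.
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_errors <- function(n, error_law = c("normal", "t3", "cauchy",
                                        "multinomial_normal", "lognormal"),
                       seed = 1L) {
  error_law <- match.arg(error_law)
  check_scalar_number(n, "n", lower = 1)
  n <- as.integer(n)
  with_seed(seed, switch(error_law,
    normal = rnorm(n),
    t3 = rt(n, df = 3),
    cauchy = rcauchy(n),
    lognormal = exp(rnorm(n)),
    multinomial_normal = {
      e <- rnorm(n)
      i <- sample.int(n, 1L)
      s <- sample(c(-1, 1), 1L)
      e[i] <- rnorm(1L, mean = s * 1e4, sd = 1)
      e
    }))
}

#' Location-model response
#'
#' `Y = X beta + Z theta + eps`.  By the test's shift invariance the value
#' of `theta` is irrelevant to every permutation p-value, so the default is
#' `theta = 0`; a nonzero `theta` is accepted for end-to-end invariance
#' checks.
#'
#' @param X,Z design matrices.
#' @param beta effect size (scalar or length-`d` vector).
#' @param errors error vector from [gen_errors()].
#' @param theta control coefficients (default zero).
#' @return Numeric response vector.
#' @export
gen_location_response <- function(X, Z, beta, errors, theta = NULL) {
  X <- as.matrix(X)
  Y <- as.numeric(X %*% rep_len(beta, ncol(X))) + as.numeric(errors)
  if (!is.null(theta)) Y <- Y + as.numeric(as.matrix(Z) %*% theta)
  Y
}

#' Heteroskedastic (dispersion-model) response
#'
#' `Y_i = Z_i' theta + (1 + beta X_i) eps_i` with binary `X`: the noise of
#' the case group (`X = 1`) is scaled by `1 + beta`.
#'
#' @param X_binary 0/1 indicator vector.
#' @param Z control matrix.
#' @param beta dispersion effect, `beta > -1`.
#' @param errors error vector.
#' @param theta control coefficients (default zero).
#' @return Numeric response vector.
#' @export
gen_dispersion_response <- function(X_binary, Z, beta, errors, theta = NULL) {
  x <- as.numeric(X_binary)
  if (!all(x %in% c(0, 1)))
    stop_input("`X_binary` must be a 0/1 indicator")
  check_scalar_number(beta, "beta")
  if (beta <= -1)
    stop_input("`beta` must exceed -1 (noise scale must stay positive)")
  Y <- (1 + beta * x) * as.numeric(errors)
  if (!is.null(theta)) Y <- Y + as.numeric(as.matrix(Z) %*% theta)
  Y
}

# Balanced 0/1 allocation in random order
gen_binary_x <- function(n, seed) {
  with_seed(seed, sample(rep(c(0, 1), length.out = n)))
}

#' Define one simulation scenario
#'
#' One cell of a Monte-Carlo study: a data-generating configuration plus
#' the method applied to each replicate.  Defaults mirror the benchmark
#' study conditions: `p = 6` controls (intercept plus Cauchy draws),
#' univariate Cauchy `X`, `B = 999` permutations, `alpha = 0.05`.
#'
#' @param n sample size.
#' @param p control columns including the intercept.
#' @param d covariate-of-interest columns (location model only).
#' @param error_law,design_law see [gen_errors()], [gen_design()].
#' @param beta effect size (`0` for type I error studies).
#' @param B permutations per test.
#' @param alpha nominal level.
#' @param n_reps Monte-Carlo replicates.
#' @param seed master seed; all per-replicate seeds are derived from it.
#' @param method `"<fitter>-<evaluator>"` (e.g. `"huber-huber"`,
#'   `"ols-l2"`, `"ols-huber"`), `"ftest"`, `"bptest"` or `"dispersion"`.
#' @param model `"location"` (response `Y = X beta + Z theta + eps`) or
#'   `"dispersion"` (`Y = Z theta + (1 + beta X) eps` with balanced binary
#'   `X`).
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n = 100L, p = 6L, d = 1L,
                            error_law = "normal", design_law = "cauchy",
                            beta = 0, B = 999L, alpha = 0.05,
                            n_reps = 1000L, seed = 1L,
                            method = "huber-huber",
                            model = c("location", "dispersion")) {
  model <- match.arg(model)
  check_scalar_number(n, "n", lower = 3)
  check_scalar_number(p, "p", lower = 1)
  check_scalar_number(d, "d", lower = 1)
  if (n <= p + d)
    stop_input("need n > p + d")
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar_number(n_reps, "n_reps", lower = 1)
  check_scalar_number(B, "B", lower = 1)
  error_law <- match.arg(error_law, c("normal", "t3", "cauchy",
                                      "multinomial_normal", "lognormal"))
  design_law <- match.arg(design_law, c("cauchy", "normal", "t3",
                                        "anova_balanced"))
  structure(list(n = as.integer(n), p = as.integer(p), d = as.integer(d),
                 error_law = error_law, design_law = design_law,
                 beta = beta, B = as.integer(B), alpha = alpha,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 method = method, model = model),
            class = "scenario_config")
}

# One replicate's data under a scenario; seeds: design, binary X, errors
gen_scenario_data <- function(cfg, seed_design, seed_x, seed_errors) {
  des <- gen_design(cfg$n, cfg$p, cfg$d, cfg$design_law, seed_design)
  eps <- gen_errors(cfg$n, cfg$error_law, seed_errors)
  if (cfg$model == "dispersion") {
    x <- gen_binary_x(cfg$n, seed_x)
    palmrt_problem(gen_dispersion_response(x, des$Z, cfg$beta, eps),
                   x, des$Z)
  } else {
    palmrt_problem(gen_location_response(des$X, des$Z, cfg$beta, eps),
                   des$X, des$Z)
  }
}

# p-value of the scenario's method on one replicate
apply_method <- function(cfg, problem, seed_perms) {
  m <- cfg$method
  if (m == "ftest") return(partial_f_test(problem))
  if (m == "bptest") return(koenker_bp_test(problem))
  if (m == "dispersion") {
    perms <- sample_permutations(cfg$n, cfg$B, seed_perms)
    return(run_dispersion_test(problem, perms, alpha = cfg$alpha)$pvalue)
  }
  parts <- strsplit(m, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop_input(sprintf("unknown method '%s'", m))
  fitter <- palmrt_fitter(parts[1])
  evaluator <- palmrt_evaluator(parts[2])
  perms <- sample_permutations(cfg$n, cfg$B, seed_perms)
  run_test(problem, fitter, evaluator, perms, alpha = cfg$alpha)$pvalue
}

#' Run a Monte-Carlo study
#'
#' Applies each scenario's method to `n_reps` independently generated
#' datasets and tabulates rejection rates with binomial standard errors.
#' Per-replicate seeds are derived from the scenario's master seed, so the
#' result is fully deterministic and independent of worker scheduling when
#' run in parallel.  Individual replicate failures (e.g. a degenerate
#' scale) are tolerated and counted up to 1% of replicates; beyond that the
#' scenario aborts.
#'
#' @param configs a [scenario_config()] or a list of them.
#' @param cores number of worker processes (forked via \pkg{parallel};
#'   default 1 = serial).
#' @return A data frame with one row per scenario: the configuration echo
#'   plus `rejection_rate`, `mc_se`, `n_failed`.
#' @export
run_study <- function(configs, cores = 1L) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  out <- lapply(configs, run_one_scenario, cores = cores)
  do.call(rbind, out)
}

run_one_scenario <- function(cfg, cores = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  rep_seeds <- derive_seeds(cfg$seed, cfg$n_reps)
  one <- function(i) {
    sds <- derive_seeds(rep_seeds[i], 4L)
    tryCatch({
      problem <- gen_scenario_data(cfg, sds[1], sds[2], sds[3])
      apply_method(cfg, problem, sds[4])
    }, error = function(e) NA_real_)
  }
  pvals <- if (cores > 1L) {
    unlist(parallel::mclapply(seq_len(cfg$n_reps), one, mc.cores = cores))
  } else {
    vapply(seq_len(cfg$n_reps), one, numeric(1))
  }
  n_failed <- sum(is.na(pvals))
  if (n_failed > 0.01 * cfg$n_reps)
    stop_rpalmrt(sprintf("%d of %d replicates failed in scenario (method %s)",
                         n_failed, cfg$n_reps, cfg$method),
                 "rpalmrt_study_error")
  rate <- mean(pvals[!is.na(pvals)] <= cfg$alpha)
  data.frame(n = cfg$n, p = cfg$p, d = cfg$d, error_law = cfg$error_law,
             design_law = cfg$design_law, beta = cfg$beta, B = cfg$B,
             alpha = cfg$alpha, method = cfg$method, model = cfg$model,
             n_reps = cfg$n_reps, seed = cfg$seed,
             rejection_rate = rate,
             mc_se = sqrt(rate * (1 - rate) / sum(!is.na(pvals))),
             n_failed = n_failed,
             stringsAsFactors = FALSE)
}

#' Calibrate the effect size to a target F-test power
#'
#' Finds `beta >= 0` such that the Monte-Carlo power of the partial F-test
#' at level `scenario$alpha` equals `target_power`, by bisection with
#' common random numbers: one set of `n_eval_reps` replicates of
#' `(X, Z, eps)` is drawn up front and reused at every candidate `beta`.
#' Because the response enters the F statistic only through the residualised
#' quantities `e_Z = (I - P_Z) eps` and `x_Z = (I - P_Z) X`, the power at
#' any `beta` is evaluated in closed form from three precomputed sums per
#' replicate, making each bisection step essentially free.
#'
#' @param target_power desired F-test power in (0, 1).
#' @param scenario a [scenario_config()] supplying `n`, `p`, `error_law`,
#'   `design_law`, `alpha` and the calibration seed.
#' @param n_eval_reps replicates per power evaluation (default 2000).
#' @param tol power tolerance for accepting a candidate (default 0.02).
#' @param beta_max upper limit for bracket expansion.
#' @return The calibrated `beta` (scalar).
#' @export
calibrate_beta <- function(target_power, scenario, n_eval_reps = 2000L,
                           tol = 0.02, beta_max = 1e6) {
  check_scalar_number(target_power, "target_power", lower = 1e-6,
                      upper = 1 - 1e-6)
  stopifnot(inherits(scenario, "scenario_config"))
  n <- scenario$n; p <- scenario$p; alpha <- scenario$alpha
  if (scenario$d != 1L)
    stop_input("calibration is defined for a univariate covariate of interest")
  seeds <- derive_seeds(scenario$seed, n_eval_reps)
  stats <- vapply(seeds, function(s) {
    sds <- derive_seeds(s, 4L)
    des <- gen_design(n, p, 1L, scenario$design_law, sds[1])
    eps <- gen_errors(n, scenario$error_law, sds[3])
    qz <- qr(des$Z)
    ez <- qr.resid(qz, eps)
    xz <- qr.resid(qz, as.numeric(des$X))
    c(sum(ez^2), sum(ez * xz), sum(xz^2))
  }, numeric(3))
  df2 <- n - p - 1L
  fcrit <- qf(1 - alpha, 1, df2)
  power_at <- function(beta) {
    rss0 <- stats[1, ] + 2 * beta * stats[2, ] + beta^2 * stats[3, ]
    red <- (stats[2, ] + beta * stats[3, ])^2 / stats[3, ]
    rss1 <- pmax(rss0 - red, 0)
    f <- ifelse(rss1 > 0, red / (rss1 / df2), Inf)
    mean(f > fcrit)
  }
  p0 <- power_at(0)
  if (p0 >= target_power) {
    if (p0 - target_power <= tol) return(0)
    stop_rpalmrt(sprintf(
      "null rejection rate %.3f already exceeds target power %.3f", p0,
      target_power), "rpalmrt_calibration_error")
  }
  hi <- 1
  while (power_at(hi) < target_power) {
    hi <- hi * 2
    if (hi > beta_max)
      stop_rpalmrt(sprintf(
        "no beta below %g reaches target power %.3f (power at %g: %.3f)",
        beta_max, target_power, beta_max, power_at(beta_max)),
        "rpalmrt_calibration_error")
  }
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pm <- power_at(mid)
    if (abs(pm - target_power) <= tol) return(mid)
    if (pm < target_power) lo <- mid else hi <- mid
    if (hi - lo < 1e-10 * (1 + hi)) break
  }
  (lo + hi) / 2
}
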