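# Small simulated problems shared across tests.

make_problem <- function(n = 30, p = 3, d = 1, beta = 0, seed = 1,
                         error_law = "normal", design_law = "normal") {
  des <- gen_design(n, p, d, design_law, seed = seed)
  eps <- gen_errors(n, error_law, seed = seed + 1000)
  palmrt_problem(gen_location_response(des$X, des$Z, beta, eps), des$X, des$Z)
}

make_dispersion_problem <- function(n = 60, p = 3, beta = 0, seed = 1,
                                    error_law = "normal") {
  des <- gen_design(n, p, 1, "cauchy", seed = seed)
  x <- rpalmrt:::gen_binary_x(n, seed + 500)
  eps <- gen_errors(n, error_law, seed = seed + 1000)
  palmrt_problem(gen_dispersion_response(x, des$Z, beta, eps), x, des$Z)
}

# an augmented control matrix like the ones the engine builds
make_zaug <- function(Z, seed = 1) {
  pi_b <- rpalmrt:::with_seed(seed, sample.int(nrow(Z)))
  cbind(Z, Z[pi_b, , drop = FALSE])
}
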