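#' Sample a set of random permutations
#'
#' Draws `B` permutations of `1..n` independently and uniformly from the
#' symmetric group, with replacement.  The identity may occur by chance and
#' duplicates are kept: the exchangeability argument behind the test's
#' finite-sample guarantee assumes i.i.d. draws.  Regeneration from the same
#' `(n, B, seed)` is bit-identical, and the caller's RNG state is left
#' untouched.
#'
#' @param n number of observations.
#' @param B number of permutations to draw.
#' @param seed integer seed governing the draw.
#' @return An object of class `"palmrt_perms"`: list with `perms` (a list of
#'   `B` integer vectors), `n`, `B`, `seed`.
#' @examples
#' ps <- sample_permutations(5, 3, seed = 7)
#' ps$perms[[1]]
#' @export
sample_permutations <- function(n, B, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_input("`n` must be a positive integer")
  if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B))
    stop_input("`B` must be a positive integer")
  n <- as.integer(n)
  B <- as.integer(B)
  seed <- as.integer(seed)
  perms <- with_seed(seed, replicate(B, sample.int(n), simplify = FALSE))
  structure(list(perms = perms, n = n, B = B, seed = seed),
            class = "palmrt_perms")
}

#' @export
print.palmrt_perms <- function(x, ...) {
  cat(sprintf("<palmrt_perms> B = %d permutations of 1..%d (seed %d)\n",
              x$B, x$n, x$seed))
  invisible(x)
}
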