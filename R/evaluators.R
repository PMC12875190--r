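#' Evaluation losses for fitted models
#'
#' An evaluator maps a [fit_summary()] to a single score with the convention
#' that smaller means a better fit.  All shipped scores are symmetric
#' functions of the residual vector, so the composed fit-then-score
#' statistic inherits the row-symmetry the permutation framework needs.
#'
#' `l1_score` and `l2_score` ignore the fitted scale; `scaled_huber_score`
#' standardises the residuals by the fitter's frozen scale before summing
#' the Huber loss, so that the two members of a permutation pair — which
#' share that scale by construction — are compared on equal footing.
#'
#' @param r numeric residual vector.
#' @return A nonnegative score.
#' @name evaluators
NULL

#' @rdname evaluators
#' @export
l2_score <- function(r) sum(as.numeric(r)^2)

#' @rdname evaluators
#' @export
l1_score <- function(r) sum(abs(as.numeric(r)))

#' @rdname evaluators
#' @param fit a [fit_summary()] with a positive `scale`.
#' @param delta Huber corner (default 1.345).
#' @export
scaled_huber_score <- function(fit, delta = 1.345) {
  s <- fit$scale
  if (is.null(s) || is.na(s) || !(s > 0))
    stop_input("scaled Huber evaluation needs a fit with a positive scale estimate")
  sum(huber_rho(fit$residuals / s, delta))
}

#' Construct a registered evaluator
#'
#' Registered names: `"l1"`, `"l2"` (residual-only) and `"huber"` (the
#' scaled Huber norm, requiring a scale-aware fitter).  The paper-style
#' method labels compose a fitter and an evaluator: OLS-L2 is
#' `palmrt_fitter("ols")` with `palmrt_evaluator("l2")`, Huber-Huber is
#' `palmrt_fitter("huber")` with `palmrt_evaluator("huber")`, and so on.
#'
#' @param name `"l1"`, `"l2"` or `"huber"`.
#' @param delta Huber corner for `name = "huber"`.
#' @return An object of class `"palmrt_evaluator"`: list with `name`,
#'   `score(fit)` and `needs_scale`.
#' @export
palmrt_evaluator <- function(name = c("l2", "l1", "huber"), delta = 1.345) {
  name <- match.arg(name)
  switch(name,
    l2 = structure(list(name = "l2", needs_scale = FALSE,
                        score = function(fit) l2_score(fit$residuals),
                        engine = list(code = 0L, delta = NA_real_)),
                   class = "palmrt_evaluator"),
    l1 = structure(list(name = "l1", needs_scale = FALSE,
                        score = function(fit) l1_score(fit$residuals),
                        engine = list(code = 1L, delta = NA_real_)),
                   class = "palmrt_evaluator"),
    huber = structure(list(name = "huber", needs_scale = TRUE,
                           score = function(fit) scaled_huber_score(fit, delta),
                           engine = list(code = 2L, delta = delta)),
                      class = "palmrt_evaluator")
  )
}
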