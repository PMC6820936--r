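# Economic environment: treatment value, adverse effects, production cost,
# two candidate biomarker tests, and the investment-cost distribution bound.

#' Specify a candidate biomarker test
#'
#' A diagnostic test attached to one of the two candidate predictive
#' biomarkers.  Sensitivity is the probability that a responder tests
#' positive; specificity the probability that a non-responder tests negative.
#' The prior is the ex-ante probability that this biomarker is the one truly
#' associated with treatment response.
#'
#' @param sensitivity Probability a responder tests positive, in \[0, 1\].
#' @param specificity Probability a non-responder tests negative, in \[0, 1\].
#' @param price Cost of administering the test to one patient, >= 0.
#' @param prior Probability this biomarker is the true one, in (0, 1).
#' @return An object of class `test_spec`.
#' @examples
#' test_spec(sensitivity = 0.9, specificity = 0.9, price = 0.5, prior = 0.5)
#' @export
test_spec <- function(sensitivity, specificity, price, prior) {
  stopifnot(
    is.numeric(sensitivity), length(sensitivity) == 1L, is.finite(sensitivity),
    is.numeric(specificity), length(specificity) == 1L, is.finite(specificity),
    is.numeric(price), length(price) == 1L, is.finite(price),
    is.numeric(prior), length(prior) == 1L, is.finite(prior)
  )
  if (sensitivity < 0 || sensitivity > 1)
    stop("`sensitivity` must lie in [0, 1]", call. = FALSE)
  if (specificity < 0 || specificity > 1)
    stop("`specificity` must lie in [0, 1]", call. = FALSE)
  if (price < 0)
    stop("`price` must be non-negative", call. = FALSE)
  if (prior <= 0 || prior >= 1)
    stop("`prior` must lie strictly inside (0, 1)", call. = FALSE)
  structure(
    list(s = sensitivity, e = specificity, t = price, q = prior),
    class = "test_spec"
  )
}

#' Expected test characteristics under the biomarker prior
#'
#' Aggregates the two candidate tests into the prior-weighted expected
#' sensitivity, specificity and test price.  All equilibrium objects of the
#' model depend on the tests only through these expectations, because every
#' payoff is linear in the realized test characteristics.
#'
#' @param tests A list of exactly two [test_spec()] objects whose priors sum
#'   to one.
#' @return A list with components `s`, `e` and `t`: the expected sensitivity,
#'   specificity and per-patient test price.
#' @examples
#' expected_test(list(
#'   test_spec(0.8, 0.9, 0.4, 0.5),
#'   test_spec(1.0, 0.9, 0.6, 0.5)
#' ))
#' @export
expected_test <- function(tests) {
  if (!is.list(tests) || length(tests) != 2L ||
      !all(vapply(tests, inherits, logical(1), "test_spec")))
    stop("`tests` must be a list of exactly two `test_spec` objects",
         call. = FALSE)
  q <- vapply(tests, `[[`, numeric(1), "q")
  if (abs(sum(q) - 1) > 1e-9)
    stop("biomarker priors must sum to 1 (got ",
         format(sum(q), digits = 12), ")", call. = FALSE)
  list(
    s = sum(q * vapply(tests, `[[`, numeric(1), "s")),
    e = sum(q * vapply(tests, `[[`, numeric(1), "e")),
    t = sum(q * vapply(tests, `[[`, numeric(1), "t"))
  )
}

#' Construct the economic environment of the pricing game
#'
#' Bundles the health value of a cure `B`, the adverse-effect loss `L`
#' suffered by a treated non-responder, the unit production cost `c`, the two
#' candidate biomarker tests, and the upper bound `I_bar` of the uniform
#' R&D investment-cost distribution.  All monetary-equivalent quantities share
#' a single unit.  The prior-weighted expected test characteristics
#' (`s`, `e`, `t`) are derived on construction.
#'
#' Construction enforces only typing and positivity; the model's economic
#' assumptions are checked by [validate_params()], which returns a report
#' rather than throwing, so that deliberately violating scenarios can be
#' built for negative testing.
#'
#' @param B Health benefit of curing one responder, > 0.
#' @param L Health loss of treating one non-responder, > 0.
#' @param c Unit production cost of the treatment, >= 0.
#' @param tests List of two [test_spec()] objects; priors must sum to one.
#' @param I_bar Upper bound of the Uniform(0, I_bar) investment-cost
#'   distribution, > 0.
#' @return An object of class `econ_params` with fields `B`, `L`, `c`,
#'   `tests`, the expected characteristics `s`, `e`, `t`, and `I_bar`.
#' @examples
#' tests <- list(test_spec(0.9, 0.9, 0.5, 0.5), test_spec(0.9, 0.9, 0.5, 0.5))
#' econ_params(B = 10, L = 4, c = 1, tests = tests, I_bar = 10)
#' @export
econ_params <- function(B, L, c, tests, I_bar) {
  stopifnot(
    is.numeric(B), length(B) == 1L, is.finite(B),
    is.numeric(L), length(L) == 1L, is.finite(L),
    is.numeric(c), length(c) == 1L, is.finite(c),
    is.numeric(I_bar), length(I_bar) == 1L, is.finite(I_bar)
  )
  if (B <= 0) stop("`B` must be positive", call. = FALSE)
  if (L <= 0) stop("`L` must be positive", call. = FALSE)
  if (c < 0) stop("`c` must be non-negative", call. = FALSE)
  if (I_bar <= 0) stop("`I_bar` must be positive", call. = FALSE)
  et <- expected_test(tests)
  structure(
    list(B = B, L = L, c = c, tests = tests,
         s = et$s, e = et$e, t = et$t, I_bar = I_bar),
    class = "econ_params"
  )
}

# The maintained assumptions, each as (name, lhs, rhs, strict-inequality).
# Kept in one place so validation, diagnostics and the scenario generator
# agree on the list.
assumption_table <- function(p) {
  with(p, data.frame(
    assumption = c(
      "L > c", "L > t", "e + s > 1",
      "t < s(B - c)", "t < e(c + L)",
      "(c + L)(B - c)(e + s - 1) > t(B + L)",
      "I_bar > 0"
    ),
    lhs = c(L, L, e + s, s * (B - c), e * (c + L),
            (c + L) * (B - c) * (e + s - 1), I_bar),
    rhs = c(c, t, 1, t, t, t * (B + L), 0),
    stringsAsFactors = FALSE
  ))
}

#' Validate the model's maintained assumptions
#'
#' Evaluates every maintained economic assumption on a parameter set and
#' reports, per assumption, whether it holds together with the two sides of
#' the inequality.  Validation never throws: downstream solvers refuse
#' inadmissible parameters, but the report itself can be inspected for any
#' parameter set, including deliberately violating ones.
#'
#' @param params An [econ_params()] object.
#' @return A data frame of class `validation_report` with columns
#'   `assumption`, `satisfied`, `lhs` and `rhs`, one row per maintained
#'   assumption (all inequalities strict, of the form `lhs > rhs`).
#' @seealso [is_admissible()]
#' @examples
#' validate_params(canonical_scenario()$params)
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "econ_params"))
  tab <- assumption_table(params)
  out <- data.frame(
    assumption = tab$assumption,
    satisfied = tab$lhs > tab$rhs,
    lhs = tab$lhs,
    rhs = tab$rhs,
    stringsAsFactors = FALSE
  )
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Is a parameter set admissible?
#'
#' @param params An [econ_params()] object.
#' @return `TRUE` iff every maintained assumption in [validate_params()]
#'   holds.
#' @export
is_admissible <- function(params) {
  all(validate_params(params)$satisfied)
}

assert_admissible <- function(params) {
  rep <- validate_params(params)
  if (!all(rep$satisfied)) {
    bad <- rep$assumption[!rep$satisfied]
    stop("inadmissible parameters; violated assumption(s): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  invisible(params)
}

#' @export
print.econ_params <- function(x, ...) {
  cat("Economic environment (pay-for-performance pricing game)\n")
  cat(sprintf("  B = %g, L = %g, c = %g, I_bar = %g\n",
              x$B, x$L, x$c, x$I_bar))
  cat(sprintf("  expected test: s = %g, e = %g, t = %g\n", x$s, x$e, x$t))
  for (i in seq_along(x$tests)) {
    ts <- x$tests[[i]]
    cat(sprintf("  test %d: s = %g, e = %g, t = %g, prior q = %g\n",
                i, ts$s, ts$e, ts$t, ts$q))
  }
  cat(if (is_admissible(x)) "  all maintained assumptions hold\n"
      else "  WARNING: some maintained assumptions are violated\n")
  invisible(x)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Assumption check:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-40s (lhs = %.6g, rhs = %.6g)\n",
                if (x$satisfied[i]) "ok" else "FAIL",
                x$assumption[i], x$lhs[i], x$rhs[i]))
  }
  invisible(x)
}
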