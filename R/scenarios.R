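# Scenario generation: admissible (and deliberately inadmissible) parameter
# sets with response-rate grids, so every stage of the analysis can be
# exercised without external data.

#' Default sampling ranges for scenario generation
#'
#' Bounds within which [sample_admissible()] draws each primitive parameter
#' uniformly.  Chosen so that all maintained assumptions are simultaneously
#' satisfiable with a workable acceptance rate; override any element to
#' focus the sampler.
#'
#' @return Named list of length-2 numeric ranges: `B`, `L`, `c`, `t`
#'   (per-test price), `se` (per-test sensitivity and specificity), `q1`
#'   (prior on the first biomarker) and `I_bar`.
#' @export
default_ranges <- function() {
  list(B = c(2, 50), L = c(0.5, 20), c = c(0, 5), t = c(0.01, 2),
       se = c(0.6, 1), q1 = c(0.1, 0.9), I_bar = c(1, 100))
}

new_scenario <- function(params, delta_grid, seed = NULL) {
  stopifnot(!is.unsorted(delta_grid, strictly = TRUE),
            all(delta_grid >= 0), all(delta_grid <= 1))
  structure(
    list(params = params, delta_grid = delta_grid, seed = seed,
         admissible = is_admissible(params)),
    class = "scenario"
  )
}

draw_scenario <- function(r) {
  B <- stats::runif(1, r$B[1], r$B[2])
  L <- stats::runif(1, r$L[1], r$L[2])
  cc <- stats::runif(1, r$c[1], r$c[2])
  q1 <- stats::runif(1, r$q1[1], r$q1[2])
  tests <- list(
    test_spec(stats::runif(1, r$se[1], r$se[2]),
              stats::runif(1, r$se[1], r$se[2]),
              stats::runif(1, r$t[1], r$t[2]), q1),
    test_spec(stats::runif(1, r$se[1], r$se[2]),
              stats::runif(1, r$se[1], r$se[2]),
              stats::runif(1, r$t[1], r$t[2]), 1 - q1)
  )
  econ_params(B, L, cc, tests, stats::runif(1, r$I_bar[1], r$I_bar[2]))
}

#' Sample admissible parameter scenarios
#'
#' Rejection-samples the primitive parameters uniformly within `ranges`
#' until `n` parameter sets satisfy every maintained assumption.  The
#' acceptance rate is attached to the result; if the rejection budget is
#' exhausted, the error message names the assumption that failed most often.
#'
#' By default the sampler also requires the investment-cost bound to exceed
#' the peak equilibrium investment threshold ([peak_invest_threshold()]):
#' the model maintains that `I_bar` is high enough for the R&D probability
#' to stay interior, and the closed-form prices are optima only under that
#' condition.  Set `require_interior = FALSE` to sample scenarios where the
#' probability may saturate.
#'
#' @param n Number of admissible scenarios to return.
#' @param ranges Sampling bounds, see [default_ranges()].
#' @param seed Optional RNG seed.
#' @param grid_n Length of each scenario's response-rate grid (interior,
#'   equally spaced).
#' @param max_tries Rejection budget (total draws allowed).
#' @param require_interior Also require `I_bar > peak_invest_threshold()`.
#' @return A list of `scenario` objects, each admissible, with attribute
#'   `acceptance_rate`.
#' @examples
#' sc <- sample_admissible(5, seed = 1)
#' attr(sc, "acceptance_rate")
#' @export
sample_admissible <- function(n, ranges = default_ranges(), seed = NULL,
                              grid_n = 101L, max_tries = 400L * n,
                              require_interior = TRUE) {
  stopifnot(n >= 1)
  r <- utils::modifyList(default_ranges(), ranges)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq_len(grid_n) / (grid_n + 1)
  out <- vector("list", n)
  got <- 0L; tries <- 0L
  fail_count <- integer(0)
  while (got < n) {
    if (tries >= max_tries) {
      worst <- names(sort(fail_count, decreasing = TRUE))[1]
      stop("rejection budget exhausted after ", tries, " draws (",
           got, "/", n, " admissible); most-violated assumption: ",
           worst, call. = FALSE)
    }
    tries <- tries + 1L
    p <- draw_scenario(r)
    rep <- validate_params(p)
    bad <- rep$assumption[!rep$satisfied]
    if (length(bad) == 0 && require_interior &&
        p$I_bar <= peak_invest_threshold(p))
      bad <- "I_bar > peak invest threshold (interior R&D probability)"
    if (length(bad) == 0) {
      got <- got + 1L
      out[[got]] <- new_scenario(p, grid, seed = seed)
    } else {
      for (b in bad)
        fail_count[b] <- (if (b %in% names(fail_count)) fail_count[b] else 0L) + 1L
    }
  }
  attr(out, "acceptance_rate") <- n / tries
  out
}

#' The canonical reference scenario
#'
#' A fixed, admissible environment used throughout the package's examples
#' and verification suites: `B = 10`, `L = 4`, `c = 1`, two identical
#' candidate tests with sensitivity and specificity 0.9, price 0.5 and
#' priors 0.5 each, `I_bar = 10`, and a 200-point interior response-rate
#' grid.  Its thresholds are (to 6 d.p.) `delta_hat = 0.285714`,
#' `delta_lower = 0.095238`, `delta_tilde = 0.357143`, `delta_bar = 0.75`,
#' `delta_cross = 0.631579`.
#'
#' @return A `scenario` object.
#' @export
canonical_scenario <- function() {
  tests <- list(test_spec(0.9, 0.9, 0.5, 0.5),
                test_spec(0.9, 0.9, 0.5, 0.5))
  new_scenario(econ_params(B = 10, L = 4, c = 1, tests = tests, I_bar = 10),
               delta_grid = seq_len(200L) / 201)
}

#' Perfect-test variant of a scenario
#'
#' Same economic environment with both candidate tests made error-free
#' (sensitivity = specificity = 1).  In this limit the thresholds reduce to
#' simple forms — `delta_lower = t / (B - c)`,
#' `delta_bar = (L + c - t) / (L + c)`, price crossing at
#' `1 - t / (L - c)` — used by the reduction tests.
#'
#' @param scenario A `scenario` object.
#' @return The modified `scenario`.
#' @export
perfect_test_variant <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  p <- scenario$params
  tests <- lapply(p$tests, function(ts) test_spec(1, 1, ts$t, ts$q))
  new_scenario(econ_params(p$B, p$L, p$c, tests, p$I_bar),
               scenario$delta_grid, scenario$seed)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario (%s), delta grid of %d points\n",
              if (x$admissible) "admissible" else "NOT admissible",
              length(x$delta_grid)))
  print(x$params)
  invisible(x)
}
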