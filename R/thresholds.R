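# Response-rate thresholds.  The proportion of responders delta is the
# game's state variable; five cutpoints partition [0, 1] into the decision
# regimes of the equilibrium.

#' Authorization threshold
#'
#' Minimum proportion of responders at which the treatment is authorized
#' without stratification: the population expected health benefit
#' `delta * B - (1 - delta) * L` is non-negative iff `delta >= L / (B + L)`.
#'
#' @param params Admissible [econ_params()].
#' @return The threshold `L / (B + L)`, in (0, 1).
#' @export
delta_hat <- function(params) {
  assert_admissible(params)
  params$L / (params$B + params$L)
}

#' Authority-indifference threshold
#'
#' Below this proportion of responders the health authority is worse off
#' marketing the unstratified treatment even at the lowest price compatible
#' with firm participation (`p_l = c / delta`): the net health benefit
#' `delta * B - c - (1 - delta) * L` is negative iff
#' `delta < (L + c) / (B + L)`.  Strictly exceeds [delta_hat()] whenever
#' `c > 0`.
#'
#' @inheritParams delta_hat
#' @return The threshold `(L + c) / (B + L)`, in (0, 1).
#' @export
delta_tilde <- function(params) {
  assert_admissible(params)
  (params$L + params$c) / (params$B + params$L)
}

#' Marketing-viability threshold
#'
#' Below this proportion of responders even the stratified treatment is not
#' marketed: the equilibrium stratified price in the personalized-only
#' regime falls to the production cost `c` exactly at this point.
#'
#' @inheritParams delta_hat
#' @return `(t + (1 - e)(L - c)) / (s(B - c) + (1 - e)(L - c))`, in (0, 1).
#' @export
delta_lower <- function(params) {
  assert_admissible(params)
  with(params, (t + (1 - e) * (L - c)) / (s * (B - c) + (1 - e) * (L - c)))
}

#' No-stratification threshold
#'
#' Above this proportion of responders the authority prefers treating the
#' whole population and offers no incentive to stratify: the shared-regime
#' stratified price falls to `c` at this point.
#'
#' @inheritParams delta_hat
#' @return `(eL + (2 - e)c - t) / (eL + (2 - e)c + (B - c)(1 - s))`, in (0, 1).
#' @export
delta_bar <- function(params) {
  assert_admissible(params)
  with(params, (e * L + (2 - e) * c - t) /
         (e * L + (2 - e) * c + (B - c) * (1 - s)))
}

#' Price-crossing threshold
#'
#' Within the regime where both stratification and uniform treatment are on
#' the table, the stratified price exceeds the uniform price iff the
#' proportion of responders is below this cutpoint.
#'
#' @inheritParams delta_hat
#' @return `(e(L - c) + 2c(1 - s) - t) / (e(L - c) + 2c(1 - s) + (1 - s)(B - c))`.
#' @export
delta_cross <- function(params) {
  assert_admissible(params)
  with(params, (e * (L - c) + 2 * c * (1 - s) - t) /
         (e * (L - c) + 2 * c * (1 - s) + (1 - s) * (B - c)))
}

#' All five response-rate thresholds
#'
#' @inheritParams delta_hat
#' @return An object of class `threshold_set`: a named list with components
#'   `delta_hat`, `delta_lower`, `delta_tilde`, `delta_bar`, `delta_cross`.
#'   Admissibility guarantees `delta_lower < delta_tilde < delta_bar`.
#' @examples
#' thresholds(canonical_scenario()$params)
#' @export
thresholds <- function(params) {
  assert_admissible(params)
  structure(
    list(
      delta_hat = delta_hat(params),
      delta_lower = delta_lower(params),
      delta_tilde = delta_tilde(params),
      delta_bar = delta_bar(params),
      delta_cross = delta_cross(params)
    ),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Response-rate thresholds:\n")
  cat(sprintf("  authorization      delta_hat   = %.6f\n", x$delta_hat))
  cat(sprintf("  marketing          delta_lower = %.6f\n", x$delta_lower))
  cat(sprintf("  indifference       delta_tilde = %.6f\n", x$delta_tilde))
  cat(sprintf("  no-stratification  delta_bar   = %.6f\n", x$delta_bar))
  cat(sprintf("  price-crossing     delta_cross = %.6f\n", x$delta_cross))
  invisible(x)
}

#' Response-rate window with a positive R&D probability
#'
#' The equilibrium stratified price exceeds production cost on the whole
#' interval `(delta_lower, delta_bar)`, but with `c > 0` the firm's
#' investment threshold — its gross stratified profit at that price — turns
#' positive only strictly inside it.  Outside this window the R&D
#' probability is zero at any price: the positive-profit and
#' positive-surplus price ranges do not overlap, so stratification cannot be
#' induced.  The window endpoints are the roots of the two investment
#' thresholds evaluated at the equilibrium prices:
#' `(t + (1 - e)(L + c)) / (s(B - c) + (1 - e)(L + c))` and
#' `(e(c + L) - t) / (e(c + L) + (B - c)(1 - s))`.  With a perfect test
#' (`s = e = 1`) the window fills the whole marketing interval.
#'
#' @inheritParams delta_hat
#' @return Numeric length-2 vector, the open interval of response rates with
#'   a strictly positive equilibrium R&D probability; it always contains
#'   `delta_tilde`.
#' @export
rnd_window <- function(params) {
  assert_admissible(params)
  with(params, c(
    (t + (1 - e) * (L + c)) / (s * (B - c) + (1 - e) * (L + c)),
    (e * (c + L) - t) / (e * (c + L) + (B - c) * (1 - s))
  ))
}

#' Largest equilibrium investment threshold across response rates
#'
#' The firm's equilibrium investment threshold rises with the response rate
#' in the personalized-only regime and falls in the shared regime, peaking
#' at the indifference threshold where it equals
#' `((B - c)(L + c)(e + s - 1)/(B + L) - t) / 2`.  The model's closed-form
#' prices are interior optima only while the investment-cost bound exceeds
#' this peak (`I_bar` "sufficiently high"); otherwise the R&D probability
#' saturates at one and [solve_equilibrium()] raises its `clamped` flag.
#'
#' @inheritParams delta_hat
#' @return The peak threshold (monetary units).
#' @export
peak_invest_threshold <- function(params) {
  assert_admissible(params)
  with(params,
       ((B - c) * (L + c) * (e + s - 1) / (B + L) - t) / 2)
}

#' Regime labels of the equilibrium
#'
#' @return Character vector of the four regime labels in increasing order of
#'   the proportion of responders.
#' @export
regime_levels <- function() {
  c("not_marketed", "pm_only", "pm_or_all", "all_patients")
}

#' Classify a proportion of responders into its decision regime
#'
#' Intervals are half-open on the right: `[delta_lower, delta_tilde)` is the
#' personalized-only regime, `[delta_tilde, delta_bar)` the regime where
#' stratification competes with uniform treatment, and `[delta_bar, 1]` the
#' uniform-treatment regime.  At `delta = delta_lower` the personalized-only
#' equilibrium is degenerate (price equals cost, R&D probability zero), so
#' placing the boundary on either side leads to identical outcomes.
#'
#' @param delta Proportion(s) of responders in \[0, 1\]; vectorized.
#' @param thr A `threshold_set` from [thresholds()], or an [econ_params()]
#'   object (thresholds are then computed).
#' @return A factor with levels [regime_levels()].
#' @examples
#' thr <- thresholds(canonical_scenario()$params)
#' classify_regime(c(0.05, 0.2, 0.5, 0.8), thr)
#' @export
classify_regime <- function(delta, thr) {
  if (inherits(thr, "econ_params")) thr <- thresholds(thr)
  stopifnot(inherits(thr, "threshold_set"), is.numeric(delta))
  if (any(delta < 0 | delta > 1))
    stop("`delta` must lie in [0, 1]", call. = FALSE)
  lab <- ifelse(delta < thr$delta_lower, "not_marketed",
         ifelse(delta < thr$delta_tilde, "pm_only",
         ifelse(delta < thr$delta_bar, "pm_or_all", "all_patients")))
  factor(lab, levels = regime_levels())
}
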