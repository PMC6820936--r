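# The health authority's side: equilibrium prices, expected net health
# benefits, the pricing objectives it maximizes, and the assembled
# subgame perfect equilibrium at any proportion of responders.

#' Uniform-treatment price
#'
#' When the treatment is given to all patients the authority appropriates
#' the whole surplus, leaving the firm with exactly zero profit: the
#' participation constraint `delta * p_l - c >= 0` binds, so
#' `p_l = c / delta`.
#'
#' @param delta Proportion of responders, > 0; vectorized.
#' @param c Unit production cost.
#' @return The price `c / delta`.
#' @export
price_low <- function(delta, c) {
  stopifnot(all(delta > 0))
  c / delta
}

#' Stratified price in the personalized-only regime
#'
#' For `delta` in `[delta_lower, delta_tilde)` the authority discourages
#' unstratified authorization and chooses `p_h` to maximize the R&D
#' probability times the stratified net health benefit.  The interior
#' optimum is
#' `p_h = c + (s delta (B - c) - t - (1 - delta)(1 - e)(L - c)) / (2 s delta)`.
#' The price rises with the proportion of responders and with both test
#' characteristics, and falls to `c` exactly at `delta_lower`.
#'
#' @param delta Proportion of responders in `[delta_lower, delta_tilde]`;
#'   vectorized.  The upper endpoint is admitted so continuity with the
#'   shared-regime price can be evaluated.
#' @param params Admissible [econ_params()].
#' @return The equilibrium stratified price.
#' @export
price_high_pm_only <- function(delta, params) {
  assert_admissible(params)
  dl <- delta_lower(params); dt <- delta_tilde(params)
  if (any(delta < dl))
    stop("below `delta_lower` the treatment is not marketed; ",
         "the stratified price is undefined", call. = FALSE)
  if (any(delta > dt))
    stop("above `delta_tilde` use `price_high_shared()`", call. = FALSE)
  with(params,
       c + (s * delta * (B - c) - t - (1 - delta) * (1 - e) * (L - c)) /
         (2 * s * delta))
}

#' Stratified price in the shared regime
#'
#' For `delta` in `[delta_tilde, delta_bar)` the firm could also market to
#' everyone at `p_l = c / delta`; the authority's optimal stratified price is
#' `p_h = c + ((1 - delta)(eL + (2 - e)c) - delta (B - c)(1 - s) - t) / (2 s delta)`.
#' It decreases in `delta` and reaches `c` at `delta_bar`; for
#' `delta >= delta_bar` any price at or below cost is optimal (no R&D takes
#' place) and the supremum `c` is returned as the canonical representative,
#' keeping the price path continuous.
#'
#' @param delta Proportion of responders in `[delta_tilde, 1]`; vectorized.
#' @param params Admissible [econ_params()].
#' @return The equilibrium stratified price.
#' @export
price_high_shared <- function(delta, params) {
  assert_admissible(params)
  dt <- delta_tilde(params); db <- delta_bar(params)
  if (any(delta < dt))
    stop("below `delta_tilde` use `price_high_pm_only()`", call. = FALSE)
  p <- with(params,
            c + ((1 - delta) * (e * L + (2 - e) * c) -
                   delta * (B - c) * (1 - s) - t) / (2 * s * delta))
  ifelse(delta >= db, params$c, p)
}

#' Expected net health benefit under stratification
#'
#' The test is administered to the whole (unit) population at expected price
#' `t`; the `s * delta` identified responders are cured and paid for at
#' `p_h`; the `(1 - delta)(1 - e)` false positives are treated and suffer
#' the adverse effect: `s delta (B - p_h) - (1 - delta)(1 - e) L - t`.
#'
#' @param delta Proportion of responders; vectorized.
#' @param p_h Stratified price; vectorized.
#' @param params An [econ_params()] object.
#' @return Net health benefit per unit population.
#' @export
nhb_stratified <- function(delta, p_h, params) {
  with(params, s * delta * (B - p_h) - (1 - delta) * (1 - e) * L - t)
}

#' Expected net health benefit without stratification
#'
#' All patients are treated; responders are cured and paid for at `p_l`,
#' non-responders suffer the adverse effect:
#' `delta (B - p_l) - (1 - delta) L`.
#'
#' @param delta Proportion of responders; vectorized.
#' @param p_l Uniform-treatment price; vectorized.
#' @param params An [econ_params()] object.
#' @return Net health benefit per unit population.
#' @export
nhb_uniform <- function(delta, p_l, params) {
  delta * (params$B - p_l) - (1 - delta) * params$L
}

#' Authority's pricing objective in the personalized-only regime
#'
#' `F(I(p_h)) * nhb_stratified(delta, p_h)` with `F` the Uniform(0, I_bar)
#' distribution function (clamped to \[0, 1\]).  Used directly by the
#' numerical oracle; the closed form [price_high_pm_only()] is its interior
#' argmax.
#'
#' @param p_h Candidate stratified price; vectorized.
#' @param delta Proportion of responders.
#' @param params Admissible [econ_params()].
#' @return Objective value.
#' @export
objective_p1 <- function(p_h, delta, params) {
  thr <- profit_stratified_gross(delta, p_h, params)
  f <- pmin(pmax(thr / params$I_bar, 0), 1)
  f * nhb_stratified(delta, p_h, params)
}

#' Authority's pricing objective in the shared regime
#'
#' After substituting the binding uniform price `p_l = c / delta`, the
#' objective is `F(I(p_h, c/delta)) * bracket + (delta B - c - (1 - delta) L)`
#' with `bracket = s delta (B - p_h) + e (1 - delta) L - t - delta B + c`:
#' the authority's gain from stratification over its uniform-treatment
#' fallback, weighted by the R&D probability.
#'
#' @inheritParams objective_p1
#' @return Objective value.
#' @export
objective_p2 <- function(p_h, delta, params) {
  thr <- profit_stratified_gross(delta, p_h, params)  # fallback profit is 0
  f <- pmin(pmax(thr / params$I_bar, 0), 1)
  bracket <- with(params,
                  s * delta * (B - p_h) + e * (1 - delta) * L - t -
                    delta * B + c)
  fallback <- with(params, delta * B - c - (1 - delta) * L)
  f * bracket + fallback
}

#' Solve the pricing game at one proportion of responders
#'
#' Assembles the subgame perfect equilibrium: the authority's announced
#' prices, the firm's investment threshold and R&D probability, and both
#' players' expected payoffs, in the regime `delta` falls into.
#'
#' * **not marketed** (`delta < delta_lower`): no viable price exists; no
#'   prices, zero payoffs.
#' * **personalized only** (`delta_lower <= delta < delta_tilde`): the
#'   authority prices only stratified marketing ([price_high_pm_only()]);
#'   the treatment reaches patients only if the firm's investment cost is
#'   low enough.
#' * **personalized or uniform** (`delta_tilde <= delta < delta_bar`): both
#'   prices are announced ([price_high_shared()], `p_l = c / delta`); the
#'   firm stratifies when its investment cost is low, otherwise everyone is
#'   treated.
#' * **all patients** (`delta >= delta_bar`): no stratification incentive;
#'   `p_l = c / delta`, `p_h = c`, R&D probability zero.
#'
#' The firm's expected profit is ex ante: the investment option value
#' `threshold^2 / (2 I_bar)` (its fallback profit is zero in every regime).
#' The authority's expected net health benefit equals the R&D probability
#' times its stratification surplus plus, where uniform treatment is on the
#' table, the fallback `delta B - c - (1 - delta) L`.
#'
#' @param delta Proportion of responders in \[0, 1\] (scalar).
#' @param params Admissible [econ_params()].
#' @return An object of class `equilibrium_outcome`: list with `delta`,
#'   `regime`, `policy` ([pricing_policy()]), `invest_threshold`,
#'   `rnd_prob`, `nhb`, `firm_profit`, `marketed` and `clamped`.
#' @examples
#' solve_equilibrium(0.5, canonical_scenario()$params)
#' @export
solve_equilibrium <- function(delta, params) {
  stopifnot(length(delta) == 1L, delta >= 0, delta <= 1)
  assert_admissible(params)
  thr_set <- thresholds(params)
  regime <- as.character(classify_regime(delta, thr_set))
  I_bar <- params$I_bar

  if (regime == "not_marketed") {
    out <- list(delta = delta, regime = regime,
                policy = pricing_policy(),
                invest_threshold = NA_real_, rnd_prob = 0,
                nhb = 0, firm_profit = 0,
                marketed = FALSE, clamped = FALSE)
  } else if (regime == "pm_only") {
    p_h <- price_high_pm_only(delta, params)
    pol <- pricing_policy(p_h = p_h)
    thr <- invest_threshold(delta, pol, params, authorization_feasible = FALSE)
    prob <- rnd_probability(thr, I_bar)
    out <- list(delta = delta, regime = regime, policy = pol,
                invest_threshold = thr, rnd_prob = as.numeric(prob),
                nhb = as.numeric(prob) * nhb_stratified(delta, p_h, params),
                firm_profit = expected_option_value(thr, I_bar),
                marketed = TRUE, clamped = attr(prob, "clamped"))
  } else if (regime == "pm_or_all") {
    p_h <- price_high_shared(delta, params)
    p_l <- price_low(delta, params$c)
    pol <- pricing_policy(p_l = p_l, p_h = p_h)
    thr <- invest_threshold(delta, pol, params, authorization_feasible = TRUE)
    prob <- rnd_probability(thr, I_bar)
    bracket <- with(params,
                    s * delta * (B - p_h) + e * (1 - delta) * L - t -
                      delta * B + c)
    fallback <- with(params, delta * B - c - (1 - delta) * L)
    out <- list(delta = delta, regime = regime, policy = pol,
                invest_threshold = thr, rnd_prob = as.numeric(prob),
                nhb = as.numeric(prob) * bracket + fallback,
                firm_profit = expected_option_value(thr, I_bar),
                marketed = TRUE, clamped = attr(prob, "clamped"))
  } else {
    p_l <- price_low(delta, params$c)
    fallback <- with(params, delta * B - c - (1 - delta) * L)
    out <- list(delta = delta, regime = regime,
                policy = pricing_policy(p_l = p_l, p_h = params$c),
                invest_threshold = NA_real_, rnd_prob = 0,
                nhb = fallback, firm_profit = 0,
                marketed = TRUE, clamped = FALSE)
  }
  structure(out, class = "equilibrium_outcome")
}

# Ex-ante expected firm profit from holding the investment option:
# E[max(threshold - I, 0)] under I ~ Uniform(0, I_bar).
expected_option_value <- function(threshold, I_bar) {
  if (threshold <= 0) return(0)
  if (threshold >= I_bar) return(threshold - I_bar / 2)
  threshold^2 / (2 * I_bar)
}

#' @export
print.equilibrium_outcome <- function(x, ...) {
  cat(sprintf("Equilibrium at delta = %g: regime %s\n", x$delta, x$regime))
  cat(sprintf("  prices: p_l = %s, p_h = %s\n",
              format(x$policy$p_l), format(x$policy$p_h)))
  cat(sprintf("  R&D probability = %g%s\n", x$rnd_prob,
              if (isTRUE(x$clamped)) " (clamped: I_bar not high enough)" else ""))
  cat(sprintf("  expected net health benefit = %g, firm expected profit = %g\n",
              x$nhb, x$firm_profit))
  invisible(x)
}
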