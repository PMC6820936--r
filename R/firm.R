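# The firm's side of the game: profits under each action and the
# investment decision rule given an announced pricing policy.

#' Announce a pricing policy
#'
#' The authority's policy is a pair of pay-for-performance prices: `p_l` per
#' cured patient if the firm markets the treatment to everyone without
#' stratifying, `p_h` per cured patient if the firm invests in R&D and the
#' population is stratified by the biomarker test.  Either price may be
#' absent (`NA`): an absent `p_l` represents a discouraging authorization
#' price (any price at which the firm would make a loss serving everyone),
#' an absent `p_h` means stratified marketing is not priced at all.
#'
#' @param p_l Uniform-treatment price per cured patient, or `NA`.
#' @param p_h Stratified-treatment price per cured patient, or `NA`.
#' @return An object of class `pricing_policy`.
#' @export
pricing_policy <- function(p_l = NA_real_, p_h = NA_real_) {
  stopifnot(length(p_l) == 1L, length(p_h) == 1L)
  p_l <- as.numeric(p_l); p_h <- as.numeric(p_h)
  if (!is.na(p_l) && p_l < 0) stop("`p_l` must be non-negative", call. = FALSE)
  if (!is.na(p_h) && p_h < 0) stop("`p_h` must be non-negative", call. = FALSE)
  structure(list(p_l = p_l, p_h = p_h), class = "pricing_policy")
}

#' Firm's gross profit under stratification
#'
#' Expected profit from marketing only to test-positive patients, before
#' subtracting the R&D investment cost.  The firm produces for every
#' test-positive patient — the `s * delta` true positives and the
#' `(1 - delta) * (1 - e)` false positives — but under pay-for-performance
#' it is paid only for the `s * delta` patients who are cured:
#' `s delta (p_h - c) - c (1 - delta)(1 - e)`.
#'
#' @param delta Proportion of responders in \[0, 1\]; vectorized.
#' @param p_h Stratified price per cured patient; vectorized.
#' @param params An [econ_params()] object.
#' @return Gross stratified profit (monetary units, unit population).
#' @export
profit_stratified_gross <- function(delta, p_h, params) {
  with(params, s * delta * (p_h - c) - c * (1 - delta) * (1 - e))
}

#' Firm's profit from unstratified marketing
#'
#' All patients are treated at unit cost `c`; only the `delta` responders
#' are cured and paid for: `delta * p_l - c`.
#'
#' @param delta Proportion of responders; vectorized.
#' @param p_l Uniform-treatment price per cured patient.
#' @param c Unit production cost.
#' @return Profit per unit population.
#' @export
profit_authorized <- function(delta, p_l, c) {
  delta * p_l - c
}

#' Maximum investment cost at which the firm undertakes R&D
#'
#' The firm invests iff the realized investment cost `I` does not exceed the
#' gross stratified profit minus the best alternative payoff.  When
#' unstratified authorization is feasible the alternative is
#' `max(delta * p_l - c, 0)`; when it is not (the response rate is below the
#' authorization threshold, or the authority discourages authorization with
#' an absent `p_l`), the alternative is exit with zero profit.
#'
#' @param delta Proportion of responders.
#' @param policy A [pricing_policy()]; `p_h` must be present.
#' @param params Admissible [econ_params()].
#' @param authorization_feasible Is applying for unstratified authorization
#'   feasible?  Defaults to `delta >= delta_hat(params)`.
#' @return The investment threshold `I(p_h, p_l)` (may be negative, in which
#'   case the firm never invests).
#' @export
invest_threshold <- function(delta, policy, params,
                             authorization_feasible = NULL) {
  stopifnot(inherits(policy, "pricing_policy"))
  if (is.na(policy$p_h))
    stop("`policy` must offer a stratified price `p_h`", call. = FALSE)
  if (is.null(authorization_feasible))
    authorization_feasible <- delta >= delta_hat(params)
  gross <- profit_stratified_gross(delta, policy$p_h, params)
  if (!authorization_feasible) return(gross)
  if (is.na(policy$p_l)) {
    if (delta >= delta_tilde(params))
      stop("inconsistent policy: authorization is feasible at this delta ",
           "but no authorization price p_l is offered", call. = FALSE)
    # discouraging price: the firm's alternative payoff is zero
    return(gross)
  }
  gross - pmax(profit_authorized(delta, policy$p_l, params$c), 0)
}

#' R&D probability under the uniform investment-cost distribution
#'
#' With `I ~ Uniform(0, I_bar)` the probability of investing is
#' `F(threshold) = threshold / I_bar`, clamped to \[0, 1\].  A threshold above
#' `I_bar` violates the maintained "I_bar sufficiently high" assumption under
#' which the closed-form prices are interior optima; the returned value then
#' carries attribute `clamped = TRUE`.
#'
#' @param threshold Investment threshold from [invest_threshold()]; vectorized.
#' @param I_bar Upper bound of the investment-cost distribution, > 0.
#' @return Probability in \[0, 1\] with logical attribute `clamped`.
#' @export
rnd_probability <- function(threshold, I_bar) {
  stopifnot(I_bar > 0)
  p <- pmin(pmax(threshold / I_bar, 0), 1)
  attr(p, "clamped") <- any(threshold > I_bar)
  p
}

#' The firm's decision given prices and a realized investment cost
#'
#' Implements the firm's best response once it has learnt the proportion of
#' responders and its private investment cost: invest whenever
#' `I <= invest_threshold` (ties resolve to investing — a zero-probability
#' event under the continuous cost distribution); otherwise apply for
#' unstratified authorization when that is feasible and at least breaks
#' even; otherwise exit.
#'
#' @param delta Proportion of responders.
#' @param policy A [pricing_policy()].
#' @param params Admissible [econ_params()].
#' @param I Realized investment cost in \[0, I_bar\].
#' @return An object of class `firm_decision`: list with `action` (one of
#'   `"invest"`, `"apply"`, `"exit"`), `I`, `gross_stratified`,
#'   `authorization_profit` and `threshold`.
#' @export
firm_decide <- function(delta, policy, params, I) {
  stopifnot(inherits(policy, "pricing_policy"),
            I >= 0, I <= params$I_bar)
  feasible <- !is.na(policy$p_l) && delta >= delta_hat(params)
  auth_profit <- if (feasible)
    profit_authorized(delta, policy$p_l, params$c) else NA_real_
  if (!is.na(policy$p_h)) {
    thr <- invest_threshold(delta, policy, params,
                            authorization_feasible = feasible)
    gross <- profit_stratified_gross(delta, policy$p_h, params)
  } else {
    thr <- -Inf
    gross <- NA_real_
  }
  action <- if (I <= thr) "invest"
    else if (feasible && !is.na(auth_profit) && auth_profit >= 0) "apply"
    else "exit"
  structure(
    list(action = action, I = I, gross_stratified = gross,
         authorization_profit = auth_profit, threshold = thr),
    class = "firm_decision"
  )
}

#' @export
print.firm_decision <- function(x, ...) {
  cat(sprintf("Firm decision: %s (I = %g, invest threshold = %g)\n",
              toupper(x$action), x$I, x$threshold))
  invisible(x)
}
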