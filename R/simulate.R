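# Monte Carlo machinery: finite patient cohorts screened by a realized
# biomarker test, and replicated play of the full game.  Confirms that the
# analytic expected payoffs are the means of simulated ones.

#' Simulate screening of a finite patient cohort
#'
#' Each of `N` patients is independently a responder with probability
#' `delta`; responders test positive with the test's sensitivity,
#' non-responders test negative with its specificity.  Under stratification
#' the test positives are treated, the true positives are cured (responder
#' efficacy is one) and the false positives suffer the adverse effect.
#'
#' @param N Cohort size, >= 1.
#' @param delta Proportion of responders in \[0, 1\].
#' @param test A [test_spec()] object.
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `cohort_outcome`: list of counts `n`,
#'   `responders`, `tp`, `fp`, `tn`, `fn`, `treated` (= `tp + fp`),
#'   `cured` (= `tp`) and `adverse` (= `fp`).
#' @examples
#' simulate_cohort(1000, 0.5, test_spec(0.9, 0.9, 0.5, 0.5), seed = 1)
#' @export
simulate_cohort <- function(N, delta, test, seed = NULL) {
  stopifnot(N >= 1, delta >= 0, delta <= 1, inherits(test, "test_spec"))
  if (!is.null(seed)) set.seed(seed)
  responders <- stats::rbinom(1L, N, delta)
  tp <- stats::rbinom(1L, responders, test$s)
  fp <- stats::rbinom(1L, N - responders, 1 - test$e)
  structure(
    list(n = N, responders = responders,
         tp = tp, fp = fp,
         tn = N - responders - fp, fn = responders - tp,
         treated = tp + fp, cured = tp, adverse = fp),
    class = "cohort_outcome"
  )
}

#' @export
print.cohort_outcome <- function(x, ...) {
  cat(sprintf("Cohort of %d: %d responders; TP %d, FP %d, TN %d, FN %d\n",
              x$n, x$responders, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Monte Carlo replication of the sequential game
#'
#' Plays the game `n_reps` times at a fixed proportion of responders.  Each
#' replicate draws the firm's private investment cost `I ~ Uniform(0,
#' I_bar)` and applies the firm's decision rule under `policy`.  If the firm
#' invests, the true biomarker is drawn from the priors, a cohort of
#' `cohort_N` patients is screened with that test's realized sensitivity,
#' specificity and price, test positives are treated, and payoffs are scaled
#' to the unit population.  If it applies for authorization, everyone is
#' treated.  Otherwise payoffs are zero.
#'
#' Firm profit per replicate is per-cure revenue minus production cost for
#' every treated patient, minus the realized investment cost when investing.
#' Net health benefit is cures times `B` minus adverse events times `L`,
#' minus payments and (under stratification) per-patient test costs.
#'
#' Because every payoff is linear in the realized test characteristics,
#' redrawing the true biomarker each replicate reproduces the expected-test
#' algebra of the analytic solution exactly in expectation.
#'
#' @param delta Proportion of responders.
#' @param params Admissible [econ_params()].
#' @param policy A [pricing_policy()]; defaults to the equilibrium policy
#'   from [solve_equilibrium()].
#' @param n_reps Number of game replicates, >= 1.
#' @param cohort_N Patients per simulated cohort, >= 1.
#' @param seed Optional RNG seed.
#' @return An object of class `simulation_result`: list with `delta`,
#'   `n_reps`, `cohort_N`, `seed`, `rnd_freq` (empirical investment
#'   frequency), `rnd_freq_se`, `firm_profit_mean`, `firm_profit_se`,
#'   `nhb_mean`, `nhb_se`, and the per-replicate `actions` table.
#' @examples
#' p <- canonical_scenario()$params
#' simulate_game(0.5, p, n_reps = 1000, cohort_N = 1000, seed = 1)
#' @export
simulate_game <- function(delta, params, policy = NULL,
                          n_reps = 10000L, cohort_N = 10000L, seed = NULL) {
  if (n_reps < 1 || cohort_N < 1)
    stop("`n_reps` and `cohort_N` must be positive", call. = FALSE)
  assert_admissible(params)
  if (is.null(policy)) policy <- solve_equilibrium(delta, params)$policy
  stopifnot(inherits(policy, "pricing_policy"))
  if (!is.null(seed)) set.seed(seed)

  I_bar <- params$I_bar
  feasible <- !is.na(policy$p_l) && delta >= delta_hat(params) &&
    profit_authorized(delta, policy$p_l, params$c) >= 0
  thr <- if (!is.na(policy$p_h))
    invest_threshold(delta, policy, params) else -Inf

  I <- stats::runif(n_reps, 0, I_bar)
  invest <- I <= thr
  n_inv <- sum(invest)

  profit <- numeric(n_reps)
  nhb <- numeric(n_reps)
  action <- ifelse(invest, "invest", if (feasible) "apply" else "exit")

  if (n_inv > 0) {
    # realized biomarker per investing replicate
    q1 <- params$tests[[1]]$q
    which_test <- ifelse(stats::runif(n_inv) < q1, 1L, 2L)
    s_i <- vapply(params$tests, `[[`, numeric(1), "s")[which_test]
    e_i <- vapply(params$tests, `[[`, numeric(1), "e")[which_test]
    t_i <- vapply(params$tests, `[[`, numeric(1), "t")[which_test]
    resp <- stats::rbinom(n_inv, cohort_N, delta)
    tp <- stats::rbinom(n_inv, resp, s_i)
    fp <- stats::rbinom(n_inv, cohort_N - resp, 1 - e_i)
    profit[invest] <- (tp * policy$p_h - (tp + fp) * params$c) / cohort_N -
      I[invest]
    nhb[invest] <- (tp * (params$B - policy$p_h) - fp * params$L) / cohort_N -
      t_i
  }
  if (feasible && n_inv < n_reps) {
    idx <- !invest
    resp <- stats::rbinom(sum(idx), cohort_N, delta)
    profit[idx] <- (resp * policy$p_l) / cohort_N - params$c
    nhb[idx] <- (resp * (params$B - policy$p_l) -
                   (cohort_N - resp) * params$L) / cohort_N
  }

  se <- function(x) stats::sd(x) / sqrt(length(x))
  freq <- n_inv / n_reps
  structure(
    list(delta = delta, n_reps = n_reps, cohort_N = cohort_N, seed = seed,
         rnd_freq = freq,
         rnd_freq_se = sqrt(freq * (1 - freq) / n_reps),
         firm_profit_mean = mean(profit), firm_profit_se = se(profit),
         nhb_mean = mean(nhb), nhb_se = se(nhb),
         actions = table(factor(action, levels = c("invest", "apply", "exit")))),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Game simulation at delta = %g (%d replicates, cohorts of %d)\n",
              x$delta, x$n_reps, x$cohort_N))
  cat(sprintf("  R&D frequency        %.4f (SE %.4f)\n",
              x$rnd_freq, x$rnd_freq_se))
  cat(sprintf("  firm profit mean     %.5f (SE %.5f)\n",
              x$firm_profit_mean, x$firm_profit_se))
  cat(sprintf("  net health benefit   %.5f (SE %.5f)\n",
              x$nhb_mean, x$nhb_se))
  invisible(x)
}
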