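---
title: "Pay-for-performance pricing and the adoption of biomarker-stratified treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pay-for-performance pricing and the adoption of biomarker-stratified treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratprice)
```

## The model

A unit-mass population suffers a disease. A fraction $\delta \in [0,1]$ of
patients — the *responders* — would be cured by a newly developed treatment
(efficacy one for responders); each cure is worth $B$ in monetary-equivalent
health benefit. A treated non-responder is not cured and suffers an adverse
effect valued at $L$. Producing one course of treatment costs $c \ge 0$, with
$L > c$.

Whether a patient responds is governed by an unknown genetic factor. Two
candidate predictive biomarkers exist; biomarker $i$ is the true one with
prior probability $q_i$ ($q_1 + q_2 = 1$), and a marketed diagnostic test for
it has sensitivity $s_i$, specificity $e_i$ and per-patient price $t_i$.
Because every payoff below is linear in the realized test characteristics,
only the prior-weighted expectations $s = \sum_i q_i s_i$,
$e = \sum_i q_i e_i$, $t = \sum_i q_i t_i$ enter the analysis
(`expected_test()`).

The firm may undertake an R&D project that identifies the true biomarker, at
a private cost $I \sim \mathrm{Uniform}(0, \bar I)$ (the distribution is
common knowledge, the realization is not). If it invests, the population is
screened and only test positives are treated — *stratified* or personalized
marketing. If it does not invest, it can apply for authorization and treat
everyone, provided the regulator's (exogenous) rule allows it:
authorization requires non-negative expected health benefit,
$\delta B - (1-\delta)L \ge 0$, i.e. $\delta \ge \hat\delta = L/(B+L)$.

The health authority moves first, announcing a *pay-for-performance* pricing
policy: it pays the firm only per cured patient — $p_l$ per cure if the
population is unstratified, $p_h$ per cure if it is stratified. The firm
then learns $\delta$ and $I$ and best-responds. The solution concept is
subgame perfect equilibrium, solved by backward induction.

### Payoffs

Under stratification the firm produces for every test positive
($s\delta$ true positives plus $(1-\delta)(1-e)$ false positives) but is paid
only for the cured true positives:

$$\pi_{strat}(p_h) = s\delta(p_h - c) - c(1-\delta)(1-e) - I.$$

Without stratification its profit is $\delta p_l - c$. The authority's
expected net health benefit (NHB) — health gains minus adverse effects,
payments and test costs — is
$s\delta(B - p_h) - (1-\delta)(1-e)L - t$ with stratification (the test is
administered to everyone) and $\delta(B - p_l) - (1-\delta)L$ without.

### Maintained assumptions

`validate_params()` reports, without throwing, on the seven maintained
assumptions: $L > c$, $L > t$, $e + s > 1$, $t < s(B-c)$, $t < e(c+L)$,
$\bar I > 0$, and the headline condition

$$(c+L)(B-c)(e+s-1) > t(B+L),$$

which guarantees the regime thresholds below are strictly ordered. A
parameter set is *admissible* when all seven hold; solvers refuse
inadmissible sets while the validator stays usable on deliberately violating
ones (negative testing).

## The equilibrium

Five response-rate cutpoints organize the solution (`thresholds()`):

| quantity | closed form | meaning |
|---|---|---|
| $\hat\delta$ | $L/(B+L)$ | authorization feasible above |
| $\underline\delta$ | $\dfrac{t+(1-e)(L-c)}{s(B-c)+(1-e)(L-c)}$ | stratified marketing viable above |
| $\tilde\delta$ | $(L+c)/(B+L)$ | uniform treatment worth paying for above |
| $\bar\delta$ | $\dfrac{eL+(2-e)c-t}{eL+(2-e)c+(B-c)(1-s)}$ | no stratification incentive above |
| $\overleftrightarrow\delta$ | $\dfrac{e(L-c)+2c(1-s)-t}{e(L-c)+2c(1-s)+(1-s)(B-c)}$ | $p_h \gtrless p_l$ as $\delta \lessgtr$ this |

Admissibility implies $\underline\delta < \tilde\delta < \bar\delta$.
`classify_regime()` maps any $\delta$ into four regimes with half-open
intervals:

* $\delta < \underline\delta$: **not marketed**.
* $\underline\delta \le \delta < \tilde\delta$: **personalized only**. Even
  though authorization may be formally feasible ($\delta \ge \hat\delta$),
  the authority's NHB from uniform treatment is negative at any
  participation-compatible price, so it announces a discouraging $p_l$
  (represented here as an absent price) and prices only stratified
  marketing:
  $$p_h = c + \frac{s\delta(B-c) - t - (1-\delta)(1-e)(L-c)}{2s\delta},$$
  increasing in $\delta$ and equal to $c$ exactly at $\underline\delta$.
* $\tilde\delta \le \delta < \bar\delta$: **personalized or all**. The
  participation constraint $\delta p_l - c \ge 0$ binds — $p_l = c/\delta$,
  the authority appropriates the whole uniform-treatment surplus, which also
  maximizes the firm's incentive to stratify — and
  $$p_h = c + \frac{(1-\delta)(eL+(2-e)c) - \delta(B-c)(1-s) - t}{2s\delta},$$
  decreasing in $\delta$, continuous with the previous branch at
  $\tilde\delta$, and equal to $c$ at $\bar\delta$.
* $\delta \ge \bar\delta$: **all patients**. Any $p_h \le c$ is optimal; we
  return the supremum $c$ so the price path stays continuous. $p_l =
  c/\delta$, no R&D.

With $I \sim U(0,\bar I)$ the R&D probability is
$F(I^\ast) = I^\ast/\bar I$ where the investment threshold $I^\ast$ is the
firm's gross stratified profit minus its best fallback
(`invest_threshold()`). At the equilibrium prices
$I^\ast = [s\delta(B-c) - t - (1-\delta)(1-e)(L+c)]/2$ in the
personalized-only regime and
$I^\ast = [e(1-\delta)(c+L) - \delta(B-c)(1-s) - t]/2$ in the shared regime.

**Equal-split property.** Both pricing objectives are products of two affine
functions of $p_h$ (probability times surplus) plus a constant, so at the
interior optimum the firm's gross profit equals the authority's
stratification surplus — the optimum splits the joint stratification surplus
in half. This is the structural identity the suite asserts to $10^{-10}$,
and it makes the maximized objectives $(I^\ast)^2/\bar I$.

### Two findings the closed forms imply but do not advertise

Working through the verification suite surfaced two structural facts worth
recording, both now first-class API:

1. **A positive price band does not imply positive R&D probability.** With
   $c > 0$, on $(\underline\delta, \tilde\delta)$ near $\underline\delta$ and
   on $(\tilde\delta, \bar\delta)$ near $\bar\delta$, the equilibrium price
   exceeds $c$ yet $I^\ast < 0$: *no* price produces both positive firm
   profit and positive authority surplus, and stratification cannot be
   induced at all. The response rates with strictly positive equilibrium R&D
   probability form the window `rnd_window()`, with endpoints the roots of
   the two $I^\ast$ numerators; the headline condition guarantees the window
   contains $\tilde\delta$, and with a perfect test it fills
   $(\underline\delta, \bar\delta)$ entirely. The brute-force oracle
   (below) compares argmaxima inside this window, where an interior optimum
   exists.
2. **The interiority bound on $\bar I$ is explicit.** $I^\ast(\delta)$
   increases up to $\tilde\delta$ and decreases after, so the model's
   "investment-cost bound sufficiently high" assumption is exactly
   $$\bar I > \texttt{peak\_invest\_threshold} =
     \frac{(B-c)(L+c)(e+s-1)/(B+L) - t}{2}.$$
   Below that bound the R&D probability saturates at one near
   $\tilde\delta$, the authority would prefer a corner price, and the
   closed forms lose optimality. `solve_equilibrium()` clamps $F$ to
   $[0,1]$ and raises a `clamped` flag rather than failing; the scenario
   generator enforces the bound by default (`require_interior = TRUE`).

```{r window}
p <- canonical_scenario()$params
thresholds(p)
rnd_window(p)
peak_invest_threshold(p)
```

## Numerical choices

* **Brute-force oracle.** `maximize_p1()` / `maximize_p2()` deliberately
  share no algebra with the closed forms: they scan the objective on a
  10,000-point price grid over $[c, B]$ and refine the best point by
  golden-section search to an interval tolerance of $10^{-8}$. The upper
  bracket end $B$ is safe because prices above $B$ give the authority
  negative per-cure surplus (objective decreasing); the tests include a
  widened-bracket spot check. `verify_lemma1()` confirms the binding
  participation constraint by exhaustive evaluation on a
  $(p_l, p_h)$ grid; the argmax must sit at the first $p_l$ grid point
  $c/\delta$.
* **Boundary conventions.** Regime intervals are half-open on the right;
  $\delta = \underline\delta$ is classified into the personalized-only
  regime, where the equilibrium is degenerate ($p_h = c$, R&D probability
  zero), so either classification of the boundary yields identical
  outcomes. For $\delta \ge \bar\delta$ the canonical stratified price is
  $c$ (the supremum of the optimal set). Ties in the firm's rule
  ($I = I^\ast$) resolve to investing — a zero-probability event under the
  continuous cost distribution.
* **Degenerate inputs.** `price_low()` requires $\delta > 0$;
  `rnd_probability()` clamps to $[0,1]$ and flags clamping; validation
  reports rather than throws.

## The scenario generator

`sample_admissible()` rejection-samples primitives uniformly within
documented default ranges — $B \in [2,50]$, $L \in [0.5,20]$, $c \in [0,5]$,
per-test $t_i \in [0.01,2]$, $s_i, e_i \in [0.6,1]$, $q_1 \in [0.1,0.9]$,
$\bar I \in [1,100]$ — keeping draws that satisfy all maintained assumptions
plus, by default, the interiority bound on $\bar I$. The ranges mirror the
model's intended setting: a test informative enough to matter
($s_i, e_i \ge 0.6$), test prices small relative to health stakes (the
headline condition fails quickly otherwise), and production cost below the
adverse-effect loss. `canonical_scenario()` fixes the reference environment
$B = 10$, $L = 4$, $c = 1$, two identical tests with $s = e = 0.9$,
$t = 0.5$, $q = 0.5$, $\bar I = 10$, and a 200-point response-rate grid;
all worked examples and the acceptance script use it.
`perfect_test_variant()` sets $s_i = e_i = 1$, under which the thresholds
collapse to $\underline\delta = t/(B-c)$,
$\bar\delta = (L+c-t)/(L+c)$ and the price crossing to $1 - t/(L-c)$.

## Monte Carlo design

`simulate_cohort()` replaces the model's unit-mass continuum with a finite
binomial cohort: each of $N$ patients is independently a responder with
probability $\delta$, responders test positive with probability $s_i$,
non-responders negative with probability $e_i$. `simulate_game()` replays
the whole game: per replicate it draws $I$, applies the firm's decision
rule, redraws the true biomarker from the priors when the firm invests (the
ex-ante expectation the analytic solution uses), screens a cohort with the
*realized* test, and scales payoffs to the unit population. Because payoffs
are linear in $(s_i, e_i, t_i)$, mixing realized biomarkers reproduces the
expected-test algebra exactly in expectation, which is what the
3-standard-error agreement tests check at $\delta \in \{0.2, 0.5, 0.8\}$
with $10^4$ replicates of $10^4$-patient cohorts (the verification suite's
default problem size; smaller sizes appear in unit tests).

What the simulation does *not* emulate: real dossiers where $\delta$ is
estimated with error from trials, correlated or more than two candidate
biomarkers, partial responder efficacy, launch delays, monitoring costs, and
firm pricing power — all outside the model. Passing simulation tests show
internal consistency of the analytic expectations, not external validity.

## Limitations

* Closed forms are specific to the uniform investment-cost distribution;
  other choices of $F$ change prices and thresholds qualitatively.
* The authorization rule is exogenous; price bargaining and firm-set prices
  are not modeled.
* Monitoring of cure status is costless and perfect, and payment is per
  cure only.
* Outside the interiority bound on $\bar I$ the package reports flagged,
  clamped quantities rather than re-deriving corner-optimal prices.
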