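# stratprice

Pricing and R&D incentives for biomarker-stratified treatments under
pay-for-performance reimbursement.

## What problem this solves

When a new treatment helps only the fraction δ of patients who carry an
unknown genetic factor, the developing firm faces a strategic choice before
launch: apply for marketing authorization and sell to everyone under a
pay-for-performance scheme (paid only per cured patient), or invest in R&D
to identify the predictive biomarker so that a diagnostic test can stratify
the population and only likely responders are treated. The health
authority, which sets the prices, moves first and shapes that choice.

`stratprice` is for health economists and HTA/pricing analysts who want a
transparent, fully verified implementation of this sequential game: the
subgame perfect equilibrium prices, the response-rate thresholds that
partition the decision regimes, the probability that stratification
happens, both players' expected payoffs, and Monte Carlo machinery that
checks every analytic expectation by replicated game play.

## The model in brief

A unit population; responders (fraction δ) gain health benefit B from a
cure; treated non-responders suffer adverse-effect loss L; production costs
c per course. Two candidate biomarkers with priors q₁, q₂ carry tests with
sensitivity sᵢ, specificity eᵢ, price tᵢ; only the prior-weighted
expectations (s, e, t) matter. The firm's R&D cost is private,
I ~ Uniform(0, Ī). The authority pays p_l per cure without stratification,
p_h per cure with it, and maximizes expected net health benefit (health
gains minus adverse effects, payments and test costs); the firm maximizes
expected profit.

The equilibrium is organized by thresholds of δ:

- δ < δ̲ — not marketed;
- δ̲ ≤ δ < δ̃ = (L+c)/(B+L) — personalized only: the authority discourages
  unstratified marketing and sets
  p_h = c + [sδ(B−c) − t − (1−δ)(1−e)(L−c)]/(2sδ), rising in δ;
- δ̃ ≤ δ < δ̄ — personalized or all: p_l = c/δ (participation binds) and
  p_h = c + [(1−δ)(eL+(2−e)c) − δ(B−c)(1−s) − t]/(2sδ), falling in δ;
- δ ≥ δ̄ — all patients treated, no stratification incentive.

The R&D probability is F(I*) = I*/Ī with I* the firm's investment
threshold; the stratified price is *not* necessarily above the uniform one
(they cross at δ↔). Every closed form is verified in the test suite by an
independent grid + golden-section optimizer and, for the binding
participation constraint, by exhaustive two-price grid search. See the
vignette `vignettes/pricing-stratification.Rmd` for the full treatment,
including the positive-R&D window `rnd_window()` and the explicit
interiority bound on Ī.

## Worked example

```r
library(stratprice)

sc <- canonical_scenario()     # B = 10, L = 4, c = 1, s = e = 0.9, t = 0.5, Ī = 10
thresholds(sc$params)
#> Response-rate thresholds:
#>   authorization      delta_hat   = 0.285714
#>   marketing          delta_lower = 0.095238
#>   indifference       delta_tilde = 0.357143
#>   no-stratification  delta_bar   = 0.750000
#>   price-crossing     delta_cross = 0.631579

solve_equilibrium(0.5, sc$params)
#> Equilibrium at delta = 0.5: regime pm_or_all
#>   prices: p_l = 2, p_h = 2.555556
#>   R&D probability = 0.065
#>   expected net health benefit = 2.04225, firm expected profit = 0.021125
```

At δ = 0.5 both options are on the table: the authority offers the
break-even uniform price p_l = c/δ = 2 and a stratified price of about
2.556 per cure; the firm invests in the biomarker whenever its realized
R&D cost is below 0.65, which happens with probability 0.065; the
authority's expected net health benefit, 2.042, exceeds its no-R&D fallback
δB − c − (1−δ)L = 2 by the option value of stratification. Replicated game
play with finite cohorts reproduces these expectations:

```r
simulate_game(0.5, sc$params, n_reps = 10000, cohort_N = 10000, seed = 1)
#> Game simulation at delta = 0.5 (10000 replicates, cohorts of 10000)
#>   R&D frequency        0.0674 (SE 0.0025)
#>   firm profit mean     0.02221 (SE 0.00096)
#>   net health benefit   2.04413 (SE 0.00173)
```

A full sweep tabulates the regime bands and price curves (the data behind a
regime map and price plot):

```r
sw <- sweep_equilibrium(sc)
table(sw$regime)
#> not_marketed      pm_only    pm_or_all all_patients
#>           19           52           79           50
```

A thin command-line front end over these functions lives at
`inst/cli/stratprice.R` (subcommands `solve`, `sweep`, `simulate`,
`verify`, `sample`); configuration-driven batch runs go through
`run_config()`.

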