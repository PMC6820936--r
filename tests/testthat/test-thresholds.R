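# Each threshold has a defining sign condition; bisection on that condition
# is the independent oracle for the closed form.

test_that("closed-form thresholds equal the roots of their defining conditions", {
  p <- canon()
  B <- p$B; L <- p$L; cc <- p$c; s <- p$s; e <- p$e; tt <- p$t

  # authorization: population expected health benefit changes sign
  expect_equal(delta_hat(p),
               bisect_root(function(d) d * B - (1 - d) * L, 0, 1),
               tolerance = 1e-10)
  expect_equal(delta_hat(p), 4 / 14)

  # indifference: net benefit at the break-even uniform price changes sign
  expect_equal(delta_tilde(p),
               bisect_root(function(d) d * B - cc - (1 - d) * L, 0, 1),
               tolerance = 1e-10)
  expect_equal(delta_tilde(p), 5 / 14)

  # marketing viability: personalized-only price numerator changes sign
  expect_equal(delta_lower(p),
               bisect_root(function(d)
                 s * d * (B - cc) - tt - (1 - d) * (1 - e) * (L - cc), 0, 1),
               tolerance = 1e-10)
  expect_equal(delta_lower(p), 0.8 / 8.4)

  # no stratification: shared-regime price numerator changes sign
  expect_equal(delta_bar(p),
               bisect_root(function(d)
                 (1 - d) * (e * L + (2 - e) * cc) -
                   d * (B - cc) * (1 - s) - tt, 0, 1),
               tolerance = 1e-10)
  expect_equal(delta_bar(p), 0.75)

  # price crossing: numerator of p_h - p_l changes sign
  expect_equal(delta_cross(p),
               bisect_root(function(d)
                 (1 - d) * (e * (L - cc) + 2 * cc * (1 - s)) -
                   d * (1 - s) * (B - cc) - tt, 0, 1),
               tolerance = 1e-10)
  expect_equal(delta_cross(p), 2.4 / 3.8)
})

test_that("threshold special cases behave as the model predicts", {
  # symmetric benefit and loss authorize at one half
  expect_equal(delta_hat(make_params(B = 4, L = 4)), 0.5)

  # costless production: authorization and indifference coincide
  p0 <- make_params(c = 0)
  expect_equal(delta_hat(p0), delta_tilde(p0))

  # indifference threshold rises with production cost
  cs <- c(0.5, 1, 1.5, 2)
  dts <- vapply(cs, function(cc) delta_tilde(make_params(c = cc)), numeric(1))
  expect_true(all(diff(dts) > 0))

  # with positive cost, indifference strictly exceeds authorization
  expect_gt(delta_tilde(canon()), delta_hat(canon()))
})

test_that("thresholds are ordered and authorization-dominated on sampled scenarios", {
  for (sc in shared_scenario_pool()) {
    th <- thresholds(sc$params)
    expect_lt(th$delta_lower, th$delta_tilde)
    expect_lt(th$delta_tilde, th$delta_bar)
    expect_lt(th$delta_bar, 1)
    if (sc$params$c > 0) expect_lt(th$delta_hat, th$delta_tilde)
  }
})

test_that("regimes partition the response-rate axis with half-open intervals", {
  p <- canon()
  th <- thresholds(p)

  expect_identical(as.character(classify_regime(0, th)), "not_marketed")
  expect_identical(as.character(classify_regime(1, th)), "all_patients")
  expect_identical(as.character(classify_regime(0.2, th)), "pm_only")
  expect_identical(as.character(classify_regime(0.5, th)), "pm_or_all")
  expect_identical(as.character(classify_regime(0.8, th)), "all_patients")

  # boundary convention: the left endpoint belongs to the upper regime
  expect_identical(as.character(classify_regime(th$delta_lower, th)), "pm_only")
  expect_identical(as.character(classify_regime(th$delta_tilde, th)), "pm_or_all")
  expect_identical(as.character(classify_regime(th$delta_bar, th)), "all_patients")

  expect_error(classify_regime(1.2, th), "\\[0, 1\\]")
  expect_error(classify_regime(-0.1, th), "\\[0, 1\\]")

  # every point maps to exactly one regime
  grid <- seq(0, 1, length.out = 401)
  expect_false(anyNA(classify_regime(grid, th)))
})

test_that("the positive-R&D window sits strictly inside the marketing interval", {
  for (sc in shared_scenario_pool()[1:40]) {
    p <- sc$params
    th <- thresholds(p)
    win <- rnd_window(p)
    expect_gte(win[1], th$delta_lower)
    expect_lte(win[2], th$delta_bar)
    # the window always contains the indifference threshold (a consequence
    # of the headline admissibility condition)
    expect_lt(win[1], th$delta_tilde)
    expect_gt(win[2], th$delta_tilde)
    # window endpoints are the roots of the investment-threshold numerators
    expect_equal(p$s * win[1] * (p$B - p$c) - p$t -
                   (1 - win[1]) * (1 - p$e) * (p$L + p$c), 0,
                 tolerance = 1e-10)
    expect_equal(p$e * (1 - win[2]) * (p$c + p$L) -
                   win[2] * (p$B - p$c) * (1 - p$s) - p$t, 0,
                 tolerance = 1e-10)
  }

  # perfect tests: the window fills the whole marketing interval
  pv <- perfect_test_variant(canonical_scenario())$params
  expect_equal(rnd_window(pv), c(delta_lower(pv), delta_bar(pv)))

  # inside the marketing interval but outside the window, the equilibrium
  # R&D probability is zero although the price still exceeds cost
  p <- canon()
  win <- rnd_window(p)
  dead <- (delta_lower(p) + win[1]) / 2
  eq <- solve_equilibrium(dead, p)
  expect_identical(eq$regime, "pm_only")
  expect_gt(eq$policy$p_h, p$c)
  expect_equal(eq$rnd_prob, 0)
})

test_that("the equilibrium investment threshold peaks at the indifference threshold", {
  for (sc in c(list(canonical_scenario()), shared_scenario_pool()[1:20])) {
    p <- sc$params
    peak <- peak_invest_threshold(p)
    # the peak is the common value of both regime thresholds at delta_tilde
    dt <- delta_tilde(p)
    pol <- pricing_policy(p_h = price_high_pm_only(dt, p))
    expect_equal(invest_threshold(dt, pol, p, authorization_feasible = FALSE),
                 peak, tolerance = 1e-10)
    # and no grid point beats it
    grid <- seq(0.01, 0.99, length.out = 99)
    thr <- vapply(grid, function(d) {
      eq <- solve_equilibrium(d, p)
      if (is.na(eq$invest_threshold)) -Inf else eq$invest_threshold
    }, numeric(1))
    expect_lte(max(thr), peak + 1e-10)
    # sampled scenarios keep the R&D probability interior (no clamping)
    expect_gt(p$I_bar, peak)
    expect_lt(solve_equilibrium(dt, p)$rnd_prob, 1)
  }
})

test_that("threshold functions refuse inadmissible parameters", {
  bad <- make_params(t = 4)
  expect_error(thresholds(bad), "inadmissible")
  expect_error(delta_hat(bad), "inadmissible")
})
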