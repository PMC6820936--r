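test_that("gross stratified profit matches its revenue-minus-cost decomposition", {
  p <- canon()

  # pricing at cost leaves only the false-positive production loss
  expect_equal(profit_stratified_gross(0.3, p$c, p),
               -p$c * (1 - 0.3) * (1 - p$e))

  # at the canonical personalized-only optimum the gross profit is 0.36
  p_h <- price_high_pm_only(0.2, p)
  expect_equal(p_h, 1 + 0.88 / 0.36, tolerance = 1e-12)
  g <- profit_stratified_gross(0.2, p_h, p)
  expect_equal(g, 0.36, tolerance = 1e-12)
  # decomposition: per-cure revenue minus production for every test positive
  expect_equal(g, p$s * 0.2 * p_h - p$c * (p$s * 0.2 + 0.8 * (1 - p$e)))

  # a perfect test has no false-positive loss
  pp <- make_params(s = 1, e = 1)
  expect_equal(profit_stratified_gross(0.3, 2, pp), 0.3 * (2 - pp$c))
})

test_that("authorization profit is linear and vanishes at the break-even price", {
  expect_equal(profit_authorized(0.5, 2, 1), 0)
  expect_equal(profit_authorized(0.5, 3, 1), 0.5)
  expect_equal(profit_authorized(0.4, 1 / 0.4, 1), 0)
})

test_that("the investment threshold agrees between price plug-in and closed form", {
  p <- canon()

  # personalized-only regime at delta = 0.2: closed form uses (L + c)
  pol <- pricing_policy(p_h = price_high_pm_only(0.2, p))
  thr <- invest_threshold(0.2, pol, p, authorization_feasible = FALSE)
  closed <- (p$s * 0.2 * (p$B - p$c) - p$t -
               0.8 * (1 - p$e) * (p$L + p$c)) / 2
  expect_equal(thr, closed, tolerance = 1e-10)

  # shared regime at delta = 0.5
  pol <- pricing_policy(p_l = price_low(0.5, p$c),
                        p_h = price_high_shared(0.5, p))
  thr <- invest_threshold(0.5, pol, p)
  closed <- (p$e * 0.5 * (p$c + p$L) - 0.5 * (p$B - p$c) * (1 - p$s) - p$t) / 2
  expect_equal(thr, closed, tolerance = 1e-10)
  expect_equal(thr, 0.65, tolerance = 1e-12)

  # the two routes agree across sampled scenarios
  for (sc in shared_scenario_pool()[1:40]) {
    pr <- sc$params
    th <- thresholds(pr)
    d1 <- (th$delta_lower + th$delta_tilde) / 2
    t1 <- invest_threshold(d1, pricing_policy(p_h = price_high_pm_only(d1, pr)),
                           pr, authorization_feasible = FALSE)
    c1 <- (pr$s * d1 * (pr$B - pr$c) - pr$t -
             (1 - d1) * (1 - pr$e) * (pr$L + pr$c)) / 2
    expect_equal(t1, c1, tolerance = 1e-10)

    d2 <- (th$delta_tilde + th$delta_bar) / 2
    t2 <- invest_threshold(d2,
                           pricing_policy(p_l = price_low(d2, pr$c),
                                          p_h = price_high_shared(d2, pr)),
                           pr)
    c2 <- (pr$e * (1 - d2) * (pr$c + pr$L) -
             d2 * (pr$B - pr$c) * (1 - pr$s) - pr$t) / 2
    expect_equal(t2, c2, tolerance = 1e-10)
  }
})

test_that("a break-even authorization price leaves the threshold unchanged", {
  p <- canon()
  d <- 0.5
  pol_both <- pricing_policy(p_l = p$c / d, p_h = 2.5)
  pol_only <- pricing_policy(p_h = 2.5)
  expect_equal(invest_threshold(d, pol_both, p),
               invest_threshold(d, pol_only, p, authorization_feasible = FALSE))
})

test_that("the threshold is monotone in the announced prices", {
  p <- canon()
  d <- 0.5
  ph <- seq(1.5, 4, by = 0.25)
  thr_h <- vapply(ph, function(x)
    invest_threshold(d, pricing_policy(p_l = 2.5, p_h = x), p), numeric(1))
  expect_true(all(diff(thr_h) > 0))

  pl <- seq(2, 4, by = 0.25)
  thr_l <- vapply(pl, function(x)
    invest_threshold(d, pricing_policy(p_l = x, p_h = 3), p), numeric(1))
  expect_true(all(diff(thr_l) <= 0))
})

test_that("an offered-nothing policy above the indifference threshold is refused", {
  p <- canon()
  expect_error(
    invest_threshold(0.5, pricing_policy(p_h = 3), p,
                     authorization_feasible = TRUE),
    "inconsistent policy")
  # below the indifference threshold an absent p_l is a discouraging price
  expect_no_error(
    invest_threshold(0.3, pricing_policy(p_h = 3), p,
                     authorization_feasible = TRUE))
})

test_that("R&D probability is the clamped uniform distribution function", {
  expect_equal(as.numeric(rnd_probability(-0.2, 10)), 0)
  expect_equal(as.numeric(rnd_probability(0.65, 10)), 0.065)
  expect_equal(as.numeric(rnd_probability(10, 10)), 1)
  expect_false(attr(rnd_probability(0.65, 10), "clamped"))
  expect_true(attr(rnd_probability(12, 10), "clamped"))

  # matches the empirical invest frequency in 1e5 uniform draws
  set.seed(404)
  I <- runif(1e5, 0, 10)
  emp <- mean(I <= 0.65)
  se <- sqrt(0.065 * (1 - 0.065) / 1e5)
  expect_lt(abs(emp - 0.065), 3 * se)
})

test_that("the firm's decision rule picks invest, apply or exit correctly", {
  p <- canon()
  th <- thresholds(p)

  # costless investment with a profitable stratified price
  d <- firm_decide(0.2, pricing_policy(p_h = 3.4), p, I = 0)
  expect_identical(d$action, "invest")

  # huge investment cost, break-even uniform price above indifference
  d <- firm_decide(0.5, pricing_policy(p_l = 2, p_h = 2.5), p, I = p$I_bar)
  expect_identical(d$action, "apply")

  # huge cost and a discouraging policy: exit
  d <- firm_decide(0.3, pricing_policy(p_h = 3.4), p, I = p$I_bar)
  expect_identical(d$action, "exit")

  # tie at the threshold resolves to invest
  pol <- pricing_policy(p_h = price_high_pm_only(0.2, p))
  thr <- invest_threshold(0.2, pol, p, authorization_feasible = FALSE)
  expect_identical(firm_decide(0.2, pol, p, I = thr)$action, "invest")

  # a price at cost never induces investment
  d <- firm_decide(0.2, pricing_policy(p_h = p$c), p, I = 0.001)
  expect_identical(d$action, "exit")
  expect_lt(d$threshold, 0)
})
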