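# Brute-force numerical verification of the closed forms.  The oracle
# shares no algebra with the analytic solution: it evaluates the pricing
# objectives directly on a grid and refines with golden-section search.

golden_section_max <- function(f, lo, hi, tol = 1e-8) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  xm <- (a + b) / 2
  list(argmax = xm, value = f(xm))
}

oracle_maximize <- function(objective, delta, params, bracket, tol, grid_n) {
  if (is.null(bracket)) bracket <- c(params$c, params$B)
  grid <- seq(bracket[1], bracket[2], length.out = grid_n)
  vals <- objective(grid, delta, params)
  i <- which.max(vals)
  if (vals[i] <= 0)
    return(list(argmax = NA_real_, value = max(vals), marketed = FALSE))
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, grid_n)]
  res <- golden_section_max(function(p) objective(p, delta, params),
                            lo, hi, tol = tol)
  c(res, marketed = TRUE)
}

#' Brute-force maximization of the personalized-only pricing objective
#'
#' Scans [objective_p1()] on a price grid and refines the best point by
#' golden-section search.  Serves as an independent check of
#' [price_high_pm_only()]: it never uses the closed form.
#'
#' @param delta Proportion of responders, ideally in
#'   `(delta_lower, delta_tilde)`.
#' @param params Admissible [econ_params()].
#' @param bracket Price search interval; defaults to `[c, B]` (prices above
#'   `B` give the authority negative per-cure surplus, so the objective is
#'   decreasing there).
#' @param tol Golden-section interval tolerance.
#' @param grid_n Number of initial grid points.
#' @return List with `argmax`, `value` and `marketed` (`FALSE` when the
#'   objective is non-positive on the whole bracket: no viable price).
#' @export
maximize_p1 <- function(delta, params, bracket = NULL, tol = 1e-8,
                        grid_n = 10000L) {
  assert_admissible(params)
  oracle_maximize(objective_p1, delta, params, bracket, tol, grid_n)
}

#' Brute-force maximization of the shared-regime pricing objective
#'
#' Same grid-plus-golden-section scheme as [maximize_p1()], applied to
#' [objective_p2()]; checks [price_high_shared()].  The additive fallback
#' term does not move the argmax, so `marketed` reports whether the
#' stratification part improves on the fallback.
#'
#' @inheritParams maximize_p1
#' @return List with `argmax`, `value` and `marketed`.
#' @export
maximize_p2 <- function(delta, params, bracket = NULL, tol = 1e-8,
                        grid_n = 10000L) {
  assert_admissible(params)
  fallback <- with(params, delta * B - c - (1 - delta) * L)
  res <- oracle_maximize(function(p, d, prm) objective_p2(p, d, prm) - fallback,
                         delta, params, bracket, tol, grid_n)
  res$value <- res$value + fallback
  res
}

#' Grid verification that the uniform-price constraint binds
#'
#' In the shared regime the authority's unconstrained problem is
#' two-dimensional: it picks both prices subject to the firm's participation
#' constraint `delta * p_l - c >= 0`.  The equilibrium sets `p_l = c / delta`
#' (the constraint binds).  This routine evaluates the two-price objective —
#' R&D probability times stratified net benefit, plus the complementary
#' probability times uniform net benefit — on a full `(p_l, p_h)` grid and
#' reports whether the grid argmax has `p_l` at the constraint.
#'
#' @param delta Proportion of responders in `[delta_tilde, delta_bar)`.
#' @param params Admissible [econ_params()].
#' @param grid_n Points per axis.
#' @return List with the grid argmax `p_l_star`, `p_h_star`, the maximal
#'   objective `value`, the `p_l` grid step, and `binding` (`TRUE` iff the
#'   argmax `p_l` is the first grid point, `c / delta`).
#' @export
verify_lemma1 <- function(delta, params, grid_n = 201L) {
  assert_admissible(params)
  c0 <- params$c; B <- params$B; I_bar <- params$I_bar
  p_l_grid <- seq(price_low(delta, c0), B, length.out = grid_n)
  p_h_grid <- seq(c0, B, length.out = grid_n)
  gross <- profit_stratified_gross(delta, p_h_grid, params)   # by p_h
  auth <- pmax(profit_authorized(delta, p_l_grid, c0), 0)     # by p_l
  thr <- outer(auth, gross, function(a, g) g - a)             # p_l x p_h
  f <- pmin(pmax(thr / I_bar, 0), 1)
  nhb_s <- nhb_stratified(delta, p_h_grid, params)
  nhb_u <- nhb_uniform(delta, p_l_grid, params)
  obj <- sweep(f, 2, nhb_s, "*") + (1 - f) * nhb_u
  i <- which(obj == max(obj), arr.ind = TRUE)[1, ]
  list(
    p_l_star = p_l_grid[i[1]],
    p_h_star = p_h_grid[i[2]],
    value = max(obj),
    p_l_step = p_l_grid[2] - p_l_grid[1],
    binding = unname(i[1] == 1L)
  )
}

#' Run the full closed-form verification suite
#'
#' Samples admissible scenarios, draws one response rate per pricing regime
#' inside the positive-R&D window ([rnd_window()]) — where the closed forms
#' are interior optima — and compares the brute-force argmax against the
#' closed-form price, plus a constraint-binding check in the shared regime.
#' This is the machinery behind the `verify` command-line subcommand.
#'
#' @param n Number of sampled scenarios.
#' @param seed RNG seed for scenario sampling and regime draws.
#' @param tol Golden-section tolerance passed to the oracle.
#' @param lemma_grid_n Points per axis for the two-price grid check.
#' @return A data frame of class `oracle_report`, one row per (scenario,
#'   regime) check, with columns `scenario`, `regime`, `delta`,
#'   `closed_form`, `oracle`, `abs_error`, `rel_error` (scaled by `B - c`)
#'   and `lemma1_binding` (`NA` outside the shared regime); attribute
#'   `max_rel_error`.
#' @export
oracle_report <- function(n = 200L, seed = NULL, tol = 1e-8,
                          lemma_grid_n = 121L) {
  scen <- sample_admissible(n, seed = seed)
  rows <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    p <- scen[[i]]$params
    th <- thresholds(p)
    win <- rnd_window(p)
    # interior draws, one per regime, inside the positive-R&D window where
    # the closed forms are interior optima
    u <- stats::runif(2, 0.15, 0.85)
    d1 <- win[1] + u[1] * (th$delta_tilde - win[1])
    d2 <- th$delta_tilde + u[2] * (win[2] - th$delta_tilde)

    o1 <- maximize_p1(d1, p, tol = tol)
    cf1 <- price_high_pm_only(d1, p)
    k <- k + 1L
    rows[[k]] <- data.frame(scenario = i, regime = "pm_only", delta = d1,
                            closed_form = cf1, oracle = o1$argmax,
                            lemma1_binding = NA)

    o2 <- maximize_p2(d2, p, tol = tol)
    cf2 <- price_high_shared(d2, p)
    lem <- verify_lemma1(d2, p, grid_n = lemma_grid_n)
    k <- k + 1L
    rows[[k]] <- data.frame(scenario = i, regime = "pm_or_all", delta = d2,
                            closed_form = cf2, oracle = o2$argmax,
                            lemma1_binding = lem$binding)
  }
  out <- do.call(rbind, rows)
  scale <- vapply(out$scenario,
                  function(i) scen[[i]]$params$B - scen[[i]]$params$c,
                  numeric(1))
  out$abs_error <- abs(out$oracle - out$closed_form)
  out$rel_error <- out$abs_error / scale
  class(out) <- c("oracle_report", "data.frame")
  attr(out, "max_rel_error") <- max(out$rel_error)
  out
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf(
    "Closed-form verification: %d checks, max |oracle - closed form|/(B - c) = %.3g\n",
    nrow(x), attr(x, "max_rel_error")))
  shared <- x$lemma1_binding[!is.na(x$lemma1_binding)]
  cat(sprintf("  uniform-price constraint binding in %d/%d shared-regime checks\n",
              sum(shared), length(shared)))
  invisible(x)
}
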