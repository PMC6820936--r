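# Sweeps over the response rate, parameter-file I/O, and configuration-
# driven report bundles (CSV + JSON).  These are the data behind the
# regime-band and price-curve figures.

#' Sweep the equilibrium across a response-rate grid
#'
#' Solves the pricing game at every grid point and tabulates the regime,
#' prices, R&D probability and expected payoffs.  The threshold set is
#' attached as an attribute; a regime-band plot and a two-curve price plot
#' can be drawn from the table directly (see [plot.equilibrium_sweep()]).
#'
#' @param scenario A `scenario` object, or an admissible [econ_params()]
#'   (then `delta` must be given or defaults to a 200-point interior grid).
#' @param delta Optional response-rate grid overriding the scenario's.
#' @return A data frame of class `equilibrium_sweep` with one row per grid
#'   point: `delta`, `regime`, `p_l`, `p_h`, `rnd_prob`, `firm_profit`,
#'   `nhb`, `marketed`, `clamped`; attribute `thresholds`.
#' @examples
#' sw <- sweep_equilibrium(canonical_scenario())
#' table(sw$regime)
#' @export
sweep_equilibrium <- function(scenario, delta = NULL) {
  if (inherits(scenario, "econ_params")) {
    params <- scenario
    if (is.null(delta)) delta <- seq_len(200L) / 201
  } else {
    stopifnot(inherits(scenario, "scenario"))
    if (!scenario$admissible) {
      print(validate_params(scenario$params))
      stop("scenario is not admissible; see the validation report above",
           call. = FALSE)
    }
    params <- scenario$params
    if (is.null(delta)) delta <- scenario$delta_grid
  }
  assert_admissible(params)
  if (length(delta) < 1L) stop("empty `delta` grid", call. = FALSE)
  rows <- lapply(delta, function(d) {
    eq <- solve_equilibrium(d, params)
    data.frame(delta = d, regime = eq$regime,
               p_l = eq$policy$p_l, p_h = eq$policy$p_h,
               rnd_prob = eq$rnd_prob, firm_profit = eq$firm_profit,
               nhb = eq$nhb, marketed = eq$marketed, clamped = eq$clamped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$regime <- factor(out$regime, levels = regime_levels())
  attr(out, "thresholds") <- thresholds(params)
  class(out) <- c("equilibrium_sweep", "data.frame")
  out
}

#' Plot an equilibrium sweep
#'
#' Draws the two price curves over the response rate with regime bands
#' shaded and thresholds marked.  Requires ggplot2.
#'
#' @param x An `equilibrium_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.equilibrium_sweep <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  thr <- attr(x, "thresholds")
  cuts <- c(thr$delta_lower, thr$delta_tilde, thr$delta_bar)
  long <- rbind(
    data.frame(delta = x$delta, price = x$p_l, which = "p_l"),
    data.frame(delta = x$delta, price = x$p_h, which = "p_h")
  )
  long <- long[!is.na(long$price), ]
  ggplot2::ggplot(long, ggplot2::aes(.data$delta, .data$price,
                                     colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = cuts, linetype = "dashed") +
    ggplot2::labs(x = "proportion of responders", y = "price per cure",
                  colour = NULL)
}

#' Read an economic environment from a YAML or JSON file
#'
#' Expected keys: `B`, `L`, `c`, `I_bar` and `tests`, a list of two entries
#' each with `s`, `e`, `t`, `q`.  The format is inferred from the file
#' extension (`.json` vs anything YAML-parsable).
#'
#' @param path File path.
#' @return An [econ_params()] object.
#' @export
read_econ_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  params_from_list(raw)
}

params_from_list <- function(raw) {
  need <- c("B", "L", "c", "I_bar", "tests")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("parameter specification is missing key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(raw$tests) != 2L)
    stop("`tests` must list exactly two candidate biomarker tests",
         call. = FALSE)
  tests <- lapply(raw$tests, function(ts) {
    m <- setdiff(c("s", "e", "t", "q"), names(ts))
    if (length(m) > 0)
      stop("test entry is missing key(s): ", paste(m, collapse = ", "),
           call. = FALSE)
    test_spec(ts$s, ts$e, ts$t, ts$q)
  })
  econ_params(raw$B, raw$L, raw$c, tests, raw$I_bar)
}

params_to_list <- function(params) {
  list(B = params$B, L = params$L, c = params$c, I_bar = params$I_bar,
       tests = lapply(params$tests, function(ts)
         list(s = ts$s, e = ts$e, t = ts$t, q = ts$q)))
}

#' Write an economic environment to a YAML file
#'
#' @param params An [econ_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_econ_params <- function(params, path) {
  stopifnot(inherits(params, "econ_params"))
  yaml::write_yaml(params_to_list(params), path)
  invisible(path)
}

#' Execute a configuration file and write its artifact bundle
#'
#' Reads a YAML (or JSON) configuration describing a scenario and a list of
#' actions, runs them against the installed solvers, and writes CSV/JSON
#' outputs plus a run log.  Every output echoes the scenario parameters,
#' the package version and the seed for provenance.
#'
#' Recognized configuration keys:
#' \describe{
#'   \item{`scenario`}{Inline parameter block (`B`, `L`, `c`, `I_bar`,
#'     `tests`), or}
#'   \item{`params_file`}{path to a parameter file (one of the two is
#'     required).}
#'   \item{`actions`}{subset of `"solve"`, `"sweep"`, `"simulate"`,
#'     `"verify"` (required).}
#'   \item{`delta`}{response rate(s) for `solve`.}
#'   \item{`grid`}{sweep grid length (default 200).}
#'   \item{`simulate`}{block with `reps`, `cohort`, `deltas`.}
#'   \item{`seed`}{integer seed (default 1).}
#' }
#'
#' @param path Configuration file path.
#' @param out_dir Output directory (created if needed).
#' @return Named list of the paths written, invisibly.
#' @export
run_config <- function(path, out_dir = dirname(path)) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  known <- c("scenario", "params_file", "actions", "delta", "grid",
             "simulate", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$actions))
    stop("configuration is missing key: actions", call. = FALSE)
  bad <- setdiff(cfg$actions, c("solve", "sweep", "simulate", "verify"))
  if (length(bad) > 0)
    stop("unknown action(s): ", paste(bad, collapse = ", "), call. = FALSE)
  params <- if (!is.null(cfg$scenario)) params_from_list(cfg$scenario)
    else if (!is.null(cfg$params_file)) read_econ_params(cfg$params_file)
    else stop("configuration needs either key `scenario` or `params_file`",
              call. = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  provenance <- list(package = "stratprice",
                     version = as.character(utils::packageVersion("stratprice")),
                     seed = seed, params = params_to_list(params))
  written <- list()
  log <- function(...) message("[stratprice] ", sprintf(...))

  if ("solve" %in% cfg$actions) {
    if (is.null(cfg$delta))
      stop("action `solve` needs configuration key: delta", call. = FALSE)
    sol <- lapply(as.numeric(cfg$delta), function(d) {
      eq <- solve_equilibrium(d, params)
      list(delta = eq$delta, regime = eq$regime,
           p_l = eq$policy$p_l, p_h = eq$policy$p_h,
           rnd_prob = eq$rnd_prob, firm_profit = eq$firm_profit,
           nhb = eq$nhb, marketed = eq$marketed, clamped = eq$clamped)
    })
    f <- file.path(out_dir, "solve.json")
    jsonlite::write_json(c(provenance, list(equilibria = sol)), f,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    log("solve: %d equilibria -> %s", length(sol), f)
    written$solve <- f
  }
  if ("sweep" %in% cfg$actions) {
    grid_n <- if (is.null(cfg$grid)) 200L else as.integer(cfg$grid)
    if (grid_n < 1L) stop("`grid` must be a positive length", call. = FALSE)
    sw <- sweep_equilibrium(params, delta = seq_len(grid_n) / (grid_n + 1))
    f <- file.path(out_dir, "sweep.csv")
    utils::write.csv(as.data.frame(sw), f, row.names = FALSE)
    thr <- attr(sw, "thresholds")
    f2 <- file.path(out_dir, "sweep_thresholds.json")
    jsonlite::write_json(c(provenance, list(thresholds = unclass(thr))), f2,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log("sweep: %d rows -> %s", nrow(sw), f)
    written$sweep <- f; written$sweep_thresholds <- f2
  }
  if ("simulate" %in% cfg$actions) {
    sim_cfg <- cfg$simulate
    if (is.null(sim_cfg) || is.null(sim_cfg$reps) || is.null(sim_cfg$cohort) ||
        is.null(sim_cfg$deltas))
      stop("action `simulate` needs configuration key: simulate ",
           "(with reps, cohort, deltas)", call. = FALSE)
    rows <- lapply(seq_along(as.numeric(sim_cfg$deltas)), function(i) {
      d <- as.numeric(sim_cfg$deltas)[i]
      r <- simulate_game(d, params, n_reps = as.integer(sim_cfg$reps),
                         cohort_N = as.integer(sim_cfg$cohort),
                         seed = seed + i - 1L)
      data.frame(delta = d, rnd_freq = r$rnd_freq,
                 rnd_freq_se = r$rnd_freq_se,
                 firm_profit_mean = r$firm_profit_mean,
                 firm_profit_se = r$firm_profit_se,
                 nhb_mean = r$nhb_mean, nhb_se = r$nhb_se,
                 n_reps = r$n_reps, cohort_N = r$cohort_N,
                 seed = seed + i - 1L)
    })
    f <- file.path(out_dir, "simulation.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    log("simulate: %d delta values -> %s", length(rows), f)
    written$simulate <- f
  }
  if ("verify" %in% cfg$actions) {
    rep <- oracle_report(n = 50L, seed = seed)
    f <- file.path(out_dir, "verify.json")
    jsonlite::write_json(
      c(provenance,
        list(checks = nrow(rep),
             max_rel_error = attr(rep, "max_rel_error"),
             lemma1_all_binding = all(rep$lemma1_binding, na.rm = TRUE),
             pass = attr(rep, "max_rel_error") < 1e-5 &&
               all(rep$lemma1_binding, na.rm = TRUE))),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log("verify -> %s", f)
    written$verify <- f
  }
  invisible(written)
}
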