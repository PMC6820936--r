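# Shared fixtures and independent oracles used across the suite.

# Canonical environment: B = 10, L = 4, c = 1, s = e = 0.9, t = 0.5, I_bar = 10.
canon <- function() canonical_scenario()$params

# Environment with two identical tests carrying the given characteristics,
# so the expected test equals each test exactly.
make_params <- function(B = 10, L = 4, c = 1, s = 0.9, e = 0.9, t = 0.5,
                        I_bar = 10) {
  econ_params(B, L, c,
              list(test_spec(s, e, t, 0.5), test_spec(s, e, t, 0.5)),
              I_bar)
}

# Independent root finder: bisection on a sign-changing function.  Used to
# recover each threshold from its defining condition without touching the
# closed forms.
bisect_root <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo); fhi <- f(hi)
  stopifnot(sign(flo) != sign(fhi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# A modest pool of admissible scenarios shared by the property tests.
shared_scenario_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) pool <<- sample_admissible(100, seed = 914)
    pool
  }
})
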