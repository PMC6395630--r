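# Random curve/pair generators used across the suite. All randomness is
# drawn from the calling test's seeded stream.

random_curve <- function(e_min = 0, e_max = 1) {
  hill_curve(
    e_min, e_max,
    ec50 = exp(stats::runif(1, log(0.3), log(3))),
    n = stats::runif(1, 0.6, 4)
  )
}

# Equal maximal effects (no partial agent), shared unit scale.
random_full_pair <- function() {
  curve_pair(random_curve(), random_curve())
}

# Partial agent A with e_max drawn below 1, full agent B.
random_partial_pair <- function(e_max_partial = stats::runif(1, 0.5, 0.9)) {
  curve_pair(random_curve(e_max = e_max_partial), random_curve())
}

# Mix of both regimes.
random_pair <- function(p_partial = 0.5) {
  if (stats::runif(1) < p_partial) random_partial_pair() else random_full_pair()
}

# Parallel curves: same e_max and n, EC50s differing by the potency ratio.
random_constant_potency_pair <- function() {
  n <- stats::runif(1, 0.6, 4)
  ec50_a <- exp(stats::runif(1, log(0.3), log(3)))
  alpha <- exp(stats::runif(1, log(0.2), log(5)))
  curve_pair(
    hill_curve(0, 1, ec50_a, n),
    hill_curve(0, 1, ec50_a / alpha, n)
  )
}

# Doses spanning the informative range of a curve.
random_dose <- function(curve, n = 1) {
  curve$ec50 * exp(stats::runif(n, log(0.2), log(5)))
}
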