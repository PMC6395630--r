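# Numerical core of the Hand model.
#
# The combined dose-effect curve f_AB,lambda of the fixed-ratio mixture
# C_lambda is characterised by an autonomous ODE in the effect: its
# sensitivity (effect gain per unit mixture dose) at effect level x is
# the mixture-weighted sum of the single-agent sensitivities,
#     s_AB,lambda(x) = lambda * s_A(x) + (1 - lambda) * s_B(x),
# with each sensitivity extended by zero above that agent's maximal
# effect. The ODE is degenerate at the baseline whenever s(e_min) = 0
# (the initial condition is an equilibrium), so the robust primary route
# is the inverse-curve integral
#     f_AB,lambda^{-1}(x) = int_{e_min}^{x} 1 / s_AB,lambda(y) dy,
# inverted by monotone root finding.
#
# The integrand 1/s diverges at both the baseline (for Hill coefficients
# above 1) and the attainable supremum, so the integral is evaluated
# after the substitution y = g(t) with g a reference Hill curve sharing
# the baseline, the supremum and the largest Hill coefficient of the
# pair: the transformed integrand g'(t)/s(g(t)) is bounded at both
# endpoints, and the divergence of the inverse curve at saturation
# becomes linear growth in t, which bracketed root finding handles
# without special-casing.

# Validation-free closures for the quadrature hot path.
fast_sens_fn <- function(crv) {
  e_min <- crv$e_min; e_max <- crv$e_max
  scale <- crv$n / (crv$ec50 * (e_max - e_min))
  p_lo <- 1 - 1 / crv$n; p_hi <- 1 + 1 / crv$n
  function(x) {
    out <- numeric(length(x))
    i <- x >= e_min & x <= e_max
    xi <- x[i]
    out[i] <- scale * (xi - e_min)^p_lo * (e_max - xi)^p_hi
    out
  }
}

# Weight on curve A is lambda; the rest goes to B.
combined_sens_fn <- function(pair, lambda) {
  sa <- fast_sens_fn(pair$curve_a)
  sb <- fast_sens_fn(pair$curve_b)
  force(lambda)
  function(x) lambda * sa(x) + (1 - lambda) * sb(x)
}

# Supremum of the effect attainable by the mixture C_lambda: only curves
# with positive weight contribute.
attainable_sup <- function(pair, lambda) {
  if (lambda == 1) {
    pair$curve_a$e_max
  } else if (lambda == 0) {
    pair$curve_b$e_max
  } else {
    max(pair$curve_a$e_max, pair$curve_b$e_max)
  }
}

# Reference curve for the regularising substitution.
ref_curve <- function(pair, lambda) {
  hill_curve(
    pair$e_min,
    attainable_sup(pair, lambda),
    lambda * pair$curve_a$ec50 + (1 - lambda) * pair$curve_b$ec50,
    max(pair$curve_a$n, pair$curve_b$n)
  )
}

# Interior kink of the combined sensitivity: the partial agent's e_max.
pair_kinks <- function(pair) {
  if (pair$equal_e_max) {
    numeric(0)
  } else {
    min(pair$curve_a$e_max, pair$curve_b$e_max)
  }
}

# Transformed integrand dJ/dt = g'(t) / s(g(t)); bounded at both
# endpoints by construction of the reference curve g.
make_integrand <- function(s_fn, ref) {
  g_min <- ref$e_min; g_max <- ref$e_max; g_ec <- ref$ec50; g_n <- ref$n
  g_sens <- fast_sens_fn(ref)
  function(t) {
    y <- ifelse(t > 0, g_min + (g_max - g_min) / (1 + (g_ec / t)^g_n), g_min)
    g_sens(y) / s_fn(y)
  }
}

# J over [t_lo, t_hi], split at interior kink images.
piece_integral <- function(integrand, t_lo, t_hi, kinks_t = numeric(0),
                           rel_tol = 1e-10) {
  if (t_hi <= t_lo) return(0)
  breaks <- sort(unique(c(t_lo, kinks_t[kinks_t > t_lo & kinks_t < t_hi],
                          t_hi)))
  total <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    piece <- stats::integrate(
      integrand, breaks[i], breaks[i + 1L],
      rel.tol = rel_tol, abs.tol = 1e-13, subdivisions = 400L,
      stop.on.error = FALSE
    )
    if (!piece$message %in% c("OK", "roundoff error was detected")) {
      stop_combonull(
        "combonull_quadrature_failure",
        sprintf(
          "quadrature of the inverse combined curve failed on t in [%g, %g]: %s (abs.error %g)",
          breaks[i], breaks[i + 1L], piece$message, piece$abs.error
        ),
        achieved_error = piece$abs.error
      )
    }
    total <- total + piece$value
  }
  total
}

# Generic engine on an arbitrary combined-sensitivity function. `ref`
# fixes the substitution; its e_max must equal the attainable sup of
# s_fn and its Hill coefficient must be >= the coefficients shaping s_fn
# at both endpoints for the transformed integrand to stay bounded.
hand_inverse_sens <- function(s_fn, ref, x, kinks_y = numeric(0)) {
  if (x <= ref$e_min) stop_effect_below_range(x, ref$e_min)
  if (x >= ref$e_max) stop_effect_above_range(x, ref$e_max)
  kinks_t <- vapply(kinks_y[kinks_y > ref$e_min & kinks_y < x],
                    function(k) hill_inverse(ref, k), numeric(1))
  piece_integral(make_integrand(s_fn, ref), 0, hill_inverse(ref, x),
                 kinks_t)
}

# Solve f^{-1}(x) = cc for x: root in the substituted variable t, where
# J is smooth and grows without bound as t -> Inf. J values are
# memoized at every queried t and new queries integrate only from the
# nearest anchor, so the root search costs a handful of short
# quadratures instead of repeated integrals from zero.
hand_solve_sens <- function(s_fn, ref, cc, kinks_y = numeric(0)) {
  if (cc <= 0) return(ref$e_min)
  kt_all <- vapply(kinks_y[kinks_y > ref$e_min & kinks_y < ref$e_max],
                   function(k) hill_inverse(ref, k), numeric(1))
  integrand <- make_integrand(s_fn, ref)
  anchors_t <- 0
  anchors_j <- 0
  jfun <- function(t) {
    i <- findInterval(t, anchors_t)
    if (i >= 1 && anchors_t[i] == t) return(anchors_j[i])
    val <- if (i >= 1) {
      anchors_j[i] + piece_integral(integrand, anchors_t[i], t, kt_all)
    } else {
      anchors_j[1] - piece_integral(integrand, t, anchors_t[1], kt_all)
    }
    keep <- order(c(anchors_t, t))
    anchors_t <<- c(anchors_t, t)[keep]
    anchors_j <<- c(anchors_j, val)[keep]
    val
  }
  lo <- 0; j_lo <- 0
  hi <- ref$ec50
  j_hi <- jfun(hi)
  tries <- 0
  while (j_hi < cc && tries < 200) {
    lo <- hi; j_lo <- j_hi
    hi <- hi * 2
    j_hi <- jfun(hi)
    tries <- tries + 1
  }
  if (j_hi < cc) {
    stop_combonull(
      "combonull_bracket_failure",
      sprintf("could not bracket mixture dose %g (reached J(%g) = %g)",
              cc, hi, j_hi)
    )
  }
  # Safeguarded Newton on J(t) = cc: J is smooth and increasing with
  # dJ/dt = integrand(t) available at no extra quadrature cost.
  tol_c <- 1e-11 * max(cc, ref$ec50)
  t <- lo + (cc - j_lo) * (hi - lo) / (j_hi - j_lo)
  for (it in 1:80) {
    jt <- jfun(t)
    if (jt > cc) { hi <- t; j_hi <- jt } else { lo <- t; j_lo <- jt }
    if (abs(jt - cc) <= tol_c || (hi - lo) <= 1e-13 * max(hi, ref$ec50)) break
    d <- integrand(t)
    t_new <- t - (jt - cc) / d
    if (!is.finite(t_new) || t_new <= lo || t_new >= hi) {
      t_new <- (lo + hi) / 2
    }
    t <- t_new
  }
  hill_eval(ref, t)
}

#' Combined effect-sensitivity of a drug mixture
#'
#' Sensitivity of the fixed-ratio mixture \eqn{C_\lambda} at effect level
#' `x`: the mixture-weighted sum
#' \eqn{s_{AB,\lambda}(x) = \lambda s_A(x) + (1-\lambda) s_B(x)}, with
#' each single-agent sensitivity extended by zero above that agent's
#' maximal effect. When A is the partial agent and
#' \eqn{E_{max,A} \le x < E_{max,B}} this reduces to
#' \eqn{(1-\lambda) s_B(x)}: beyond the partial agent's saturation only
#' the full agent drives the effect. Vectorised over `x`.
#'
#' @param pair A [curve_pair()].
#' @param lambda Mixture ratio in `[0, 1]` (fraction of the mixture dose
#'   that is drug A).
#' @param x Effect level(s).
#' @return Sensitivity value(s).
#' @export
combined_sensitivity <- function(pair, lambda, x) {
  stopifnot(inherits(pair, "curve_pair"),
            is.numeric(lambda), length(lambda) == 1L,
            lambda >= 0, lambda <= 1)
  combined_sens_fn(pair, lambda)(x)
}

#' Inverse of the Hand combined dose-effect curve
#'
#' The mixture dose of \eqn{C_\lambda} needed to reach effect `x` under
#' the Hand model, computed as the integral of the reciprocal combined
#' sensitivity from the baseline up to `x`.
#'
#' @inheritParams combined_sensitivity
#' @param x Effect level strictly between the baseline and the mixture's
#'   attainable supremum (the contributing full agent's `e_max`).
#' @return Mixture dose (scalar).
#' @export
hand_inverse <- function(pair, lambda, x) {
  stopifnot(inherits(pair, "curve_pair"),
            is.numeric(lambda), length(lambda) == 1L,
            lambda >= 0, lambda <= 1,
            is.numeric(x), length(x) == 1L, is.finite(x))
  if (lambda == 1) return(hill_inverse(pair$curve_a, x))
  if (lambda == 0) return(hill_inverse(pair$curve_b, x))
  hand_inverse_sens(combined_sens_fn(pair, lambda), ref_curve(pair, lambda),
                    x, kinks_y = pair_kinks(pair))
}

#' Hand combined dose-effect curve
#'
#' Effect of a mixture dose `cc` of \eqn{C_\lambda} under the Hand model,
#' obtained by inverting [hand_inverse()] through monotone root finding.
#' For a partial agent and `cc` beyond the critical dose
#' \eqn{c^*(\lambda)} (see [c_star()]) the ODE is driven by the full
#' agent alone and the closed form
#' \eqn{f_B(f_B^{-1}(E_{max,A}) + (1-\lambda)(cc - c^*))} (for partial
#' agent A) is used.
#'
#' @inheritParams combined_sensitivity
#' @param cc Mixture dose, non-negative (scalar).
#' @return Effect (scalar).
#' @export
hand_combined_curve <- function(pair, lambda, cc) {
  stopifnot(inherits(pair, "curve_pair"),
            is.numeric(lambda), length(lambda) == 1L,
            lambda >= 0, lambda <= 1,
            is.numeric(cc), length(cc) == 1L, is.finite(cc))
  if (cc < 0) stop("mixture dose must be non-negative")
  if (cc == 0) return(pair$e_min)
  if (lambda == 1) return(hill_eval(pair$curve_a, cc))
  if (lambda == 0) return(hill_eval(pair$curve_b, cc))

  if (!pair$equal_e_max) {
    if (pair$partial == "a") {
      full <- pair$curve_b; wf <- 1 - lambda
    } else {
      full <- pair$curve_a; wf <- lambda
    }
    e_max_p <- min(pair$curve_a$e_max, pair$curve_b$e_max)
    cs <- c_star_weighted(pair, lambda)
    if (is.finite(cs) && cc >= cs) {
      return(hill_eval(full, hill_inverse(full, e_max_p) + wf * (cc - cs)))
    }
  }
  hand_solve_sens(combined_sens_fn(pair, lambda), ref_curve(pair, lambda),
                  cc, kinks_y = pair_kinks(pair))
}

# c*(lambda) for arbitrary orientation of the partial agent.
c_star_weighted <- function(pair, lambda) {
  e_max_p <- min(pair$curve_a$e_max, pair$curve_b$e_max)
  wf <- if (pair$partial == "a") 1 - lambda else lambda
  if (wf == 0) return(Inf) # pure partial agent saturates only asymptotically
  hand_inverse_sens(combined_sens_fn(pair, lambda), ref_curve(pair, lambda),
                    e_max_p)
}

#' Critical mixture dose of a partial/full agent pair
#'
#' For a partial agent A and full agent B, \eqn{c^*(\lambda)} is the dose
#' of the mixture \eqn{C_\lambda} at which the Hand combined curve
#' attains the partial agent's maximal effect:
#' \deqn{c^*(\lambda) = \int_{E_{min}}^{E_{max,A}}
#'   \left(\lambda s_A(x) + (1-\lambda) s_B(x)\right)^{-1} dx.}
#' Beyond it only the full agent contributes. At \eqn{\lambda = 1} the
#' pure partial agent saturates only asymptotically and `Inf` is
#' returned.
#'
#' @param pair A [curve_pair()] with a partial agent (unequal maximal
#'   effects).
#' @param lambda Mixture ratio (fraction of drug A).
#' @return Positive mixture dose, or `Inf` when the mixture contains
#'   only the partial agent.
#' @export
c_star <- function(pair, lambda) {
  stopifnot(inherits(pair, "curve_pair"),
            is.numeric(lambda), length(lambda) == 1L,
            lambda >= 0, lambda <= 1)
  if (pair$equal_e_max) {
    stop("c_star requires a partial agent (unequal maximal effects)")
  }
  c_star_weighted(pair, lambda)
}

#' Limit isobole of the Hand model at the partial agent's maximal effect
#'
#' For a partial agent A and full agent B, the level set of the Hand
#' surface at effect \eqn{E_{max,A}} is parametrised by the mixture ratio
#' as \eqn{\lambda \mapsto (a^*(\lambda), b^*(\lambda))} with
#' \eqn{a^* = \lambda c^*(\lambda)}, \eqn{b^* = (1-\lambda) c^*(\lambda)}.
#' The B-component decreases continuously to 0 as \eqn{\lambda \to 1},
#' in contrast with the Loewe model's horizontal limit isobole at
#' \eqn{b = f_B^{-1}(E_{max,A})}.
#'
#' @param pair A [curve_pair()] with a partial agent (either
#'   orientation; `lambda` is always the fraction of drug A).
#' @param lambdas Mixture ratios at which to evaluate. On the
#'   pure-partial-agent ray the limiting dose is infinite and the
#'   partial agent's own coordinate is 0.
#' @return A data frame with columns `lambda`, `c_star`, `a_star`,
#'   `b_star`.
#' @export
limit_isobole <- function(pair, lambdas = seq(0, 0.98, length.out = 50)) {
  stopifnot(inherits(pair, "curve_pair"))
  if (pair$equal_e_max) {
    stop("limit_isobole requires a partial agent (unequal maximal effects)")
  }
  cs <- vapply(lambdas, function(l) c_star_weighted(pair, l), numeric(1))
  a_star <- lambdas * cs
  b_star <- (1 - lambdas) * cs
  # the pure-partial-agent ray saturates only asymptotically: its own
  # coordinate stays 0 and the limiting dose is infinite
  pure <- !is.finite(cs)
  if (any(pure)) {
    if (pair$partial == "a") {
      b_star[pure] <- 0
    } else {
      a_star[pure] <- 0
    }
  }
  data.frame(lambda = lambdas, c_star = cs, a_star = a_star, b_star = b_star)
}

#' Finite-N alternating dose-equivalence scheme
#'
#' Splits the doses into `N` equal portions `da = a/N`, `db = b/N` and
#' applies them alternately, each step converting the current effect into
#' an equivalent dose of the agent about to act. `N = 1` with
#' `order = "a_first"` reproduces the Tallarida model
#' \eqn{E_{T,A\to B}} exactly; as `N` grows the scheme converges, for
#' either ordering, to the Hand model — the construction that motivates
#' the Hand ODE. When the current effect already exceeds the acting
#' agent's maximal effect, that portion contributes nothing (the step is
#' capped), mirroring the Hand model's zero-extension of the
#' sensitivity.
#'
#' @param pair A [curve_pair()].
#' @param a,b Doses of A and B (non-negative scalars).
#' @param n_steps Number of portions `N >= 1`.
#' @param order `"a_first"` or `"b_first"`: which agent acts first in
#'   each alternating round.
#' @return Effect (scalar).
#' @export
tallarida_iterated <- function(pair, a, b, n_steps,
                               order = c("a_first", "b_first")) {
  order <- match.arg(order)
  stopifnot(inherits(pair, "curve_pair"),
            is.numeric(a), length(a) == 1L, a >= 0,
            is.numeric(b), length(b) == 1L, b >= 0,
            is.numeric(n_steps), length(n_steps) == 1L, n_steps >= 1)
  n_steps <- as.integer(n_steps)
  da <- a / n_steps
  db <- b / n_steps
  first <- if (order == "a_first") pair$curve_a else pair$curve_b
  second <- if (order == "a_first") pair$curve_b else pair$curve_a
  d_first <- if (order == "a_first") da else db
  d_second <- if (order == "a_first") db else da
  # inlined Hill arithmetic: this loop runs up to millions of scalar
  # steps in convergence studies
  p1 <- c(first$e_min, first$e_max, first$ec50, first$n)
  p2 <- c(second$e_min, second$e_max, second$ec50, second$n)
  step <- function(p, d, x) {
    if (d == 0) return(x)
    cap <- p[2] - 1e-12 * (p[2] - p[1])
    # saturated agent contributes nothing (zero-extension)
    if (x >= cap) return(x)
    dose0 <- if (x <= p[1]) 0 else p[3] * ((x - p[1]) / (p[2] - x))^(1 / p[4])
    p[1] + (p[2] - p[1]) / (1 + (p[3] / (d + dose0))^p[4])
  }
  x <- pair$e_min
  for (i in seq_len(n_steps)) {
    x <- step(p1, d_first, x)
    x <- step(p2, d_second, x)
  }
  x
}
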