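#' Four-parameter Hill dose-effect curve
#'
#' Constructs a strictly increasing Hill curve
#' \deqn{f(a) = E_{min} + \frac{E_{max} - E_{min}}{1 + (EC_{50}/a)^{n}}}
#' describing the effect of a single agent as a function of its dose.
#' `e_min` is the effect of the untreated condition (the value at dose 0,
#' taken as the limit of the formula), `e_max` the asymptotic saturation
#' level, `ec50` the dose at which the half-maximal effect is reached and
#' `n` the Hill coefficient controlling steepness.
#'
#' @param e_min Baseline effect (untreated condition).
#' @param e_max Maximal (asymptotic) effect; must exceed `e_min`.
#' @param ec50 Half-maximal dose; must be positive.
#' @param n Hill coefficient; must be positive.
#'
#' @return An object of class `hill_curve`.
#' @examples
#' crv <- hill_curve(0, 1, ec50 = 2, n = 1.5)
#' hill_eval(crv, 2) # 0.5 at the EC50
#' @export
hill_curve <- function(e_min, e_max, ec50, n) {
  stopifnot(
    is.numeric(e_min), length(e_min) == 1L, is.finite(e_min),
    is.numeric(e_max), length(e_max) == 1L, is.finite(e_max),
    is.numeric(ec50), length(ec50) == 1L, is.finite(ec50),
    is.numeric(n), length(n) == 1L, is.finite(n)
  )
  if (e_max <= e_min) {
    stop("e_max must be strictly greater than e_min (increasing curve)")
  }
  if (ec50 <= 0) stop("ec50 must be positive")
  if (n <= 0) stop("Hill coefficient n must be positive")
  structure(
    list(e_min = e_min, e_max = e_max, ec50 = ec50, n = n),
    class = "hill_curve"
  )
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf(
    "Hill curve: e_min = %g, e_max = %g, EC50 = %g, n = %g\n",
    x$e_min, x$e_max, x$ec50, x$n
  ))
  invisible(x)
}

#' Zero-effect (flat) dose-effect curve
#'
#' A constant curve returning `e_min` at every dose. Used as the
#' parsimonious alternative in monotherapy model selection for drugs
#' showing no dose response; it has no inverse.
#'
#' @param e_min Constant effect level.
#' @return An object of class `zero_effect_curve`.
#' @export
zero_effect_curve <- function(e_min) {
  stopifnot(is.numeric(e_min), length(e_min) == 1L, is.finite(e_min))
  structure(list(e_min = e_min), class = "zero_effect_curve")
}

#' @export
print.zero_effect_curve <- function(x, ...) {
  cat(sprintf("Zero-effect curve: constant effect %g\n", x$e_min))
  invisible(x)
}

#' Evaluate a Hill curve
#'
#' Returns the effect at dose `a`. At `a = 0` the baseline `e_min` is
#' returned by the limit convention (the closed-form expression contains
#' `EC50/a`). Vectorised over `a`.
#'
#' @param curve A [hill_curve()].
#' @param a Dose(s), non-negative.
#' @return Effect value(s).
#' @export
hill_eval <- function(curve, a) {
  UseMethod("hill_eval")
}

#' @export
hill_eval.hill_curve <- function(curve, a) {
  stopifnot(is.numeric(a), all(is.finite(a)))
  if (any(a < 0)) stop("dose must be non-negative")
  out <- numeric(length(a))
  pos <- a > 0
  out[!pos] <- curve$e_min
  if (any(pos)) {
    out[pos] <- curve$e_min + (curve$e_max - curve$e_min) /
      (1 + (curve$ec50 / a[pos])^curve$n)
  }
  out
}

#' @export
hill_eval.zero_effect_curve <- function(curve, a) {
  stopifnot(is.numeric(a), all(is.finite(a)))
  if (any(a < 0)) stop("dose must be non-negative")
  rep(curve$e_min, length(a))
}

#' Invert a Hill curve
#'
#' Returns the dose at which the curve attains effect `x`:
#' `ec50 * ((x - e_min)/(e_max - x))^(1/n)`. Defined only for effects
#' strictly between `e_min` and `e_max`; the two out-of-range cases raise
#' distinct conditions (`combonull_effect_below_range`,
#' `combonull_effect_above_range`) because an effect at or above `e_max`
#' signals the partial-agent regime downstream. Vectorised over `x`.
#'
#' @param curve A [hill_curve()].
#' @param x Effect value(s) with `e_min < x < e_max`.
#' @return Dose(s).
#' @export
hill_inverse <- function(curve, x) {
  stopifnot(inherits(curve, "hill_curve"), is.numeric(x), all(is.finite(x)))
  if (any(x <= curve$e_min)) stop_effect_below_range(min(x), curve$e_min)
  if (any(x >= curve$e_max)) stop_effect_above_range(max(x), curve$e_max)
  curve$ec50 * ((x - curve$e_min) / (curve$e_max - x))^(1 / curve$n)
}

# Internal inverse with the baseline convention inverse(e_min) = 0,
# used along iterated-dosing trajectories that start at the baseline.
hill_inverse0 <- function(curve, x) {
  ifelse(x <= curve$e_min, 0, hill_inverse(curve, pmin(x, curve$e_max)))
}

#' Effect-sensitivity of a Hill curve
#'
#' The sensitivity `s(x) = f'(f^{-1}(x))` of a dose-effect curve expressed
#' as a function of the effect level (effect gained per unit dose at the
#' dose where effect `x` is reached). For a Hill curve it has the closed
#' form
#' \deqn{s(x) = \frac{n}{EC_{50}(E_{max}-E_{min})}
#'   (x - E_{min})^{1 - 1/n} (E_{max} - x)^{1 + 1/n}.}
#' Outside `[e_min, e_max]` the sensitivity is zero by convention: a
#' saturated (partial) agent contributes no further effect gain, and the
#' zero-extension keeps the Hand model's integrands total functions.
#' Vectorised over `x`.
#'
#' @param curve A [hill_curve()].
#' @param x Effect level(s).
#' @return Sensitivity value(s) in effect per dose (never negative).
#' @export
hill_sensitivity <- function(curve, x) {
  stopifnot(inherits(curve, "hill_curve"), is.numeric(x), all(is.finite(x)))
  out <- numeric(length(x))
  inside <- x >= curve$e_min & x <= curve$e_max
  if (any(inside)) {
    xi <- x[inside]
    scale <- curve$n / (curve$ec50 * (curve$e_max - curve$e_min))
    out[inside] <- scale *
      (xi - curve$e_min)^(1 - 1 / curve$n) *
      (curve$e_max - xi)^(1 + 1 / curve$n)
  }
  out
}

#' Potency ratio of two curves at an effect level
#'
#' `alpha(x) = f_A^{-1}(x) / f_B^{-1}(x)`: how much less of A than of B is
#' needed to produce effect `x`. Constant in `x` exactly when the two
#' curves coincide in maximal effect and Hill coefficient (parallel curves
#' on a log-dose axis), the regime in which all dose-equivalence models
#' coincide.
#'
#' @param curve_a,curve_b [hill_curve()] objects.
#' @param x Effect level strictly inside the range attained by both curves.
#' @return Positive ratio.
#' @export
potency_ratio <- function(curve_a, curve_b, x) {
  hill_inverse(curve_a, x) / hill_inverse(curve_b, x)
}
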