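# Reference-effect evaluation E(a, b) for the five null models.
#
# Every model agrees with the monotherapies on the axes:
# E(a, 0) = f_A(a), E(0, b) = f_B(b). They differ in how the two
# dose-effect curves are combined in the interior, and in where they are
# defined at all (Loewe breaks down at effect levels the partial agent
# cannot reach; the Tallarida equivalent dose can be undefined).

MODEL_NAMES <- c(
  "loewe", "loewe_hsa", "tallarida_ab", "tallarida_ba",
  "tallarida_lb", "tallarida_ub", "hand", "bliss", "hsa"
)

# Generic Loewe solver on two inverse-dose functions. The left-hand side
# of the additivity equation a/inv_a(x) + b/inv_b(x) is strictly
# decreasing in x, so a bracketed root is unique when it exists.
loewe_solve <- function(inv_a, inv_b, a, b, e_min, x_lim, tol = 1e-10) {
  if (a == 0 && b == 0) return(e_min)
  range <- x_lim - e_min
  eps <- 1e-12 * range
  lhs <- function(x) a / inv_a(x) + b / inv_b(x) - 1
  hi <- x_lim - eps
  f_hi <- lhs(hi)
  if (f_hi > 0) stop_loewe_undefined(x_lim)
  lo <- e_min + eps
  f_lo <- lhs(lo)
  # f_lo is +Inf-like for any positive dose; guard pathological rounding
  if (!is.finite(f_lo)) f_lo <- .Machine$double.xmax
  if (f_lo < 0) return(e_min) # doses negligible at solver resolution
  stats::uniroot(lhs, lower = lo, upper = hi, f.lower = f_lo, f.upper = f_hi,
                 tol = tol * range)$root
}

#' Loewe additivity reference effect
#'
#' Solves the Loewe additivity equation
#' \deqn{\frac{a}{f_A^{-1}(x)} + \frac{b}{f_B^{-1}(x)} = 1}
#' for the effect `x` by bracketed root search. The model postulates
#' straight isoboles whose slope at level `x` is the potency ratio. It is
#' undefined for effect levels at or above the smaller of the two maximal
#' effects: with a partial agent A, dose pairs above the horizontal limit
#' isobole `b = f_B^{-1}(e_max_A)` raise a `combonull_loewe_undefined`
#' condition carrying the limiting level (see [loewe_hsa_effect()] for
#' the extension).
#'
#' @param pair A [curve_pair()].
#' @param a,b Doses of A and B (non-negative scalars).
#' @return Effect (scalar).
#' @export
loewe_effect <- function(pair, a, b) {
  check_dose_pair(a, b)
  stopifnot(inherits(pair, "curve_pair"))
  # on the axes the additivity equation reduces to the monotherapy curve,
  # including effect levels beyond the other agent's range
  if (a == 0) return(hill_eval(pair$curve_b, b))
  if (b == 0) return(hill_eval(pair$curve_a, a))
  x_lim <- min(pair$curve_a$e_max, pair$curve_b$e_max)
  loewe_solve(
    function(x) hill_inverse(pair$curve_a, x),
    function(x) hill_inverse(pair$curve_b, x),
    a, b, pair$e_min, x_lim
  )
}

#' Loewe reference with HSA extension beyond its domain
#'
#' Equal to [loewe_effect()] wherever the Loewe model is defined; where
#' it is not (the partial-agent regime beyond the horizontal limit
#' isobole), the Highest Single Agent reference is used instead. The two
#' pieces join continuously at the limit isobole, where both equal the
#' partial agent's maximal effect.
#'
#' @inheritParams loewe_effect
#' @return Effect (scalar).
#' @export
loewe_hsa_effect <- function(pair, a, b) {
  tryCatch(
    loewe_effect(pair, a, b),
    combonull_loewe_undefined = function(cnd) hsa_effect(pair, a, b)
  )
}

#' Tallarida dose-equivalence reference effect
#'
#' The ordering `a_to_b` converts dose `a` into the B-equivalent dose
#' producing the same effect and evaluates
#' \eqn{E_{T,A\to B}(a,b) = f_B(b + f_B^{-1}(f_A(a)))}; `b_to_a` swaps
#' the roles. The two orderings generally disagree (the model is not
#' commutative), which is the ambiguity the Hand model resolves. The
#' equivalent dose is undefined when the leading agent's effect exceeds
#' the other curve's maximal effect; a
#' `combonull_equivalent_dose_undefined` condition names the saturating
#' curve.
#'
#' @inheritParams loewe_effect
#' @param direction `"a_to_b"` (A acts first) or `"b_to_a"`.
#' @return Effect (scalar).
#' @export
tallarida_effect <- function(pair, a, b, direction = c("a_to_b", "b_to_a")) {
  direction <- match.arg(direction)
  check_dose_pair(a, b)
  stopifnot(inherits(pair, "curve_pair"))
  if (direction == "a_to_b") {
    first <- pair$curve_a; second <- pair$curve_b
    d_first <- a; d_second <- b; second_name <- "B"
  } else {
    first <- pair$curve_b; second <- pair$curve_a
    d_first <- b; d_second <- a; second_name <- "A"
  }
  if (d_first == 0) return(hill_eval(second, d_second))
  x1 <- hill_eval(first, d_first)
  if (x1 >= second$e_max) {
    stop_equivalent_dose_undefined(second_name, x1, second$e_max)
  }
  hill_eval(second, d_second + hill_inverse(second, x1))
}

#' Lower/upper envelope of the two Tallarida orderings
#'
#' Returns both directional Tallarida references and their minimum
#' (TallaridaLB) and maximum (TallaridaUB), the bracket within which any
#' ordering-based dose-equivalence prediction falls. When only one
#' ordering is defined its value serves as both bounds, flagged via
#' `both_defined = FALSE`; when neither is defined an error is raised.
#'
#' @inheritParams loewe_effect
#' @return A list with elements `lb`, `ub`, `a_to_b`, `b_to_a` (each an
#'   effect or `NA` if undefined) and `both_defined`.
#' @export
tallarida_envelope <- function(pair, a, b) {
  val <- function(direction) {
    tryCatch(
      tallarida_effect(pair, a, b, direction),
      combonull_equivalent_dose_undefined = function(cnd) NA_real_
    )
  }
  ab <- val("a_to_b")
  ba <- val("b_to_a")
  if (is.na(ab) && is.na(ba)) {
    stop_combonull(
      "combonull_envelope_undefined",
      "both Tallarida orderings are undefined at this dose pair"
    )
  }
  list(
    lb = min(ab, ba, na.rm = TRUE),
    ub = max(ab, ba, na.rm = TRUE),
    a_to_b = ab, b_to_a = ba,
    both_defined = !is.na(ab) && !is.na(ba)
  )
}

#' Bliss independence reference effect
#'
#' \eqn{E_{Bliss}(a,b) = f_A(a) + f_B(b) - f_A(a) f_B(b)}, interpreting
#' normalised effects as probabilities of independent events. The formula
#' requires the effect scale on which the baseline is 0 and the larger of
#' the two maximal effects is 1; by default an unnormalised pair is an
#' error, and `normalise = TRUE` rescales via [normalise_pair()] first
#' (the returned effect is then on the unit scale).
#'
#' @inheritParams loewe_effect
#' @param normalise Auto-apply the unit-scale normalisation when needed.
#' @return Effect (scalar).
#' @export
bliss_effect <- function(pair, a, b, normalise = FALSE) {
  check_dose_pair(a, b)
  stopifnot(inherits(pair, "curve_pair"))
  if (!is_unit_scale(pair)) {
    if (!normalise) {
      stop_combonull(
        "combonull_not_normalised",
        "Bliss requires effects normalised to [0, 1]; normalise the pair or set normalise = TRUE"
      )
    }
    pair <- normalise_pair(pair)
  }
  fa <- hill_eval(pair$curve_a, a)
  fb <- hill_eval(pair$curve_b, b)
  fa + fb - fa * fb
}

#' Highest Single Agent reference effect
#'
#' \eqn{E_{HSA}(a,b) = \max\{f_A(a), f_B(b)\}}: the combination is
#' credited only with the better of the two monotherapies. Defined
#' everywhere, but violates the sham combination principle and
#' systematically predicts lower effects than every other model here.
#'
#' @inheritParams loewe_effect
#' @return Effect (scalar).
#' @export
hsa_effect <- function(pair, a, b) {
  check_dose_pair(a, b)
  stopifnot(inherits(pair, "curve_pair"))
  max(hill_eval(pair$curve_a, a), hill_eval(pair$curve_b, b))
}

#' Hand reference effect
#'
#' Evaluates the Hand model
#' \eqn{E_H(a,b) = f_{AB,\lambda}(a+b)} with mixture ratio
#' \eqn{\lambda = a/(a+b)}, where the combined curve solves the Hand ODE
#' (mixture-weighted summation of effect-sensitivity curves; see
#' [hand_combined_curve()]). Defined for all dose pairs, including
#' partial/full agent combinations.
#'
#' @inheritParams loewe_effect
#' @return Effect (scalar).
#' @export
hand_effect <- function(pair, a, b) {
  check_dose_pair(a, b)
  stopifnot(inherits(pair, "curve_pair"))
  if (a + b == 0) return(pair$e_min)
  hand_combined_curve(pair, a / (a + b), a + b)
}

check_dose_pair <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (a < 0 || b < 0) stop("doses must be non-negative")
  invisible(TRUE)
}

#' Null-model surface
#'
#' Binds a model name to a curve pair (plus evaluation settings) as an
#' evaluatable reference surface `E(a, b)`.
#'
#' @param model One of `"loewe"`, `"loewe_hsa"`, `"tallarida_ab"`,
#'   `"tallarida_ba"`, `"tallarida_lb"`, `"tallarida_ub"`, `"hand"`,
#'   `"bliss"`, `"hsa"`.
#' @param pair A [curve_pair()].
#' @param bliss_normalise Auto-normalise the pair for Bliss evaluation.
#' @return An object of class `null_surface`.
#' @export
null_surface <- function(model, pair, bliss_normalise = FALSE) {
  model <- match.arg(model, MODEL_NAMES)
  stopifnot(inherits(pair, "curve_pair"))
  structure(
    list(model = model, pair = pair, bliss_normalise = bliss_normalise),
    class = "null_surface"
  )
}

#' @export
print.null_surface <- function(x, ...) {
  cat(sprintf("Null-model surface: %s\n", x$model))
  print(x$pair)
  invisible(x)
}

#' Evaluate a null-model surface at one dose pair
#'
#' Dispatches to the model-specific reference function. Where the model
#' is undefined the underlying structured condition propagates; use
#' [evaluate_surface()] for status-coded grid evaluation.
#'
#' @param surface A [null_surface()].
#' @param a,b Doses (non-negative scalars).
#' @return Effect (scalar).
#' @export
surface_effect <- function(surface, a, b) {
  stopifnot(inherits(surface, "null_surface"))
  pair <- surface$pair
  switch(surface$model,
    loewe = loewe_effect(pair, a, b),
    loewe_hsa = loewe_hsa_effect(pair, a, b),
    tallarida_ab = tallarida_effect(pair, a, b, "a_to_b"),
    tallarida_ba = tallarida_effect(pair, a, b, "b_to_a"),
    tallarida_lb = tallarida_envelope(pair, a, b)$lb,
    tallarida_ub = tallarida_envelope(pair, a, b)$ub,
    hand = hand_effect(pair, a, b),
    bliss = bliss_effect(pair, a, b, normalise = surface$bliss_normalise),
    hsa = hsa_effect(pair, a, b)
  )
}

#' Evaluate a null-model surface on a dose grid
#'
#' Evaluates the reference effect on the Cartesian grid
#' `dose_a x dose_b`. Cells where the model is undefined (Loewe beyond
#' the partial agent's range, an undefined Tallarida equivalent dose) are
#' returned as `NaN` with a machine-readable reason in the parallel
#' status matrix — undefined regions are model content, not numerical
#' failures. Row/column at dose 0 reproduce the monotherapy curves.
#'
#' @param surface A [null_surface()].
#' @param dose_a,dose_b Ascending non-negative dose grids.
#' @return A list of class `surface_grid` with matrices `effect` and
#'   `status` (rows index `dose_a`, columns `dose_b`; statuses `"ok"`,
#'   `"undefined_loewe"`, `"undefined_equivalent_dose"`).
#' @export
evaluate_surface <- function(surface, dose_a, dose_b) {
  stopifnot(inherits(surface, "null_surface"),
            is.numeric(dose_a), is.numeric(dose_b),
            all(dose_a >= 0), all(dose_b >= 0),
            !is.unsorted(dose_a), !is.unsorted(dose_b))
  eff <- matrix(NaN, length(dose_a), length(dose_b),
                dimnames = list(dose_a, dose_b))
  status <- matrix("ok", length(dose_a), length(dose_b),
                   dimnames = list(dose_a, dose_b))
  for (i in seq_along(dose_a)) {
    for (j in seq_along(dose_b)) {
      res <- tryCatch(
        surface_effect(surface, dose_a[i], dose_b[j]),
        combonull_loewe_undefined = function(cnd) {
          status[i, j] <<- "undefined_loewe"
          NaN
        },
        combonull_equivalent_dose_undefined = function(cnd) {
          status[i, j] <<- "undefined_equivalent_dose"
          NaN
        },
        combonull_envelope_undefined = function(cnd) {
          status[i, j] <<- "undefined_equivalent_dose"
          NaN
        }
      )
      eff[i, j] <- res
    }
  }
  structure(list(effect = eff, status = status,
                 dose_a = dose_a, dose_b = dose_b,
                 model = surface$model),
            class = "surface_grid")
}
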