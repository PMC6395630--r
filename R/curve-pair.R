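#' Pair of monotherapy dose-effect curves
#'
#' Bundles the two Hill curves of a combination experiment. The baseline
#' effects must agree (both describe the same untreated condition); the
#' two maximal effects may differ, in which case the drug with the lower
#' `e_max` is the partial agent and the other the full agent.
#'
#' @param curve_a,curve_b [hill_curve()] objects with equal `e_min`.
#' @param tol Relative tolerance used both for the shared-baseline check
#'   and for deciding whether the two maximal effects are equal (which
#'   controls whether partial-agent code paths activate).
#' @return An object of class `curve_pair` with elements `curve_a`,
#'   `curve_b`, `e_min`, logical `equal_e_max`, and `partial`
#'   (`"a"`, `"b"` or `NA` when the maximal effects are equal).
#' @export
curve_pair <- function(curve_a, curve_b, tol = 1e-9) {
  stopifnot(inherits(curve_a, "hill_curve"), inherits(curve_b, "hill_curve"))
  base_scale <- max(1, abs(curve_a$e_min), abs(curve_b$e_min))
  if (abs(curve_a$e_min - curve_b$e_min) > tol * base_scale) {
    stop("the two curves must share the same baseline e_min")
  }
  emax_scale <- max(abs(curve_a$e_max), abs(curve_b$e_max))
  equal_e_max <- abs(curve_a$e_max - curve_b$e_max) <= tol * emax_scale
  partial <- if (equal_e_max) {
    NA_character_
  } else if (curve_a$e_max < curve_b$e_max) "a" else "b"
  structure(
    list(
      curve_a = curve_a, curve_b = curve_b,
      e_min = curve_a$e_min,
      equal_e_max = equal_e_max,
      partial = partial
    ),
    class = "curve_pair"
  )
}

#' @export
print.curve_pair <- function(x, ...) {
  cat("Curve pair\n  A: ")
  print(x$curve_a)
  cat("  B: ")
  print(x$curve_b)
  if (x$equal_e_max) {
    cat("  equal maximal effects (no partial agent)\n")
  } else {
    cat(sprintf("  partial agent: %s\n", toupper(x$partial)))
  }
  invisible(x)
}

#' Swap the two curves of a pair
#'
#' Convenience for commutativity checks and for orienting the pair so
#' that a chosen drug plays the role of A.
#'
#' @param pair A [curve_pair()].
#' @return The pair with curves A and B exchanged.
#' @export
swap_pair <- function(pair) {
  stopifnot(inherits(pair, "curve_pair"))
  curve_pair(pair$curve_b, pair$curve_a)
}

#' Normalise a curve pair to the unit effect scale
#'
#' Affinely rescales effects so that the shared baseline maps to 0 and
#' the larger of the two maximal effects maps to 1. The Bliss model
#' requires this normalisation; the dose-effect based models (Loewe,
#' Tallarida, Hand) do not, so the transformation is offered as explicit
#' preprocessing rather than applied silently.
#'
#' @param pair A [curve_pair()].
#' @return A normalised `curve_pair`.
#' @export
normalise_pair <- function(pair) {
  stopifnot(inherits(pair, "curve_pair"))
  span <- max(pair$curve_a$e_max, pair$curve_b$e_max) - pair$e_min
  resc <- function(crv) {
    hill_curve(
      (crv$e_min - pair$e_min) / span,
      (crv$e_max - pair$e_min) / span,
      crv$ec50, crv$n
    )
  }
  curve_pair(resc(pair$curve_a), resc(pair$curve_b))
}

# TRUE when the pair is already on the unit scale expected by Bliss.
is_unit_scale <- function(pair, tol = 1e-9) {
  abs(pair$e_min) <= tol &&
    abs(max(pair$curve_a$e_max, pair$curve_b$e_max) - 1) <= tol
}
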