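# Structured conditions: undefined regions of a null model are scientific
# content (they delimit where a model applies), so they carry data and a
# dedicated class rather than being plain errors.

stop_combonull <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "combonull_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

#' @noRd
stop_effect_below_range <- function(x, e_min) {
  stop_combonull(
    "combonull_effect_below_range",
    sprintf("effect %g is at or below the baseline e_min = %g", x, e_min),
    x = x, bound = e_min
  )
}

#' @noRd
stop_effect_above_range <- function(x, e_max) {
  stop_combonull(
    "combonull_effect_above_range",
    sprintf(
      "effect %g is at or above the maximal effect e_max = %g (partial-agent regime)",
      x, e_max
    ),
    x = x, bound = e_max
  )
}

#' @noRd
stop_loewe_undefined <- function(limit) {
  stop_combonull(
    "combonull_loewe_undefined",
    sprintf(
      "Loewe reference undefined: required effect reaches the limiting level %g (min of the two maximal effects)",
      limit
    ),
    limit = limit
  )
}

#' @noRd
stop_equivalent_dose_undefined <- function(which_curve, x, e_max) {
  stop_combonull(
    "combonull_equivalent_dose_undefined",
    sprintf(
      "Tallarida equivalent dose undefined: effect %g is not attained by curve %s (e_max = %g)",
      x, which_curve, e_max
    ),
    which_curve = which_curve, x = x, bound = e_max
  )
}
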