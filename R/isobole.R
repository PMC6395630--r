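# Isobole extraction and convexity diagnostics.
#
# An isobole is the level set of a reference surface at effect x,
# projected onto the (dose A, dose B) plane. Every surface here is
# non-decreasing along rays of fixed mixture ratio, so the level set is
# found robustly by one bracketed root search per ray angle, rather than
# by contouring the gridded surface.

# Mixture dose c at which the Hand surface reaches level x along the
# ray with ratio lambda; closed form beyond the partial agent's
# saturation, integral inversion (exact inverse) below it.
hand_ray_dose <- function(pair, lambda, x) {
  if (lambda == 1) return(hill_inverse(pair$curve_a, x))
  if (lambda == 0) return(hill_inverse(pair$curve_b, x))
  if (!pair$equal_e_max) {
    e_max_p <- min(pair$curve_a$e_max, pair$curve_b$e_max)
    if (x >= e_max_p) {
      full <- if (pair$partial == "a") pair$curve_b else pair$curve_a
      wf <- if (pair$partial == "a") 1 - lambda else lambda
      cs <- c_star_weighted(pair, lambda)
      extra <- (hill_inverse(full, x) - hill_inverse(full, e_max_p)) / wf
      return(cs + extra)
    }
  }
  hand_inverse(pair, lambda, x)
}

#' Extract an isobole from a null-model surface
#'
#' Computes the level set of the surface at effect `x` by solving
#' `E(lambda * c, (1 - lambda) * c) = x` for the mixture dose `c` on each
#' of `resolution` ray angles. Vertices are ordered from the pure-A ray
#' (`lambda = 1`) to the pure-B ray, so dose-A coordinates decrease and
#' dose-B coordinates increase along the polyline. Rays on which the
#' model is undefined (Loewe beyond the partial agent's range, a
#' saturating Tallarida conversion) or the level is unreachable are kept
#' with a non-`"ok"` status, so truncation by the model's domain is
#' visible rather than silently dropped.
#'
#' @param surface A [null_surface()].
#' @param x Effect level strictly between the baseline and the surface's
#'   attainable supremum.
#' @param resolution Number of ray angles.
#' @return An object of class `isobole`: data frame `vertices` with
#'   columns `lambda`, `a`, `b`, `status`, plus fields `model`, `level`
#'   and overall `status` (`"closed"` if every ray produced a vertex,
#'   `"truncated"` otherwise).
#' @export
compute_isobole <- function(surface, x, resolution = 50) {
  stopifnot(inherits(surface, "null_surface"),
            is.numeric(x), length(x) == 1L, is.finite(x),
            resolution >= 2)
  pair <- surface$pair
  if (x <= pair$e_min) stop_effect_below_range(x, pair$e_min)
  lambdas <- seq(1, 0, length.out = resolution)
  scale0 <- (pair$curve_a$ec50 + pair$curve_b$ec50) / 2

  one_ray <- function(lambda) {
    solve_ray(surface, lambda, x, scale0)
  }
  res <- lapply(lambdas, one_ray)
  cc <- vapply(res, `[[`, numeric(1), "c")
  status <- vapply(res, `[[`, character(1), "status")
  vertices <- data.frame(
    lambda = lambdas,
    a = lambdas * cc,
    b = (1 - lambdas) * cc,
    status = status
  )
  if (!any(status == "ok")) {
    stop_combonull(
      "combonull_empty_isobole",
      sprintf("effect level %g is unreachable on every ray", x)
    )
  }
  structure(
    list(vertices = vertices, model = surface$model, level = x,
         status = if (all(status == "ok")) "closed" else "truncated"),
    class = "isobole"
  )
}

# Root search for one ray; returns list(c, status).
solve_ray <- function(surface, lambda, x, scale0) {
  pair <- surface$pair
  # closed-form rays where available
  if (surface$model == "loewe") {
    x_lim <- min(pair$curve_a$e_max, pair$curve_b$e_max)
    if (x >= x_lim) {
      return(list(c = NaN, status = "undefined"))
    }
    inv_a <- hill_inverse(pair$curve_a, x)
    inv_b <- hill_inverse(pair$curve_b, x)
    if (lambda == 1) return(list(c = inv_a, status = "ok"))
    if (lambda == 0) return(list(c = inv_b, status = "ok"))
    return(list(c = 1 / (lambda / inv_a + (1 - lambda) / inv_b),
                status = "ok"))
  }
  if (surface$model == "hand") {
    sup <- attainable_sup(pair, lambda)
    if (x >= sup) return(list(c = NaN, status = "unreachable"))
    return(list(c = hand_ray_dose(pair, lambda, x), status = "ok"))
  }
  # generic monotone bracketing along the ray
  eval_ray <- function(cc) surface_effect(surface, lambda * cc, (1 - lambda) * cc)
  g <- function(cc) eval_ray(cc) - x
  res <- tryCatch({
    hi <- scale0
    g_hi <- g(hi)
    tries <- 0
    while (g_hi < 0 && tries < 60) {
      hi <- hi * 2
      g_hi <- g(hi)
      tries <- tries + 1
    }
    if (g_hi < 0) {
      list(c = NaN, status = "unreachable")
    } else {
      root <- stats::uniroot(g, lower = 0, upper = hi,
                             f.lower = pair$e_min - x, f.upper = g_hi,
                             tol = 1e-11 * hi)
      list(c = root$root, status = "ok")
    }
  },
  combonull_error = function(cnd) list(c = NaN, status = "undefined"))
  res
}

#' @export
print.isobole <- function(x, ...) {
  ok <- sum(x$vertices$status == "ok")
  cat(sprintf("Isobole of %s at effect %g: %d/%d vertices (%s)\n",
              x$model, x$level, ok, nrow(x$vertices), x$status))
  invisible(x)
}

#' Convexity diagnostic for an isobole
#'
#' Treats the isobole as `b` as a function of `a` and inspects the
#' discrete second differences (successive slope changes) of the vertex
#' polyline. Convex isoboles — a proved property of the Hand model, and
#' exactly zero curvature for Loewe's straight isoboles — have all
#' second differences non-negative up to a tolerance. Truncated isoboles
#' are analysed on their defined vertices.
#'
#' @param isobole An [compute_isobole()] result with at least 3 defined
#'   vertices.
#' @param tol Negative slack allowed before declaring non-convexity,
#'   interpreted relative to the isobole's dose scale.
#' @return A list with `min_second_diff`, `convex` (logical),
#'   `n_vertices`, `tol_used`.
#' @export
convexity_diagnostic <- function(isobole, tol = 1e-7) {
  stopifnot(inherits(isobole, "isobole"))
  v <- isobole$vertices[isobole$vertices$status == "ok", ]
  if (nrow(v) < 3) stop("need at least 3 defined vertices")
  v <- v[order(v$a), ]
  slopes <- diff(v$b) / diff(v$a)
  second <- diff(slopes)
  scale <- max(abs(v$b), abs(v$a))
  tol_used <- tol * scale
  list(
    min_second_diff = min(second),
    convex = all(second >= -tol_used),
    n_vertices = nrow(v),
    tol_used = tol_used
  )
}
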