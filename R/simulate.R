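# Synthetic monotherapy and checkerboard data with known ground truth.
#
# The generator emulates the dosing design of large combination screens:
# each combination measured on a small factorial checkerboard (4 x 4 by
# default) plus EC50-anchored monotherapy titrations, with additive
# Gaussian readout noise. A chosen null model provides the zero-
# interaction ground truth; an optional interaction factor perturbs it
# so classifiers can be exercised against known synergy/antagonism.

#' Specification of a synthetic combination screen
#'
#' @param pair A [curve_pair()]: the ground-truth monotherapy curves.
#' @param model Name of the ground-truth null model (see
#'   [null_surface()]); defaults to `"loewe_hsa"` so every grid cell has
#'   a defined reference.
#' @param dose_a,dose_b Checkerboard dose grids; default 4 doses per
#'   drug, log-spaced around each EC50 (`ec50 * 2^(-2..1)`).
#' @param kappa Interaction factor: `1` means no interaction.
#' @param interaction `"multiplicative"` (measured expectation
#'   `kappa * reference`, clipped to the attainable effect range) or
#'   `"additive"` (`reference + (kappa - 1)`, clipped likewise).
#' @param noise_sd Gaussian noise standard deviation in effect units.
#' @param replicates Replicates per checkerboard cell.
#' @param seed Seed making the generated tables fully reproducible.
#' @return An object of class `screen_spec`.
#' @export
screen_spec <- function(pair, model = "loewe_hsa",
                        dose_a = NULL, dose_b = NULL,
                        kappa = 1,
                        interaction = c("multiplicative", "additive"),
                        noise_sd = 0.02, replicates = 1, seed = 1) {
  stopifnot(inherits(pair, "curve_pair"))
  interaction <- match.arg(interaction)
  model <- match.arg(model, MODEL_NAMES)
  if (is.null(dose_a)) dose_a <- pair$curve_a$ec50 * 2^(-2:1)
  if (is.null(dose_b)) dose_b <- pair$curve_b$ec50 * 2^(-2:1)
  stopifnot(all(dose_a > 0), all(dose_b > 0), kappa > 0, noise_sd >= 0,
            replicates >= 1)
  structure(
    list(pair = pair, model = model,
         dose_a = sort(dose_a), dose_b = sort(dose_b),
         kappa = kappa, interaction = interaction,
         noise_sd = noise_sd, replicates = as.integer(replicates),
         seed = seed),
    class = "screen_spec"
  )
}

#' Generate a synthetic monotherapy table
#'
#' Effects are the Hill-curve values plus additive Gaussian noise,
#' reproducible under `seed`.
#'
#' @param curve A [hill_curve()].
#' @param doses Dose vector; default EC50-anchored log-spaced titration
#'   `ec50 * 2^(-3..3)`.
#' @param replicates Replicates per dose.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Seed (or `NULL` to use the current RNG stream).
#' @return Data frame with columns `dose`, `effect`, `replicate`.
#' @export
generate_monotherapy <- function(curve, doses = NULL, replicates = 3,
                                 noise_sd = 0.02, seed = 1) {
  stopifnot(inherits(curve, "hill_curve"))
  if (is.null(doses)) doses <- curve$ec50 * 2^(-3:3)
  stopifnot(all(doses >= 0), noise_sd >= 0, replicates >= 1)
  tab <- expand.grid(dose = doses, replicate = seq_len(replicates),
                     KEEP.OUT.ATTRS = FALSE)
  truth <- hill_eval(curve, tab$dose)
  noise <- with_local_seed(seed, stats::rnorm(nrow(tab), 0, noise_sd))
  tab$effect <- truth + noise
  tab[c("dose", "effect", "replicate")]
}

#' Generate a synthetic combination checkerboard
#'
#' Evaluates the ground-truth null model on the checkerboard grid,
#' applies the interaction perturbation, clips to the attainable effect
#' range, and adds Gaussian noise. Cells where the ground-truth model is
#' undefined are emitted with `NA` effect and a non-`"ok"` status
#' rather than fabricated.
#'
#' @param spec A [screen_spec()].
#' @return A list of class `checkerboard_sim`: `checkerboard` (data
#'   frame `dose_a`, `dose_b`, `effect`, `replicate`, `status`),
#'   `reference` (the unperturbed reference per cell) and `truth`
#'   (generating model, `kappa`, `noise_sd`, `seed`).
#' @export
generate_checkerboard <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  pair <- spec$pair
  surf <- null_surface(spec$model, pair,
                       bliss_normalise = !is_unit_scale(pair))
  grid <- evaluate_surface(surf, spec$dose_a, spec$dose_b)
  cells <- expand.grid(dose_a = spec$dose_a, dose_b = spec$dose_b,
                       KEEP.OUT.ATTRS = FALSE)
  ref <- as.vector(grid$effect)
  status <- as.vector(grid$status)

  e_lo <- pair$e_min
  e_hi <- max(pair$curve_a$e_max, pair$curve_b$e_max)
  expected <- switch(spec$interaction,
    multiplicative = spec$kappa * ref,
    additive = ref + (spec$kappa - 1)
  )
  expected <- pmin(pmax(expected, e_lo), e_hi)

  tab <- do.call(rbind, lapply(seq_len(spec$replicates), function(r) {
    data.frame(cells, expected = expected, replicate = r, status = status)
  }))
  noise <- with_local_seed(spec$seed,
                           stats::rnorm(nrow(tab), 0, spec$noise_sd))
  tab$effect <- ifelse(tab$status == "ok", tab$expected + noise, NA_real_)
  checkerboard <- tab[c("dose_a", "dose_b", "effect", "replicate", "status")]
  structure(
    list(
      checkerboard = checkerboard,
      reference = data.frame(cells, reference = ref, status = status),
      truth = list(model = spec$model, kappa = spec$kappa,
                   interaction = spec$interaction,
                   noise_sd = spec$noise_sd, seed = spec$seed)
    ),
    class = "checkerboard_sim"
  )
}
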