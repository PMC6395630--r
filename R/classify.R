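# Synergy/antagonism classification and cross-model comparison.

#' Classify measured dose pairs against null-model references
#'
#' For each measured dose pair and each reference surface, compares the
#' measured effect with the model's reference effect: synergistic if it
#' exceeds the reference by more than the additive band half-width
#' `delta`, antagonistic if it falls short by more than `delta`,
#' additive within the band. `delta = 0` reproduces the strict
#' synergistic/antagonistic dichotomy. Where a model's reference is
#' undefined the verdict is `"undefined"`, never dropped: with different
#' models the same measured point can legitimately receive opposite
#' verdicts, which is the heart of the model-choice problem.
#'
#' @param measured Data frame with columns `dose_a`, `dose_b`, `effect`
#'   (a `replicate` column is carried through if present).
#' @param surfaces A list of [null_surface()] objects (named or not; the
#'   model name is taken from each surface).
#' @param delta Additive band half-width in effect units.
#' @return A data frame of class `synergy_calls` with one row per
#'   (dose pair, model): `dose_a`, `dose_b`, `effect`, `model`,
#'   `reference`, `status`, `verdict`, `delta`.
#' @export
classify_synergy <- function(measured, surfaces, delta = 0.01) {
  stopifnot(is.data.frame(measured),
            all(c("dose_a", "dose_b", "effect") %in% names(measured)),
            is.list(surfaces), length(surfaces) >= 1,
            is.numeric(delta), delta >= 0)
  for (s in surfaces) stopifnot(inherits(s, "null_surface"))

  rows <- vector("list", nrow(measured) * length(surfaces))
  k <- 0L
  for (i in seq_len(nrow(measured))) {
    a <- measured$dose_a[i]
    b <- measured$dose_b[i]
    eff <- measured$effect[i]
    for (s in surfaces) {
      ref <- tryCatch(
        surface_effect(s, a, b),
        combonull_error = function(cnd) NaN
      )
      status <- if (is.nan(ref)) "undefined" else "ok"
      verdict <- if (status != "ok") {
        "undefined"
      } else if (eff > ref + delta) {
        "synergistic"
      } else if (eff < ref - delta) {
        "antagonistic"
      } else {
        "additive"
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        dose_a = a, dose_b = b, effect = eff,
        model = s$model, reference = ref,
        status = status, verdict = verdict, delta = delta
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("synergy_calls", class(out))
  out
}

#' Compare null-model reference surfaces on a shared dose grid
#'
#' Evaluates every surface on the Cartesian grid `dose_a x dose_b` and
#' summarises pairwise: signed differences (row model minus column
#' model: mean, median, quartiles, fraction positive) and Spearman rank
#' correlations, each computed over the cells where both models are
#' defined (excluded cells are counted). On top of visual scatter
#' comparisons this makes the systematic orderings between models —
#' HSA below everything, Loewe below Hand, the Tallarida envelope —
#' checkable at a glance.
#'
#' @param surfaces A list of [null_surface()] objects sharing one curve
#'   pair.
#' @param dose_a,dose_b Ascending non-negative dose grids.
#' @return An object of class `model_comparison`: `long` (data frame
#'   `dose_a`, `dose_b`, `model`, `reference`, `status`), `differences`
#'   (data frame per ordered model pair), `correlations` (Spearman
#'   matrix with unit diagonal).
#' @export
compare_models <- function(surfaces, dose_a, dose_b) {
  stopifnot(is.list(surfaces), length(surfaces) >= 2)
  models <- vapply(surfaces, function(s) s$model, character(1))
  if (anyDuplicated(models)) stop("each model may appear only once")

  grids <- lapply(surfaces, evaluate_surface, dose_a = dose_a,
                  dose_b = dose_b)
  cells <- expand.grid(dose_a = dose_a, dose_b = dose_b,
                       KEEP.OUT.ATTRS = FALSE)
  long <- do.call(rbind, lapply(seq_along(surfaces), function(i) {
    data.frame(
      cells,
      model = models[i],
      reference = as.vector(grids[[i]]$effect),
      status = as.vector(grids[[i]]$status)
    )
  }))

  nm <- length(models)
  cors <- matrix(NA_real_, nm, nm, dimnames = list(models, models))
  diag(cors) <- 1
  diffs <- list()
  for (i in seq_len(nm)) {
    for (j in seq_len(nm)) {
      if (i == j) next
      xi <- as.vector(grids[[i]]$effect)
      xj <- as.vector(grids[[j]]$effect)
      ok <- !is.nan(xi) & !is.nan(xj)
      d <- xi[ok] - xj[ok]
      if (i < j) {
        cors[i, j] <- cors[j, i] <- if (sum(ok) >= 3) {
          stats::cor(xi[ok], xj[ok], method = "spearman")
        } else NA_real_
      }
      diffs[[paste(models[i], models[j], sep = "-")]] <- data.frame(
        model_1 = models[i], model_2 = models[j],
        n_cells = sum(ok), n_excluded = sum(!ok),
        mean = mean(d), median = stats::median(d),
        q25 = unname(stats::quantile(d, 0.25)),
        q75 = unname(stats::quantile(d, 0.75)),
        frac_positive = mean(d > 0),
        frac_nonneg = mean(d >= -1e-9)
      )
    }
  }
  structure(
    list(long = long, differences = do.call(rbind, c(diffs, make.row.names = FALSE)),
         correlations = cors),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison across", nrow(x$correlations), "null models\n")
  cat("Spearman correlations:\n")
  print(round(x$correlations, 3))
  invisible(x)
}
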