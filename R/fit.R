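# Hill-curve fitting and BIC-based monotherapy model selection.

# Run code with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

validate_monotherapy <- function(table) {
  stopifnot(is.data.frame(table))
  if (!all(c("dose", "effect") %in% names(table))) {
    stop("monotherapy table needs columns 'dose' and 'effect'")
  }
  if (!all(is.finite(table$dose)) || any(table$dose < 0)) {
    stop("doses must be finite and non-negative")
  }
  if (!all(is.finite(table$effect))) stop("effects must be finite")
  invisible(table)
}

#' Fit a Hill curve to monotherapy data
#'
#' Least-squares fit of the four-parameter Hill curve under a Gaussian
#' noise assumption. Because Hill objective surfaces are multi-modal,
#' the optimiser is restarted from `n_starts` latin-hypercube initial
#' points (seeded, hence deterministic); `ec50` and `n` are
#' log-transformed internally to enforce positivity.
#'
#' @param table Data frame with columns `dose` and `effect` (a
#'   `replicate` column is allowed and ignored by the fit).
#' @param n_starts Number of multi-start initial points.
#' @param seed Seed for the start design (fits are deterministic given
#'   it).
#' @return An object of class `hill_fit`: `curve` (the [hill_curve()]
#'   estimate), `rss`, `sigma2` (MLE noise variance), `loglik`, `n_obs`,
#'   and `converged` (`FALSE` flags optimiser non-convergence of the
#'   best start, reported rather than silenced).
#' @export
fit_hill <- function(table, n_starts = 10, seed = 1) {
  validate_monotherapy(table)
  dose <- table$dose
  eff <- table$effect
  m <- length(dose)
  if (length(unique(dose)) < 4) {
    stop("under-determined: need at least 4 distinct doses for 4 Hill parameters")
  }

  rss_fn <- function(theta) {
    crv <- list(
      e_min = theta[1], e_max = theta[1] + exp(theta[2]),
      ec50 = exp(theta[3]), n = exp(theta[4])
    )
    class(crv) <- "hill_curve"
    sum((hill_eval(crv, dose) - eff)^2)
  }

  span <- max(diff(range(eff)), 1e-3)
  pos_dose <- dose[dose > 0]
  log_d_lo <- log(min(pos_dose))
  log_d_hi <- log(max(pos_dose))

  design <- with_local_seed(seed, lhs::randomLHS(n_starts, 4))
  best <- NULL
  for (k in seq_len(n_starts)) {
    u <- design[k, ]
    theta0 <- c(
      min(eff) + (u[1] - 0.25) * 0.4 * span,
      log(span * (0.5 + 1.5 * u[2])),
      log_d_lo + u[3] * (log_d_hi - log_d_lo),
      log(0.3) + u[4] * (log(5) - log(0.3))
    )
    opt <- tryCatch(
      stats::optim(theta0, rss_fn, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimiser starts failed")
  # Levenberg-Marquardt polish of the winning start
  resid_fn <- function(theta) {
    crv <- list(
      e_min = theta[1], e_max = theta[1] + exp(theta[2]),
      ec50 = exp(theta[3]), n = exp(theta[4])
    )
    class(crv) <- "hill_curve"
    hill_eval(crv, dose) - eff
  }
  lm <- tryCatch(
    minpack.lm::nls.lm(best$par, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL
  )
  if (!is.null(lm) && sum(lm$fvec^2) <= best$value) {
    best <- list(par = lm$par, value = sum(lm$fvec^2),
                 convergence = if (lm$info %in% 1:4) 0L else 1L)
  }

  theta <- best$par
  curve <- hill_curve(theta[1], theta[1] + exp(theta[2]),
                      exp(theta[3]), exp(theta[4]))
  rss <- best$value
  sigma2 <- max(rss / m, .Machine$double.xmin)
  loglik <- -m / 2 * (log(2 * pi * sigma2) + 1)
  structure(
    list(curve = curve, rss = rss, sigma2 = sigma2, loglik = loglik,
         n_obs = m, converged = best$convergence == 0L),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  print(x$curve)
  cat(sprintf("  RSS = %.4g, logLik = %.4g, n = %d%s\n",
              x$rss, x$loglik, x$n_obs,
              if (x$converged) "" else " [optimiser did not converge]"))
  invisible(x)
}

#' Fit the zero-effect (flat) model
#'
#' Gaussian maximum-likelihood fit of a constant effect level, the
#' parsimonious alternative for drugs without dose response.
#'
#' @inheritParams fit_hill
#' @return A list of class `zero_fit` with `curve`
#'   ([zero_effect_curve()]), `rss`, `sigma2`, `loglik`, `n_obs`.
#' @export
fit_zero_effect <- function(table) {
  validate_monotherapy(table)
  eff <- table$effect
  m <- length(eff)
  mu <- mean(eff)
  rss <- sum((eff - mu)^2)
  sigma2 <- max(rss / m, .Machine$double.xmin)
  loglik <- -m / 2 * (log(2 * pi * sigma2) + 1)
  structure(
    list(curve = zero_effect_curve(mu), rss = rss, sigma2 = sigma2,
         loglik = loglik, n_obs = m),
    class = "zero_fit"
  )
}

#' BIC-based monotherapy model selection
#'
#' Fits both the Hill curve and the zero-effect model and selects the one
#' with lower Bayesian Information Criterion, `BIC = k log(m) - 2 logL`.
#' Both models are charged for their estimated noise variance (k = 5 for
#' Hill: four mean parameters plus noise; k = 2 for zero-effect), keeping
#' the comparison symmetric. Ties break toward the zero-effect model
#' (parsimony).
#'
#' @inheritParams fit_hill
#' @return A list with `selected` (`"hill"` or `"zero_effect"`),
#'   `bic_hill`, `bic_zero`, `hill_fit`, `zero_fit`.
#' @export
select_monotherapy_model <- function(table, n_starts = 10, seed = 1) {
  hf <- fit_hill(table, n_starts = n_starts, seed = seed)
  zf <- fit_zero_effect(table)
  m <- hf$n_obs
  bic_hill <- 5 * log(m) - 2 * hf$loglik
  bic_zero <- 2 * log(m) - 2 * zf$loglik
  list(
    selected = if (bic_hill < bic_zero) "hill" else "zero_effect",
    bic_hill = bic_hill, bic_zero = bic_zero,
    hill_fit = hf, zero_fit = zf
  )
}
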