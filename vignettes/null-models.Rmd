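---
title: "Null models for two-drug combinations: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models for two-drug combinations: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combonull)
```

## The problem

A combination experiment measures the effect of dose pairs $(a, b)$ of two
drugs A and B. Whether a measured effect counts as *synergistic* or
*antagonistic* is always relative to a **null model**: a reference surface
$E(a, b)$ that extrapolates the two monotherapy dose-effect curves to the
whole dose plane under an assumption of zero interaction. Different null
models encode different additivity concepts and can give opposite verdicts
for the same measurement, so the choice of model is part of the scientific
claim. This package implements five of them on a common footing so that
they can be evaluated, compared and used for classification side by side.

Monotherapies are modelled as four-parameter Hill curves

$$f(a) = E_{min} + \frac{E_{max} - E_{min}}{1 + (EC_{50}/a)^{n}},$$

strictly increasing in the dose, with `hill_curve()` /
`hill_eval()` / `hill_inverse()`. The baseline $E_{min}$ is the untreated
condition and is shared by the two drugs of a pair (`curve_pair()` enforces
this); the maximal effects may differ, in which case the drug with the
lower $E_{max}$ is the *partial agent*. Decreasing readouts (e.g.
viability) are handled by the documented pre-transformation
$\text{effect} \mapsto 1 - \text{effect}$, not natively.

A note on the inverse: the closed form used throughout is the algebraic
inverse of the Hill curve,
$f^{-1}(x) = EC_{50}\,((x - E_{min})/(E_{max} - x))^{1/n}$,
which is the form consistent with the forward curve (round-trip
`hill_eval(hill_inverse(x)) = x` is tested to $10^{-9}$).

## The five models

* **Loewe** (`loewe_effect()`): postulates straight isoboles; the
  reference effect is the unique root of
  $a/f_A^{-1}(x) + b/f_B^{-1}(x) = 1$. Undefined at effect levels the
  partial agent cannot reach — dose pairs beyond the horizontal limit
  isobole $b = f_B^{-1}(E_{max,A})$ raise a structured condition.
  `loewe_hsa_effect()` extends those cells with the HSA value, continuous
  across the boundary; this mirrors how screen-scale comparisons usually
  handle the gap.
* **Tallarida** (`tallarida_effect()`): converts dose $a$ into the
  B-equivalent dose at the same effect and applies $f_B$ on top:
  $E_{T,A\to B} = f_B(b + f_B^{-1}(f_A(a)))$. The two orderings disagree
  whenever the potency ratio varies with the effect level; the pair of
  values is exposed as the envelope (`tallarida_envelope()`, LB/UB).
* **Hand** (`hand_effect()`): resolves the Tallarida ambiguity by letting
  both agents contribute *instantaneously*. On the effect-sensitivity
  scale $s(x) = f'(f^{-1}(x))$ the combined curve of the fixed-ratio
  mixture $C_\lambda$ is defined by the weighted sum
  $s_{AB,\lambda}(x) = \lambda s_A(x) + (1-\lambda) s_B(x)$, each
  sensitivity extended by zero above its curve's $E_{max}$; the reference
  is $E_H(a,b) = f_{AB,\lambda}(a+b)$ with $\lambda = a/(a+b)$.
* **Bliss** (`bliss_effect()`): probabilistic independence,
  $f_A + f_B - f_A f_B$, requiring the unit effect scale (baseline 0,
  larger $E_{max}$ equal to 1). An unnormalised pair is an error by
  default; `normalise = TRUE` rescales explicitly, because silent
  rescaling changes verdicts.
* **HSA** (`hsa_effect()`): $\max\{f_A(a), f_B(b)\}$.

Sham combinations (a drug paired with itself) are reproduced exactly by
Loewe, Tallarida and Hand ($E = f_A(a+b)$); Bliss and HSA violate the sham
principle, which the test suite demonstrates quantitatively. When the two
curves share $E_{max}$ and $n$ (constant potency ratio $\alpha$), Loewe,
Tallarida and Hand all collapse to the closed form $f_A(a + \alpha b)$ —
the central cross-model oracle in the tests. Everywhere, the proved
orderings hold: HSA $\le$ Loewe $\le$ Hand, HSA $\le$ Bliss, HSA $\le$
TallaridaLB $\le$ TallaridaUB.

## Numerics of the Hand engine

The Hand ODE $f'_{AB,\lambda}(f^{-1}_{AB,\lambda}(x)) = s_{AB,\lambda}(x)$
is degenerate at the baseline whenever $s(E_{min}) = 0$ (the initial
condition sits on an equilibrium, for Hill coefficients above 1), so the
engine works with the equivalent inverse-curve integral

$$f_{AB,\lambda}^{-1}(x) = \int_{E_{min}}^{x} \frac{dy}{\lambda s_A(y) + (1-\lambda)s_B(y)}.$$

Two numerical points matter:

1. **Endpoint behaviour.** The integrand diverges (integrably) at the
   baseline and diverges towards the attainable supremum. The integral is
   therefore evaluated after the substitution $y = g(t)$, where $g$ is a
   reference Hill curve sharing the baseline, the attainable supremum and
   the larger Hill coefficient of the pair. The transformed integrand
   $g'(t)/s(g(t))$ is bounded at both endpoints, and the divergence of
   the inverse curve at saturation becomes linear growth in $t$. Adaptive
   quadrature (`stats::integrate`, relative tolerance $10^{-10}$) then
   converges without special-casing; the kink that the zero-extension
   introduces at the partial agent's $E_{max}$ is an explicit panel
   boundary.
2. **Inversion.** Evaluating the combined curve at a mixture dose $c$
   solves $J(t) = c$ for the substituted variable by safeguarded Newton
   within a doubling bracket; the derivative $dJ/dt$ is the integrand
   itself, so Newton steps cost no extra quadrature, and all $J$
   evaluations are memoized incrementally along the search path.

For a partial agent A, the critical mixture dose
$c^*(\lambda) = f_{AB,\lambda}^{-1}(E_{max,A})$ is finite for
$\lambda < 1$ (`c_star()`); beyond it the combined curve follows the full
agent alone in the closed form
$f_B(f_B^{-1}(E_{max,A}) + (1-\lambda)(c - c^*))$, and continuity at
$c^*$ is verified from both sides. The level set at $E_{max,A}$ — the
Hand limit isobole $\lambda \mapsto (\lambda c^*, (1-\lambda)c^*)$
(`limit_isobole()`) — contrasts with Loewe's horizontal limit isobole:
its B-component decreases continuously to zero as the mixture becomes
pure partial agent.

As an independent cross-check of the same construction, the finite-$N$
alternating scheme (`tallarida_iterated()`) applies the doses in $N$
alternating portions with the equivalent-dose conversion at every step;
$N = 1$ *is* the Tallarida model and $N \to \infty$ converges to the Hand
model at first order in $1/N$, for either ordering. One empirical detail:
with a partial agent, the capped trajectory can make the *signed*
iteration error cross zero once, so the absolute error per ordering is
not strictly monotone in $N$ for a small fraction of instances; the
envelope over both orderings decays monotonically, which is what the
acceptance suite asserts (alongside monotone per-ordering decay for
equal-$E_{max}$ pairs and the final error bound).

Isoboles (`compute_isobole()`) are extracted per ray angle rather than by
contouring: every surface here is non-decreasing along rays of fixed
mixture ratio, so one bracketed root per ray is robust, and
undefined/unreachable rays are reported as vertex statuses instead of
being dropped. Loewe rays and Hand rays use their closed-form/integral
inverses directly. Convexity is diagnosed by the sign of the discrete
slope changes of $b$ as a function of $a$
(`convexity_diagnostic()`); Hand isoboles are convex (tested over random
pairs, levels and rays at tolerance $10^{-7} \cdot$ scale), which is why
the Hand reference bounds Loewe from above.

## Fitting and model selection

`fit_hill()` minimises the residual sum of squares under a Gaussian noise
assumption, with `ec50` and `n` log-transformed to enforce positivity.
Because Hill objectives are multi-modal, the optimiser (BFGS) is
restarted from 10 latin-hypercube initial points (seeded, deterministic)
and the winner is polished by Levenberg–Marquardt; non-convergence is
reported in the fit object, never silenced. `select_monotherapy_model()`
compares the Hill fit against a constant (zero-effect) fit by BIC
($k\ln m - 2\ln L$), charging both models for their noise variance
($k = 5$ vs $k = 2$) so the comparison is symmetric; ties go to the
zero-effect model. Identifiability requires at least 4 distinct doses; a
design with a vehicle control (dose 0) anchors the baseline and is what
the recovery simulations use.

## The synthetic-data generator

`generate_monotherapy()` and `generate_checkerboard()` (driven by
`screen_spec()`) produce tables with known ground truth, emulating the
design of large combination screens: a 4×4 factorial checkerboard per
combination with doses log-spaced around each drug's EC50
($EC_{50}\cdot 2^{-2..1}$), monotherapy titrations at
$EC_{50}\cdot 2^{-3..3}$, and additive Gaussian readout noise
(default sd 0.02 in effect units, a realistic plate-reader scale and the
level used by the recovery studies). The ground-truth reference comes
from a chosen null model (default `loewe_hsa`, so every cell is defined);
an interaction factor $\kappa$ perturbs it multiplicatively (or an
additive offset mode), clipped to the attainable effect range, so
classifiers can be exercised against known synergy. Seeds fix the output
bitwise, and the generator's RNG use is isolated from the caller's
stream.

What the generator deliberately does **not** emulate: plate/edge effects,
heteroscedastic or correlated noise, and real screens' dose-selection
quirks. Passing tests on synthetic screens therefore validate the
*machinery* (models, classification, recovery), not the noise robustness
of any particular laboratory pipeline.

## Classification and comparison

`classify_synergy()` compares measured effects with each model's
reference under an additive band of half-width $\delta$ (default 0.01
effect units; $\delta = 0$ gives the strict synergy/antagonism
dichotomy). Undefined references yield the verdict `"undefined"`, never
dropped rows. Because the models are systematically ordered, verdicts are
ordered too — a point antagonistic against a lower reference cannot be
synergistic against a higher one — and the suite checks this consistency.
`compare_models()` evaluates a set of surfaces on a shared grid and
summarises pairwise signed differences and Spearman rank correlations
(rank-based because the relations between models are nonlinear),
excluding and counting undefined cells.

## Problem sizes and tolerances used by the test suite

The property suites run at these scales: 1000 random curves for the
round-trip invariant; 500 random pairs × 8×8 dose grids for the
inequality chain (tolerance $10^{-6}$); 200 random instances for the
alternating-scheme convergence (final error $< 5\times 10^{-4}$ at
$N = 4096$); 100 pairs × 5 levels × 50 rays for isobole convexity; 100
seeded replicates for parameter recovery (median absolute relative error
below 10% per parameter at noise sd 0.02 with 18 points). Solver
tolerances default to $10^{-10}$ (Loewe root, quadrature) and are
surfaced where a user would reasonably tune them.

## Known limitations

* Only increasing Hill curves are supported natively; decreasing
  readouts require the $1 - \text{effect}$ pre-transformation.
* Two-drug combinations only; the ray construction would extend to more
  components but is not implemented.
* Convexity and associativity of the Hand model are verified numerically
  at the stated scales, not proved symbolically.
* No statistical significance machinery for synergy calls (the additive
  band is a deterministic buffer, not a test); no combination-index
  computation.
* With both Hill coefficients below 1 the baseline sensitivity is
  infinite; the integral route handles this (the integrand tends to
  zero), but forward-ODE cross-checks of such pairs need a small offset
  from the baseline.
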