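# combonull

Null models for two-drug combination effects.

Synergy and antagonism are always judged against a **null model**: a
reference surface `E(a, b)` that extends the two monotherapy dose-effect
curves to the dose plane under an assumption of zero interaction. The
choice of model changes verdicts — the same measured point can be
synergistic under one model and antagonistic under another — so this
package puts five established models on one footing, for researchers
analysing checkerboard combination assays and for methodologists
comparing the models themselves.

Monotherapies are four-parameter Hill curves
`f(a) = E_min + (E_max − E_min) / (1 + (EC50/a)^n)`. On top of them:

| Model | Reference effect | Notes |
|---|---|---|
| Loewe | root of `a/f_A⁻¹(x) + b/f_B⁻¹(x) = 1` | straight isoboles; undefined beyond the partial agent's range (HSA extension provided) |
| Tallarida | `f_B(b + f_B⁻¹(f_A(a)))` and the mirrored ordering | orderings disagree in general; exposed as an LB/UB envelope |
| Hand | combined curve of the mixture solving `s_AB,λ(x) = λ s_A(x) + (1−λ) s_B(x)` | sensitivities `s = f′∘f⁻¹` add with mixture weights; defined everywhere, convex isoboles |
| Bliss | `f_A + f_B − f_A·f_B` | requires effects normalised to `[0, 1]` |
| HSA | `max{f_A, f_B}` | highest single agent |

Loewe, Tallarida and Hand satisfy the sham-combination principle
(`E = f_A(a+b)` when a drug is combined with itself) and collapse to the
closed form `f_A(a + αb)` for parallel curves (constant potency ratio
α); the proved orderings HSA ≤ Loewe ≤ Hand, HSA ≤ Bliss and
HSA ≤ TallaridaLB ≤ TallaridaUB hold everywhere both sides are defined.
The package also provides Hill fitting with BIC selection against a
zero-effect model, isobole extraction with convexity diagnostics,
synergy classification, cross-model comparison summaries, and a
synthetic-screen generator with known ground truth. See the vignette
(`vignettes/null-models.Rmd`) for the models, their assumptions and all
numerical choices.

## Worked example

A full agent A and a partial agent B (`E_max` 0.8), evaluated at the
dose pair (1, 1):

```r
library(combonull)

curve_a <- hill_curve(0, 1,   ec50 = 1, n = 1)
curve_b <- hill_curve(0, 0.8, ec50 = 2, n = 2)
pair <- curve_pair(curve_a, curve_b)

models <- c("hsa", "bliss", "tallarida_lb", "tallarida_ub", "loewe", "hand")
refs <- sapply(models, function(m)
  surface_effect(null_surface(m, pair, bliss_normalise = TRUE), 1, 1))
round(refs, 4)
#>          hsa        bliss tallarida_lb tallarida_ub        loewe         hand
#>       0.5000       0.5800       0.5435       0.6099       0.5882       0.5986
```

The references span 0.50–0.61: a measured effect of 0.5 at this dose
pair would be *additive* for HSA but *antagonistic* for Loewe and Hand:

```r
calls <- classify_synergy(
  data.frame(dose_a = 1, dose_b = 1, effect = 0.5),
  lapply(c("hsa", "loewe", "hand"), null_surface, pair = pair),
  delta = 0.01)
calls[c("model", "reference", "verdict")]
#>   model reference      verdict
#> 1   hsa 0.5000000     additive
#> 2 loewe 0.5882353 antagonistic
#> 3  hand 0.5985595 antagonistic
```

Because B is partial, the Hand model has a curved limit isobole at
effect 0.8 — the more of the partial agent in the mix, the more total
dose is needed (`c_star`), with the partial agent's own contribution
never sufficient on its own:

```r
limit_isobole(pair, c(0, 0.25, 0.5, 0.75, 0.95))
#>   lambda c_star a_star b_star
#> 1   0.00    Inf 0.0000    Inf
#> 2   0.25 8.6013 2.1503 6.4510
#> 3   0.50 6.0512 3.0256 3.0256
#> 4   0.75 4.7904 3.5928 1.1976
#> 5   0.95 4.1345 3.9278 0.2067
```

A command-line front end for gridded reference surfaces, synergy calls
on checkerboard CSVs and synthetic-screen generation is installed at
`inst/cli/combonull` (see its header for usage).

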