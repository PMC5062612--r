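# rnselect

Selection-index machinery for breeding programs when a trait shows
genotype-by-environment interaction (GxE) of the linear reaction-norm
form

> P = mu + b x + A_int + A_sl x + E,   x ~ N(0, 1),

with genetic variance in both the intercept (level) and the slope
(environmental sensitivity) of the norm.  The package answers two
questions a breeder faces under GxE:

1. **How accurate are environment-specific (genomic) breeding values?**
   Per-environment accuracies of progeny-based and genomic evaluations
   are predicted with selection-index theory on a 13-class discretization
   of the gradient, for a reaction-norm model and for a conventional
   model that ignores GxE.
2. **Which scheme exploits GxE best?**  Sib-testing, progeny-testing and
   genomic-selection breeding schemes are compared with a pseudo-BLUP
   index (family means, parental EBV, Bulmer equilibrium,
   finite-population selection intensities) under a linear "proportional"
   breeding goal and a non-linear "resilience" goal derived from a
   diminishing-returns profit equation, Profit = 1 − exp(−0.3 P).

Genomic accuracy per environment uses the reference-population formula
r = sqrt(N h² / (N h² + M_e)).  It is aimed at quantitative geneticists
designing breeding programs for resilience (disease, heat stress,
variable water temperature, ...).

## Worked example

```r
library(rnselect)

grid <- env_grid()                      # 13 environment classes
params <- rn_params()                   # var_int 0.3, var_sl 0.05, var_e 0.7
goal <- breeding_goal(grid, "proportional")

fit <- breeding_scheme("genomic", params, grid, goal, ref_size = 5000)
fit
#> Breeding scheme: genomic (goal: proportional)
#>   accuracy r_IH: male 0.730, female 0.730
#>   response: intercept 0.5748, slope -0.0000 per generation
#>   Bulmer equilibrium after 13 iterations (var_int 0.300 -> 0.209)
```

The fit reports the accuracy of selection for the aggregate genotype
(0.73 for both sexes here: genomic values carry the same information for
males and females), the per-generation response in the reaction-norm
intercept, and the response in slope — zero for this symmetric goal, as
selection has no incentive to change environmental sensitivity.  The
Bulmer line shows how much intercept variance truncation selection has
eroded at equilibrium.  `summary(fit)` adds per-environment responses
and accuracies, `coef(fit)` the intercept/slope responses,
`plot(fit)` the response profile, and `simulate(fit, ...)` draws seeded
Monte-Carlo populations to check predictions against realized responses.

Comparing schemes under the resilience goal:

```r
scheme_comparison_table(h2 = 0.3, ref_size = 5000)
#>   comparison  h2 ref_size      low   middle     high intercept     slope
#> 1     GS/sib 0.3     5000 1.609058 1.375916 1.175465  1.375916 -1.483146
#> 2 GS/progeny 0.3     5000 1.440483 1.307406 1.179195  1.307406 -5.706982
```

Genomic selection beats sib testing by 61% in the worst environment and
18% in the best; the negative slope ratios say that only genomic
selection *decreases* environmental sensitivity while the traditional
schemes increase it.

A thin CLI over the same functions lives at `inst/cli/rnselect.R`
(subcommands `table1`, `accuracy`, `response`, `compare`, `oracle`).

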