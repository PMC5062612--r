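---
title: "Selection index theory for reaction-norm GxE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection index theory for reaction-norm GxE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnselect)
```

## The model

A single sex-limited trait (think milk yield or litter size) is recorded
once per animal along a continuous environmental gradient $x$, taken to be
a standardized contemporary-group effect, $x \sim N(0,1)$.  Genotype by
environment interaction is generated by a linear reaction norm:

$$P = \mu + b x + A_{int} + A_{sl}\,x + E,$$

where $A_{int}$ and $A_{sl}$ are additive-genetic intercept and slope
(environmental sensitivity) with variances $\sigma^2_{A_{int}}$,
$\sigma^2_{A_{sl}}$ and covariance $\sigma_{A_{int},A_{sl}}$, and the
residual variance is constant across environments.  The genetic variance
in environment $x$ is therefore quadratic in $x$, heritability changes
along the gradient, and performances in two environments are genetically
correlated by less than one whenever $\sigma^2_{A_{sl}} > 0$ — the raw
material for breeding more resilient animals.

Because a linear reaction norm is equivalent to a multivariate trait
observed at a grid of environments, all predictions are done on a
discretized gradient: 11 equal-width classes between $-2$ and $2$ plus the
two tails (13 classes).  Class masses are normal-interval probabilities
and class values are conditional (truncated-normal) means, computed
analytically — $\phi$-differences over $\Phi$-differences, the inverse
Mills ratio in the tails — so the discretization is exact to machine
precision rather than by quadrature.  Animal counts allocated to classes
are deliberately kept real-valued; rounding is a display concern.

```{r}
g <- env_grid()
head(gradient_table(), 3)
```

## Breeding goals

The aggregate genotype is $H = \sum_i v_i A_i$ over environment classes.
Two goals are built in:

* **proportional** — $v_i$ equals the class frequency: improve the trait
  wherever animals actually are (a linear profit equation);
* **resilience** — $v_i$ is the derivative of the diminishing-returns
  profit equation $1 - e^{-0.3 P}$ at the class mean, so poor environments
  carry roughly four times the weight of the best ones.  Maximum profit
  is gained by lifting performance where it is low, i.e. by lowering
  environmental sensitivity.

The per-class goal has an exact intercept/slope representation
($v_{int} = \sum v_i$, $v_{sl} = \sum v_i \bar x_i$), exposed by
`goal_components()`.

## Index machinery

All predictions use classic selection-index algebra: for information
sources with covariance matrix $P$ and source-by-goal covariances $G$,
weights are $b = P^{-1} G v$, and the accuracy of the index for the
breeding value in class $i$ is $b'g_i / (\sigma_I \sigma_{A_i})$.  Three
kinds of sources are implemented:

* per-environment means of half sibs or of progeny (group-size-dependent
  variances with within-group additive relationship 0.25, each group
  member from a distinct dam);
* per-environment genomic breeding values, scaled to unit variance, with
  accuracy $r_i = \sqrt{N_i h_i^2/(N_i h_i^2 + M_e)}$ from the class's
  share of the reference population, and between-class correlations
  attenuated by $r_i r_j$;
* parental estimated breeding values, handled through the matrix
  $B = G' P^{-1} G$ of the parent's own index, which is simultaneously
  the covariance matrix of the parent's EBV across environments and
  their covariance with the parent's true breeding values.

A *conventional* evaluation that ignores GxE is modeled by pooling the
progeny means into one weighted source, or by combining the genomic
values with weights computed under the no-GxE assumption.  In both cases
the reported per-environment accuracy is the *realized* accuracy of those
weights under the true reaction-norm covariances; it factorizes exactly
into the intercept accuracy times the genetic correlation with the
average environment when intercept and slope are uncorrelated.  We chose
the realized evaluation (rather than the naive model-internal one)
because the naive variant can report accuracies above the truth for a
misspecified model, which is not an accuracy at all.

## Breeding schemes and the Bulmer equilibrium

`breeding_scheme()` evaluates three designs with both sexes selected
(5% of males, 20% of females, from a nucleus of 2000 candidates):

* **sib testing** — 100 commercial half sibs spread across environments,
  a full-sib mean in the nucleus environment (the best class,
  $x = 2.37$), own performance for females, and parental EBV in the best
  and worst environment plus a pooled EBV of the half sibs' dams;
* **progeny testing** — males replace half-sib means by means of their
  own 100 half-sib progeny and carry a 1.6-fold generation interval;
  females are as in sib testing;
* **genomic selection** — the 13 per-environment genomic values only.

Truncation selection builds gametic-phase disequilibrium; the package
iterates the standard infinitesimal recurrence on the $2\times2$
intercept/slope covariance,

$$C_{t+1} = \tfrac14 C^{*}_{sires} + \tfrac14 C^{*}_{dams} + \tfrac12 C_0,
\qquad C^{*} = C - k\,\frac{c\,c'}{\sigma_I^2},$$

to its fixed point.  Two features matter for fidelity and were design
choices:

1. **Path-aware covariances.**  Relatives' covariances are not taken as
   relationship coefficients times one equilibrium variance: they are
   decomposed into selected-sire, selected-dam and Mendelian-sampling
   paths.  A candidate's half sibs carry the *selected* sire's (strongly
   reduced) variance, so schemes with highly accurate male selection
   erode the value of sib information for the other sex.  This is what
   separates the two sexes' accuracies in a progeny-testing scheme, and
   a uniform-equilibrium variant we tried first could not reproduce that
   separation.
2. **Parental EBV under selection.**  Second moments of a selected
   parent's EBV follow from the same reduction applied to the parent's
   $B$ matrix; parental accuracies are those of the previous generation's
   index, so the generation fixed point and the Bulmer fixed point are
   iterated together.

Genomic accuracies $r_i$ are computed from *base-generation*
heritabilities — the reference population is commercial and is treated as
unselected — while all genetic correlations, variances and the aggregate
genotype use the equilibrium parameters.  Evaluating $r_i$ at the eroded
equilibrium heritabilities instead depresses the genomic index accuracy
noticeably and was rejected.

Selection intensities use the infinite-population value for the Bulmer
coefficient $k = i(i - z)$, and finite-population values for responses:
Burrows' correction with an effective candidate number
$n/(1 + (n-1)\bar\rho)$, where $\bar\rho$ is the mean pairwise
correlation of index values over candidate pairs.  That correlation is
computed exactly from the index weights and pair-type cross-covariance
matrices (full-sib and paternal half-sib pairs; sib-scheme candidates of
the same sire share almost all their information, genomic candidates only
their relationship-scaled genomic values).

Response per environment is
$R_e = (i_m\,b_m'g_e/\sigma_{I_m} + i_f\,b_f'g_e/\sigma_{I_f})/(L_m+L_f)$;
because the reaction norm is linear the 13 responses lie exactly on a
line, giving the intercept response (response in the average environment)
and the slope response (change in environmental sensitivity).

### Heritability scenarios

Alternative heritabilities (0.1, 0.3, 0.5 in the average environment) are
realized by scaling the whole genetic architecture against the residual:
`scenario_params(h2)` sets $\sigma^2_{A_{int}} = h^2$,
$\sigma^2_{A_{sl}} = h^2/6$ and $\sigma^2_e = 1 - h^2$.  This keeps the
genetic-correlation profile along the gradient identical across
scenarios, so "heritability" changes exactly one thing.  Keeping
$\sigma^2_{A_{sl}}$ fixed at 0.05 instead makes relative GxE explode at
low heritability and changes the sign structure of slope responses; we
tested both and the scaled architecture is the coherent reading (it is
also observationally equivalent to fixing the architecture and varying
only the residual variance).

## The simulator and what passing tests mean

`simulate_families()` draws hierarchical half-sib/full-sib families under
the exact bivariate architecture and assigns progeny to classes either
multinomially (the population-structure view) or with fixed
largest-remainder counts per sire.  The deterministic index algebra
conditions on group sizes, so its validation uses the fixed allocation
and one progeny per dam; with multinomial assignment the realized
accuracy is biased downward by $E[1/n]$ inflation and empty tail classes,
which is a statement about lumpy data, not about the algebra.  The
simulator draws no markers: genomic values enter the deterministic
machinery only through their accuracy, and the oracle therefore validates
the family-information and response machinery, not the genomic accuracy
formula itself.  Test sizes: 2000 sires with 100 progeny each for the
acceptance check (a few seconds), smaller populations in unit tests.

## Numerical choices

* Fixed-point tolerance $10^{-8}$ on the intercept/slope covariance, with
  an elementwise Aitken $\Delta^2$ step every third iteration (the
  recurrence contracts geometrically with ratio about 0.4-0.5; the
  extrapolation is accepted only when the step sizes are shrinking).
  Convergence in 7-16 iterations for all standard scenarios.
* Information sources with pairwise correlation above $1 - 10^{-8}$ are
  pruned (with a warning) before inversion — stacking EBV of many
  environments is the classic way to make $P$ singular; dropping the
  redundant source mirrors standard practice and avoids ridge terms.
* Degenerate inputs: an all-zero goal returns a zero-response fit; one
  selected proportion of 1 gives zero intensity and no Bulmer reduction;
  a single-class grid (whole real line) is supported.
* Ratios with denominators below $10^{-12}$ are reported `NA` rather than
  divided.

## Known limitations

* The slope (environmental-sensitivity) response of the traditional
  schemes is a difference of near-cancelling male- and female-path
  contributions, one to two orders of magnitude below the response level.
  Ratios of such slopes are hypersensitive: a few percent change in
  either path moves them severalfold.  Their signs are robust; their
  magnitudes should be read as order-of-magnitude statements.  For the
  same reason the slope response is not invariant to refining the
  environmental grid, while the response level changes by well under 1%.
* Parental-EBV sources follow a standard pseudo-BLUP construction; the
  exact composition used in older progeny-testing literature is not
  printed anywhere, and male progeny-testing accuracy is the quantity
  most sensitive to it.
* Single generation at equilibrium only: no inbreeding, no overlapping
  generations beyond relative generation intervals, no multi-generation
  cumulative response.
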