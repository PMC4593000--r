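---
title: "Quantitative fitness analysis: models, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative fitness analysis: models, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qfascreen)
```

## The growth model and fitness measures

A spotted culture's density is modelled by the generalized logistic
equation $dx/dt = r\,x\,(1 - (x/K)^\nu)$, whose solution from inoculation
density $x_0$ is

$$x(t) = \frac{K}{\left(1 + \left[(K/x_0)^\nu - 1\right]
  e^{-r\nu t}\right)^{1/\nu}}.$$

The parameters, with units and defaults as used throughout:

* $x_0$ — density at inoculation, in the arbitrary intensity units produced
  by colony image quantification. It is treated as a single constant shared
  by every spot on every plate of an experiment, because all cultures are
  inoculated from comparably saturated liquid cultures by the same robot.
  It is **not** fitted per curve: with only the early observations to
  constrain it, $x_0$ is barely identifiable and letting it float degrades
  the identifiability of $r$ and $\nu$. The default estimate
  ([`default_x0()`]) is the 5th percentile of first-timepoint densities
  across the whole experiment — low enough to sit below essentially every
  real inoculum, robust to the occasional spot that has already grown by
  the first photograph.
* $r$ — growth-rate parameter, per day. Bounded to $(0, 50]$ in fitting;
  healthy yeast colonies fit around $r \approx 4$–$8$/day.
* $K$ — carrying capacity, same units as $x_0$; bounded between $x_0$ and
  ten times the largest observed density of the curve.
* $\nu$ — dimensionless shape parameter; $\nu = 1$ recovers the ordinary
  logistic; bounded to $[0.1, 10]$.

Evaluation of the solution is done on the log scale
(`expm1`/`log1p`) so that extreme but legal parameter combinations (e.g.
$x_0/K = 10^{-9}$) do not overflow.

Three scalar measures summarise a fitted curve:

* **MDP** $= \log_2(K/x_0)$, the number of doublings available to the
  culture.
* **MDR** $= r\nu \,/\, \ln\!\frac{(K/x_0)^\nu - 1}{(K/2x_0)^\nu - 1}$, the
  reciprocal of the time at which the solution first reaches $2x_0$. This
  closed form follows directly from inverting the analytical solution; it
  is verified in the test suite against root finding on the solution to
  $10^{-8}$ relative accuracy, and tends to $r/\ln 2$ as $x_0/K \to 0$.
* **fitness** $=$ MDR $\times$ MDP (doublings$^2$/day), a single number
  rewarding both fast growth and large growth potential.

A culture whose fitted capacity cannot sustain one doubling
($K \le 2x_0$), or with $r = 0$, is flagged `never_doubles` and assigned
MDR $= 0$, hence fitness $0$: such spots are biologically dead or failed
and should rank at the bottom, not produce undefined values.

## Curve fitting

`fit_growth()` minimises $\sum_i (x^{obs}_i - x(t_i))^2$ on the linear
density scale with $x_0$ held fixed, using bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) from a deterministic $3\times3\times3$ grid of
starting values for $(r, K, \nu)$ ($r \in \{0.5, 3, 15\}$,
$K \in \{0.95, 1.1, 2\}\times\max x^{obs}$, $\nu \in \{0.5, 1, 2\}$), taking
the converged start with the smallest residual sum of squares. The grid
makes the fit reproducible without random restarts; linear-scale residuals
weight the (well-measured) plateau more than the noisy early points, which
suits intensity data whose absolute error grows with signal.

Degenerate inputs are handled explicitly rather than by optimizer failure:
fewer than four observations cannot constrain three free parameters and
return the degenerate fallback ($r=0$, $K=x_0$, `converged = FALSE`);
curves never exceeding $x_0$ return the dead-culture result ($K=x_0$,
$r=0$, fitness 0). If no start converges the degenerate fallback is
returned, so `converged = FALSE` always implies fallback parameters.

Noiseless self-generated curves are recovered to $10^{-4}$ relative (in
practice to machine precision). At 5% multiplicative noise with 4-hourly
imaging, the median relative error of $\hat K$ is well under 1% while
$\hat r$ sits around 4–5%: only six to eight observations lie on the
rising limb of a colony growing at $r \approx 5$/day, and $r$ trades off
against $\nu$ there. This is a property of the design (imaging interval ×
growth rate), not of the optimizer.

## Genetic interaction strength

Under Fisher's multiplicative model of genetic independence, a
non-interacting library gene's mean fitness in the query background is
proportional to its mean fitness in the control background,
$\tilde q_g = m\,\tilde c_g$. Assuming most of the library does not
interact, $m$ is the through-origin least-squares slope
$\hat m = \sum_g \tilde c_g \tilde q_g / \sum_g \tilde c_g^2$ over all
strains. There is deliberately no intercept — the model is purely
multiplicative.

Per gene, the predicted query sample is $m \times c_{g,i}$ for each
observed control replicate $i$, so the prediction inherits the control
replicate spread, and an unpaired two-tailed Welch t-test (unequal
variances, Welch–Satterthwaite degrees of freedom) compares observed and
predicted query fitnesses. Welch is a documented choice: the equal-variance
assumption is not defensible when the query background rescales fitness
and its variance. The p-values of all *testable* genes (at least two
replicates on each side) are Benjamini–Hochberg adjusted; untestable genes
are reported with `call = "none"` and `NA` p/q and are excluded from the
BH denominator, so they neither gain nor grant multiplicity.

$\mathrm{GIS}_g = \tilde q_g^{obs} - \tilde q_g^{pred}$: negative GIS means
the double mutant grew worse than the multiplicative expectation (a
negative interaction, enhancer), positive GIS better (suppressor). A
configuration switch (`sign = "pred_minus_obs"`) reports the reversed
convention; calls keep their biological meaning under either.

Genes linked to the query locus are removed before testing
(`strip_genes()`): double mutants within ~20 kb of the query mutation are
depleted after meiosis, so their apparent interactions are artefacts. The
distance is the gap between gene and query-locus intervals on the same
chromosome (1-based inclusive coordinates), inclusive at exactly 20 kb.
Explicit exclusion lists handle strains that failed the array procedure.
The slope is estimated *after* stripping by default (configurable via
`test_interactions()` directly), so linked artefacts cannot bias $\hat m$.

## Profiles and Venn classification

A gene's fitness profile is its vector of mean fitnesses across screens.
For similarity searches the profiles are z-standardized per screen (mean 0,
unit variance across genes within a screen) and compared by Euclidean
distance: screens differ widely in overall fitness scale, and without
standardization the most variable screen would dominate every distance. The
exact metric used by interactive profiling tools in this field is generally
unstated; Euclidean-on-z-scores is the simplest choice that makes screens
commensurable, and the brute-force oracle tests pin its implementation
rather than its optimality. Candidates missing a value in any included
screen are dropped from that query's ranking rather than imputed, and ties
are broken lexicographically by gene name for determinism.

`venn_classify()` assigns each gene in the union of per-screen significant
sets to exactly one area keyed by its exact membership pattern, so area
counts always sum to the union size.

## The synthetic screen generator

`simulate_screen_pair()` emulates the study design the pipeline targets:
a library of $n$ genes spotted in 384 format with 8 replicate cultures per
genotype, imaged every 4 h over 5 days, shared inoculum $x_0 = 10^{-3}$,
per-gene $(r, K, \nu)$ drawn log-normally around $r \approx 5$/day,
$K \approx 0.12$ density units and $\nu \approx 1$ (giving
MDP $\approx 7$ doublings and fitness $\approx 40$, typical of fitted
colony data), multiplicative log-normal observation noise (default
$\sigma = 0.05$, mean-one so the noise is unbiased on the density scale),
and a query background that multiplies the growth rate by
$m_{true} = 0.5$ — screens are run at temperatures chosen to reduce query
fitness to roughly half of control. Because MDR is exactly proportional to
$r$ at fixed $(x_0, K, \nu)$, scaling $r$ scales expected fitness exactly,
so the generative slope is exactly $m_{true}$. Planted interacting genes
(a configurable fraction) additionally multiply the query growth rate by
an effect drawn uniformly from $[0.1, 0.9]$ — spanning near-lethal to mild
negative interactions. Plate positions are assigned deterministically and
the whole simulation is reproducible byte-for-byte from its seed.

`simulate_fitness_screens()` is the fitness-level counterpart: it draws
per-gene fitnesses and mean-one log-normal replicate noise directly,
skipping curve simulation and fitting. It exists to calibrate the testing
stage at genome scale (thousands of genes, a hundred seeds) at desk-scale
cost; the curve-level generator exercises the identical downstream code at
smaller sizes.

What the generator does **not** emulate: spatial plate effects (edge
growth advantage, neighbour competition), the fitness dependence between
replicates pinned to the same plate, SGA mating/selection failures beyond
explicit exclusion lists, and non-multiplicative noise (e.g. image
segmentation failures producing zero or saturated spots). Passing tests
therefore demonstrate the correctness of the estimation machinery under
the declared generative model, not robustness to every artefact of real
plates — linked-gene stripping and exclusion lists are exactly the tools
the real pipeline uses against such artefacts.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle rather
than against itself: the analytical solution against numerical ODE
integration (100 random parameter sets, $10^{-6}$ relative); MDR against
root finding on the solution ($10^{-8}$); the slope against its closed
form and a dense grid minimisation; BH against a literal step-up
implementation (1000 random vectors); the Welch test against the textbook
formulas; Venn areas and nearest-profile rankings against exhaustive
enumeration on small inputs.

Statistical calibration runs at the sizes a genome-wide screen implies:
100 seeded null screens of 2000 genes × 8 replicates at 5% noise (mean
false discovery proportion at $q < 0.05$ within Benjamini–Hochberg's
guarantee plus Monte-Carlo error; $\hat m$ within 0.02 of $m_{true}$), and
20 seeded screens with 5% planted interactors (sensitivity and FDP
reported; Spearman correlation between $|\mathrm{GIS}|$ and true effect
size above 0.8). These fitness-level sizes were chosen so the whole suite
runs in a couple of minutes on one CPU; the curve-level end-to-end path is
exercised at 120–200 genes, which already fits 2000–3000 individual growth
curves.

## Known limitations

* $r$ and $\nu$ are weakly identified from sparse rising-limb data; MDR
  and fitness are much better determined than either alone, which is one
  reason fitness, not $r$, is the screen currency.
* The multiplicative model is fitted to *mean* fitnesses and assumes a
  mostly non-interacting library; a library enriched for true interactors
  would bias $\hat m$ toward their effects.
* Stripping requires locus coordinates; genes absent from the locus table
  are retained (and logged), not guessed.
* Profile search treats screens as independent axes; it does not model
  correlated measurement error between screens run on the same plates.
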