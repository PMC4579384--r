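---
title: "Threshold-character analysis of an examination registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-character analysis of an examination registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threshtrait)
```

## The model

The package analyses a binary trait — motivated by canine distichiasis in
a high-prevalence breed — as a *threshold character*: each individual
carries a latent liability $L$, standard normal in the population, and is
affected when $L$ exceeds a threshold $T$. Liability decomposes
additively, $L = A + E$ with $A \sim N(0, h^2)$ the breeding value and
$E \sim N(0, 1-h^2)$ the environmental residual, so $h^2$ is the
heritability of liability. Offspring receive the midparental breeding
value plus a Mendelian sampling deviation of variance $h^2/2$.

For an incidence $p$ the machinery of truncation applies: the threshold
deviate is $x = \Phi^{-1}(1-p)$, $z = \varphi(x)$ is the normal ordinate
at the threshold, and $a = z/p$ is the mean liability of affected
individuals (the selection intensity of truncation at $x$).

```{r}
liability_point(0.4931)
```

## Heritability estimators

Two estimators of $h^2$ from group incidences are implemented. With a
control group ($x_c$, $a_c$) and a group of relatives of affected
individuals ($x_r$), the classical regression estimator is
$b = (x_c - x_r)/a_c$, $h^2 = b/r$, where $r$ is the additive
relationship between the relatives and the affected individuals defining
them. The variance-corrected estimator,

$$b = \frac{x_c - x_r\sqrt{1-(x_c^2-x_r^2)(1-x_c/a_c)}}
           {a_c + x_r^2(a_c-x_c)},$$

additionally accounts for the reduced liability variance among relatives
of selected (affected) individuals. The two agree to first order as
$x_r \to x_c$; the corrected form is the package default because the
incidence contrasts in this design are large.

```{r}
falconer_h2(0.368098, 0.462882, r = 0.5)
reich_h2(394/799, 105/157, r = 1)
```

Negative estimates (relatives less often affected than the control) are
returned as-is with a `negative` flag, never clipped: clipping would bias
simulation studies that average over replicates.

### Control group and relationship: an open design choice

The trio design classifies offspring by parental affection, giving three
incidences (neither / one / both parents affected) plus the overall
cohort prevalence. Which pair of groups to feed the estimator is a real
choice, and `h2_variants()` computes the full grid so the sensitivity is
visible rather than hidden:

```{r}
h2_variants(p_cohort = 394/799, p_neither = 60/163,
            p_one = 106/229, p_both = 105/157)
```

The package defaults are:

* **Both-affected contrast**: control = cohort prevalence, relatives =
  both-affected-class offspring, midparent $r = 1$. Under the additive
  model this configuration is consistent: both parents are selected
  through the *same* truncation that defines $a_c$, so the offspring mean
  shift is $h^2 a_c$ and dividing by $a_c \cdot r$ recovers $h^2$. In the
  package's simulation checks it recovers the generating $h^2$ to within
  about $\pm 0.02$ at $5\times10^4$ offspring per class.
* **One-affected contrast**: control = neither-affected-class offspring,
  $r = 0.5$. This follows the usual practice of contrasting adjacent
  exposure classes, but it is *not* consistent under the additive model:
  the control class is itself selected (two unaffected parents), and
  moving one parent from unaffected to affected shifts the offspring mean
  by $h^2(z/p + z/q)/2$, not by the $a_c/2$ the estimator divides by. At
  a prevalence near one half this overstates $h^2$ by roughly 60 %.
  The alternative — cohort prevalence as control — is no better here: at
  $p \approx 0.5$ the selection differentials of one affected and one
  unaffected parent nearly cancel, the expected shift is close to zero,
  and the estimate is dominated by noise (on the observed counts it is in
  fact negative). Both variants are therefore reported, and the
  both-affected midparent estimate should be preferred whenever its class
  is populated.

This asymmetry is the package's explanation for why a one-affected-parent
estimate can disagree substantially with a both-affected estimate on the
same data — the published range 0.22–0.51 for the motivating cohort being
a case in point; the lower value cannot be reproduced by any
estimator/control combination in the grid, and the grid makes the
candidates explicit instead of guessing.

Uncertainty is quantified by a binomial bootstrap of both group counts
(`bootstrap_h2_ci()`), with degenerate replicates dropped and counted.

## Association statistics

All 2×2 tests use the Yates-corrected chi-square, with the
$\max(0, |ad-bc| - n/2)$ clamp so near-proportional tables are not
over-corrected; the correction is on by default because the corrected
statistics are what the motivating analyses report. The omnibus test on
the 2×3 mating-type table is the plain Pearson chi-square at df 2. The
risk-difference interval is a Wald interval whose half-width is widened
by $(1/n_1 + 1/n_2)/2$ — the continuity correction matching the corrected
test. Relative risks are reported at full precision and at one decimal.
No multiple-testing adjustment is applied across the three pairwise
contrasts, matching the design this package re-implements; users who need
one can apply `p.adjust` to the `p_value` column.

All three pairwise contrasts and the omnibus test derive from a single
`mating_type_table` object, so no count is ever re-entered by hand.

## The registry rules

* A dog is **affected** if any single examination records the trait; the
  resolved grade is the worst ever recorded, with severity ordered
  `none < ungraded < mild < moderate < severe` (a graded positive
  dominates an ungraded positive; a positive never reverts).
* The inclusion window is closed on both ends (`2004-01-01` to
  `2013-12-31` by default); parental certificates may predate the window.
* The trio cohort contains exactly the dogs whose sire and dam both have
  a resolved record; exclusion is silent but counted in messages.
* Severity grading from cilia counts: mild for 1–5 cilia in total across
  the four palpebrae, moderate for 6–10, severe for 11 or more. The
  published rule of thumb overlaps at five and ten; the package resolves
  the overlap in favour of the milder grade and raises any grade to at
  least moderate when secondary ocular changes are present.
* Dogs of unknown sex are kept everywhere except the sex-association
  test, where their exclusion is reported.

## The simulator

`simulate_registry()` emulates the structure the analysis assumes: a
cohort of roughly 800 examined dogs at ~49 % prevalence containing a trio
subset of roughly 550 offspring; a mating mix near 29/42/30 % for
both/one/neither affected parents; a popular-sire skew (symmetric-
Dirichlet weights over the sire pool); a mild female excess induced by a
sex-specific threshold offset; and a mild-heavy grading distribution from
a `1 + Poisson` cilia-count model. One integer seed drives a single
generator pass and the caller's random state is restored afterwards, so
fixed-seed runs are byte-identical.

```{r}
sim <- simulate_registry(simulation_config(seed = 1))
nrow(sim$registry)
```

`expected_offspring_incidence()` is the simulator's closed-form check:
for each mating class it propagates the truncated-normal moments of the
parents' breeding values through the additive model and returns the
expected offspring incidence, against which simulated class frequencies
are tested within three Monte-Carlo standard deviations.

Deliberate idealisations — what passing simulation tests does **not**
establish about real registries:

* every simulated dog is examined exactly once, so the
  affected-if-ever rule is exercised by hand-written cases, not by the
  simulator;
* all affected dogs are graded, whereas real grading schemes start
  mid-window and cover a fraction of cases;
* there is no ascertainment bias (real registries over-represent
  intended breeding animals), no inbreeding, no multi-generation
  pedigree, and no secular trend in prevalence;
* the sex-threshold offset default (0.2 liability units) is qualitative
  only — it reproduces a female excess of the observed direction, not a
  fitted effect size.

## Numerical choices and problem sizes

Normal quantiles come from the AS 241 rational approximation in
`stats::qnorm`, wrapped with domain validation; the liability machinery
requires the round-trip $|\Phi(x(p)) - (1-p)| < 10^{-9}$ and the test
suite verifies it against independent numerical inversion of the CDF.
Mating-class sizes are allocated by largest-remainder rounding of the mix;
parent sampling is by rejection from the affected/unaffected pools,
erroring (rather than silently re-weighting) when a pool is empty.

The test suite's simulation sizes are chosen so that Monte-Carlo noise is
small against the tolerances they check: $5\times10^4$ offspring per
mating class for estimator recovery (binomial standard error
$\approx 0.002$ on an incidence, well under the $\pm 0.07$ recovery
band), $10^5$ offspring for the marginal-variance check (2 % band), and
$10^4$ random tables for the chi-square oracle equivalence at $10^{-10}$
relative tolerance.

## Limitations

The package estimates heritability from group incidences only; it does
not fit an animal model (REML on the full pedigree), so estimates are not
comparable to additive-genetic-variance analyses of the same trait in
other breeds. The two-generation design ignores deeper pedigree
information, and the threshold model assumes a single normal liability —
a major-gene architecture would violate it. Registry-level biases
(voluntary examination, breeding-driven ascertainment) propagate directly
into prevalence and incidence inputs and are out of scope.
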