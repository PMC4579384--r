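# threshtrait

Retrospective cohort analysis of a binary inherited trait recorded in an
eye-examination registry, with heritability estimation on the liability
scale. The package was built around canine distichiasis — aberrant extra
eyelashes emerging from the meibomian gland orifices — in the English
Cocker spaniel, where roughly half of the examined population is affected
and the trait behaves as a threshold character: a continuous, normally
distributed liability underlies a discontinuous (affected/unaffected)
phenotype, and an individual is affected when its liability exceeds a
threshold.

It is intended for veterinary geneticists and epidemiologists working with
examination registries of the ECVO-certificate type: one row per
examination, repeated examinations per dog, flat sire/dam pedigree links,
and an affected-if-ever-diagnosed phenotype rule.

## What it computes

**Familial association.** Offspring with two examined parents are
classified by parental mating type (both / one / neither parent affected).
The package computes the omnibus Pearson chi-square on the 2×3 table and,
for each pairwise contrast, the Yates-corrected chi-square

    X² = n (max(0, |ad − bc| − n/2))² / (r₁ r₂ c₁ c₂),

the relative risk `RR = p₁/p₂`, and a continuity-corrected Wald interval
for the risk difference with half-width
`z₀.₉₇₅ √(p₁q₁/n₁ + p₂q₂/n₂) + (1/n₁ + 1/n₂)/2`.

**Liability-scale heritability.** For an incidence `p`, the threshold
deviate is `x = Φ⁻¹(1 − p)`, `z = φ(x)`, and `a = z/p` is the mean
liability of affected individuals. With a control group (subscript `c`)
and a group of relatives of affected individuals (subscript `r`), the
classical threshold-character estimator is

    b = (x_c − x_r) / a_c,        h² = b / r,

with `r = 0.5` for a single affected parent and `r = 1` for a midparent
(both-parents-affected) contrast. The package default is the
variance-corrected estimator

    b = [x_c − x_r √(1 − (x_c² − x_r²)(1 − x_c/a_c))] / [a_c + x_r²(a_c − x_c)],

which accounts for the reduced liability variance among relatives of
affected individuals. Bootstrap percentile intervals are available by
binomial resampling of the group counts.

**Simulation.** A two-generation additive liability-threshold simulator
(`simulate_registry()`) generates registries in the same schema, with
configurable heritability, prevalence, mating-type mix, popular-sire skew,
sex-specific thresholds and severity grading, plus a closed-form oracle
(`expected_offspring_incidence()`) for the expected offspring incidence in
each mating class. Parameter-recovery checks for the estimators run
entirely on simulated data.

## Worked example

`reference_registry()` emits a deterministic 799-dog registry reproducing
the published cohort margins of the Danish English Cocker spaniel study
population (one examination row per dog).

```r
library(threshtrait)
bundle <- run_analysis(analysis_config(reference_registry(),
                                       avg_yearly_registrations = 420))
print(bundle)
```

```
Cohort: 799 dogs, 394 affected (prevalence 49.31 %)
Sex association: chi-square = 6.7599, p = 0.009323
Trio cohort: 549 offspring; omnibus chi-square = 30.41 (df 2), p = 2.49e-07
Mating-type table:
                  outcome
mating_class       affected unaffected
  both_affected         105         52
  one_affected          106        123
  neither_affected       60        103
Pairwise comparisons:
 comparison statistic_2dp      p_value rd_lower_2dp rd_upper_2dp rr_1dp
 +/- vs -/-          3.13 7.702864e-02        -0.01         0.20    1.3
 +/+ vs +/-         15.11 1.011674e-04         0.10         0.31    1.4
 +/+ vs -/-         27.76 1.373631e-07         0.19         0.41    1.8
Heritability (default variants):
  both_affected contrast (reich, control = cohort, r = 1): h2 = 0.51
  one_affected contrast (reich, control = neither_offspring, r = 0.5): h2 = 0.48
Grading: 135 of 394 affected graded (mild/moderate/severe = 116/15/4)
```

Reading the output: the cohort is evenly split between affected and
unaffected with a female excess (the corrected sex chi-square 6.76 at
df 1, p ≈ 0.009); offspring affection is strongly associated with the
parental mating type (omnibus p ≪ 10⁻⁴); the risk of affected offspring
rises from the neither-affected to the both-affected mating class
(relative risks 1.3 and 1.8 against the neither-affected class); and the
corrected midparent estimator puts the heritability of liability at 0.51
for the both-affected contrast. `render_report(bundle, "json", dir)`
writes every number at full precision; `"tsv"` and `"markdown"` give
count/comparison tables with the conventional rounding.

A simulated registry runs through exactly the same pipeline:

```r
sim <- simulate_registry(simulation_config(seed = 1, h2_true = 0.35))
bundle <- run_analysis(analysis_config(sim$registry))
```

A thin command-line front end with `simulate`, `analyze`, `heritability`
and `fixture` subcommands is installed at `inst/scripts/threshtrait.R`.

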