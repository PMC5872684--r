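---
title: "Screening gene-environment interactions and scoring genetic sensitivity to body-fat loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene-environment interactions and scoring genetic sensitivity to body-fat loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsens)
```

## The problem

Weight-loss interventions do not work equally well for everyone: the body-fat
response to cutting carbohydrates, cutting fat, cutting total calories, or
taking up regular exercise varies across individuals, and part of that
variation tracks genotype. `grsens` implements a screening-and-scoring
pipeline that turns a candidate panel of obesity-associated SNPs plus a
longitudinal cohort (two dietary survey waves; several exercise-status waves
with body-composition measurements) into a per-individual *sensitivity
profile*: four signed genetic risk scores (GRS) and four quartile classes —
very low (VL), low (L), high (H), very high (VH) — one per intervention
category:

* **CE** — sensitivity of body-fat change to carbohydrate-intake change,
* **FE** — to fat-intake change,
* **TE** — to total-calorie-intake change,
* **EE** — to exercise onset.

The cohorts this kind of analysis runs on are access-restricted, so the
package ships a seeded synthetic cohort generator that reproduces the
statistical structure the analysis assumes. The generator is first-class,
tested code: every downstream stage is exercised end-to-end on cohorts with
*planted* (known) effects, which is how the pipeline's operating
characteristics are established.

## Models and procedure

### Phenotype derivation

Per individual, dietary changes are follow-up minus baseline across the two
diet waves: ΔC (carbohydrate, g/day), ΔF (fat, g/day), ΔTC (total calories,
kcal/day) and Δbodyfat (kg). Only individuals with complete intake and
body-fat records at both waves enter; exclusions are counted.

Exercise status is a binary survey answer (1 = no, 2 = yes) observed over
five waves with uneven missingness. The exercise phenotype Δbodyfat\* is
*orientation-normalized*: over every pair of consecutive observed waves where
the status changes, record body fat at the exercising wave minus body fat at
the non-exercising wave — regardless of which came first — and average the
oriented differences. The statistic is by construction invariant to
reversing the time order of the records (a tested property). Individuals
with no usable transition are excluded.

One sign convention deserves a note. Read literally, "the difference from
the exercising time point to the non-exercising one" would be no-minus-yes;
but with that convention a cohort whose exercise starters lose fat and whose
stoppers regain it would show a *positive* average. We fix the convention as
**yes-state minus no-state**, so that a negative Δbodyfat\* means exercise is
associated with lower body fat, which is the only reading under which the
started/stopped subgroup summaries and the overall average can agree in
sign. Pairs without a status change carry no information about exercise
onset and contribute nothing; a pair with missing body fat is skipped
without discarding the individual. Consecutiveness is required among
*observed* waves (an individual observed at waves 3, 5, 7 contributes the
pairs 3–5 and 5–7), since requiring calendar-consecutive waves would discard
most of a sparsely observed cohort.

### Per-SNP screening models

Each SNP is coded additively as its minor-allele count ∈ {0, 1, 2} and
tested with three Gaussian linear models (OLS; equivalently the
gaussian-identity GLM), adjusted for gender and age:

* **Model 1 (diet interactions)**
  Δbodyfat = β₀ + β_g·gender + β_a·age + β_t·ΔTC + β_s·SNP + β₁·ΔC + β₂·ΔF
  + **β_c**·(ΔC×SNP) + **β_f**·(ΔF×SNP).
  The ΔTC adjustment isolates nutrient-composition effects from total energy.
* **Model 2 (calorie interaction)**
  Δbodyfat = β₀ + β_g·gender + β_a·age + β_t·ΔTC + β_s·SNP +
  **β_TC**·(ΔTC×SNP).
* **Model 3 (exercise main effect)**
  Δbodyfat\* = β₀ + β_g·gender + β_a·age + **β_E**·SNP.

The bold coefficients are the *target terms*; their two-sided p-values drive
selection. Standard errors use the unbiased residual variance and p-values
the t distribution with n − p degrees of freedom rather than a Wald normal
approximation — identical asymptotically, finite-sample correct, and what
`summary.lm` reports. Fits are complete-case per SNP, so a missing genotype
reduces that SNP's n only. Rank-deficient designs are refused with the
collinear terms named, and SNPs with fewer than 5 minor-allele carriers are
skipped with a logged reason instead of producing unstable estimates
(`min_carriers`, configurable).

A SNP enters category CE when its β_c p-value is strictly below α (default
0.05), and analogously FE (β_f), TE (β_TC), EE (β_E). The same SNP may enter
several categories. The threshold is deliberately *uncorrected* for multiple
testing: the selection is an input to an aggregate score, not a set of
individual discovery claims, and false positives act as zero-mean noise SNPs
in the score. A Benjamini–Hochberg option exists (`adjust = "BH"`) but is
off by default.

### LD pruning

Selected SNPs within a category are often statistically redundant through
linkage disequilibrium, which would double-count alleles in the score. LD
is measured as the squared Pearson correlation r² of allele counts in the
analysis cohort itself, over pairwise-complete individuals (reference-panel
lookups would tie the package to an external service and a population that
may not match the cohort). Pairs with r² **strictly** greater than the
threshold (default 0.7) are linked; linkage groups are the **connected
components** of that graph. Components — rather than maximal cliques or
greedy sequential pruning — make the grouping deterministic and independent
of input order; a chain A–B–C where only the adjacent pairs exceed the
threshold is treated as one group. Each component keeps exactly the SNP with
the smallest category p-value, ties broken lexicographically by SNP id so
output is reproducible. Pruning is idempotent (a tested property). An r²
that is undefined (zero variance, or fewer than two complete pairs) is a
missing edge, never a link.

### Signed scores and quartile classes

Each surviving SNP gets a sign: +1 if its target coefficient is positive,
−1 if negative — except EE, where the sign is *reversed*: a positive β_E
means carriers gain fat on exercise onset, i.e. exercise is less effective
for them, and the score should rank effective responders high. A coefficient
of exactly zero has no sign and is an error.

The GRS for a category is the unweighted signed allele count
Σᵢ signᵢ·countᵢ. A missing genotype contributes its expected count 2·MAF
instead — contributing zero would push carriers of missing calls toward the
extreme class of whichever sign dominates — so scores are integers exactly
when no call is missing.

Classes come from the population quartiles of each category's score
distribution: VL below the 25th percentile, L from the 25th (inclusive) to
the 50th, H from the 50th (inclusive) to the 75th, VH at or above the 75th.
With all three cutpoints equal the upper rule wins (VH). Percentiles use
linear interpolation between order statistics (position 1 + p·(n−1),
`quantile` type 7). On integer-valued scores the class boundaries genuinely
depend on this choice, so it is frozen and documented, with a nearest-rank
alternative (`method = "nearest"`) for sensitivity analysis. Cutpoints are
computed on the population being classified, as in a one-cohort analysis;
`sensitivity_profiles(cutpoints = ...)` classifies new individuals against
stored reference cutpoints instead.

### Evaluation

The classification is evaluated where it should matter: among *responders*,
the individuals who actually changed behaviour. For CE/FE/TE these are the
quarter with the largest intake reduction — intake change strictly below the
25th percentile of the cohort's change distribution (computed from the data,
not hard-coded thresholds, so the definition transfers across cohorts; fixed
thresholds can be passed for strict reproduction of a particular cohort).
For EE, responders are individuals contributing at least one no→yes
transition. Per class, the mean and SD of Δbodyfat (Δbodyfat\* for EE) are
reported; a useful classification shows means decreasing from VL to VH. The
package quantifies that pattern with an ordinal trend regression of the
individual outcome on the class code (VL = 0 … VH = 3), reported alongside —
never instead of — the per-class means. Score distributions are summarised
(mean, SD, median, range) with a Shapiro–Wilk normality p-value; above
n = 5000 the test runs on a seeded subsample of 5000, the test's defined
range.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; every generator output is a pure
function of the configuration, including its seed.

* **Genotypes**: per SNP, two independent Bernoulli(MAF) allele draws
  (Hardy–Weinberg), MAF drawn per SNP from `maf_range`, default
  (0.01, 0.49). LD blocks: member SNPs share the block seed's MAF and copy
  its alleles, each allele independently *redrawn* from Bernoulli(MAF) with
  probability 1 − r, giving expected genotype correlation r against the
  seed SNP while preserving the marginal MAF. Missing calls are
  missing-completely-at-random at a configurable rate (default 0).
* **Diet waves**: ΔC ~ N(−18.4, 132.38²) g/day and ΔF ~ N(−4.71, 22.1²)
  g/day match the cohort the method was developed on. ΔTC is linked through
  the Atwater energy factors, ΔTC = 4·ΔC + 9·ΔF + N(−31.1, 506²) kcal/day;
  the noise moments are solved so the marginal ΔTC distribution has mean
  −147.12 and SD ≈ 759 kcal/day. The link is a modelling convenience — the
  real survey covariances are unpublished — chosen to give model 1's ΔTC
  adjustment realistic collinearity to contend with. Δbodyfat is the
  configured linear predictor (intercept −0.42 kg; optional covariate
  effects, default 0; planted interaction effects) plus N(0, 2.57²) kg
  noise. Two waves are emitted whose differences equal the drawn deltas
  exactly; baseline levels are nudged up in the rare case a follow-up value
  would go negative, preserving the delta.
* **Exercise waves**: five waves; status evolves as a two-state chain with
  switching probability 0.3 per wave from initial exercising prevalence
  0.5. Between waves body fat increments by N(0, 2.2²) kg; on a status
  switch the increment additionally carries the oriented effect — population
  mean −0.08 kg plus planted per-allele EE effects — positively when
  switching to exercise, negatively when switching away. These four values
  are not published quantities; they were fixed once at the scale of the
  target cohort's per-interval summaries and are configuration, not
  estimates. The additive per-transition increment is the minimal structure
  model 3 can detect, deliberately so.
* **Planted effects** (`effects`): per SNP and category, an interaction
  coefficient in the model's own units (CE/FE: kg fat per g·allele; TE: kg
  per kcal·allele; EE: kg per allele). With noise set to zero the generator
  is exactly the models' data-generating process, and the screening recovers
  planted coefficients to machine precision — the package's strongest
  internal consistency check.

What the generator does **not** emulate: population stratification, MAF-
dependent effect sizes, informative missingness, item-level food-frequency
measurement error, secular trends across waves, or correlation between diet
and exercise behaviour. Passing tests therefore demonstrate that the
*pipeline* is correct and well calibrated under its stated assumptions —
not that those assumptions hold in any real cohort.

## Worked example

A compact run of the whole pipeline (the `analysis/` scripts run the same
stages at n = 10⁴ with a 30-SNP panel and 16 planted effects):

```{r example, eval = FALSE}
effects <- data.frame(snp_id = c("snp_001", "snp_002"),
                      category = c("CE", "EE"),
                      effect = c(0.006, -0.2))
cfg <- run_config(sim = sim_config(n_individuals = 2000, n_snps = 12,
                                   effects = effects),
                  out_dir = "run", seed = 1)
manifest <- run_all(cfg)
read.delim("run/group_summaries.tsv")
```

Every stage writes its table under `out_dir`, and `manifest.yaml` records
the seed, a configuration hash and per-stage counts (individuals included
and excluded, SNPs tested, skipped, selected and pruned) so a run can be
audited. Rerunning with the same configuration reproduces the directory
byte for byte.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere the rules state them: selection requires
  p < α (p = α is out), LD linkage requires r² > threshold (r² = threshold
  is no edge), responders require change < the quartile (a constant change
  distribution yields an empty subset, with a warning).
* Quartile cutpoints: `quantile` type 7; classes use `findInterval`, so
  boundary scores land in the upper class (q25 → L, q75 → VH) and degenerate
  cutpoints cascade to VH.
* p-value ties in pruning break lexicographically by SNP id.
* Genotype cells outside {0, 1, 2} become missing with a counted warning on
  read; duplicate individual ids, uncoded exercise values and negative
  body-fat or intake values are hard errors.
* Tables are written tab-delimited with doubles at 17 significant digits, so
  a write/read round trip reproduces every value exactly.
* Problem sizes in the shipped tests and scripts were chosen as the smallest
  that pin each property sharply: null calibration at 2000 individuals ×
  1000 SNPs, sign-recovery power at n = 4000 × 200 replicates, end-to-end
  monotonicity at n = 10⁴ × 50 replicates.

## Limitations

* The score is unweighted (sign × count). Coefficient-weighted or shrunken
  scores are out of scope by design, matching the procedure the package
  implements.
* Selection at raw α = 0.05 across a panel admits false positives by
  construction; the pipeline reports audit counts rather than pretending
  otherwise, and the BH option narrows the selection when inference on
  individual SNPs is wanted.
* Quartile classes depend on the reference population; profiles computed in
  one cohort do not transfer to another without stored cutpoints.
* The exercise phenotype treats all transitions as exchangeable and ignores
  exercise intensity and duration, which a binary survey answer cannot
  carry.
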