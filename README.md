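# grsens

Gene–environment interaction screening and genetic sensitivity scores for
body-fat change.

People respond differently to the same weight-loss intervention, and part of
that difference is genetic. `grsens` is an R package for biostatisticians and
nutrition/exercise epidemiologists who want to score an individual's genetic
sensitivity to body-fat loss under four interventions — carbohydrate
reduction (CE), fat reduction (FE), total-calorie reduction (TE) and exercise
onset (EE) — from a candidate SNP panel and a longitudinal cohort with
dietary survey waves and body-composition measurements.

## Method

For each SNP (additively coded as the minor-allele count 0/1/2) three
Gaussian linear models are fit by OLS with t tests, adjusted for gender and
age:

```
(1)  Δbodyfat  = gender + age + ΔTC + SNP + ΔC + ΔF + βc·(ΔC × SNP) + βf·(ΔF × SNP)
(2)  Δbodyfat  = gender + age + ΔTC + SNP + βTC·(ΔTC × SNP)
(3)  Δbodyfat* = gender + age + βE·SNP
```

where ΔC, ΔF, ΔTC are the intake changes between the two diet waves and
Δbodyfat\* is the orientation-normalized mean body-fat difference across
exercise-status transitions (exercising state minus non-exercising state,
regardless of time direction). SNPs whose target coefficient (βc, βf, βTC,
βE) has p < 0.05 enter the corresponding category; within a category,
SNPs linked by genotype r² > 0.7 are pruned to the smallest-p member of each
connected component. Each survivor gets a sign from its coefficient
(reversed for EE), and the per-individual genetic risk score is the signed
allele count

```
GRS = Σi signi · counti
```

Population quartiles of each score cut the four sensitivity classes
VL / L / H / VH, and the classification is evaluated among *responders* (the
quarter with the largest intake reduction, or exercise starters) as the
class-wise mean body-fat change plus an ordinal trend test.

Because the cohorts this analysis runs on are access-restricted, the package
includes a seeded synthetic cohort generator (Hardy–Weinberg genotypes,
optional LD blocks, realistic dietary/body-fat marginals, longitudinal
exercise chains, configurable planted effects) so the full pipeline is
testable and demonstrable without any restricted data.

## Worked example

The `analysis/` directory holds the study as numbered stage scripts
(simulate → derive → screen → prune/score/classify → evaluate), each a thin
driver over the package that writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_derive_phenotypes.R
Rscript analysis/03_screen_gxe.R
Rscript analysis/04_prune_score_classify.R
Rscript analysis/05_evaluate.R
```

On the default study (n = 10 000 individuals, 30 SNPs, 16 planted effects,
seed 1) the stages print:

```
diet: n = 10000 (0 excluded); carb change -18.5 +/- 134.0 g, fat -4.72 +/- 22.1 g,
      calorie -149 +/- 769 kcal, body fat -0.34 +/- 2.79 kg
exercise: n = 7607 with >= 1 transition (2393 excluded); oriented delta -0.21 +/- 1.94 kg
tested 30 SNPs (0 skipped); selected CE 10, FE 7, TE 11, EE 5
planted effects recovered: 16 of 16
CE responders (n = 2500): mean body-fat change VL 1.60, L 0.54, H -0.24, VH -1.61 kg;
      trend slope -1.05 (p = 3.7e-75)
EE responders (n = 5530): mean body-fat change VL 0.08, L -0.06, H -0.28, VH -0.49 kg;
      trend slope -0.19 (p = 7.9e-19)
```

Read: all 16 planted gene–environment effects were recovered by the screen
(plus a few expected false positives at raw α = 0.05), and among individuals
who actually reduced intake or started exercising, mean body-fat loss grows
monotonically from the very-low to the very-high sensitivity class — the
pattern the classification exists to produce. The negative trend slope is
the per-class-step change in kg of body fat.

The same pipeline is available as one call (`run_all()`) on simulated or
loaded cohort files, with a YAML-configurable generator and a run manifest
recording seed, configuration hash and per-stage audit counts; see the
vignette `vignettes/genetic-sensitivity-screening.Rmd` for the full model
description and design rationale.

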