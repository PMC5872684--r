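#!/usr/bin/env Rscript
# Stage 2: derive the per-individual analysis variables.
#
# Diet: follow-up minus baseline changes in carbohydrate, fat and calorie
# intake and body fat mass. Exercise: the orientation-normalized mean
# body-fat difference across status transitions (exercising-state minus
# non-exercising-state, regardless of time direction).

suppressPackageStartupMessages(library(grsens))

cohort_dir <- "results/cohort"
out <- "results/derived"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

diet_cohort <- read_cohort(file.path(cohort_dir, "diet_cohort.tsv"))
exercise_cohort <- read_cohort(file.path(cohort_dir, "exercise_cohort.tsv"))

diet_deltas <- compute_diet_deltas(diet_cohort)
exercise_deltas <- compute_exercise_delta(exercise_cohort)

write_table(diet_deltas, file.path(out, "diet_deltas.tsv"))
write_table(exercise_deltas, file.path(out, "exercise_deltas.tsv"))

message(sprintf(
  "diet: n = %d (%d excluded); carb change %.1f +/- %.1f g, fat %.2f +/- %.1f g, calorie %.0f +/- %.0f kcal, body fat %.2f +/- %.2f kg",
  nrow(diet_deltas), attr(diet_deltas, "n_excluded"),
  mean(diet_deltas$d_carb), sd(diet_deltas$d_carb),
  mean(diet_deltas$d_fat), sd(diet_deltas$d_fat),
  mean(diet_deltas$d_kcal), sd(diet_deltas$d_kcal),
  mean(diet_deltas$d_bodyfat), sd(diet_deltas$d_bodyfat)))
message(sprintf(
  "exercise: n = %d with >= 1 transition (%d excluded); oriented delta %.2f +/- %.2f kg",
  nrow(exercise_deltas), attr(exercise_deltas, "n_excluded"),
  mean(exercise_deltas$d_bodyfat_star), sd(exercise_deltas$d_bodyfat_star)))
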