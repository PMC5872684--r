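# Derivation of the per-individual analysis variables: dietary deltas between
# the two food-frequency waves, and the orientation-normalized averaged
# exercise body-fat delta.

#' Compute dietary and body-fat changes between two survey waves
#'
#' For each individual with complete intake and body-fat records at both
#' waves, computes follow-up minus baseline differences of carbohydrate
#' intake, fat intake, total calorie intake and body fat mass. Individuals
#' missing either wave (or any required field at either wave) are excluded;
#' their number is attached as attribute `n_excluded`.
#'
#' @param cohort Long-format cohort data frame (see [read_cohort()]).
#' @param baseline_wave,followup_wave Wave ids; must differ.
#' @return Data frame with columns `individual`, `gender`, `age`,
#'   `d_bodyfat` (kg), `d_carb` (g/day), `d_fat` (g/day), `d_kcal`
#'   (kcal/day).
#' @export
compute_diet_deltas <- function(cohort, baseline_wave = 1,
                                followup_wave = 2) {
  cohort <- as_cohort(cohort)
  if (identical(baseline_wave, followup_wave) ||
      baseline_wave == followup_wave)
    stop("baseline and follow-up waves must differ")
  need <- c("carb_g", "fat_g", "kcal", "bodyfat_kg")
  base <- cohort[cohort$wave == baseline_wave, , drop = FALSE]
  fup <- cohort[cohort$wave == followup_wave, , drop = FALSE]
  all_ids <- unique(cohort$individual)
  m <- merge(base, fup, by = "individual", suffixes = c("_0", "_1"))
  ok <- complete.cases(m[, c(paste0(need, "_0"), paste0(need, "_1"))])
  m <- m[ok, , drop = FALSE]
  out <- data.frame(individual = m$individual,
                    gender = m$gender_0,
                    age = m$age_0,
                    d_bodyfat = m$bodyfat_kg_1 - m$bodyfat_kg_0,
                    d_carb = m$carb_g_1 - m$carb_g_0,
                    d_fat = m$fat_g_1 - m$fat_g_0,
                    d_kcal = m$kcal_1 - m$kcal_0)
  out <- out[order(out$individual), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- length(all_ids) - nrow(out)
  out
}

#' Compute the orientation-normalized exercise body-fat delta
#'
#' Scans each individual's consecutive observed wave pairs with non-missing
#' exercise status. For every pair where the status changes, the oriented
#' difference is recorded as body fat at the exercising ("yes") wave minus
#' body fat at the non-exercising ("no") wave, regardless of which came
#' first in time; pairs with missing body fat at either wave are skipped.
#' The per-individual delta is the mean of these oriented differences.
#' Individuals contributing no usable transition are excluded; their number
#' is attached as attribute `n_excluded`.
#'
#' @param cohort Long-format cohort data frame with >= 2 waves of exercise
#'   status.
#' @return Data frame with columns `individual`, `gender`, `age`,
#'   `d_bodyfat_star` (kg), `n_transitions` (usable status-change pairs) and
#'   `n_onsets` (no-to-yes pairs among them).
#' @export
compute_exercise_delta <- function(cohort) {
  cohort <- as_cohort(cohort)
  obs <- cohort[!is.na(cohort$exercise), , drop = FALSE]
  if (nrow(obs) == 0) stop("no exercise records in cohort")
  obs <- obs[order(obs$individual, obs$wave), , drop = FALSE]
  m <- nrow(obs)
  # consecutive observed-wave pairs within each individual, vectorized
  i <- if (m >= 2) which(obs$individual[-m] == obs$individual[-1]) else integer()
  s0 <- obs$exercise[i]
  s1 <- obs$exercise[i + 1]
  f0 <- obs$bodyfat_kg[i]
  f1 <- obs$bodyfat_kg[i + 1]
  usable <- s0 != s1 & !is.na(f0) & !is.na(f1)
  oriented <- ifelse(s0 == 2, f0 - f1, f1 - f0)
  grp <- factor(obs$individual[i][usable])
  if (nlevels(grp) > 0) {
    star <- tapply(oriented[usable], grp, mean)
    ntr <- as.integer(table(grp))
    ons <- as.integer(tapply(as.integer(s0 == 1 & s1 == 2)[usable], grp, sum))
    first <- match(levels(grp), obs$individual)
    out <- data.frame(individual = levels(grp),
                      gender = obs$gender[first],
                      age = obs$age[first],
                      d_bodyfat_star = as.numeric(star),
                      n_transitions = ntr,
                      n_onsets = ons)
  } else {
    out <- data.frame(individual = character(), gender = numeric(),
                      age = numeric(), d_bodyfat_star = numeric(),
                      n_transitions = integer(), n_onsets = integer())
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- length(unique(obs$individual)) - nrow(out)
  out
}
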