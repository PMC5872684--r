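#!/usr/bin/env Rscript
# Stage 5: evaluate the classification.
#
# Responder subgroups (the quarter with the largest intake reduction per
# diet category; exercise-onset individuals for EE) are summarised per
# sensitivity class, with an ordinal trend test across classes and
# descriptive statistics / Shapiro-Wilk normality tests of each score
# distribution.

suppressPackageStartupMessages(library(grsens))

out <- "results/evaluation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

diet_deltas <- read.delim("results/derived/diet_deltas.tsv")
exercise_deltas <- read.delim("results/derived/exercise_deltas.tsv")
profiles <- read.delim("results/classify/profiles.tsv")
grs <- read.delim("results/classify/grs.tsv")
for (col in grep("_class$", names(profiles), value = TRUE))
  profiles[[col]] <- factor(profiles[[col]],
                            levels = c("VL", "L", "H", "VH"))

summaries <- list()
trends <- list()
for (cat in intersect(c("CE", "FE", "TE", "EE"), unique(grs$category))) {
  deltas <- if (cat == "EE") exercise_deltas else diet_deltas
  responders <- responder_subset(deltas, cat)
  summaries[[cat]] <- group_means(responders, profiles, deltas, cat)
  tr <- trend_statistic(responders, profiles, deltas, cat)
  trends[[cat]] <- data.frame(category = cat, slope = tr$slope,
                              p_value = tr$p_value, n = tr$n)
  m <- summaries[[cat]]$mean_change
  message(sprintf(
    "%s responders (n = %d): mean body-fat change VL %.2f, L %.2f, H %.2f, VH %.2f kg; trend slope %.2f (p = %.2g)",
    cat, tr$n, m[1], m[2], m[3], m[4], tr$slope, tr$p_value))
}

write_table(do.call(rbind, summaries), file.path(out, "group_summaries.tsv"))
write_table(do.call(rbind, trends), file.path(out, "trend.tsv"))
desc <- grs_descriptives(grs, subsample_seed = 1L)
write_table(desc, file.path(out, "grs_descriptives.tsv"))
message("score distributions:")
for (i in seq_len(nrow(desc)))
  message(sprintf("  %s: mean %.2f (SD %.2f), median %g, range [%g, %g], Shapiro-Wilk p = %.2g",
                  desc$category[i], desc$mean[i], desc$sd[i], desc$median[i],
                  desc$min[i], desc$max[i], desc$shapiro_p[i]))
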