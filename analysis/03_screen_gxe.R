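#!/usr/bin/env Rscript
# Stage 3: per-SNP gene-environment screening.
#
# Fits the three per-SNP models -- diet interactions (carbohydrate, fat),
# calorie interaction, exercise main effect -- and selects per category at
# raw p < 0.05 (the screening is deliberately uncorrected; the selection is
# an input to scoring, not a discovery claim).

suppressPackageStartupMessages(library(grsens))

out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genotypes <- read_genotypes("results/cohort/genotypes.tsv",
                            panel = read_panel("results/cohort/panel.tsv"))
diet_deltas <- read.delim("results/derived/diet_deltas.tsv")
exercise_deltas <- read.delim("results/derived/exercise_deltas.tsv")

fits <- screen_snps(genotypes, diet_deltas, exercise_deltas)
selection <- select_snps(fits, alpha = 0.05)

write_table(fits, file.path(out, "fits.tsv"))
skipped <- attr(fits, "skipped")
if (nrow(skipped) > 0) write_table(skipped, file.path(out, "skipped.tsv"))
write_table(selection, file.path(out, "selection.tsv"))

counts <- table(factor(selection$category, levels = c("CE", "FE", "TE", "EE")))
message(sprintf("tested %d SNPs (%d skipped); selected CE %d, FE %d, TE %d, EE %d",
                length(unique(fits$snp_id)), nrow(skipped),
                counts["CE"], counts["FE"], counts["TE"], counts["EE"]))

planted <- read.delim("results/cohort/planted_effects.tsv")
hit <- merge(planted, selection, by = c("snp_id", "category"))
message(sprintf("planted effects recovered: %d of %d", nrow(hit),
                nrow(planted)))
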