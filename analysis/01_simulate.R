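#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# The genotype panel holds 30 SNPs; four per category carry planted
# gene-environment effects at the coefficient magnitudes the screening is
# meant to detect (|beta_c| ~ 0.006 kg per g.allele, |beta_f| ~ 0.01-0.03,
# |beta_TC| ~ 0.0003-0.0006 kg per kcal.allele, |beta_E| ~ 0.14-0.21 kg per
# allele). Dietary and body-composition marginals follow the cohort the
# method was developed on. Everything is a pure function of the seed.

suppressPackageStartupMessages(library(grsens))

seed <- 1L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

effects <- rbind(
  data.frame(snp_id = sprintf("snp_%03d", 1:4), category = "CE",
             effect = c(0.006, -0.006, 0.004, -0.004)),
  data.frame(snp_id = sprintf("snp_%03d", 5:8), category = "FE",
             effect = c(-0.01, 0.012, -0.029, 0.017)),
  data.frame(snp_id = sprintf("snp_%03d", 9:12), category = "TE",
             effect = c(0.00056, -0.00056, 0.0004, -0.0003)),
  data.frame(snp_id = sprintf("snp_%03d", 13:16), category = "EE",
             effect = c(-0.14, 0.15, -0.21, 0.19)))

cfg <- sim_config(n_individuals = 10000, n_snps = 30, seed = seed,
                  effects = effects)
genotypes <- generate_genotypes(cfg)
diet_cohort <- generate_diet_outcomes(cfg, genotypes)
exercise_cohort <- generate_exercise_series(cfg, genotypes)

write_genotypes(genotypes, file.path(out, "genotypes.tsv"))
write_table(genotypes$snps, file.path(out, "panel.tsv"))
write_table(effects, file.path(out, "planted_effects.tsv"))
write_table(diet_cohort, file.path(out, "diet_cohort.tsv"))
write_table(exercise_cohort, file.path(out, "exercise_cohort.tsv"))

message(sprintf("cohort: %d individuals, %d SNPs (%d with planted effects)",
                nrow(genotypes$counts), ncol(genotypes$counts),
                length(unique(effects$snp_id))))
message(sprintf("diet waves: %d records; exercise waves: %d records",
                nrow(diet_cohort), nrow(exercise_cohort)))
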