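#!/usr/bin/env Rscript
# Stage 4: LD pruning, risk-allele signs, genetic risk scores, classes.
#
# Within each category the selected SNPs are pruned by genotype r^2 > 0.7
# (connected components; smallest-p survivor). Survivors get signs from
# their coefficient (reversed for the exercise category), individuals get
# one signed score per category, and population quartiles cut the four
# classes VL / L / H / VH.

suppressPackageStartupMessages(library(grsens))

out <- "results/classify"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genotypes <- read_genotypes("results/cohort/genotypes.tsv",
                            panel = read_panel("results/cohort/panel.tsv"))
selection <- read.delim("results/screen/selection.tsv")

pruned <- prune_by_ld(selection, genotypes, threshold = 0.7)
edges <- attr(pruned, "edges")
if (nrow(edges) > 0) write_table(edges, file.path(out, "ld_edges.tsv"))
write_table(pruned, file.path(out, "selection_pruned.tsv"))

signed <- assign_signs(pruned)
write_table(signed[, c("snp_id", "category", "sign")],
            file.path(out, "weights.tsv"))

grs <- compute_grs(genotypes, signed)
classified <- sensitivity_profiles(grs)
write_table(grs, file.path(out, "grs.tsv"))
write_table(classified$profiles, file.path(out, "profiles.tsv"))
cuts <- do.call(rbind, lapply(names(classified$cutpoints), function(cat)
  data.frame(category = cat, t(classified$cutpoints[[cat]]))))
write_table(cuts, file.path(out, "cutpoints.tsv"))

for (cat in unique(signed$category))
  message(sprintf("%s: %d SNPs after pruning (%d removed); cutpoints %s",
                  cat, sum(signed$category == cat),
                  sum(selection$category == cat) - sum(signed$category == cat),
                  paste(round(classified$cutpoints[[cat]], 2),
                        collapse = " / ")))
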