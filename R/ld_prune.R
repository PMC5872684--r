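# LD pruning within a category's selected SNPs. LD is measured as the squared
# Pearson correlation of additive allele counts in the analysis cohort itself
# (the composite genotypic r^2). Pairs with r^2 strictly above the threshold
# form edges; within each connected component exactly one SNP survives, the
# one whose category p-value is smallest (ties broken by snp_id).

#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation of allele counts over pairwise-complete
#' individuals. Undefined (returned as `NA`) when fewer than two complete
#' pairs exist or either SNP has zero variance among them.
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @return A single value in [0, 1], or `NA`.
#' @export
compute_r2 <- function(genotypes, snp_a, snp_b) {
  a <- snp_column(genotypes, snp_a)
  b <- snp_column(genotypes, snp_b)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]
  b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' LD edge list among a set of SNPs
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_ids SNPs to compare pairwise.
#' @param threshold Edges require `r2 > threshold` (strict).
#' @return Data frame with columns `snp_a`, `snp_b`, `r2`.
#' @export
ld_edges <- function(genotypes, snp_ids, threshold = 0.7) {
  snp_ids <- unique(snp_ids)
  edges <- list()
  if (length(snp_ids) >= 2) {
    pairs <- utils::combn(snp_ids, 2)
    for (k in seq_len(ncol(pairs))) {
      r2 <- compute_r2(genotypes, pairs[1, k], pairs[2, k])
      if (!is.na(r2) && r2 > threshold)
        edges[[length(edges) + 1]] <- data.frame(
          snp_a = pairs[1, k], snp_b = pairs[2, k], r2 = r2)
    }
  }
  if (length(edges) == 0)
    return(data.frame(snp_a = character(), snp_b = character(),
                      r2 = numeric()))
  do.call(rbind, edges)
}

#' Prune a category selection by linkage disequilibrium
#'
#' Builds the LD graph over the selection's SNPs at the threshold and keeps,
#' within each connected component, exactly the SNP with the smallest
#' category p-value (ties broken lexicographically by snp_id). Coefficients,
#' p-values and signs of survivors are preserved. When the selection covers
#' several categories, each category is pruned independently.
#'
#' @param selection Selection table from [select_snps()] (optionally signed).
#' @param genotypes A [genotype_matrix()].
#' @param threshold LD threshold; pairs with `r2 > threshold` are linked.
#' @return The pruned selection, with the per-category edge lists attached
#'   as attribute `edges`.
#' @export
prune_by_ld <- function(selection, genotypes, threshold = 0.7) {
  if (nrow(selection) == 0) {
    attr(selection, "edges") <- data.frame(category = character(),
                                           snp_a = character(),
                                           snp_b = character(),
                                           r2 = numeric())
    return(selection)
  }
  kept <- list()
  edge_tabs <- list()
  for (cat in unique(selection$category)) {
    sel <- selection[selection$category == cat, , drop = FALSE]
    edges <- ld_edges(genotypes, sel$snp_id, threshold)
    if (nrow(edges) > 0)
      edge_tabs[[cat]] <- cbind(category = cat, edges)
    g <- igraph::graph_from_data_frame(edges[, c("snp_a", "snp_b")],
                                       directed = FALSE,
                                       vertices = sel$snp_id)
    comp <- igraph::components(g)$membership[sel$snp_id]
    keep_rows <- unlist(lapply(split(seq_len(nrow(sel)), comp), function(i) {
      i[order(sel$p_value[i], sel$snp_id[i])[1]]
    }))
    kept[[cat]] <- sel[sort(keep_rows), , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$category, out$p_value, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "edges") <- if (length(edge_tabs) > 0)
    do.call(rbind, c(edge_tabs, list(make.row.names = FALSE)))
  else data.frame(category = character(), snp_a = character(),
                  snp_b = character(), r2 = numeric())
  out
}
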