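# Signed genetic risk scores and quartile sensitivity classes. Each selected
# SNP carries a sign taken from its screening coefficient: positive
# coefficient -> +1 for the diet categories, while the exercise category
# reverses the sign (a positive main effect there means exercise onset adds
# body fat, i.e. low exercise sensitivity). The per-individual score is the
# sign-weighted sum of minor-allele counts; quartiles of the population score
# distribution define the very-low / low / high / very-high classes.

#' Assign risk-allele signs to a selection
#'
#' CE/FE/TE: sign = +1 when the screening coefficient is positive, -1 when
#' negative. EE: reversed (+1 when negative). A coefficient of exactly zero
#' has no defined sign and raises an error.
#'
#' @param selection Selection table from [select_snps()] or [prune_by_ld()].
#' @return The selection with a `sign` column in \{-1, +1\}.
#' @export
assign_signs <- function(selection) {
  if (any(selection$coefficient == 0))
    stop("coefficient exactly zero; sign undefined for SNP(s): ",
         paste(selection$snp_id[selection$coefficient == 0], collapse = ", "))
  base_sign <- ifelse(selection$coefficient > 0, 1L, -1L)
  selection$sign <- ifelse(selection$category == "EE", -base_sign, base_sign)
  selection
}

#' Compute signed genetic risk scores
#'
#' For every category in the signed selection, each individual's score is
#' `sum(sign_i * count_i)` over the category's SNPs. A missing genotype
#' contributes its expected count `2 * maf` instead of the observed one, so
#' scores are integers exactly when no genotype is missing.
#'
#' @param genotypes A [genotype_matrix()].
#' @param selection Signed selection from [assign_signs()].
#' @return Long data frame with columns `individual`, `category`, `grs`.
#' @export
compute_grs <- function(genotypes, selection) {
  if (!"sign" %in% names(selection))
    stop("selection must be signed; call assign_signs() first")
  missing_snps <- setdiff(selection$snp_id, colnames(genotypes$counts))
  if (length(missing_snps) > 0)
    stop("selection SNP(s) absent from genotype matrix: ",
         paste(missing_snps, collapse = ", "))
  counts <- filled_counts(genotypes)
  ids <- rownames(counts)
  out <- lapply(unique(selection$category), function(cat) {
    sel <- selection[selection$category == cat, , drop = FALSE]
    score <- as.numeric(counts[, sel$snp_id, drop = FALSE] %*% sel$sign)
    data.frame(individual = ids, category = cat, grs = score)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Population quartile cutpoints of a score distribution
#'
#' The 25th, 50th and 75th percentiles, by default via linear interpolation
#' between order statistics (position `1 + p * (n - 1)`; `stats::quantile`
#' type 7). `method = "nearest"` uses the nearest-rank (type 1) definition
#' instead.
#'
#' @param grs Numeric score vector, length >= 4.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return Named numeric vector `c(q25, q50, q75)`.
#' @export
quartile_cutpoints <- function(grs, method = c("linear", "nearest")) {
  method <- match.arg(method)
  grs <- grs[!is.na(grs)]
  if (length(grs) < 4)
    stop("at least 4 scores are needed for quartile cutpoints")
  q <- quantile(grs, probs = c(0.25, 0.5, 0.75),
                type = if (method == "linear") 7 else 1, names = FALSE)
  setNames(q, c("q25", "q50", "q75"))
}

#' Classify scores into sensitivity classes
#'
#' `VL` below the 25th percentile; `L` from the 25th (inclusive) up to the
#' 50th; `H` from the 50th (inclusive) up to the 75th; `VH` at or above the
#' 75th. With degenerate cutpoints the upper rule wins (a score equal to all
#' three cutpoints is `VH`).
#'
#' @param grs Numeric score vector.
#' @param cuts Cutpoints from [quartile_cutpoints()].
#' @return Factor with levels `VL`, `L`, `H`, `VH`.
#' @export
classify_grs <- function(grs, cuts) {
  if (length(cuts) != 3 || is.unsorted(cuts))
    stop("cuts must be a non-decreasing (q25, q50, q75) vector")
  idx <- findInterval(grs, cuts)
  factor(CLASSES[idx + 1], levels = CLASSES)
}

#' Build per-individual sensitivity profiles
#'
#' Computes, for each category present in the signed selection, the
#' population quartile cutpoints (or uses supplied ones) and the class of
#' every individual. The result is the wide per-individual table of four
#' scores and four classes.
#'
#' @param grs Long score table from [compute_grs()].
#' @param cutpoints Optional named list of per-category cutpoints (as from
#'   [quartile_cutpoints()]); when omitted they are computed from `grs`
#'   itself, i.e. the population being classified. Supplying stored
#'   cutpoints classifies new individuals against a reference population.
#' @param method Percentile method, see [quartile_cutpoints()].
#' @return List with `profiles` (wide data frame: `individual`, then
#'   `<cat>_grs` and `<cat>_class` per category) and `cutpoints` (named list).
#' @export
sensitivity_profiles <- function(grs, cutpoints = NULL,
                                 method = c("linear", "nearest")) {
  method <- match.arg(method)
  cats <- intersect(CATEGORIES, unique(grs$category))
  if (length(cats) == 0) stop("no categories in score table")
  ids <- unique(grs$individual)
  profiles <- data.frame(individual = ids)
  cuts_out <- list()
  for (cat in cats) {
    d <- grs[grs$category == cat, , drop = FALSE]
    cuts <- if (!is.null(cutpoints)) {
      if (is.null(cutpoints[[cat]]))
        stop("no stored cutpoints for category ", cat)
      cutpoints[[cat]]
    } else {
      quartile_cutpoints(d$grs, method = method)
    }
    cuts_out[[cat]] <- cuts
    idx <- match(ids, d$individual)
    profiles[[paste0(cat, "_grs")]] <- d$grs[idx]
    profiles[[paste0(cat, "_class")]] <- classify_grs(d$grs[idx], cuts)
  }
  list(profiles = profiles, cutpoints = cuts_out)
}
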