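# Plain-text IO for the pipeline's tables: tab-delimited UTF-8, single header
# row, missing values written as "NA". Numeric columns are printed with "%.17g"
# so a write/read round trip reproduces every double exactly.

COHORT_COLUMNS <- c("individual", "wave", "gender", "age", "carb_g", "fat_g",
                    "kcal", "bodyfat_kg", "bmi", "exercise")

#' Construct a genotype matrix object
#'
#' Bundles an individuals-by-SNPs matrix of additive minor-allele counts
#' (0/1/2, `NA` for missing) with per-SNP metadata. This is the container all
#' screening, LD and scoring steps operate on.
#'
#' @param counts Numeric matrix, rows = individuals (rownames are ids),
#'   columns = SNPs (colnames are SNP ids); entries in `{0, 1, 2, NA}`.
#' @param snps Data frame with columns `snp_id`, `gene`, `maf` matching the
#'   columns of `counts`. `maf` must lie in (0, 0.5].
#' @return An object of class `genotype_matrix`: a list with elements
#'   `counts` and `snps`.
#' @export
genotype_matrix <- function(counts, snps) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs individual rownames and SNP colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate individual ids in genotype matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate SNP ids in genotype matrix")
  snps <- as.data.frame(snps)
  required <- c("snp_id", "gene", "maf")
  if (!all(required %in% names(snps)))
    stop("`snps` must have columns snp_id, gene, maf")
  if (!identical(as.character(snps$snp_id), colnames(counts)))
    stop("`snps$snp_id` must match colnames(counts) in order")
  if (any(!is.finite(snps$maf)) || any(snps$maf <= 0) || any(snps$maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  bad <- !is.na(counts) & !(counts %in% c(0, 1, 2))
  if (any(bad)) stop("genotype counts must be 0, 1, 2 or NA")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d missing calls)\n",
              nrow(x$counts), ncol(x$counts), sum(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Read a wide genotype table
#'
#' Reads a tab-delimited table with one row per individual: first column
#' `individual`, remaining columns named by SNP id and holding additive
#' minor-allele counts. Cells outside `{0, 1, 2}` (including non-numeric text)
#' are set to missing; the number of such cells is attached as attribute
#' `n_invalid` and reported through a warning.
#'
#' @param path Path to the TSV file.
#' @param panel Optional SNP metadata data frame (`snp_id`, `gene`, `maf`) as
#'   read by [read_panel()]. When omitted, `gene` is set to "intergenic" and
#'   `maf` to the empirical minor-allele frequency (folded at 0.5).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = "NA")
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop("genotype file is empty or has no SNP columns: ", path)
  if (names(raw)[1] != "individual")
    stop("first column of a genotype table must be `individual`")
  ids <- raw$individual
  if (anyDuplicated(ids)) stop("duplicate individual id in ", path)
  cells <- as.matrix(raw[, -1, drop = FALSE])
  counts <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                    dimnames = list(ids, colnames(cells))))
  invalid <- (!is.na(cells)) & (is.na(counts) | !(counts %in% c(0, 1, 2)))
  n_invalid <- sum(invalid)
  counts[invalid] <- NA_real_
  if (n_invalid > 0)
    warning(sprintf("%d genotype cell(s) outside {0,1,2} set to missing",
                    n_invalid))
  if (is.null(panel)) {
    p_hat <- colMeans(counts, na.rm = TRUE) / 2
    p_hat <- pmin(pmax(ifelse(is.nan(p_hat), 0.5, p_hat), 1e-6), 1 - 1e-6)
    maf <- pmin(p_hat, 1 - p_hat)
    snps <- data.frame(snp_id = colnames(counts), gene = "intergenic",
                       maf = as.numeric(maf))
  } else {
    panel <- as.data.frame(panel)
    missing_meta <- setdiff(colnames(counts), panel$snp_id)
    if (length(missing_meta) > 0)
      stop("panel lacks metadata for SNPs: ",
           paste(utils::head(missing_meta, 5), collapse = ", "))
    snps <- panel[match(colnames(counts), panel$snp_id),
                  c("snp_id", "gene", "maf")]
    rownames(snps) <- NULL
  }
  gm <- genotype_matrix(counts, snps)
  attr(gm, "n_invalid") <- n_invalid
  gm
}

#' Read a SNP panel file
#'
#' @param path TSV with columns `snp_id`, `gene`, `maf`.
#' @return Data frame of SNP metadata with unique ids and maf in (0, 0.5].
#' @export
read_panel <- function(path) {
  panel <- read.delim(path, check.names = FALSE, na.strings = "NA")
  required <- c("snp_id", "gene", "maf")
  if (!all(required %in% names(panel)))
    stop("panel file must have columns snp_id, gene, maf")
  if (anyDuplicated(panel$snp_id)) stop("duplicate snp_id in panel")
  if (any(!is.finite(panel$maf)) || any(panel$maf <= 0) || any(panel$maf > 0.5))
    stop("panel maf must lie in (0, 0.5]")
  panel
}

#' Read a longitudinal cohort table
#'
#' Long-format table with one row per individual per survey wave. Exercise
#' status is coded 1 = no, 2 = yes (missing allowed); gender is coded
#' 0 = male, 1 = female. Waves need not be contiguous per individual.
#'
#' @param path Path to the TSV file with columns `individual`, `wave`,
#'   `gender`, `age`, `carb_g`, `fat_g`, `kcal`, `bodyfat_kg`, `bmi`,
#'   `exercise`.
#' @return A validated data frame (class `cohort`).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cohort <- read.delim(path, check.names = FALSE, na.strings = "NA")
  as_cohort(cohort)
}

#' Validate a longitudinal cohort data frame
#'
#' @param cohort Data frame with the columns listed in [read_cohort()].
#' @return The validated data frame with class `cohort` prepended.
#' @export
as_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cohort[c("individual", "wave")]))
    stop("duplicate (individual, wave) record in cohort")
  for (col in c("carb_g", "fat_g", "kcal", "bodyfat_kg", "bmi", "exercise"))
    if (is.logical(cohort[[col]]) && all(is.na(cohort[[col]])))
      cohort[[col]] <- as.numeric(cohort[[col]])  # all-NA column read back
  ex <- cohort$exercise
  if (!is.numeric(ex) || any(!is.na(ex) & !(ex %in% c(1, 2))))
    stop("exercise status must be coded 1 (no), 2 (yes) or NA")
  for (col in c("carb_g", "fat_g", "kcal", "bodyfat_kg")) {
    v <- cohort[[col]]
    if (!is.numeric(v)) stop(col, " must be numeric")
    if (any(!is.na(v) & v < 0)) stop("negative ", col, " in cohort table")
  }
  if (!inherits(cohort, "cohort")) class(cohort) <- c("cohort", class(cohort))
  cohort
}

#' Write a result table as tab-delimited text
#'
#' Writes with a single header row, tab separator, `NA` for missing, and
#' doubles printed with 17 significant digits so re-reading reproduces them
#' exactly.
#'
#' @param records Non-empty data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  if (is.null(records) || !is.data.frame(records) || nrow(records) == 0)
    stop("refusing to write an empty table to ", path)
  out <- as.data.frame(records)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- out[[col]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[col]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a genotype matrix as a wide TSV
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  tab <- data.frame(individual = rownames(genotypes$counts),
                    genotypes$counts, check.names = FALSE)
  write_table(tab, path)
}

#' Read genotypes from a VCF file
#'
#' Maps VCF genotypes to additive minor-allele counts. The panel decides which
#' allele is minor: when the panel's `minor_allele` matches the record's REF
#' allele, the ALT dosage is flipped (count = 2 - ALT dosage); otherwise the
#' ALT dosage is used directly. Requires the `vcfR` package.
#'
#' @param path Path to a VCF 4.x file.
#' @param panel Panel data frame with columns `snp_id`, `gene`, `maf` and
#'   `minor_allele` (single base).
#' @return A [genotype_matrix()] restricted to panel SNPs present in the VCF.
#' @export
read_genotypes_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf() requires the vcfR package")
  if (!"minor_allele" %in% names(panel))
    stop("panel must carry a `minor_allele` column for VCF ingestion")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  keep <- which(fix$ID %in% panel$snp_id)
  if (length(keep) == 0) stop("no panel SNPs found in VCF ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  alt_dose <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  counts <- t(apply(gt, 1:2, alt_dose))  # individuals x snps
  meta <- panel[match(fix$ID[keep], panel$snp_id), ]
  flip <- meta$minor_allele == fix$REF[keep]
  counts[, flip] <- 2 - counts[, flip, drop = FALSE]
  colnames(counts) <- fix$ID[keep]
  genotype_matrix(counts, meta[, c("snp_id", "gene", "maf")])
}
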