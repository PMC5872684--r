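# Per-SNP gene-environment screening. Three Gaussian linear models are fit by
# ordinary least squares per SNP (the classic gaussian-family GLM), with
# two-sided t tests on each coefficient:
#
#   model 1 (diet):     d_bodyfat ~ gender + age + d_kcal + snp + d_carb +
#                                   d_fat + d_carb:snp + d_fat:snp
#   model 2 (calorie):  d_bodyfat ~ gender + age + d_kcal + snp + d_kcal:snp
#   model 3 (exercise): d_bodyfat_star ~ gender + age + snp
#
# The carbohydrate and fat interaction terms of model 1 feed the CE and FE
# categories, the calorie interaction of model 2 feeds TE, and the SNP main
# effect of model 3 feeds EE.

TARGET_TERMS <- c(CE = "carb_x_snp", FE = "fat_x_snp",
                  TE = "kcal_x_snp", EE = "snp")
TARGET_MODEL <- c(CE = 1L, FE = 1L, TE = 2L, EE = 3L)

#' Ordinary least squares with per-term t tests
#'
#' Fits `response ~ design` without an implicit intercept (include an
#' intercept column in the design if wanted). Standard errors come from the
#' unbiased residual variance and p-values from a two-sided t distribution
#' with `n - p` degrees of freedom. Rank-deficient designs are rejected with
#' an error naming the collinear columns.
#'
#' @param design Numeric matrix with named columns; rows are complete cases.
#' @param response Numeric vector, `length(response) == nrow(design)`.
#' @return Data frame with columns `term`, `estimate`, `se`, `p_value` and
#'   attribute `n` (rows used) and `sigma` (residual SD).
#' @export
fit_ols <- function(design, response) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  if (nrow(X) != length(y)) stop("design and response sizes differ")
  if (anyNA(X) || anyNA(y)) stop("fit_ols expects complete cases")
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (n <= p)
    stop(sprintf("insufficient observations: n = %d with %d terms", n, p))
  qx <- qr(X)
  if (qx$rank < p) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  dat <- data.frame(.response = y, X, check.names = FALSE)
  fit <- stats::lm(.response ~ . - 1, data = dat)
  sm <- summary(fit)$coefficients
  term <- sub("^`(.*)`$", "\\1", rownames(sm))
  out <- data.frame(term = term,
                    estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    p_value = sm[, "Pr(>|t|)"])
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "sigma") <- summary(fit)$sigma
  out
}

snp_column <- function(genotypes, snp_id) {
  if (!snp_id %in% colnames(genotypes$counts))
    stop("SNP not in genotype matrix: ", snp_id)
  genotypes$counts[, snp_id]
}

fit_snp_model <- function(deltas, genotypes, snp_id, model) {
  g <- snp_column(genotypes, snp_id)
  idx <- match(deltas$individual, names(g))
  if (anyNA(idx))
    stop("individuals in delta table missing from genotype matrix")
  snp <- as.numeric(g[idx])
  if (model == 1L) {
    df <- data.frame(y = deltas$d_bodyfat, gender = deltas$gender,
                     age = deltas$age, d_kcal = deltas$d_kcal, snp = snp,
                     d_carb = deltas$d_carb, d_fat = deltas$d_fat)
    df <- df[complete.cases(df), , drop = FALSE]
    X <- cbind(intercept = 1, gender = df$gender, age = df$age,
               d_kcal = df$d_kcal, snp = df$snp, d_carb = df$d_carb,
               d_fat = df$d_fat, carb_x_snp = df$d_carb * df$snp,
               fat_x_snp = df$d_fat * df$snp)
  } else if (model == 2L) {
    df <- data.frame(y = deltas$d_bodyfat, gender = deltas$gender,
                     age = deltas$age, d_kcal = deltas$d_kcal, snp = snp)
    df <- df[complete.cases(df), , drop = FALSE]
    X <- cbind(intercept = 1, gender = df$gender, age = df$age,
               d_kcal = df$d_kcal, snp = df$snp,
               kcal_x_snp = df$d_kcal * df$snp)
  } else {
    if (!"d_bodyfat_star" %in% names(deltas))
      stop("model 3 needs the exercise delta table (d_bodyfat_star)")
    df <- data.frame(y = deltas$d_bodyfat_star, gender = deltas$gender,
                     age = deltas$age, snp = snp)
    df <- df[complete.cases(df), , drop = FALSE]
    X <- cbind(intercept = 1, gender = df$gender, age = df$age, snp = df$snp)
  }
  res <- fit_ols(X, df$y)
  targets <- names(TARGET_TERMS)[TARGET_MODEL == model]
  res$target <- NA_character_
  for (cat in targets) res$target[res$term == TARGET_TERMS[cat]] <- cat
  cbind(snp_id = snp_id, model = model, res,
        n = attr(res, "n"))
}

#' Fit the diet interaction model for one SNP
#'
#' Model 1: body-fat change regressed on gender, age, total calorie change,
#' SNP allele count, carbohydrate change, fat change and the carbohydrate and
#' fat interaction terms (9 coefficients including the intercept), on complete
#' cases. The interaction terms are the CE and FE targets.
#'
#' @param deltas Diet delta table from [compute_diet_deltas()].
#' @param genotypes A [genotype_matrix()].
#' @param snp_id SNP to test.
#' @return Data frame of per-term estimates, SEs and p-values; target rows
#'   are labelled in column `target`.
#' @export
fit_model_diet <- function(deltas, genotypes, snp_id)
  fit_snp_model(deltas, genotypes, snp_id, 1L)

#' Fit the total-calorie interaction model for one SNP
#'
#' Model 2: body-fat change on gender, age, total calorie change, SNP count
#' and the calorie-by-SNP interaction (6 coefficients); the interaction is
#' the TE target.
#'
#' @inheritParams fit_model_diet
#' @return As [fit_model_diet()].
#' @export
fit_model_calorie <- function(deltas, genotypes, snp_id)
  fit_snp_model(deltas, genotypes, snp_id, 2L)

#' Fit the exercise main-effect model for one SNP
#'
#' Model 3: orientation-normalized exercise body-fat delta on gender, age and
#' SNP count (4 coefficients); the SNP main effect is the EE target.
#'
#' @param deltas Exercise delta table from [compute_exercise_delta()].
#' @inheritParams fit_model_diet
#' @return As [fit_model_diet()].
#' @export
fit_model_exercise <- function(deltas, genotypes, snp_id)
  fit_snp_model(deltas, genotypes, snp_id, 3L)

#' Screen every panel SNP with the three models
#'
#' Runs models 1 and 2 on the diet delta table and model 3 on the exercise
#' delta table for every SNP in the genotype matrix. SNPs with fewer than
#' `min_carriers` minor-allele carriers among the relevant complete cases
#' are skipped (near-monomorphic fits are unstable); skipped SNPs are listed
#' in attribute `skipped` with a reason.
#'
#' @param genotypes A [genotype_matrix()].
#' @param diet_deltas Diet delta table, or `NULL` to skip models 1-2.
#' @param exercise_deltas Exercise delta table, or `NULL` to skip model 3.
#' @param min_carriers Minimum number of carriers (count > 0).
#' @return Data frame of stacked per-term fit results.
#' @export
screen_snps <- function(genotypes, diet_deltas = NULL,
                        exercise_deltas = NULL, min_carriers = 5) {
  if (is.null(diet_deltas) && is.null(exercise_deltas))
    stop("at least one delta table is required")
  fits <- list()
  skipped <- list()
  for (snp_id in colnames(genotypes$counts)) {
    g <- genotypes$counts[, snp_id]
    carriers <- sum(g > 0, na.rm = TRUE)
    if (carriers < min_carriers) {
      skipped[[snp_id]] <- data.frame(
        snp_id = snp_id,
        reason = sprintf("only %d minor-allele carrier(s)", carriers))
      next
    }
    if (!is.null(diet_deltas)) {
      fits[[paste0(snp_id, "_1")]] <-
        fit_model_diet(diet_deltas, genotypes, snp_id)
      fits[[paste0(snp_id, "_2")]] <-
        fit_model_calorie(diet_deltas, genotypes, snp_id)
    }
    if (!is.null(exercise_deltas))
      fits[[paste0(snp_id, "_3")]] <-
        fit_model_exercise(exercise_deltas, genotypes, snp_id)
  }
  out <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
  if (is.null(out))
    stop("no SNP could be tested (all skipped)")
  attr(out, "skipped") <- if (length(skipped) > 0)
    do.call(rbind, c(skipped, list(make.row.names = FALSE)))
  else data.frame(snp_id = character(), reason = character())
  out
}

#' Select SNPs per category at a p-value threshold
#'
#' A SNP enters a category when its target term's p-value is strictly below
#' `alpha`: CE from the carbohydrate interaction of model 1, FE from the fat
#' interaction of model 1, TE from the calorie interaction of model 2, EE
#' from the SNP main effect of model 3. A SNP may appear in several
#' categories. Optionally, p-values are Benjamini-Hochberg adjusted within
#' each category before thresholding.
#'
#' @param fits Stacked fit results from [screen_snps()] (or the per-SNP
#'   fitters).
#' @param alpha Selection threshold (strict inequality). Default 0.05.
#' @param adjust `"none"` (default, the raw-threshold rule) or `"BH"`.
#' @return Data frame with columns `category`, `snp_id`, `coefficient`,
#'   `p_value`, ordered by category then p-value.
#' @export
select_snps <- function(fits, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  targets <- fits[!is.na(fits$target), , drop = FALSE]
  picks <- lapply(CATEGORIES, function(cat) {
    d <- targets[targets$target == cat, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    p_sel <- if (adjust == "BH") stats::p.adjust(d$p_value, "BH") else d$p_value
    d <- d[p_sel < alpha, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(category = cat, snp_id = d$snp_id,
               coefficient = d$estimate, p_value = d$p_value)
  })
  out <- do.call(rbind, picks)
  if (is.null(out))
    out <- data.frame(category = character(), snp_id = character(),
                      coefficient = numeric(), p_value = numeric())
  out <- out[order(out$category, out$p_value, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
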