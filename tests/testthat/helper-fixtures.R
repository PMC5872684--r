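# Shared fixture builders and the independent OLS oracle.

# Normal-equations + t-distribution oracle, deliberately independent of the
# package's QR-based lm route.
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  n <- nrow(X)
  p <- ncol(X)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- as.numeric(beta) / se
  data.frame(term = colnames(X),
             estimate = as.numeric(beta),
             se = as.numeric(se),
             p_value = 2 * pt(-abs(tval), n - p))
}

# small genotype matrix from an explicit count matrix
make_genotypes <- function(counts, maf = NULL) {
  n <- nrow(counts)
  p <- ncol(counts)
  rownames(counts) <- sprintf("ind_%05d", seq_len(n))
  colnames(counts) <- sprintf("snp_%03d", seq_len(p))
  if (is.null(maf)) {
    maf <- pmin(pmax(colMeans(counts, na.rm = TRUE) / 2, 0.01), 0.5)
  }
  genotype_matrix(counts, data.frame(snp_id = colnames(counts),
                                     gene = "intergenic", maf = maf))
}

# one-individual exercise cohort from (status, bodyfat) wave vectors
make_exercise_cohort <- function(status, bodyfat, waves = seq_along(status),
                                 id = "ind_00001") {
  as_cohort(data.frame(
    individual = id, wave = waves, gender = 0, age = 50,
    carb_g = NA_real_, fat_g = NA_real_, kcal = NA_real_,
    bodyfat_kg = bodyfat, bmi = NA_real_, exercise = status))
}

# two-wave diet cohort from per-individual deltas (baseline values fixed)
make_diet_cohort <- function(d_carb, d_fat, d_kcal, d_bodyfat,
                             gender = NULL, age = NULL) {
  n <- length(d_carb)
  ids <- sprintf("ind_%05d", seq_len(n))
  if (is.null(gender)) gender <- rep(0, n)
  if (is.null(age)) age <- rep(50, n)
  base <- data.frame(individual = ids, wave = 1L, gender = gender, age = age,
                     carb_g = pmax(300, -d_carb), fat_g = pmax(40, -d_fat),
                     kcal = pmax(2000, -d_kcal),
                     bodyfat_kg = pmax(18, 0.1 - d_bodyfat),
                     bmi = 24, exercise = NA_real_)
  fup <- base
  fup$wave <- 2L
  fup$carb_g <- base$carb_g + d_carb
  fup$fat_g <- base$fat_g + d_fat
  fup$kcal <- base$kcal + d_kcal
  fup$bodyfat_kg <- base$bodyfat_kg + d_bodyfat
  as_cohort(rbind(base, fup))
}
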