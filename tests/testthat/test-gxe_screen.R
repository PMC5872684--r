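test_that("fit_ols reproduces exact relationships and rejects bad designs", {
  x <- 1:10
  X <- cbind(intercept = 1, x = x)
  res <- fit_ols(X, 2 * x)
  expect_equal(res$estimate[res$term == "x"], 2)
  expect_equal(attr(res, "sigma"), 0, tolerance = 1e-12)

  expect_error(fit_ols(cbind(intercept = 1, a = x, b = 2 * x), rnorm(10)),
               "collinear term\\(s\\): b")
  expect_error(fit_ols(X[1:2, ], c(1, 2)), "insufficient observations")
})

test_that("fit_ols agrees with the normal-equations oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(30:120, 1)
    X <- cbind(intercept = 1, g = rbinom(n, 1, 0.5), a = rnorm(n, 50, 8),
               s = rbinom(n, 2, 0.3))
    y <- rnorm(n, -0.4, 2)
    got <- fit_ols(X, y)
    want <- oracle_ols(X, y)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

planted_fixture <- function(n = 200, seed = 17, beta_c = 0, beta_f = 0,
                            beta_tc = 0) {
  set.seed(seed)
  counts <- matrix(rbinom(n * 2, 2, 0.3), n, 2)
  g <- make_genotypes(counts)
  d_carb <- rnorm(n, -18, 130)
  d_fat <- rnorm(n, -5, 22)
  d_kcal <- 4 * d_carb + 9 * d_fat + rnorm(n, 0, 500)
  snp <- counts[, 1]
  d_bodyfat <- -0.4 + beta_c * d_carb * snp + beta_f * d_fat * snp +
    beta_tc * d_kcal * snp
  cohort <- make_diet_cohort(d_carb, d_fat, d_kcal, pmax(d_bodyfat, -15),
                             gender = rbinom(n, 1, 0.5),
                             age = rnorm(n, 50, 8))
  list(genotypes = g, deltas = compute_diet_deltas(cohort))
}

test_that("planted diet coefficients are recovered exactly under zero noise", {
  fx <- planted_fixture(beta_c = 0.01, beta_f = -0.02)
  fit <- fit_model_diet(fx$deltas, fx$genotypes, "snp_001")
  expect_equal(fit$estimate[fit$term == "carb_x_snp"], 0.01,
               tolerance = 1e-10)
  expect_equal(fit$estimate[fit$term == "fat_x_snp"], -0.02,
               tolerance = 1e-10)
  expect_equal(fit$target[fit$term == "carb_x_snp"], "CE")
  expect_equal(fit$target[fit$term == "fat_x_snp"], "FE")
  expect_equal(nrow(fit), 9)

  fx2 <- planted_fixture(beta_tc = 0.0005, seed = 18)
  fit2 <- fit_model_calorie(fx2$deltas, fx2$genotypes, "snp_001")
  expect_equal(fit2$estimate[fit2$term == "kcal_x_snp"], 0.0005,
               tolerance = 1e-10)
  expect_equal(nrow(fit2), 6)
})

test_that("the exercise model recovers a planted main effect exactly", {
  set.seed(19)
  n <- 150
  counts <- matrix(rbinom(n * 2, 2, 0.4), n, 2)
  g <- make_genotypes(counts)
  gender <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 55, 8)
  deltas <- data.frame(individual = rownames(g$counts),
                       gender = gender, age = age,
                       d_bodyfat_star = -0.1 - 0.14 * g$counts[, 1],
                       n_transitions = 1L, n_onsets = 1L)
  fit <- fit_model_exercise(deltas, g, "snp_001")
  expect_equal(fit$estimate[fit$term == "snp"], -0.14, tolerance = 1e-10)
  expect_equal(fit$target[fit$term == "snp"], "EE")
  expect_equal(nrow(fit), 4)
  expect_error(fit_model_exercise(deltas[1:3, ], g, "snp_001"),
               "insufficient")
})

test_that("fits are complete-case: missing genotypes reduce n", {
  fx <- planted_fixture(n = 120, seed = 20)
  g <- fx$genotypes
  g$counts[1:10, "snp_001"] <- NA
  fit <- fit_model_diet(fx$deltas, g, "snp_001")
  expect_equal(unique(fit$n), 110)
})

test_that("a monomorphic SNP is rejected by the fit and skipped in screening", {
  fx <- planted_fixture(n = 80, seed = 23)
  g <- fx$genotypes
  g$counts[, "snp_002"] <- 0
  g$counts[1, "snp_002"] <- 1  # a single carrier
  expect_error(fit_ols(cbind(intercept = 1,
                             snp = rep(0, 80)), fx$deltas$d_bodyfat),
               "collinear")
  fits <- screen_snps(g, fx$deltas)
  skipped <- attr(fits, "skipped")
  expect_equal(skipped$snp_id, "snp_002")
  expect_match(skipped$reason, "1 minor-allele carrier")
  expect_false("snp_002" %in% fits$snp_id)
})

test_that("permuting genotypes destroys a planted exercise signal", {
  set.seed(29)
  n <- 400
  g <- make_genotypes(matrix(rbinom(n, 2, 0.3), n, 1))
  deltas <- data.frame(individual = rownames(g$counts),
                       gender = rbinom(n, 1, 0.5), age = rnorm(n, 55, 8),
                       d_bodyfat_star = -0.5 * g$counts[, 1] + rnorm(n, 0, 1),
                       n_transitions = 1L, n_onsets = 1L)
  fit <- fit_model_exercise(deltas, g, "snp_001")
  expect_lt(fit$p_value[fit$term == "snp"], 1e-6)
  pvals <- replicate(30, {
    gp <- g
    gp$counts[, 1] <- sample(gp$counts[, 1])
    f <- fit_model_exercise(deltas, gp, "snp_001")
    f$p_value[f$term == "snp"]
  })
  expect_gt(median(pvals), 0.05)
})

test_that("selection uses a strict threshold per category", {
  fits <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs1"),
                     model = c(1L, 1L, 1L, 2L),
                     term = c("carb_x_snp", "carb_x_snp", "carb_x_snp",
                              "kcal_x_snp"),
                     estimate = c(0.006, -0.001, 0.002, 0.0005),
                     se = 0.001, p_value = c(0.04, 0.06, 0.05, 0.02),
                     target = c("CE", "CE", "CE", "TE"), n = 100L)
  sel <- select_snps(fits, alpha = 0.05)
  expect_equal(sel$snp_id[sel$category == "CE"], "rs1")  # 0.05 excluded
  expect_equal(sel$snp_id[sel$category == "TE"], "rs1")  # both categories
  expect_equal(nrow(sel), 2)

  sel_bh <- select_snps(fits, alpha = 0.05, adjust = "BH")
  expect_lte(nrow(sel_bh), nrow(sel))
})
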