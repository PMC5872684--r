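test_that("configuration is validated", {
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(maf_range = c(0, 0.3)), "maf_range")
  expect_error(sim_config(exercise_p_transition = 1.5), "exercise_p_transition")
  expect_error(sim_config(effects = data.frame(snp_id = "snp_001",
                                               category = "XX",
                                               effect = 1)),
               "category")
})

test_that("generators are deterministic given the configuration", {
  cfg <- sim_config(n_individuals = 60, n_snps = 8, seed = 99,
                    effects = data.frame(snp_id = "snp_002",
                                         category = "CE", effect = 0.01))
  g1 <- generate_genotypes(cfg)
  g2 <- generate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_identical(generate_diet_outcomes(cfg, g1),
                   generate_diet_outcomes(cfg, g2))
  expect_identical(generate_exercise_series(cfg, g1),
                   generate_exercise_series(cfg, g2))
})

test_that("genotypes follow Hardy-Weinberg expectations", {
  cfg <- sim_config(n_individuals = 10000, n_snps = 5,
                    maf_range = c(0.3, 0.3), seed = 4)
  g <- generate_genotypes(cfg)
  expect_true(all(g$counts %in% 0:2))
  # mean count per SNP = 2 * maf within 3 binomial standard errors
  se3 <- 3 * sqrt(2 * 0.3 * 0.7 / 10000)
  expect_true(all(abs(colMeans(g$counts) - 0.6) < se3))
  # genotype frequencies close to (q^2, 2pq, p^2)
  freq <- table(factor(g$counts[, 1], levels = 0:2)) / 10000
  expect_lt(max(abs(freq - c(0.49, 0.42, 0.09))), 0.02)
})

test_that("LD blocks reproduce the requested genotype correlation", {
  cfg <- sim_config(n_individuals = 4000, n_snps = 6, maf_range = c(0.25, 0.4),
                    ld_n_blocks = 2, ld_block_size = 3, ld_block_r = 1,
                    seed = 21)
  g <- generate_genotypes(cfg)
  expect_equal(cor(g$counts[, 1], g$counts[, 2]), 1)
  expect_equal(cor(g$counts[, 1], g$counts[, 3]), 1)
  cfg2 <- sim_config(n_individuals = 20000, n_snps = 2, maf_range = c(0.3, 0.3),
                     ld_n_blocks = 1, ld_block_size = 2, ld_block_r = 0.8,
                     seed = 22)
  g2 <- generate_genotypes(cfg2)
  expect_lt(abs(cor(g2$counts[, 1], g2$counts[, 2]) - 0.8), 0.03)
})

test_that("diet outcomes realise the configured linear predictor", {
  # no effects, no noise: the body-fat change is the intercept everywhere
  cfg0 <- sim_config(n_individuals = 50, n_snps = 3, bodyfat_noise_sd = 0,
                     seed = 5)
  g0 <- generate_genotypes(cfg0)
  d0 <- compute_diet_deltas(generate_diet_outcomes(cfg0, g0))
  expect_equal(d0$d_bodyfat, rep(cfg0$bodyfat_intercept, 50))

  # planted CE interaction, no noise: exact closed-form predictor
  cfg <- sim_config(n_individuals = 80, n_snps = 3, bodyfat_noise_sd = 0,
                    seed = 6,
                    effects = data.frame(snp_id = "snp_002",
                                         category = "CE", effect = 0.01))
  g <- generate_genotypes(cfg)
  d <- compute_diet_deltas(generate_diet_outcomes(cfg, g))
  count <- g$counts[d$individual, "snp_002"]
  expect_equal(d$d_bodyfat - cfg$bodyfat_intercept,
               unname(0.01 * d$d_carb * count))
})

test_that("default intake-change moments match the target cohort", {
  cfg <- sim_config(n_individuals = 4293, n_snps = 2, seed = 8)
  g <- generate_genotypes(cfg)
  d <- compute_diet_deltas(generate_diet_outcomes(cfg, g))
  expect_lt(abs(mean(d$d_carb) - (-18.4)), 3 * 132.38 / sqrt(4293))
  expect_lt(abs(mean(d$d_fat) - (-4.71)), 3 * 22.1 / sqrt(4293))
  expect_lt(abs(mean(d$d_kcal) - (-147.12)), 3 * 758.94 / sqrt(4293))
  expect_lt(abs(sd(d$d_kcal) - 758.94), 50)
  expect_lt(abs(mean(d$d_bodyfat) - (-0.42)), 3 * 2.57 / sqrt(4293))
})

test_that("exercise chains honour the transition probability", {
  changes_per_ind <- function(cfg) {
    g <- generate_genotypes(cfg)
    co <- generate_exercise_series(cfg, g)
    sapply(split(co, co$individual), function(d) {
      s <- d$exercise[order(d$wave)]
      sum(s[-1] != s[-length(s)])
    })
  }
  cfg0 <- sim_config(n_individuals = 40, n_snps = 2,
                     exercise_p_transition = 0, seed = 9)
  expect_true(all(changes_per_ind(cfg0) == 0))
  cfg1 <- sim_config(n_individuals = 40, n_snps = 2,
                     exercise_p_transition = 1, seed = 9)
  expect_true(all(changes_per_ind(cfg1) == 4))
})

test_that("planted exercise effects appear exactly in the oriented delta", {
  cfg <- sim_config(n_individuals = 100, n_snps = 2,
                    exercise_p_transition = 1, exercise_noise_sd = 0,
                    exercise_mean_effect = 0, seed = 10,
                    effects = data.frame(snp_id = "snp_001",
                                         category = "EE", effect = -0.5))
  g <- generate_genotypes(cfg)
  ed <- compute_exercise_delta(generate_exercise_series(cfg, g))
  count <- g$counts[ed$individual, "snp_001"]
  expect_equal(ed$d_bodyfat_star, unname(-0.5 * count))
})

test_that("planted effects must reference panel SNPs", {
  cfg <- sim_config(n_individuals = 20, n_snps = 2, seed = 1,
                    effects = data.frame(snp_id = "snp_999",
                                         category = "CE", effect = 0.01))
  g <- generate_genotypes(cfg)
  expect_error(generate_diet_outcomes(cfg, g), "unknown SNP")
})
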