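test_that("responder subsets take the largest reductions or exercise onset", {
  deltas <- data.frame(individual = c("a", "b", "c", "d"),
                       gender = 0, age = 50,
                       d_bodyfat = 0, d_carb = c(-100, -50, 0, 50),
                       d_fat = 0, d_kcal = 0)
  # 25th percentile of {-100,-50,0,50} is -62.5; only a lies strictly below
  expect_equal(responder_subset(deltas, "CE"), "a")
  deltas$d_fat <- rep(5, 4)
  expect_warning(empty <- responder_subset(deltas, "FE"), "empty responder")
  expect_length(empty, 0)

  ex <- data.frame(individual = c("a", "b"), gender = 0, age = 50,
                   d_bodyfat_star = c(-1, 1), n_transitions = c(1L, 1L),
                   n_onsets = c(1L, 0L))
  expect_equal(responder_subset(ex, "EE"), "a")
  expect_error(responder_subset(deltas, "EE"), "n_onsets")
})

eval_fixture <- function() {
  deltas <- data.frame(individual = sprintf("i%02d", 1:12), gender = 0,
                       age = 50,
                       d_bodyfat = c(1, 1, 0, 0, -1, -1, -2, -2, -3, -3, 0, 0),
                       d_carb = -100, d_fat = -10, d_kcal = -400)
  profiles <- data.frame(individual = deltas$individual,
                         CE_grs = rep(c(-3, -1, 1, 3), each = 3),
                         CE_class = factor(rep(c("VL", "L", "H", "VH"),
                                               each = 3),
                                           levels = c("VL", "L", "H", "VH")))
  list(deltas = deltas, profiles = profiles)
}

test_that("group means summarise each class over the responder subset", {
  fx <- eval_fixture()
  gm <- group_means(fx$deltas$individual, fx$profiles, fx$deltas, "CE")
  expect_equal(gm$n, rep(3L, 4))
  expect_equal(sum(gm$n), nrow(fx$deltas))
  expect_equal(gm$mean_change,
               c(mean(c(1, 1, 0)), mean(c(0, -1, -1)), mean(c(-2, -2, -3)),
                 mean(c(-3, 0, 0))))
  # a subset confined to one class leaves the others empty
  gm1 <- group_means(fx$deltas$individual[1:3], fx$profiles, fx$deltas, "CE")
  expect_equal(gm1$n, c(3L, 0L, 0L, 0L))
  expect_true(all(is.na(gm1$mean_change[-1])))
  # invariant to row order
  shuffled <- fx$deltas[c(7, 2, 11, 4, 1, 12, 3, 9, 5, 10, 6, 8), ]
  gm2 <- group_means(shuffled$individual, fx$profiles, shuffled, "CE")
  expect_equal(gm2, gm)
})

test_that("trend statistic captures monotone class effects", {
  deltas <- data.frame(individual = sprintf("i%02d", 1:8), gender = 0,
                       age = 50, d_bodyfat = rep(c(2, 1, 0, -1), each = 2),
                       d_carb = -100, d_fat = -10, d_kcal = -400)
  profiles <- data.frame(individual = deltas$individual,
                         CE_class = factor(rep(c("VL", "L", "H", "VH"),
                                               each = 2),
                                           levels = c("VL", "L", "H", "VH")))
  tr <- trend_statistic(deltas$individual, profiles, deltas, "CE")
  expect_equal(tr$slope, -1)
  expect_lt(tr$p_value, 1e-10)

  flat <- deltas
  flat$d_bodyfat <- rep(c(1, -1), 4)
  tr0 <- trend_statistic(flat$individual, profiles, flat, "CE")
  expect_equal(tr0$slope, 0, tolerance = 1e-12)

  expect_error(trend_statistic(deltas$individual[1:2], profiles, deltas,
                               "CE"),
               "fewer than 2 populated classes")
})

test_that("score descriptives report moments and Shapiro-Wilk p-values", {
  set.seed(71)
  grs <- rbind(
    data.frame(individual = 1:500, category = "CE", grs = rnorm(500)),
    data.frame(individual = 1:500, category = "FE", grs = 7))
  desc <- grs_descriptives(grs)
  ce <- desc[desc$category == "CE", ]
  expect_gt(ce$shapiro_p, 1e-4)
  expect_equal(ce$n, 500)
  fe <- desc[desc$category == "FE", ]
  expect_equal(fe$sd, 0)
  expect_true(is.na(fe$shapiro_p))
  expect_equal(c(fe$min, fe$median, fe$max), c(7, 7, 7))
})

test_that("Shapiro-Wilk calibration holds on normal scores", {
  set.seed(72)
  p <- replicate(100, shapiro_p <- grs_descriptives(
    data.frame(individual = 1:500, category = "CE",
               grs = rnorm(500)))$shapiro_p)
  expect_gte(mean(p > 0.05), 0.9)
})

test_that("large score vectors are tested on a seeded subsample", {
  set.seed(73)
  grs <- data.frame(individual = 1:6000, category = "TE", grs = rnorm(6000))
  d1 <- grs_descriptives(grs, subsample_seed = 5)
  d2 <- grs_descriptives(grs, subsample_seed = 5)
  expect_identical(d1$shapiro_p, d2$shapiro_p)
  expect_equal(attr(d1, "subsampled"), "TE")
  expect_equal(d1$n, 6000)
})

test_that("integer scores from k SNPs stay within +/- 2k", {
  set.seed(74)
  n <- 1000
  k <- 37
  counts <- matrix(rbinom(n * k, 2, 0.3), n, k)
  g <- make_genotypes(counts, maf = rep(0.3, k))
  sel <- data.frame(category = "CE", snp_id = colnames(g$counts),
                    coefficient = rnorm(k), p_value = 0.01)
  sel <- sel[sel$coefficient != 0, ]
  grs <- compute_grs(g, assign_signs(sel))
  desc <- grs_descriptives(grs)
  expect_gte(desc$min, -2 * k)
  expect_lte(desc$max, 2 * k)
})
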