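# Evaluation of the classification: responder subgroups (largest intake
# reductions, or exercise onset), class-wise mean body-fat change, an ordinal
# trend test across classes, and descriptive statistics with a Shapiro-Wilk
# normality test on each score distribution.

outcome_column <- function(category)
  if (category == "EE") "d_bodyfat_star" else "d_bodyfat"

delta_column <- function(category)
  switch(category, CE = "d_carb", FE = "d_fat", TE = "d_kcal",
         stop("no intake delta for category ", category))

#' Responder subset for a category
#'
#' CE/FE/TE: individuals whose intake change lies strictly below the 25th
#' percentile of that change's distribution in the delta table -- the
#' quarter with the largest reductions. EE: individuals who experienced
#' exercise onset, i.e. contributed at least one no-to-yes transition.
#'
#' @param deltas Diet delta table (CE/FE/TE) or exercise delta table (EE).
#' @param category One of `"CE"`, `"FE"`, `"TE"`, `"EE"`.
#' @return Character vector of individual ids (possibly empty, with a
#'   warning).
#' @export
responder_subset <- function(deltas, category) {
  category <- match.arg(category, CATEGORIES)
  if (category == "EE") {
    if (!"n_onsets" %in% names(deltas))
      stop("EE responders need the exercise delta table (n_onsets)")
    ids <- deltas$individual[deltas$n_onsets >= 1]
  } else {
    v <- deltas[[delta_column(category)]]
    cut <- quantile(v, 0.25, type = 7, names = FALSE, na.rm = TRUE)
    ids <- deltas$individual[!is.na(v) & v < cut]
  }
  if (length(ids) == 0)
    warning("empty responder subset for category ", category)
  as.character(ids)
}

#' Class-wise body-fat change among responders
#'
#' For each sensitivity class, the count, mean and SD of the body-fat change
#' (the oriented exercise delta for EE) among responder-subset members of
#' that class. Classes with no members report `n = 0` and missing moments.
#'
#' @param subset Character vector of responder ids.
#' @param profiles Wide profile table from [sensitivity_profiles()].
#' @param deltas Delta table carrying the outcome for this category.
#' @param category One of `"CE"`, `"FE"`, `"TE"`, `"EE"`.
#' @return Data frame with columns `category`, `class`, `n`, `mean_change`,
#'   `sd_change`.
#' @export
group_means <- function(subset, profiles, deltas, category) {
  category <- match.arg(category, CATEGORIES)
  class_col <- paste0(category, "_class")
  if (!class_col %in% names(profiles))
    stop("profiles lack classes for category ", category)
  out_col <- outcome_column(category)
  d <- deltas[deltas$individual %in% subset, , drop = FALSE]
  d$class <- profiles[[class_col]][match(d$individual, profiles$individual)]
  rows <- lapply(CLASSES, function(cl) {
    v <- d[[out_col]][!is.na(d$class) & d$class == cl]
    v <- v[!is.na(v)]
    data.frame(category = category, class = cl, n = length(v),
               mean_change = if (length(v) > 0) mean(v) else NA_real_,
               sd_change = if (length(v) > 1) sd(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$class <- factor(out$class, levels = CLASSES)
  out
}

#' Ordinal trend of body-fat change across sensitivity classes
#'
#' Regresses the individual body-fat change on the ordinal class code
#' (VL = 0, L = 1, H = 2, VH = 3) within the responder subset, by OLS with a
#' two-sided t test on the slope. A negative slope quantifies the pattern of
#' larger fat loss at higher sensitivity.
#'
#' @inheritParams group_means
#' @return List with elements `slope`, `p_value`, `n`.
#' @export
trend_statistic <- function(subset, profiles, deltas, category) {
  category <- match.arg(category, CATEGORIES)
  class_col <- paste0(category, "_class")
  out_col <- outcome_column(category)
  d <- deltas[deltas$individual %in% subset, , drop = FALSE]
  cls <- profiles[[class_col]][match(d$individual, profiles$individual)]
  code <- as.numeric(cls) - 1
  y <- d[[out_col]]
  ok <- !is.na(code) & !is.na(y)
  code <- code[ok]
  y <- y[ok]
  if (length(unique(code)) < 2)
    stop("fewer than 2 populated classes; trend undefined")
  res <- fit_ols(cbind(intercept = 1, class_code = code), y)
  slope <- res[res$term == "class_code", , drop = FALSE]
  list(slope = slope$estimate, p_value = slope$p_value, n = length(y))
}

#' Descriptive statistics and normality test of score distributions
#'
#' Mean, SD, median, min, max and the Shapiro-Wilk p-value per category.
#' When a category has more than 5000 scores the test runs on a seeded
#' subsample of 5000 (the test is defined up to that size); a note is
#' attached as attribute `subsampled`. Constant score vectors report a
#' missing p-value.
#'
#' @param grs Long score table from [compute_grs()].
#' @param subsample_seed Seed for the subsample draw.
#' @return Data frame with one row per category: `category`, `n`, `mean`,
#'   `sd`, `median`, `min`, `max`, `shapiro_p`.
#' @export
grs_descriptives <- function(grs, subsample_seed = 1L) {
  cats <- intersect(CATEGORIES, unique(grs$category))
  subsampled <- character()
  rows <- lapply(cats, function(cat) {
    v <- grs$grs[grs$category == cat]
    v <- v[!is.na(v)]
    n <- length(v)
    w <- v
    if (n > 5000) {
      set.seed(subsample_seed)
      w <- sample(v, 5000)
      subsampled <<- c(subsampled, cat)
    }
    sw <- if (n < 3) {
      warning("n < 3 scores in category ", cat, "; normality test undefined")
      NA_real_
    } else if (sd(w) == 0) NA_real_ else shapiro.test(w)$p.value
    if (n == 0)
      return(data.frame(category = cat, n = 0L, mean = NA_real_,
                        sd = NA_real_, median = NA_real_, min = NA_real_,
                        max = NA_real_, shapiro_p = NA_real_))
    data.frame(category = cat, n = n, mean = mean(v), sd = sd(v),
               median = median(v), min = min(v), max = max(v),
               shapiro_p = sw)
  })
  out <- do.call(rbind, rows)
  attr(out, "subsampled") <- subsampled
  out
}
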