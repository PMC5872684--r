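# End-to-end orchestration: simulate or load the cohort, derive phenotypes,
# screen, prune, score, classify, evaluate -- writing every artifact as TSV
# plus a YAML run manifest. All stages are pure functions of (inputs, config,
# seed), so a rerun with the same configuration reproduces the output
# directory byte for byte.

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort from `sim`) or
#'   `"load"` (read the tables named in `paths`).
#' @param sim A [sim_config()]; used in simulate mode.
#' @param paths Named list for load mode: `genotypes`, `diet_cohort`,
#'   `exercise_cohort`, optional `panel`.
#' @param alpha Selection threshold for [select_snps()].
#' @param ld_threshold r-squared threshold for [prune_by_ld()].
#' @param percentile_method Quartile method, see [quartile_cutpoints()].
#' @param min_carriers Carrier floor for [screen_snps()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed; in simulate mode it overrides `sim$seed`, and it
#'   always seeds the descriptive-statistics subsample.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       sim = sim_config(),
                       paths = NULL,
                       alpha = 0.05,
                       ld_threshold = 0.7,
                       percentile_method = c("linear", "nearest"),
                       min_carriers = 5,
                       out_dir,
                       seed = 1L) {
  mode <- match.arg(mode)
  percentile_method <- match.arg(percentile_method)
  if (mode == "load") {
    required <- c("genotypes", "diet_cohort", "exercise_cohort")
    if (is.null(paths) || !all(required %in% names(paths)))
      stop("load mode needs paths$genotypes, paths$diet_cohort, ",
           "paths$exercise_cohort")
  } else {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
  }
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  structure(list(mode = mode, sim = sim, paths = paths, alpha = alpha,
                 ld_threshold = ld_threshold,
                 percentile_method = percentile_method,
                 min_carriers = min_carriers, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# header-only file for legitimately empty downstream tables
write_stage_table <- function(records, template_cols, path) {
  if (!is.null(records) && is.data.frame(records) && nrow(records) > 0) {
    write_table(records, path)
  } else {
    empty <- as.data.frame(setNames(rep(list(character(0)),
                                        length(template_cols)),
                                    template_cols))
    utils::write.table(empty, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes all artifacts under
#' `config$out_dir`: the input tables (in simulate mode), delta tables, fit
#' results, the selection before and after LD pruning, the signed weights,
#' scores, cutpoints, sensitivity profiles, responder group summaries, trend
#' statistics, score descriptives, and a `manifest.yaml` recording the seed,
#' a configuration hash and per-stage row counts.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  path <- function(name) file.path(out, name)
  counts <- list()

  if (config$mode == "simulate") {
    genotypes <- run_stage("simulate", {
      g <- generate_genotypes(config$sim)
      write_genotypes(g, path("genotypes.tsv"))
      write_table(g$snps, path("panel.tsv"))
      g
    })
    diet_cohort <- run_stage("simulate",
      generate_diet_outcomes(config$sim, genotypes))
    exercise_cohort <- run_stage("simulate",
      generate_exercise_series(config$sim, genotypes))
    write_table(diet_cohort, path("diet_cohort.tsv"))
    write_table(exercise_cohort, path("exercise_cohort.tsv"))
  } else {
    genotypes <- run_stage("load", {
      panel <- if (!is.null(config$paths$panel))
        read_panel(config$paths$panel) else NULL
      read_genotypes(config$paths$genotypes, panel)
    })
    diet_cohort <- run_stage("load", read_cohort(config$paths$diet_cohort))
    exercise_cohort <- run_stage("load",
      read_cohort(config$paths$exercise_cohort))
  }
  counts$individuals <- nrow(genotypes$counts)
  counts$snps <- ncol(genotypes$counts)

  diet_deltas <- run_stage("derive", compute_diet_deltas(diet_cohort))
  exercise_deltas <- run_stage("derive",
    compute_exercise_delta(exercise_cohort))
  write_table(diet_deltas, path("diet_deltas.tsv"))
  write_stage_table(exercise_deltas,
                    c("individual", "gender", "age", "d_bodyfat_star",
                      "n_transitions", "n_onsets"),
                    path("exercise_deltas.tsv"))
  counts$diet_individuals <- nrow(diet_deltas)
  counts$diet_excluded <- attr(diet_deltas, "n_excluded")
  counts$exercise_individuals <- nrow(exercise_deltas)
  counts$exercise_excluded <- attr(exercise_deltas, "n_excluded")

  fits <- run_stage("screen",
    screen_snps(genotypes, diet_deltas, exercise_deltas,
                min_carriers = config$min_carriers))
  write_table(fits, path("fits.tsv"))
  skipped <- attr(fits, "skipped")
  write_stage_table(skipped, c("snp_id", "reason"), path("skipped_snps.tsv"))
  counts$snps_tested <- length(unique(fits$snp_id))
  counts$snps_skipped <- nrow(skipped)

  selection <- run_stage("select", select_snps(fits, alpha = config$alpha))
  sel_cols <- c("category", "snp_id", "coefficient", "p_value")
  write_stage_table(selection, sel_cols, path("selection.tsv"))
  counts$selected <- as.list(table(
    factor(selection$category, levels = CATEGORIES)))

  if (nrow(selection) == 0) {
    warning("no SNP selected in any category; downstream tables are empty")
    for (f in c("selection_pruned.tsv", "weights.tsv"))
      write_stage_table(NULL, c(sel_cols, "sign"), path(f))
    write_stage_table(NULL, c("category", "snp_a", "snp_b", "r2"),
                      path("ld_edges.tsv"))
    write_stage_table(NULL, c("individual", "category", "grs"),
                      path("grs.tsv"))
    write_stage_table(NULL, c("category", "q25", "q50", "q75"),
                      path("cutpoints.tsv"))
    write_stage_table(NULL, "individual", path("profiles.tsv"))
    write_stage_table(NULL,
                      c("category", "class", "n", "mean_change", "sd_change"),
                      path("group_summaries.tsv"))
    write_stage_table(NULL, c("category", "slope", "p_value", "n"),
                      path("trend.tsv"))
    write_stage_table(NULL,
                      c("category", "n", "mean", "sd", "median", "min",
                        "max", "shapiro_p"),
                      path("grs_descriptives.tsv"))
    manifest <- list(seed = config$seed,
                     config_hash = config_hash(config), counts = counts)
    yaml::write_yaml(manifest, path("manifest.yaml"))
    return(invisible(manifest))
  }

  pruned <- run_stage("prune",
    prune_by_ld(selection, genotypes, threshold = config$ld_threshold))
  write_table(pruned, path("selection_pruned.tsv"))
  write_stage_table(attr(pruned, "edges"),
                    c("category", "snp_a", "snp_b", "r2"),
                    path("ld_edges.tsv"))
  counts$pruned <- as.list(table(
    factor(pruned$category, levels = CATEGORIES)))

  signed <- run_stage("sign", assign_signs(pruned))
  write_table(signed[, c("snp_id", "category", "sign")],
              path("weights.tsv"))

  grs <- run_stage("score", compute_grs(genotypes, signed))
  write_table(grs, path("grs.tsv"))

  classified <- run_stage("classify",
    sensitivity_profiles(grs, method = config$percentile_method))
  profiles <- classified$profiles
  cuts_tab <- do.call(rbind, lapply(names(classified$cutpoints), function(cat)
    data.frame(category = cat, t(classified$cutpoints[[cat]]))))
  write_table(profiles, path("profiles.tsv"))
  write_table(cuts_tab, path("cutpoints.tsv"))

  run_stage("evaluate", {
    summaries <- list()
    trends <- list()
    for (cat in intersect(CATEGORIES, unique(signed$category))) {
      deltas <- if (cat == "EE") exercise_deltas else diet_deltas
      subset <- suppressWarnings(responder_subset(deltas, cat))
      counts$responders[[cat]] <- length(subset)
      if (length(subset) == 0) next
      summaries[[cat]] <- group_means(subset, profiles, deltas, cat)
      tr <- tryCatch(trend_statistic(subset, profiles, deltas, cat),
                     error = function(e) list(slope = NA_real_,
                                              p_value = NA_real_, n = 0L))
      trends[[cat]] <- data.frame(category = cat, slope = tr$slope,
                                  p_value = tr$p_value, n = tr$n)
    }
    write_stage_table(do.call(rbind, summaries),
                      c("category", "class", "n", "mean_change", "sd_change"),
                      path("group_summaries.tsv"))
    write_stage_table(do.call(rbind, trends),
                      c("category", "slope", "p_value", "n"),
                      path("trend.tsv"))
    desc <- grs_descriptives(grs, subsample_seed = config$seed)
    write_table(desc, path("grs_descriptives.tsv"))
  })

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   counts = counts)
  yaml::write_yaml(manifest, path("manifest.yaml"))
  invisible(manifest)
}

# hash of the configuration with the output location masked, so two runs of
# the same analysis into different directories carry the same hash
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  rlang::hash(cfg)
}
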