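#' Run configuration for the end-to-end pipeline
#'
#' Bundles every tunable of the pipeline with validated defaults. A YAML file
#' with any subset of the fields can be loaded with `run_config_from_yaml()`.
#'
#' @param seed Master seed; every random stage derives from it.
#' @param n_ne,n_me,n_se Synthetic group sizes.
#' @param noise_sd Flow noise as a fraction of PEF.
#' @param n_grid Descending-limb resampling grid.
#' @param fit_control Settings for [fit_biomech_model()].
#' @param damping,preference Affinity propagation settings.
#' @param k_folds Cross-validation folds.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_ne = 57L, n_me = 58L, n_se = 79L,
                       noise_sd = 0.02, n_grid = 100L, fit_control = list(),
                       damping = 0.7, preference = NULL, k_folds = 10L,
                       out_dir = "esitools-output") {
  if (!is_number(seed)) abort_domain("`seed` must be a single integer")
  if (k_folds < 2) abort_domain("`k_folds` must be >= 2")
  structure(list(seed = as.integer(seed), n_ne = as.integer(n_ne),
                 n_me = as.integer(n_me), n_se = as.integer(n_se),
                 noise_sd = noise_sd, n_grid = as.integer(n_grid),
                 fit_control = fit_control, damping = damping,
                 preference = preference, k_folds = as.integer(k_folds),
                 out_dir = out_dir),
            class = "run_config")
}

#' @param path YAML file path.
#' @rdname run_config
#' @export
run_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    abort_domain(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

log_msg <- function(...) {
  message(sprintf("[esitools] %s", sprintf(...)))
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates the seeded cohort, scores every curve, clusters the pattern
#' profiles (SILA + affinity propagation), and runs the statistical battery:
#' Welch ANOVA and Games-Howell post-hocs of the fitted score across the CT
#' severity groups, Pearson correlations of the score with the CT fractions
#' and FEV1/FVC, a chi-squared test of cluster membership against severity
#' group, and two cross-validated logistic ROC analyses (severe-vs-rest and
#' no-emphysema-vs-rest). Writes `cohort.csv`, per-subject curve CSVs and
#' score JSONs, `clusters.csv`, `report.json` and `report.md` under
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param write_files Write outputs to disk (default `TRUE`); the result list
#'   is returned either way.
#' @return Invisibly, a list: `cohort`, `clusters` (tibble), `ap`
#'   (`ap_result`), `stats` (named list of results), `config`.
#' @export
run_pipeline <- function(config = run_config(), write_files = TRUE) {
  if (!inherits(config, "run_config")) abort_domain("`config` must be a run_config")
  log_msg("generating cohort (seed %d, n = %d/%d/%d)", config$seed,
          config$n_ne, config$n_me, config$n_se)
  cohort <- generate_cohort(
    cohort_spec(n_ne = config$n_ne, n_me = config$n_me, n_se = config$n_se,
                noise_sd = config$noise_sd, seed = config$seed),
    n_grid = config$n_grid)
  n <- nrow(cohort)

  log_msg("clustering %d pattern profiles", n)
  ap <- NULL
  clusters <- NULL
  if (n >= 2L) {
    d <- sila_matrix(cohort$profile)
    ap <- affinity_propagation(d, preference = config$preference,
                               damping = config$damping)
    clusters <- tidy(ap)
    clusters$id <- cohort$id
    clusters <- dplyr::select(clusters, "id", "cluster", "is_exemplar")
  }

  stats_out <- list()
  by_group <- split(cohort$esi_fit, cohort$group, drop = TRUE)
  if (length(by_group) >= 2L) {
    stats_out$welch_anova_esi <- welch_anova(by_group)
    stats_out$games_howell_esi <- games_howell(by_group)
  } else {
    rlang::warn("fewer than 2 non-empty groups: ANOVA stage skipped")
  }
  cors <- purrr::map_dbl(
    c(laa950_insp = "laa950_insp", laa856_exp = "laa856_exp",
      plda = "plda", flda = "flda", fev1_fvc = "fev1_fvc"),
    ~ pearson_r(cohort$esi_fit, cohort[[.x]]))
  stats_out$correlations <- tibble::tibble(variable = names(cors), r = cors)
  stats_out$steiger_laa <- steiger_z(
    r_jk = pearson_r(cohort$laa950_insp, cohort$esi_fit),
    r_jh = pearson_r(cohort$laa950_insp, cohort$fev1),
    r_kh = pearson_r(cohort$esi_fit, cohort$fev1),
    n = n)
  if (!is.null(clusters) && length(unique(clusters$cluster)) > 1L &&
      length(unique(cohort$group)) > 1L) {
    tab <- table(droplevels(cohort$group), clusters$cluster)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    stats_out$chi_squared_clusters <- chi_squared(tab)
  }
  roc_seeds <- with_seed_(config$seed, sample.int(2^31 - 1, 2))
  have_both <- function(flag) {
    counts <- table(flag)
    length(counts) == 2L && all(counts >= config$k_folds)
  }
  if (have_both(cohort$group == "SE")) {
    stats_out$roc_severe <- cv_roc(cohort$esi_fit, cohort$group == "SE",
                                   k_folds = config$k_folds,
                                   seed = roc_seeds[1L])
    stats_out$best_threshold_severe <- best_threshold(stats_out$roc_severe)
  }
  if (have_both(cohort$group == "NE")) {
    stats_out$roc_absence <- cv_roc(cohort$esi_fit, cohort$group == "NE",
                                    k_folds = config$k_folds,
                                    seed = roc_seeds[2L])
    stats_out$best_threshold_absence <- best_threshold(stats_out$roc_absence)
  }

  result <- list(cohort = cohort, clusters = clusters, ap = ap,
                 stats = stats_out, config = config)
  if (write_files) write_pipeline_outputs(result)
  invisible(result)
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- result$cohort
  write_cohort(cohort, file.path(dir, "cohort.csv"),
               curve_dir = file.path(dir, "curves"))
  score_dir <- file.path(dir, "scores")
  dir.create(score_dir, showWarnings = FALSE)
  purrr::walk(seq_len(nrow(cohort)), function(i) {
    res <- list(esi = cohort$esi_fit[i], id = cohort$id[i],
                group = as.character(cohort$group[i]),
                fev1 = cohort$fev1[i], fvc = cohort$fvc[i],
                pef = cohort$pef[i])
    jsonlite::write_json(res, file.path(score_dir,
                                        paste0(cohort$id[i], ".json")),
                         auto_unbox = TRUE, digits = NA)
  })
  if (!is.null(result$clusters))
    readr::write_csv(result$clusters, file.path(dir, "clusters.csv"))
  jsonlite::write_json(stats_report_list(result$stats),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(stats_report_md(result), file.path(dir, "report.md"))
  log_msg("outputs written to %s", dir)
  invisible(dir)
}

stats_report_list <- function(st) {
  out <- list()
  if (!is.null(st$welch_anova_esi))
    out$welch_anova_esi <- as.list(st$welch_anova_esi)
  if (!is.null(st$games_howell_esi))
    out$games_howell_esi <- st$games_howell_esi
  out$correlations <- st$correlations
  out$steiger_laa <- as.list(tibble::as_tibble(st$steiger_laa))
  if (!is.null(st$chi_squared_clusters))
    out$chi_squared_clusters <- as.list(st$chi_squared_clusters)
  for (side in c("severe", "absence")) {
    roc <- st[[paste0("roc_", side)]]
    if (is.null(roc)) next
    out[[paste0("roc_", side)]] <- list(
      auc = roc$auc, mean_fold_auc = roc$mean_fold_auc,
      fold_aucs = roc$fold_aucs,
      best = as.list(st[[paste0("best_threshold_", side)]]))
  }
  out
}

stats_report_md <- function(result) {
  st <- result$stats
  co <- result$cohort
  lines <- c("# Synthetic cohort validation report", "")
  gs <- dplyr::summarise(
    dplyr::group_by(co, .data$group),
    n = dplyr::n(), esi_mean = mean(.data$esi_fit), esi_sd = sd(.data$esi_fit),
    .groups = "drop")
  lines <- c(lines, "## Fitted ESI by severity group", "",
             "| group | n | ESI mean (SD) |", "|---|---|---|",
             sprintf("| %s | %d | %.1f (%.1f) |", gs$group, gs$n,
                     gs$esi_mean, gs$esi_sd), "")
  if (!is.null(st$welch_anova_esi))
    lines <- c(lines, sprintf(
      "Welch ANOVA: F* = %.2f (df %d, %.1f), p = %.3g", st$welch_anova_esi$f_star,
      st$welch_anova_esi$df1, st$welch_anova_esi$df2, st$welch_anova_esi$p), "")
  if (!is.null(st$games_howell_esi)) {
    gh <- st$games_howell_esi
    lines <- c(lines, "## Games-Howell pairwise comparisons", "",
               "| pair | mean diff | p |", "|---|---|---|",
               sprintf("| %s vs %s | %.2f | %.3g |", gh$group1, gh$group2,
                       gh$mean_diff, gh$p), "")
  }
  cr <- st$correlations
  lines <- c(lines, "## Correlations with fitted ESI", "",
             "| variable | r |", "|---|---|",
             sprintf("| %s | %.2f |", cr$variable, cr$r), "")
  for (side in c("severe", "absence")) {
    roc <- st[[paste0("roc_", side)]]
    if (is.null(roc)) next
    bt <- st[[paste0("best_threshold_", side)]]
    lines <- c(lines, sprintf(
      "ROC (%s vs rest): AUC %.2f; best threshold %.2f (sens %.2f, spec %.2f)",
      side, roc$auc, bt$threshold, bt$sensitivity, bt$specificity), "")
  }
  lines
}
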