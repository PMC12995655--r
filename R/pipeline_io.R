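#' Read and validate a cohort panel CSV
#'
#' Expects one row per swimmer with columns \code{swimmer_id, group, sex,
#' age, years_training, best_50m} and \code{<indicator>_<timepoint>} for the
#' six indicators (bench, mbt, cmj, sj, dj, slj) at pre/mid/post. Validation
#' reports missing and unexpected columns, duplicate swimmer ids, and
#' non-numeric or missing cells with their coordinates.
#'
#' @param path path to a UTF-8 CSV with a header row and \code{.} decimals.
#' @return a validated \code{cohort_panel}.
#' @export
read_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_panel(df)
}

#' @rdname read_panel
#' @param panel data frame to validate / write.
#' @export
validate_panel <- function(panel) {
  cols <- panel_columns()
  missing <- setdiff(cols, names(panel))
  extra <- setdiff(names(panel), cols)
  if (length(missing) || length(extra))
    stop_field(
      "panel schema violation%s%s",
      if (length(missing)) paste0("; missing columns: ",
                                  paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unexpected columns: ",
                                paste(extra, collapse = ", ")) else "")
  panel <- panel[, cols]
  dup <- unique(panel$swimmer_id[duplicated(panel$swimmer_id)])
  if (length(dup))
    stop_field("duplicated swimmer_id: %s", paste(dup, collapse = ", "))
  num_cols <- setdiff(cols, c("swimmer_id", "group", "sex"))
  for (cn in num_cols) {
    v <- panel[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop_field("non-numeric cell(s) in column '%s' (row %s)", cn,
                 paste(head(bad, 5), collapse = ", "))
    }
    if (anyNA(v))
      stop_field("missing cell(s) in column '%s' (row %s)", cn,
                 paste(head(which(is.na(v)), 5), collapse = ", "))
  }
  if (anyNA(panel$group) || anyNA(panel$sex) || anyNA(panel$swimmer_id))
    stop_field("missing cells in identifier columns")
  class(panel) <- c("cohort_panel", "data.frame")
  panel
}

#' Write a cohort panel as CSV
#'
#' UTF-8, header row, \code{.} decimal separator; round-trips through
#' \code{\link{read_panel}} value-identically.
#'
#' @param panel a \code{cohort_panel}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.csv(as.data.frame(panel)[, panel_columns()], path, row.names = FALSE)
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_field("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full responder-signature pipeline
#'
#' Executes composites, descriptive statistics and pairwise contrasts,
#' responder-signature clustering with bootstrap stability and group
#' association, and the exploratory prediction models, in order. All
#' stochastic stages draw their seeds deterministically from the single
#' master \code{seed}, so a rerun with the same inputs reproduces the report
#' exactly. Procedure defaults follow the study: 100,000 permutations,
#' 20,000 bootstrap resamples for contrast CIs, 2,000 stability replicates.
#'
#' @param panel a \code{cohort_panel}; with \code{NULL}, a synthetic cohort
#'   is generated from \code{sim} (simulate mode).
#' @param sim a \code{\link{sim_config}} used when \code{panel} is
#'   \code{NULL}; its seed is overridden by a child of \code{seed}.
#' @param seed master integer seed.
#' @param n_perm permutations for contrast tests and the chi-square
#'   association test.
#' @param n_boot_ci bootstrap resamples for contrast CIs.
#' @param n_boot_stability bootstrap replicates for cluster stability.
#' @param n_boot_coef bootstrap replicates for model coefficients.
#' @param k_range candidate cluster numbers.
#' @param min_cluster_size small-cluster guard for k selection.
#' @param out_dir optional output directory; when given, table analogues
#'   (CSV), figures (PNG) and the full JSON report are written there.
#' @return object of class \code{run_report}: list with
#'   \code{panel, upper_model, lower_model, delta, descriptives, contrasts,
#'   solution, stability, association, ridge_upper, ridge_lower, logistic,
#'   provenance}.
#' @export
run_all <- function(panel = NULL, sim = sim_config(), seed = 1L,
                    n_perm = 1e5, n_boot_ci = 2e4,
                    n_boot_stability = 2000, n_boot_coef = 2000,
                    k_range = 2:4, min_cluster_size = 5,
                    out_dir = NULL) {
  for (cnt in c(n_perm, n_boot_ci, n_boot_stability, n_boot_coef))
    if (!is_count(cnt)) stop_field("all procedure counts must be >= 1")
  seeds <- child_seeds(seed, c("simulate", "contrasts", "stability",
                               "association", "ridge_upper", "ridge_lower",
                               "logistic"))
  if (is.null(panel)) {
    sim$seed <- seeds[["simulate"]]
    panel <- run_stage("simulate", generate_cohort(sim))
  } else {
    panel <- run_stage("read", validate_panel(as.data.frame(panel)))
  }

  upper_model <- run_stage("composites", fit_baseline_pca(panel, "upper"))
  lower_model <- run_stage("composites", fit_baseline_pca(panel, "lower"))
  delta <- run_stage("composites",
                     compute_deltas(upper_model, lower_model, panel))

  descriptives <- run_stage("contrasts", rbind(
    describe_deltas(delta, "delta_upper"),
    describe_deltas(delta, "delta_lower")))
  contrasts <- run_stage("contrasts",
    run_contrasts(delta, n_perm = n_perm, n_boot = n_boot_ci,
                  seed = seeds[["contrasts"]]))

  solution <- run_stage("signatures",
    find_signatures(delta, k_range = k_range,
                    min_cluster_size = min_cluster_size))
  stability <- run_stage("signatures",
    bootstrap_stability(delta, solution, n_replicates = n_boot_stability,
                        seed = seeds[["stability"]]))
  association <- run_stage("signatures",
    permutation_chi2(delta$group, solution$labels, n_perm = n_perm,
                     seed = seeds[["association"]]))

  design <- run_stage("predictors",
                      build_design(panel, delta, labels = solution$labels))
  ridge_upper <- run_stage("predictors",
    fit_ridge_loo(design, "delta_upper", n_boot = n_boot_coef,
                  seed = seeds[["ridge_upper"]]))
  ridge_lower <- run_stage("predictors",
    fit_ridge_loo(design, "delta_lower", n_boot = n_boot_coef,
                  seed = seeds[["ridge_lower"]]))
  logistic <- run_stage("predictors",
    fit_logistic_l2_loo(design, n_boot = n_boot_coef,
                        seed = seeds[["logistic"]]))

  report <- structure(
    list(panel = panel, upper_model = upper_model, lower_model = lower_model,
         delta = delta, descriptives = descriptives, contrasts = contrasts,
         solution = solution, stability = stability,
         association = association, design = design,
         ridge_upper = ridge_upper, ridge_lower = ridge_lower,
         logistic = logistic,
         provenance = list(
           seed = seed, child_seeds = as.list(seeds),
           n_perm = n_perm, n_boot_ci = n_boot_ci,
           n_boot_stability = n_boot_stability, n_boot_coef = n_boot_coef,
           k_range = k_range, min_cluster_size = min_cluster_size,
           package_version = as.character(utils::packageVersion("respsig")))),
    class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Responder-signature analysis report\n")
  cat(sprintf("  swimmers: %d in groups %s\n", nrow(x$panel),
              paste(unique(x$panel$group), collapse = ", ")))
  cat(sprintf("  PC1 variance explained: upper %.3f, lower %.3f\n",
              x$upper_model$variance_explained,
              x$lower_model$variance_explained))
  print(x$contrasts)
  print(x$solution)
  print(x$stability)
  print(x$association)
  invisible(x)
}

round_df <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

report_to_list <- function(report) {
  list(
    provenance = report$provenance,
    composites = list(
      upper = unclass(report$upper_model)[c("indicators", "loadings",
                                            "variance_explained")],
      lower = unclass(report$lower_model)[c("indicators", "loadings",
                                            "variance_explained")]),
    descriptives = report$descriptives,
    contrasts = as.data.frame(report$contrasts),
    cluster = list(k = report$solution$k,
                   silhouette = report$solution$silhouette,
                   sizes = report$solution$sizes,
                   labels = report$solution$labels,
                   candidates = report$solution$candidates,
                   profiles = report$solution$profiles),
    stability = list(n_replicates = report$stability$n_replicates,
                     ari_mean = report$stability$ari_mean,
                     ari_ci95 = report$stability$ari_ci95,
                     jaccard = report$stability$jaccard),
    association = list(
      contingency = as.data.frame.matrix(report$association$contingency),
      chi2 = report$association$chi2,
      p_perm = report$association$p_perm),
    predictors = list(
      ridge_upper = unclass(report$ridge_upper)[
        c("penalty", "loo_rmse", "cv_r2", "coefficients")],
      ridge_lower = unclass(report$ridge_lower)[
        c("penalty", "loo_rmse", "cv_r2", "coefficients")],
      logistic = unclass(report$logistic)[
        c("penalty", "loo_accuracy", "loo_logloss",
          "predicted_prob_by_group", "coefficients", "group_contrasts")]))
}

#' Write the report's table analogues, figures, and JSON to a directory
#'
#' Rendered tables round numbers to three decimals and format p values with
#' a \code{"<0.001"} floor; the JSON report keeps full precision.
#'
#' @param report a \code{run_report}.
#' @param out_dir target directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)

  loadings <- rbind(
    data.frame(construct = "upper", indicator = report$upper_model$indicators,
               loading = report$upper_model$loadings),
    data.frame(construct = "lower", indicator = report$lower_model$indicators,
               loading = report$lower_model$loadings))
  write.csv(round_df(loadings), fp("table_loadings.csv"), row.names = FALSE)
  write.csv(round_df(report$descriptives), fp("table_descriptives.csv"),
            row.names = FALSE)
  ctab <- as.data.frame(report$contrasts)
  ctab$p_perm <- format_p(ctab$p_perm)
  ctab$p_holm <- format_p(ctab$p_holm)
  write.csv(round_df(ctab), fp("table_contrasts.csv"), row.names = FALSE)
  write.csv(round_df(report$solution$candidates), fp("table_k_selection.csv"),
            row.names = FALSE)
  write.csv(round_df(report$solution$profiles), fp("table_cluster_profiles.csv"),
            row.names = FALSE)
  write.csv(round_df(report$stability$jaccard), fp("table_jaccard.csv"),
            row.names = FALSE)
  write.csv(as.data.frame.matrix(report$association$contingency),
            fp("table_group_by_cluster.csv"))
  write_panel(report$panel, fp("panel.csv"))
  jsonlite::write_json(report_to_list(report), fp("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ggplot2::ggsave(fp("fig_change_space.png"),
                  plot_change_space(report$delta, report$solution$labels),
                  width = 6, height = 5, dpi = 150)
  ggplot2::ggsave(fp("fig_silhouette_by_k.png"),
                  plot_silhouette_by_k(report$solution$candidates),
                  width = 5, height = 4, dpi = 150)
  ggplot2::ggsave(fp("fig_ari_distribution.png"),
                  plot_ari_histogram(report$stability),
                  width = 5, height = 4, dpi = 150)
  invisible(out_dir)
}
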