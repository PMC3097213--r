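challenge_groups <- function() c("NylonLarval", "NylonAdult",
                                 "BacteriaLarval", "BacteriaAdult")
procedural_groups <- function() c("PC1", "PC2")

#' Run the full lifespan analysis on one cohort
#'
#' Orchestrates the maximum-lifespan and median-lifespan analyses end to
#' end, deterministically for a given input and configuration:
#' \itemize{
#'   \item per-group maximum-lifespan quantiles, descending (plus the pooled
#'     threshold);
#'   \item each non-control group versus control: survivor proportions at
#'     the pooled threshold, ageing-acceleration ratio, exact unconditional
#'     z-pooled test;
#'   \item when both sets are present, the pooled immune-challenged groups
#'     versus the pooled procedural controls;
#'   \item the AFT comparison table (time ratio `c` with 95% CI per group,
#'     plus the control self-comparison reference row);
#'   \item the divergence scan over quantiles of overall survival time;
#'   \item a provenance block (package version, configuration, input
#'     metadata).
#' }
#'
#' @param dataset A [cohort_dataset()] (or a path to a cohort CSV).
#' @param control Control group label (default `"Control"`).
#' @param q Maximum-lifespan quantile (default 0.9).
#' @param alpha Significance level for the divergence summary (default 0.05).
#' @param distribution AFT family for the comparison table (default
#'   `"weibull"`; `"auto"` selects by AIC per comparison).
#' @param grid_points Nuisance grid size for the exact tests.
#' @return A `lifespan_report` list: `quantiles`, `threshold_days`,
#'   `comparisons`, `pooled_comparison` (or `NULL`), `aft`, `divergence`,
#'   `provenance`.
#' @export
run_report <- function(dataset, control = "Control", q = 0.9, alpha = 0.05,
                       distribution = "weibull", grid_points = 1000L) {
  if (is.character(dataset)) dataset <- read_cohort(dataset)
  stopifnot(inherits(dataset, "cohort"))
  if (!control %in% dataset$group)
    stop("[quantiles] control group not present: ", control)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  gq <- stage("quantiles", sort(group_quantiles(dataset, q = q),
                                decreasing = TRUE))
  threshold <- stage("quantiles", pooled_quantile(dataset, q = q))
  quantile_table <- data.frame(group = names(gq), quantile_days = unname(gq),
                               stringsAsFactors = FALSE)

  others <- setdiff(unique(dataset$group), control)
  comparisons <- stage("max_lifespan", {
    rows <- lapply(others, function(g) {
      cmp <- compare_max_lifespan(dataset, control, g, q = q,
                                  grid_points = grid_points)
      data.frame(comparison = paste(control, "vs", g),
                 prop_control = cmp$prop_control,
                 prop_treatment = cmp$prop_treatment,
                 treatment_effect = cmp$treatment_effect,
                 z = cmp$test$z_obs, p = cmp$test$p_value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  pooled <- NULL
  have_chal <- intersect(challenge_groups(), unique(dataset$group))
  have_proc <- intersect(procedural_groups(), unique(dataset$group))
  if (length(have_chal) > 0L && length(have_proc) > 0L)
    pooled <- stage("max_lifespan_pooled",
                    compare_max_lifespan(dataset, control = have_proc,
                                         treatment = have_chal, q = q,
                                         grid_points = grid_points))

  aft <- stage("aft", aft_report(dataset, control = control,
                                 distribution = distribution))
  divergence <- if (length(others) >= 1L)
    stage("divergence", divergence_scan(dataset, alpha = alpha)) else NULL

  structure(list(
    quantiles = quantile_table,
    threshold_days = threshold,
    comparisons = comparisons,
    pooled_comparison = pooled,
    aft = aft,
    divergence = divergence,
    provenance = list(
      package = "agemax",
      version = as.character(utils::packageVersion("agemax")),
      control = control, q = q, alpha = alpha,
      distribution = distribution, grid_points = grid_points,
      input_metadata = cohort_metadata(dataset))),
    class = "lifespan_report")
}

#' @export
print.lifespan_report <- function(x, ...) {
  cat("Lifespan analysis report\n")
  cat(sprintf("  pooled %.0fth-percentile threshold: %.1f days\n",
              100 * x$provenance$q, x$threshold_days))
  cat("  group quantiles (days):\n")
  for (i in seq_len(nrow(x$quantiles)))
    cat(sprintf("    %-15s %.1f\n", x$quantiles$group[i],
                x$quantiles$quantile_days[i]))
  cat("  maximum-lifespan comparisons:\n")
  for (i in seq_len(nrow(x$comparisons)))
    cat(sprintf("    %-28s effect = %5.2f  z = %6.2f  p = %.4g\n",
                x$comparisons$comparison[i], x$comparisons$treatment_effect[i],
                x$comparisons$z[i], x$comparisons$p[i]))
  if (!is.null(x$pooled_comparison))
    cat(sprintf("  pooled challenged vs procedural: effect = %.2f, z = %.2f, p = %.4g\n",
                x$pooled_comparison$treatment_effect,
                x$pooled_comparison$test$z_obs, x$pooled_comparison$test$p_value))
  cat("  AFT time ratios (", x$aft$distribution[1], "):\n", sep = "")
  for (i in seq_len(nrow(x$aft)))
    cat(sprintf("    %-15s c = %.3f [%.3f, %.3f]\n", x$aft$group[i],
                x$aft$c[i], x$aft$c_lower[i], x$aft$c_upper[i]))
  if (!is.null(x$divergence)) {
    fs <- attr(x$divergence, "first_significant")
    fd <- attr(x$divergence, "first_significant_day")
    cat(if (is.na(fs)) "  divergence: none detected\n" else
      sprintf("  divergence: first at quantile %.2f (day %.1f)\n", fs, fd))
  }
  invisible(x)
}

#' Write a lifespan report to disk
#'
#' Emits `report.json` (the machine-readable bundle) plus one CSV per table
#' (`quantiles.csv`, `comparisons.csv`, `aft.csv`, `divergence.csv`). Output
#' is deterministic for a given report (no timestamps).
#'
#' @param report A `lifespan_report` from [run_report()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "lifespan_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$quantiles, file.path(dir, "quantiles.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(report$aft, file.path(dir, "aft.csv"), row.names = FALSE)
  if (!is.null(report$divergence))
    utils::write.csv(report$divergence, file.path(dir, "divergence.csv"),
                     row.names = FALSE)
  json <- list(
    threshold_days = report$threshold_days,
    quantiles = report$quantiles,
    comparisons = report$comparisons,
    pooled_comparison = if (!is.null(report$pooled_comparison)) list(
      treatment_effect = report$pooled_comparison$treatment_effect,
      z = report$pooled_comparison$test$z_obs,
      p = report$pooled_comparison$test$p_value),
    aft = report$aft,
    divergence = report$divergence,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
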