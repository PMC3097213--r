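lifespans_of <- function(dataset, groups = NULL) {
  stopifnot(inherits(dataset, "cohort"))
  d <- dataset
  if (!is.null(groups)) {
    missing_g <- setdiff(groups, unique(d$group))
    if (length(missing_g) > 0L)
      stop("group(s) not present in dataset: ", paste(missing_g, collapse = ", "))
    d <- d[d$group %in% groups, , drop = FALSE]
  }
  d
}

require_all_events <- function(dataset, what) {
  if (any(!dataset$event))
    stop(what, " requires fully observed lifespans; ",
         sum(!dataset$event), " record(s) are right-censored")
  invisible(dataset)
}

#' Pooled empirical lifespan quantile
#'
#' The maximum-lifespan statistic: the empirical `q` quantile of all
#' lifespans combined across every group, using linear interpolation of
#' order statistics (position `h = (n-1)q + 1`, R's default type-7 rule).
#' With `q = 0.9` this is the usual quantile-based operationalisation of
#' maximum lifespan in ageing studies.
#'
#' @param dataset A [cohort_dataset()]; all records must be observed deaths.
#' @param q Quantile in (0, 1); default 0.9.
#' @return Lifespan in days.
#' @export
pooled_quantile <- function(dataset, q = 0.9) {
  stopifnot(length(q) == 1L, q > 0, q < 1)
  d <- lifespans_of(dataset)
  if (nrow(d) == 0L) stop("empty dataset")
  require_all_events(d, "pooled_quantile")
  unname(stats::quantile(d$lifespan_days, probs = q, type = 7))
}

#' Per-group empirical lifespan quantiles
#'
#' Same estimator as [pooled_quantile()], applied to each group separately.
#' Groups with a single individual are allowed (the quantile degenerates to
#' that lifespan) but trigger a warning.
#'
#' @inheritParams pooled_quantile
#' @return Named numeric vector, one quantile per group present.
#' @export
group_quantiles <- function(dataset, q = 0.9) {
  stopifnot(length(q) == 1L, q > 0, q < 1)
  d <- lifespans_of(dataset)
  require_all_events(d, "group_quantiles")
  sp <- split(d$lifespan_days, d$group)
  small <- names(sp)[lengths(sp) < 2L]
  if (length(small) > 0L)
    warning("group(s) with fewer than 2 individuals: ",
            paste(small, collapse = ", "))
  vapply(sp, function(x) unname(stats::quantile(x, probs = q, type = 7)),
         numeric(1))
}

#' Count and proportion of a group reaching a lifespan threshold
#'
#' "Reaching" is inclusive: an individual dying on the threshold day survived
#' to it (`lifespan_days >= threshold_days`).
#'
#' @param dataset A [cohort_dataset()].
#' @param group One or more group labels (several labels pool their
#'   individuals).
#' @param threshold_days Threshold in days.
#' @return List with `x` (count reaching), `n` (group size), `prop` (`x/n`).
#' @export
proportion_reaching <- function(dataset, group, threshold_days) {
  d <- lifespans_of(dataset, groups = group)
  x <- sum(d$lifespan_days >= threshold_days)
  list(x = x, n = nrow(d), prop = x / nrow(d))
}

#' Maximum-lifespan comparison of two treatment arms
#'
#' The full maximum-lifespan analysis for one comparison: the threshold is
#' the pooled `q` quantile over the *whole* dataset (all groups, so a single
#' threshold serves every comparison in a report), each arm's proportion
#' surviving to it is computed inclusively, the 2x2 table is tested with the
#' exact unconditional z-pooled test, and the ageing-acceleration ratio
#' `prop_control / prop_treatment` is reported (> 1 means the treatment
#' reduced maximum lifespan; `Inf` with a flag when no treatment individual
#' reaches the threshold).
#'
#' @param dataset A [cohort_dataset()] with all events observed.
#' @param control Control group label(s).
#' @param treatment Treatment group label(s); several labels are pooled by
#'   concatenating their individuals. Must be disjoint from `control`.
#' @param q Threshold quantile (default 0.9).
#' @param grid_points Nuisance grid size passed to
#'   [exact_unconditional_p()].
#' @return A `max_lifespan_comparison`: `threshold_days`, `prop_control`,
#'   `prop_treatment`, `counts` ([two_by_two()]), `treatment_effect`,
#'   `effect_infinite` flag, `test` (`exact_test_result`).
#' @export
compare_max_lifespan <- function(dataset, control = "Control", treatment,
                                 q = 0.9, grid_points = 1000L) {
  if (length(intersect(control, treatment)) > 0L)
    stop("control and treatment groups must be disjoint")
  d <- lifespans_of(dataset)
  require_all_events(d, "compare_max_lifespan")
  threshold <- pooled_quantile(d, q = q)
  pc <- proportion_reaching(d, control, threshold)
  pt <- proportion_reaching(d, treatment, threshold)
  counts <- two_by_two(pc$x, pc$n, pt$x, pt$n)
  test <- exact_unconditional_p(counts, grid_points = grid_points)
  inf_effect <- pt$prop == 0
  structure(list(
    threshold_days = threshold,
    q = q,
    control = control, treatment = treatment,
    prop_control = pc$prop, prop_treatment = pt$prop,
    counts = counts,
    treatment_effect = if (inf_effect) Inf else pc$prop / pt$prop,
    effect_infinite = inf_effect,
    test = test), class = "max_lifespan_comparison")
}

#' @export
print.max_lifespan_comparison <- function(x, ...) {
  cat(sprintf(
    "Maximum-lifespan comparison (%s vs %s)\n  threshold: %.1f days (pooled q = %.2f)\n  survivors: %d/%d (%.3f) vs %d/%d (%.3f)\n  ageing acceleration: %s\n  z = %.3f, exact unconditional p = %.4g\n",
    paste(x$control, collapse = "+"), paste(x$treatment, collapse = "+"),
    x$threshold_days, x$q,
    x$counts$x1, x$counts$n1, x$prop_control,
    x$counts$x2, x$counts$n2, x$prop_treatment,
    if (x$effect_infinite) "Inf (no treatment survivors)"
    else sprintf("%.3f", x$treatment_effect),
    x$test$z_obs, x$test$p_value))
  invisible(x)
}

#' Scan survival-time quantiles for the earliest group divergence
#'
#' For each requested quantile of overall (pooled) survival time, forms the
#' k x 2 contingency table of (alive at that day, dead before it) per group
#' and applies the Pearson chi-squared test. Quantiles at which every
#' individual shares one state (e.g. before the first death) produce a
#' degenerate margin and are skipped with an annotation. The earliest
#' quantile with p < `alpha` is attached as the `first_significant`
#' attribute, locating the point at which the survival curves begin to
#' differ.
#'
#' @param dataset A [cohort_dataset()] with >= 2 groups, all events observed.
#' @param quantiles Quantiles of overall survival time to scan (default
#'   `seq(0.01, 0.99, by = 0.01)`).
#' @param alpha Significance level for the summary (default 0.05).
#' @return Data frame with columns `quantile`, `day`, `chi2`, `df`, `p`,
#'   `note`; attributes `first_significant` (quantile, or `NA`) and
#'   `first_significant_day`.
#' @export
divergence_scan <- function(dataset, quantiles = seq(0.01, 0.99, by = 0.01),
                            alpha = 0.05) {
  d <- lifespans_of(dataset)
  require_all_events(d, "divergence_scan")
  groups <- sort(unique(d$group))
  if (length(groups) < 2L) stop("divergence_scan needs at least 2 groups")
  stopifnot(all(quantiles > 0 & quantiles < 1))
  quantiles <- sort(quantiles)
  days <- stats::quantile(d$lifespan_days, probs = quantiles, type = 7)
  sp <- split(d$lifespan_days, factor(d$group, levels = groups))
  out <- data.frame(quantile = quantiles, day = unname(days),
                    chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_along(quantiles)) {
    alive <- vapply(sp, function(x) sum(x >= days[i]), integer(1))
    dead <- lengths(sp) - alive
    tab <- cbind(alive = alive, dead = dead)
    if (any(colSums(tab) == 0L)) {
      out$note[i] <- "degenerate (all individuals in one state)"
      next
    }
    ct <- chi_squared(tab)
    out$chi2[i] <- ct$statistic
    out$df[i] <- ct$df
    out$p[i] <- ct$p
  }
  sig <- which(!is.na(out$p) & out$p < alpha)
  attr(out, "first_significant") <-
    if (length(sig) > 0L) out$quantile[sig[1L]] else NA_real_
  attr(out, "first_significant_day") <-
    if (length(sig) > 0L) out$day[sig[1L]] else NA_real_
  out
}
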