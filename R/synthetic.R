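#' Configuration for a simulated survival cohort
#'
#' Lifespans are drawn as `onset_days + c * Weibull(shape, scale)`: a shared
#' juvenile period during which no deaths occur, followed by a group-specific
#' accelerated-failure-time rescaling of a common Weibull baseline. The pure
#' time-ratio effect `c` makes the generator exactly consistent with AFT
#' fitting when `onset_days = 0`; a positive onset leaves early survival
#' near-identical across groups, emulating cohorts whose survival curves only
#' diverge well after the challenge.
#'
#' @param groups Data frame with columns `group` (labels from
#'   [group_design()]), `n` (positive integers) and `c` (positive time
#'   ratios vs Control; a Control entry must have `c = 1`).
#' @param baseline_shape Weibull shape k (> 0).
#' @param baseline_scale Weibull scale lambda in days (> 0).
#' @param onset_days Guaranteed-survival offset in days (>= 0).
#' @param seed Integer seed; identical configs yield identical cohorts.
#' @return A `cohort_sim_config` object.
#' @export
cohort_sim_config <- function(groups, baseline_shape, baseline_scale,
                              onset_days = 0, seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n", "c") %in% names(groups)),
            baseline_shape > 0, baseline_scale > 0, onset_days >= 0)
  if (any(!groups$group %in% cohort_group_levels()))
    stop("unknown group label(s): ",
         paste(setdiff(groups$group, cohort_group_levels()), collapse = ", "))
  if (anyDuplicated(groups$group)) stop("duplicate group entries")
  if (any(groups$n < 1) || any(groups$n != round(groups$n)))
    stop("group sizes must be positive integers")
  if (any(groups$c <= 0)) stop("time ratios c must be positive")
  if ("Control" %in% groups$group &&
      abs(groups$c[groups$group == "Control"] - 1) > 1e-12)
    stop("the Control entry must have c = 1")
  structure(list(groups = groups[, c("group", "n", "c")],
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 onset_days = onset_days,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a survival cohort
#'
#' Draws, for each configured group in declared order, `n` lifespans
#' `onset_days + c * rweibull(shape, scale)`. The full configuration is
#' recorded in the dataset metadata; the same config (including seed) always
#' reproduces the identical dataset.
#'
#' @param config A [cohort_sim_config()].
#' @return A [cohort_dataset()] with all events observed.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  g <- config$groups
  recs <- with_seed(config$seed, {
    do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      n <- g$n[i]
      life <- config$onset_days +
        g$c[i] * stats::rweibull(n, shape = config$baseline_shape,
                                 scale = config$baseline_scale)
      data.frame(individual_id = sprintf("%s_%04d", g$group[i], seq_len(n)),
                 group = g$group[i], lifespan_days = life, event = TRUE,
                 stringsAsFactors = FALSE)
    }))
  })
  meta <- list(
    generator = "agemax::generate_cohort",
    seed = config$seed,
    baseline_shape = config$baseline_shape,
    baseline_scale = config$baseline_scale,
    onset_days = config$onset_days,
    time_origin = "days post-hatch",
    groups = paste(sprintf("%s:n=%d,c=%g", g$group, g$n, g$c), collapse = ";"))
  cohort_dataset(recs, metadata = meta)
}

# Published group sizes and AFT time ratios of the T. molitor
# immune-challenge cohort the preset emulates.
tenebrio_design <- function() {
  data.frame(
    group = c("Control", "PC1", "PC2", "NylonLarval", "BacteriaAdult",
              "BacteriaLarval", "NylonAdult"),
    n = c(133L, 69L, 62L, 97L, 29L, 58L, 32L),
    c = c(1.000, 0.948, 0.933, 0.893, 0.891, 0.882, 0.836),
    stringsAsFactors = FALSE)
}

#' Simulate the Tenebrio molitor immune-challenge cohort
#'
#' Convenience preset emulating a seven-group mealworm-beetle ageing
#' experiment: the published group sizes (Control 133, PC1 69, PC2 62,
#' NylonLarval 97, BacteriaAdult 29, BacteriaLarval 58, NylonAdult 32) and
#' published AFT time ratios (0.836-1.000) on a Weibull baseline of shape 8,
#' with a 60-day shared onset before which no deaths occur. The baseline
#' scale is calibrated so the Control group's theoretical 90th-percentile
#' lifespan is 224 days: `scale = (224 - onset) / log(10)^(1/shape)`.
#'
#' @param seed Integer seed.
#' @param n_multiplier Integer factor inflating every group size (power
#'   studies; default 1 = published sizes).
#' @param onset_days Shared guaranteed-survival period (default 60).
#' @param baseline_shape Weibull shape (default 8).
#' @return A [cohort_dataset()].
#' @export
generate_tenebrio_cohort <- function(seed = 1L, n_multiplier = 1L,
                                     onset_days = 60, baseline_shape = 8) {
  stopifnot(n_multiplier >= 1, n_multiplier == round(n_multiplier))
  d <- tenebrio_design()
  d$n <- d$n * as.integer(n_multiplier)
  scale <- (224 - onset_days) / log(10)^(1 / baseline_shape)
  cfg <- cohort_sim_config(d, baseline_shape = baseline_shape,
                           baseline_scale = scale, onset_days = onset_days,
                           seed = seed)
  out <- generate_cohort(cfg)
  md <- attr(out, "metadata")
  md$preset <- "tenebrio"
  md$calibration_target <- "Control p90 = 224 days"
  attr(out, "metadata") <- md
  out
}

#' Configuration for a simulated kinetic absorbance trace
#'
#' Three-phase enzyme-kinetics trajectory: flat during an initial lag, then
#' linear at the configured reaction velocity, then saturating at a plateau
#' (substrate exhaustion / product absorbance ceiling), plus iid Gaussian
#' read noise. Defaults emulate a 60-minute phenoloxidase (L-DOPA) microplate
#' assay read every 15 s: 241 scheduled readings.
#'
#' @param lag_s Lag duration, seconds (>= 0; default 300).
#' @param slope_mod_per_min Linear-phase velocity in mOD/min (default 5).
#' @param start_od Baseline absorbance in OD (default 0.05).
#' @param plateau_od Saturation absorbance in OD (default 0.25; must be >=
#'   `start_od` when the slope is positive).
#' @param noise_sd_mod Read-noise SD in mOD (default 0.5).
#' @param duration_s Assay duration, seconds (default 3600).
#' @param interval_s Reading interval, seconds (default 15; must divide
#'   `duration_s` to within one reading).
#' @param seed Integer seed.
#' @return A `trace_sim_config` object.
#' @export
trace_sim_config <- function(lag_s = 300, slope_mod_per_min = 5,
                             start_od = 0.05, plateau_od = 0.25,
                             noise_sd_mod = 0.5, duration_s = 3600,
                             interval_s = 15, seed = 1L) {
  stopifnot(lag_s >= 0, noise_sd_mod >= 0, duration_s > 0, interval_s > 0)
  if (slope_mod_per_min > 0 && plateau_od < start_od)
    stop("plateau_od must be >= start_od for a positive slope")
  structure(list(lag_s = lag_s, slope_mod_per_min = slope_mod_per_min,
                 start_od = start_od, plateau_od = plateau_od,
                 noise_sd_mod = noise_sd_mod, duration_s = duration_s,
                 interval_s = interval_s, seed = as.integer(seed)),
            class = "trace_sim_config")
}

#' Simulate a kinetic absorbance trace
#'
#' @param config A [trace_sim_config()].
#' @param sample_id,group Identity of the simulated sample (default
#'   `"sim"`, `"Control"`).
#' @return A [kinetic_trace()].
#' @export
generate_trace <- function(config, sample_id = "sim", group = "Control") {
  stopifnot(inherits(config, "trace_sim_config"))
  times <- seq(0, config$duration_s, by = config$interval_s)
  slope_od_s <- config$slope_mod_per_min / 1000 / 60
  mean_od <- config$start_od + slope_od_s * pmax(0, times - config$lag_s)
  if (config$slope_mod_per_min > 0)
    mean_od <- pmin(mean_od, config$plateau_od)
  else if (config$slope_mod_per_min < 0)
    mean_od <- pmax(mean_od, config$plateau_od)
  noise <- with_seed(config$seed,
                     stats::rnorm(length(times), 0, config$noise_sd_mod / 1000))
  kinetic_trace(sample_id, group, times, mean_od + noise)
}
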