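# Shared fixture builders. Everything is generated in code; no stored data.

make_cohort <- function(lifespans_by_group, event = TRUE) {
  groups <- rep(names(lifespans_by_group), lengths(lifespans_by_group))
  cohort_dataset(data.frame(
    individual_id = sprintf("id%04d", seq_along(groups)),
    group = groups,
    lifespan_days = unlist(lifespans_by_group, use.names = FALSE),
    event = event,
    stringsAsFactors = FALSE))
}

# Two-arm Weibull cohort with a pure time-ratio effect (AFT ground truth).
make_aft_cohort <- function(cstar, n = 130, shape = 8, scale = 150,
                            onset = 0, seed = 1) {
  g <- data.frame(group = c("Control", "NylonLarval"),
                  n = c(n, n), c = c(1, cstar))
  generate_cohort(cohort_sim_config(
    g, baseline_shape = shape, baseline_scale = scale,
    onset_days = onset, seed = seed))
}

random_cohort <- function(seed) {
  with_seed <- agemax:::with_seed
  with_seed(seed, {
    levels <- group_design()$group
    k <- sample(2:4, 1)
    gs <- sample(levels, k)
    make_cohort(stats::setNames(
      lapply(seq_len(k), function(i) round(stats::rlnorm(sample(3:9, 1), 5, 0.3), 3)),
      gs))
  })
}
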