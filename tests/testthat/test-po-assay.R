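test_that("a noiseless linear trace recovers its slope over the full trace", {
  cfg <- trace_sim_config(lag_s = 0, plateau_od = 10, noise_sd_mod = 0,
                          slope_mod_per_min = 5)
  v <- extract_vmax(generate_trace(cfg))
  expect_equal(v$vmax, 5, tolerance = 1e-9)
  expect_equal(unname(v$window), c(1L, 241L))
  expect_equal(v$r_squared, 1)
  expect_false(v$flagged)
})

test_that("a strictly flat trace is perfectly linear with Vmax 0", {
  tr <- kinetic_trace("flat", "Water", seq(0, 3600, 15), rep(0.05, 241))
  v <- extract_vmax(tr)
  expect_equal(v$vmax, 0, tolerance = 1e-9)
  expect_false(v$flagged)
  expect_equal(v$r_squared, 1)
})

test_that("three-phase traces with read noise recover the true velocity", {
  est <- vapply(1:40, function(s)
    extract_vmax(generate_trace(trace_sim_config(seed = s)))$vmax, numeric(1))
  expect_lt(abs(mean(est) - 5) / 5, 0.02)
  # the selected window excludes lag (starts after reading 20 = 300 s)
  w <- extract_vmax(generate_trace(trace_sim_config(seed = 101)))$window
  expect_gt(w["start"], 15)
})

test_that("short traces are rejected; short windows are clamped", {
  expect_error(extract_vmax(kinetic_trace("s", "Water", 1:5, 1:5)),
               "at least 12")
  tr <- kinetic_trace("s", "Water", seq(0, 180, 15), seq(0, 0.12, 0.01))
  v <- extract_vmax(tr, min_window = 50)  # clamped to trace length
  expect_false(v$flagged)
})

test_that("vmax in per-minute units is invariant to the time unit density", {
  # same chemistry read every 5 s instead of 15 s
  f1 <- extract_vmax(generate_trace(trace_sim_config(seed = 3)))
  f2 <- extract_vmax(generate_trace(trace_sim_config(interval_s = 5, seed = 3)),
                     min_window = 60)
  expect_lt(abs(f1$vmax - f2$vmax) / f1$vmax, 0.02)
})

test_that("raising the linearity bar never lowers the selected window's R^2", {
  tr <- generate_trace(trace_sim_config(seed = 8, noise_sd_mod = 2))
  thresholds <- c(0.95, 0.99, 0.999)
  r2s <- vapply(thresholds, function(th)
    extract_vmax(tr, r2_threshold = th)$r_squared, numeric(1))
  flags <- vapply(thresholds, function(th)
    extract_vmax(tr, r2_threshold = th)$flagged, logical(1))
  keep <- !flags
  expect_true(all(diff(r2s[keep]) >= -1e-12))
})

test_that("hand-computed one-way ANOVA decomposition", {
  res <- anova_oneway(list(A = c(1, 2, 3), B = c(2, 3, 4)))
  expect_equal(res$ss_between, 1.5)
  expect_equal(res$ss_within, 4)
  expect_equal(res$f_stat, 1.5)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  expect_equal(res$ss_total, res$ss_between + res$ss_within)
  # five groups -> df between 4
  set.seed(2)
  five <- anova_oneway(split(rnorm(50), rep(letters[1:5], 10)))
  expect_equal(five$df_between, 4L)
})

test_that("ANOVA guards degenerate inputs", {
  expect_error(anova_oneway(list(A = 1:3)), "at least 2 groups")
  expect_error(anova_oneway(list(A = 1:3, B = 5)), "fewer than 2 values")
  expect_error(anova_oneway(list(A = c(2, 2), B = c(3, 3))),
               "zero within-group variance")
})

test_that("SS identity holds on random data", {
  set.seed(13)
  for (i in 1:10) {
    vals <- split(rnorm(60, sd = runif(1, 0.5, 3)), rep(1:4, 15))
    names(vals) <- paste0("g", 1:4)
    res <- anova_oneway(vals)
    expect_equal(res$ss_total, res$ss_between + res$ss_within,
                 tolerance = 1e-9)
  }
})

test_that("pipeline binds traces to groups and excludes the unusable", {
  mk <- function(id, group, slope, seed)
    generate_trace(trace_sim_config(slope_mod_per_min = slope, seed = seed),
                   sample_id = id, group = group)
  traces <- c(lapply(1:4, function(i) mk(paste0("c", i), "Control", 5, i)),
              lapply(1:4, function(i) mk(paste0("n", i), "Nylon", 5, 10 + i)))
  out <- po_pipeline(traces)
  expect_equal(nrow(out$vmax_table), 8L)
  expect_gt(out$anova$p, 0.05)  # equal true slopes: null construction

  # a doubled-velocity group is detected
  traces2 <- c(traces[1:4],
               lapply(1:4, function(i) mk(paste0("b", i), "Bacteria", 10, 20 + i)))
  out2 <- po_pipeline(traces2)
  expect_lt(out2$anova$p, 0.001)

  # group_map overrides and must cover all samples
  gm <- data.frame(sample_id = c(paste0("c", 1:4), paste0("n", 1:4)),
                   group = rep(c("Water", "Stab"), each = 4))
  out3 <- po_pipeline(traces, group_map = gm)
  expect_setequal(unique(out3$vmax_table$group), c("Water", "Stab"))
  expect_error(po_pipeline(traces, group_map = gm[-1, ]),
               "missing from group map: c1")
})
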