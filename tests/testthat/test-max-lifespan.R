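test_that("pooled quantile follows the interpolated order-statistic rule", {
  ds <- make_cohort(list(Control = 1:10))
  expect_equal(pooled_quantile(ds, 0.9), 9.1)  # h = 9.1
  expect_equal(pooled_quantile(make_cohort(list(Control = rep(100, 7))), 0.5),
               100)
  # pooling identity: single group pools to itself
  expect_equal(pooled_quantile(ds, 0.73),
               unname(group_quantiles(ds, 0.73)["Control"]))
})

test_that("quantiles refuse censored records and empty input", {
  cen <- make_cohort(list(Control = c(10, 20, 30)), event = c(TRUE, FALSE, TRUE))
  expect_error(pooled_quantile(cen), "censored")
  expect_error(group_quantiles(cen), "censored")
  empty <- cohort_dataset(data.frame(individual_id = character(),
                                     group = character(),
                                     lifespan_days = numeric(),
                                     event = logical()))
  expect_error(pooled_quantile(empty), "empty")
})

test_that("group quantiles handle identical, degenerate, and small groups", {
  ds <- make_cohort(list(Control = 1:10, PC1 = 1:10))
  q <- group_quantiles(ds, 0.9)
  expect_equal(unname(q["Control"]), unname(q["PC1"]))
  expect_warning(q1 <- group_quantiles(make_cohort(list(Control = 1:5, PC1 = 42)),
                                       0.9), "fewer than 2")
  expect_equal(unname(q1["PC1"]), 42)  # single order statistic
})

test_that("reaching the threshold is inclusive", {
  ds <- make_cohort(list(Control = c(5, 10)))
  r <- proportion_reaching(ds, "Control", 10)
  expect_equal(r$x, 1L)
  expect_equal(r$prop, 0.5)
  expect_equal(proportion_reaching(ds, "Control", 0)$prop, 1)
  expect_equal(proportion_reaching(ds, "Control", 11)$prop, 0)
  expect_error(proportion_reaching(ds, "PC1", 10), "not present")
})

test_that("comparison wiring is internally consistent", {
  ds <- generate_tenebrio_cohort(seed = 2)
  cmp <- compare_max_lifespan(ds, "Control", "NylonAdult")
  # threshold comes from the whole cohort, not the pair
  expect_equal(cmp$threshold_days, pooled_quantile(ds, 0.9))
  expect_equal(cmp$counts$x1 / cmp$counts$n1, cmp$prop_control)
  expect_equal(cmp$counts$x2 / cmp$counts$n2, cmp$prop_treatment)
  expect_equal(cmp$treatment_effect, cmp$prop_control / cmp$prop_treatment)
  expect_error(compare_max_lifespan(ds, "Control", "Control"), "disjoint")
})

test_that("split halves of one group behave as a null self-comparison", {
  x <- agemax:::with_seed(7, rweibull(200, 8, 150))
  ds <- make_cohort(list(Control = x[1:100], PC1 = x[101:200]))
  cmp <- compare_max_lifespan(ds, "Control", "PC1")
  expect_gt(cmp$test$p_value, 0.05)
  expect_lt(abs(cmp$treatment_effect - 1), 0.6)
})

test_that("inflated preset cohort shows acceleration in every challenged group", {
  ds <- generate_tenebrio_cohort(seed = 4, n_multiplier = 10)
  for (g in c("NylonLarval", "NylonAdult", "BacteriaLarval", "BacteriaAdult")) {
    cmp <- compare_max_lifespan(ds, "Control", g)
    expect_gt(cmp$treatment_effect, 1)
  }
  # and Control's own quantile tops every challenged group's
  q <- group_quantiles(ds)
  expect_true(all(q["Control"] >
                    q[c("NylonLarval", "NylonAdult", "BacteriaLarval",
                        "BacteriaAdult")]))
})

test_that("a vanished treatment arm yields an infinite flagged effect", {
  ds <- make_cohort(list(Control = c(rep(50, 8), rep(100, 2)),
                         PC1 = rep(40, 10)))
  cmp <- compare_max_lifespan(ds, "Control", "PC1", q = 0.9)
  expect_true(cmp$effect_infinite)
  expect_identical(cmp$treatment_effect, Inf)
  expect_lte(cmp$test$p_value, 1)  # test still valid
})

test_that("threshold lies between the extreme group quantiles and counts add up", {
  for (seed in c(3, 9)) {
    ds <- generate_tenebrio_cohort(seed = seed)
    thr <- pooled_quantile(ds)
    q <- group_quantiles(ds)
    expect_gte(thr, min(q)); expect_lte(thr, max(q))
    xs <- vapply(unique(ds$group), function(g)
      proportion_reaching(ds, g, thr)$x, integer(1))
    expect_equal(sum(xs), sum(ds$lifespan_days >= thr))
  }
})

test_that("divergence scan skips degenerate days and finds delayed effects", {
  ds <- generate_tenebrio_cohort(seed = 5, n_multiplier = 4)
  scan <- divergence_scan(ds)
  expect_equal(nrow(scan), 99L)
  expect_true(all(scan$df[!is.na(scan$df)] == 6L))  # 7 groups -> df 6
  fs_day <- attr(scan, "first_significant_day")
  expect_false(is.na(fs_day))
  # shared 60-day onset: no group differences can exist before day 60
  expect_gt(fs_day, 60)
  early <- scan[scan$day < 60, ]
  expect_true(all(is.na(early$p)))
})

test_that("a homogeneous cohort rarely shows early divergence", {
  g <- data.frame(group = c("Control", "PC1", "PC2"),
                  n = c(70, 70, 70), c = c(1, 1, 1))
  ds <- generate_cohort(cohort_sim_config(
    g, baseline_shape = 8, baseline_scale = 150, onset_days = 0, seed = 31))
  scan <- divergence_scan(ds)
  expect_true(all(scan$df[!is.na(scan$df)] == 2L))
  # null: roughly alpha of scanned quantiles significant, not a systematic run
  expect_lt(mean(scan$p < 0.05, na.rm = TRUE), 0.3)
})
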