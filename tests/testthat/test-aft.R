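test_that("an exact 0.9 time-ratio is recovered analytically", {
  ctrl <- c(10, 20, 30, 40)
  ds <- make_cohort(list(Control = ctrl, NylonLarval = 0.9 * ctrl))
  for (d in c("weibull", "lognormal")) {
    fit <- fit_aft(ds, "Control", "NylonLarval", d)
    expect_equal(fit$c, 0.9, tolerance = 1e-6)
    expect_equal(fit$beta_treatment, log(0.9), tolerance = 1e-6)
  }
})

test_that("self-comparison gives c = 1 with a bracketing CI", {
  ds <- generate_tenebrio_cohort(seed = 6)
  fit <- fit_aft(ds, "Control", "Control", "weibull")
  expect_true(fit$self_comparison)
  expect_equal(fit$c, 1, tolerance = 1e-6)
  expect_lt(fit$c_ci[1], 1); expect_gt(fit$c_ci[2], 1)
})

test_that("exponential is nested in weibull: loglik never higher", {
  for (seed in c(1, 2, 3)) {
    ds <- make_aft_cohort(0.88, n = 60, seed = seed)
    lw <- fit_aft(ds, "Control", "NylonLarval", "weibull")$loglik
    le <- fit_aft(ds, "Control", "NylonLarval", "exponential")$loglik
    expect_lte(le, lw + 1e-8)
  }
})

test_that("AIC bookkeeping is exact and parameter counts correct", {
  ds <- make_aft_cohort(0.9, n = 50, seed = 4)
  fw <- fit_aft(ds, "Control", "NylonLarval", "weibull")
  fe <- fit_aft(ds, "Control", "NylonLarval", "exponential")
  expect_equal(fw$aic, -2 * fw$loglik + 2 * fw$n_params)
  expect_equal(fw$n_params, 3L)
  expect_equal(fe$n_params, 2L)
})

test_that("time-ratio estimates are equivariant to time rescaling", {
  ds <- make_aft_cohort(0.85, n = 80, seed = 9)
  ds2 <- ds; ds2$lifespan_days <- ds2$lifespan_days * 7.3
  for (d in c("weibull", "lognormal", "exponential")) {
    f1 <- fit_aft(ds, "Control", "NylonLarval", d)
    f2 <- fit_aft(ds2, "Control", "NylonLarval", d)
    expect_equal(f1$c, f2$c, tolerance = 1e-6)
    expect_equal(f1$c_ci, f2$c_ci, tolerance = 1e-6)
  }
})

test_that("right-censoring enters the likelihood without flipping strong effects", {
  ds <- make_aft_cohort(0.8, n = 500, seed = 12)
  f0 <- fit_aft(ds, "Control", "NylonLarval", "weibull")
  cen <- ds
  idx <- which(cen$group == "NylonLarval")
  top <- idx[order(-cen$lifespan_days[idx])[1:25]]  # censor largest 5%
  cen$event[top] <- FALSE
  f1 <- fit_aft(cen, "Control", "NylonLarval", "weibull")
  expect_lt(abs(f1$c - f0$c), 0.05)
  expect_lt(f1$c_ci[2], 1)  # effect direction intact
})

test_that("degenerate data are rejected", {
  ds <- make_cohort(list(Control = rep(10, 5), PC1 = rep(10, 5)))
  expect_error(fit_aft(ds, "Control", "PC1", "weibull"), "zero-variance")
})

test_that("gaussian family reports a median ratio in place of a time ratio", {
  ds <- make_aft_cohort(0.9, n = 200, seed = 14)
  fg <- fit_aft(ds, "Control", "NylonLarval", "gaussian")
  expect_true(fg$c_is_median_ratio)
  expect_lt(fg$c, 1)
  expect_gt(fg$c, 0.8)
})

test_that("distribution selection prefers the generating family", {
  ds <- make_aft_cohort(0.9, n = 500, seed = 15)
  sel <- select_distribution(ds, "Control", "NylonLarval")
  expect_true(sel$best %in% c("weibull", "exponential"))
  expect_equal(unname(sel$delta_aic[sel$best]), 0)
  expect_length(sel$minus2ll, length(sel$fits))
  # refitting is deterministic
  sel2 <- select_distribution(ds, "Control", "NylonLarval")
  expect_equal(sel$fits$weibull$aic, sel2$fits$weibull$aic)
})

test_that("QQ diagnostics reflect constant and non-constant effects", {
  ctrl <- seq(10, 100, by = 10)
  ds <- make_cohort(list(Control = ctrl, NylonLarval = 0.9 * ctrl))
  qq <- qq_diagnostic(ds, "Control", "NylonLarval", probs = c(0.25, 0.5, 0.75))
  expect_equal(qq$ratio, rep(0.9, 3), tolerance = 1e-12)
  ident <- make_cohort(list(Control = ctrl, PC1 = ctrl))
  expect_equal(qq_diagnostic(ident, "Control", "PC1")$ratio,
               rep(1, 19))
  # delayed-onset generator: effect weaker at early quantiles
  g <- data.frame(group = c("Control", "NylonAdult"), n = c(4000, 4000),
                  c = c(1, 0.8))
  dd <- generate_cohort(cohort_sim_config(
    g, baseline_shape = 8, baseline_scale = 150, onset_days = 60, seed = 16))
  r <- qq_diagnostic(dd, "Control", "NylonAdult", probs = c(0.1, 0.9))$ratio
  expect_gt(r[1], r[2])
  expect_error(qq_diagnostic(ds, "Control", "NylonLarval", probs = c(0, 0.5)))
})

test_that("the comparison table is complete, ordered, and anchored at c = 1", {
  ds <- generate_tenebrio_cohort(seed = 17, n_multiplier = 10)
  rep_tab <- aft_report(ds)
  expect_equal(nrow(rep_tab), 7L)  # 6 comparisons + self reference
  expect_true(all(diff(rep_tab$c) <= 0))  # descending
  expect_equal(rep_tab$group[1], "Control")  # all effects harmful -> c = 1 tops
  expect_equal(rep_tab$c[1], 1, tolerance = 1e-6)
  expect_equal(rep_tab$one_minus_c, 1 - rep_tab$c)
  # at inflated n the recovered ordering separates strong from weak effects
  expect_lt(rep_tab$c[rep_tab$group == "NylonAdult"],
            rep_tab$c[rep_tab$group == "PC1"])
  expect_true(all(rep_tab$c[rep_tab$group %in%
                              c("NylonLarval", "NylonAdult",
                                "BacteriaLarval", "BacteriaAdult")] < 1))
})
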