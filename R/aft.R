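aft_distributions <- function() c("weibull", "exponential", "lognormal", "gaussian")

# Assemble the two-arm analysis frame. treatment == control requests the
# self-comparison reference fit: the arm is duplicated and labelled 0/1, so
# the maximum-likelihood treatment coefficient is exactly 0 (c = 1).
aft_frame <- function(dataset, control, treatment) {
  dc <- lifespans_of(dataset, groups = control)
  dt <- lifespans_of(dataset, groups = treatment)
  if (nrow(dc) == 0L || nrow(dt) == 0L) stop("both arms must be non-empty")
  self <- setequal(control, treatment)
  if (!self && length(intersect(control, treatment)) > 0L)
    stop("control and treatment groups must be disjoint (or identical for a self-comparison)")
  data.frame(
    time = c(dc$lifespan_days, dt$lifespan_days),
    event = c(dc$event, dt$event),
    treat = rep(c(0, 1), c(nrow(dc), nrow(dt))))
}

#' Fit an accelerated failure time model for one comparison
#'
#' Maximum-likelihood location-scale survival regression of one treatment
#' arm against a control arm, via [survival::survreg()]. For the log-time
#' families (weibull, exponential = weibull with the error scale fixed at 1,
#' lognormal) the treatment coefficient acts multiplicatively on survival
#' time and the time ratio is `c = exp(beta)`: `c = 0.9` means the treatment
#' arm lives 90% as long at every survival quantile. The gaussian family
#' acts additively on untransformed time, where no constant time ratio
#' exists; its `c` is reported as the ratio of predicted median survival
#' times (treatment/control) to keep the interface uniform, and flagged via
#' `c_is_median_ratio`. Confidence intervals are Wald at 95%, formed on the
#' coefficient scale and transformed. Right-censored records enter the
#' likelihood in the standard way.
#'
#' @param dataset A [cohort_dataset()].
#' @param control Control group label(s).
#' @param treatment Treatment group label(s) (pooled if several); pass the
#'   control label itself for the self-comparison reference fit (`c = 1`).
#' @param distribution One of `"weibull"`, `"exponential"`, `"lognormal"`,
#'   `"gaussian"`.
#' @return An `aft_fit`: `distribution`, `intercept`, `beta_treatment`,
#'   `scale_sigma`, `loglik`, `n_params`, `aic`, `c`, `c_ci`, `wald_z`,
#'   `wald_p`, `c_is_median_ratio`, `n` (per-arm sizes).
#' @export
fit_aft <- function(dataset, control = "Control", treatment,
                    distribution = c("weibull", "exponential", "lognormal",
                                     "gaussian")) {
  distribution <- match.arg(distribution)
  df <- aft_frame(dataset, control, treatment)
  if (any(df$time <= 0)) stop("lifespans must be positive")
  if (stats::sd(df$time) == 0) stop("zero-variance degenerate data")

  warn <- NULL
  fit <- withCallingHandlers(
    survival::survreg(survival::Surv(time, event) ~ treat, data = df,
                      dist = distribution,
                      control = survival::survreg.control(
                        maxiter = 100, rel.tolerance = 1e-11)),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (!is.null(warn) && grepl("Ran out of iterations", warn))
    stop("AFT fit did not converge (", distribution, "): ", warn)

  beta <- unname(stats::coef(fit)["treat"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  se <- sqrt(stats::vcov(fit)["treat", "treat"])
  ll <- fit$loglik[2L]
  k <- length(stats::coef(fit)) + if (distribution == "exponential") 0L else 1L
  zcrit <- stats::qnorm(0.975)

  if (distribution == "gaussian") {
    if (intercept <= 0) stop("gaussian fit has non-positive control median")
    cval <- (intercept + beta) / intercept
    ci <- (intercept + beta + c(-1, 1) * zcrit * se) / intercept
    median_ratio <- TRUE
  } else {
    cval <- exp(beta)
    ci <- exp(beta + c(-1, 1) * zcrit * se)
    median_ratio <- FALSE
  }

  structure(list(
    distribution = distribution,
    control = control, treatment = treatment,
    self_comparison = setequal(control, treatment),
    intercept = intercept,
    beta_treatment = beta,
    scale_sigma = fit$scale,
    loglik = ll,
    n_params = k,
    aic = -2 * ll + 2 * k,
    c = cval,
    c_ci = ci,
    se_beta = se,
    wald_z = beta / se,
    wald_p = 2 * stats::pnorm(-abs(beta / se)),
    c_is_median_ratio = median_ratio,
    n = c(control = sum(df$treat == 0), treatment = sum(df$treat == 1))),
    class = "aft_fit")
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf(
    "AFT fit (%s): %s vs %s\n  c = %.4f [%.4f, %.4f]%s, Wald p = %.4g\n  loglik = %.3f, AIC = %.3f (k = %d)\n",
    x$distribution, paste(x$control, collapse = "+"),
    paste(x$treatment, collapse = "+"),
    x$c, x$c_ci[1], x$c_ci[2],
    if (x$c_is_median_ratio) " (median ratio)" else "",
    x$wald_p, x$loglik, x$aic, x$n_params))
  invisible(x)
}

#' Choose an AFT distribution by AIC
#'
#' Fits all four candidate families (Weibull, exponential, lognormal,
#' gaussian) to the same comparison and selects the one minimising AIC
#' (`-2 logLik + 2k`). Failed fits are recorded and excluded. Ties are
#' broken toward fewer parameters, then by the declared family order.
#' Because the exponential is the Weibull with its error scale fixed, the
#' two orderings by AIC and by `-2 logLik` alone can only differ between
#' that nested pair; both are returned.
#'
#' @inheritParams fit_aft
#' @return A `distribution_selection`: `fits` (named list of `aft_fit`),
#'   `best`, `delta_aic`, `minus2ll`, `failed` (named character vector of
#'   error messages).
#' @export
select_distribution <- function(dataset, control = "Control", treatment) {
  fits <- list()
  failed <- character(0)
  for (d in aft_distributions()) {
    res <- tryCatch(fit_aft(dataset, control, treatment, distribution = d),
                    error = function(e) e)
    if (inherits(res, "error")) failed[d] <- conditionMessage(res)
    else fits[[d]] <- res
  }
  if (length(fits) == 0L)
    stop("all candidate distributions failed to fit: ",
         paste(failed, collapse = " | "))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ks <- vapply(fits, `[[`, numeric(1), "n_params")
  ord <- order(aics, ks, match(names(fits), aft_distributions()))
  best <- names(fits)[ord[1L]]
  structure(list(
    fits = fits,
    best = best,
    delta_aic = aics - aics[[best]],
    minus2ll = -2 * vapply(fits, `[[`, numeric(1), "loglik"),
    failed = failed), class = "distribution_selection")
}

#' @export
print.distribution_selection <- function(x, ...) {
  cat("AFT distribution selection (best:", x$best, ")\n")
  for (d in names(x$fits))
    cat(sprintf("  %-11s AIC = %9.3f  dAIC = %7.3f  -2LL = %9.3f\n",
                d, x$fits[[d]]$aic, x$delta_aic[[d]], x$minus2ll[[d]]))
  if (length(x$failed) > 0L)
    cat("  failed:", paste(names(x$failed), collapse = ", "), "\n")
  invisible(x)
}

#' Quantile-quantile diagnostic for an AFT comparison
#'
#' Empirical lifespans of the two arms at matched probabilities, plus their
#' ratio. Under a perfect accelerated-failure-time effect the ratio is
#' constant across probabilities (a straight-line QQ plot through the
#' origin); systematic drift in the ratio indicates a treatment effect that
#' varies over the lifespan (e.g. delayed onset). Returned as a data table;
#' plotting is left to the caller.
#'
#' @inheritParams fit_aft
#' @param probs Probabilities in (0, 1) (default `seq(0.05, 0.95, 0.05)`).
#' @return Data frame with `prob`, `t_control`, `t_treatment`, `ratio`.
#' @export
qq_diagnostic <- function(dataset, control = "Control", treatment,
                          probs = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(probs > 0 & probs < 1))
  dc <- lifespans_of(dataset, groups = control)
  dt <- lifespans_of(dataset, groups = treatment)
  require_all_events(dc, "qq_diagnostic")
  require_all_events(dt, "qq_diagnostic")
  qc <- unname(stats::quantile(dc$lifespan_days, probs = probs, type = 7))
  qt <- unname(stats::quantile(dt$lifespan_days, probs = probs, type = 7))
  data.frame(prob = probs, t_control = qc, t_treatment = qt, ratio = qt / qc)
}

#' Tabulated AFT comparisons of every group against a control
#'
#' One row per treatment group compared with the control, plus the control
#' self-comparison reference row (`c = 1` by construction), sorted in
#' descending order of the time ratio `c`. `one_minus_c` restates each
#' effect as the proportional lifespan reduction.
#'
#' @param dataset A [cohort_dataset()].
#' @param control Control group label.
#' @param groups Treatment groups to compare (default: every other group
#'   present, in data order).
#' @param distribution AFT family for every row (default `"weibull"`), or
#'   `"auto"` to select per comparison by AIC.
#' @return Data frame with columns `group`, `distribution`, `n`, `c`,
#'   `c_lower`, `c_upper`, `one_minus_c`, `wald_z`, `wald_p`, `loglik`,
#'   `aic`.
#' @export
aft_report <- function(dataset, control = "Control", groups = NULL,
                       distribution = "weibull") {
  if (is.null(groups)) groups <- setdiff(unique(dataset$group), control)
  comparisons <- c(list(control), as.list(groups))
  rows <- lapply(comparisons, function(g) {
    fit <- if (identical(distribution, "auto")) {
      sel <- select_distribution(dataset, control, g)
      sel$fits[[sel$best]]
    } else {
      fit_aft(dataset, control, g, distribution = distribution)
    }
    data.frame(group = paste(g, collapse = "+"),
               distribution = fit$distribution,
               n = unname(fit$n["treatment"]),
               c = fit$c, c_lower = fit$c_ci[1], c_upper = fit$c_ci[2],
               one_minus_c = 1 - fit$c,
               wald_z = fit$wald_z, wald_p = fit$wald_p,
               loglik = fit$loglik, aic = fit$aic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$c), , drop = FALSE]
  rownames(out) <- NULL
  out
}
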