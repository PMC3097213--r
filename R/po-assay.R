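# Rolling OLS over all contiguous windows of a trace, via cumulative sums.
# Returns slope (y-units per x-unit) and R^2 for every window of length L
# starting at each admissible index.
window_ols <- function(x, y, L) {
  n <- length(x)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  starts <- seq_len(n - L + 1L)
  ends <- starts + L - 1L
  wsum <- function(cs) cs[ends] - c(0, cs)[starts]
  Sx <- wsum(cx); Sy <- wsum(cy)
  Sxx <- wsum(cxx); Sxy <- wsum(cxy); Syy <- wsum(cyy)
  vx <- L * Sxx - Sx^2
  vy <- L * Syy - Sy^2
  cov <- L * Sxy - Sx * Sy
  slope <- cov / vx
  # a numerically zero-variance (flat) response is perfectly linear by
  # convention; the threshold is relative to the magnitude of the summands
  # so cancellation noise in the cumulative sums is not mistaken for signal
  flat <- vy <= 1e-12 * (L * Syy + Sy^2 + 1e-300)
  r2 <- ifelse(flat, 1, cov^2 / (vx * vy))
  list(start = starts, end = ends, slope = slope, r2 = pmin(1, r2))
}

#' Extract Vmax from a kinetic trace
#'
#' Algorithmic version of the manual straight-line read-off used in
#' microplate enzyme kinetics. Among all contiguous reading windows of at
#' least `min_window` points that meet the linearity criterion
#' R^2 >= `r2_threshold`, the window with the maximal OLS slope anchors the
#' read-out: it locates the steepest, i.e. maximal-velocity, phase of the
#' reaction, skipping the initial lag and the final levelling-off. The
#' reported Vmax (mOD/min) is then the slope of the *most linear* (maximal
#' R^2; ties to the longer, then earlier) qualifying window containing that
#' anchor — in a well-behaved trace, the whole straight-line phase: within
#' the clean linear phase R^2 grows with window length, and falls as soon
#' as lag or plateau readings contaminate the window, so the R^2 maximum
#' brackets the straight-line region tightly. Estimating the slope over
#' that full phase rather than the short anchor window keeps the estimator
#' from chasing read noise (the steepest short window is upward-biased
#' under noise) while still honouring the maximal-velocity definition when
#' a trace has segments of genuinely different slope. A noiseless linear
#' trace selects the full trace. If no window meets the criterion the
#' full-trace fit is returned with `flagged = TRUE`.
#'
#' A strictly flat trace has Vmax 0 with R^2 = 1 (a flat line is perfectly
#' linear) and is not flagged.
#'
#' @param trace A [kinetic_trace()] with at least 12 readings.
#' @param min_window Minimum window length in readings (default 20 = 5 min
#'   at 15-s intervals).
#' @param r2_threshold Linearity criterion (default 0.99).
#' @return A `vmax_result`: `sample_id`, `group`, `vmax` (mOD/min),
#'   `window` (start and end reading indices), `r_squared`, `flagged`.
#' @export
extract_vmax <- function(trace, min_window = 20L, r2_threshold = 0.99) {
  stopifnot(inherits(trace, "kinetic_trace"), min_window >= 2L)
  n <- length(trace$times_s)
  if (n < 12L)
    stop("trace ", trace$sample_id, " has ", n,
         " readings; at least 12 required")
  min_window <- min(min_window, n)
  x <- trace$times_s
  y <- trace$absorbance

  qual <- do.call(rbind, lapply(min_window:n, function(L) {
    w <- window_ols(x, y, L)
    ok <- which(w$r2 >= r2_threshold - 1e-12)
    if (length(ok) == 0L) return(NULL)
    data.frame(start = w$start[ok], end = w$end[ok], L = L,
               slope = w$slope[ok], r2 = w$r2[ok])
  }))

  flagged <- is.null(qual)
  if (flagged) {
    w <- window_ols(x, y, n)
    best <- list(slope = w$slope[1L], r2 = w$r2[1L], start = 1L, end = n)
  } else {
    # anchor: maximal slope; numerically tied slopes prefer the longer,
    # then earlier, window (so an exactly linear trace anchors on itself)
    smax <- max(qual$slope)
    tied <- qual[qual$slope >= smax - (abs(smax) * 1e-9 + 1e-15), , drop = FALSE]
    anchor <- tied[order(-tied$L, tied$start), ][1L, ]
    # read-out: most linear qualifying window containing the anchor
    containing <- qual[qual$start <= anchor$start & qual$end >= anchor$end, ,
                       drop = FALSE]
    best <- containing[order(-containing$r2, -containing$L,
                             containing$start), ][1L, ]
  }
  structure(list(
    sample_id = trace$sample_id,
    group = trace$group,
    vmax = best$slope * 60000,        # OD/s -> mOD/min
    window = c(start = best$start, end = best$end),
    r_squared = best$r2,
    flagged = flagged), class = "vmax_result")
}

#' @export
print.vmax_result <- function(x, ...) {
  cat(sprintf("Vmax %s [%s]: %.4f mOD/min over readings %d-%d (R^2 = %.4f)%s\n",
              x$sample_id, x$group, x$vmax, x$window["start"], x$window["end"],
              x$r_squared, if (x$flagged) " [flagged: no linear window]" else ""))
  invisible(x)
}

#' One-way analysis of variance across groups
#'
#' Classic fixed-effects one-way decomposition (equal-variance F test, via
#' [stats::oneway.test()]), with group means, standard errors of the mean,
#' and the sum-of-squares decomposition attached.
#'
#' @param values Named list mapping each group to its numeric values; at
#'   least 2 groups with at least 2 values each, and positive pooled
#'   within-group variance.
#' @return An `anova_result`: `f_stat`, `df_between`, `df_within`, `p`,
#'   `group_means`, `group_sems`, `ss_between`, `ss_within`, `ss_total`.
#' @export
anova_oneway <- function(values) {
  stopifnot(is.list(values), !is.null(names(values)))
  if (length(values) < 2L) stop("need at least 2 groups")
  sizes <- lengths(values)
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 values: ",
         paste(names(values)[sizes < 2L], collapse = ", "))
  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), sizes), levels = names(values))
  means <- vapply(values, mean, numeric(1))
  ss_within <- sum((y - means[as.integer(g)])^2)
  if (ss_within <= 0) stop("zero within-group variance; F undefined")
  ss_total <- sum((y - mean(y))^2)
  ss_between <- ss_total - ss_within
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(list(
    f_stat = unname(ow$statistic),
    df_between = unname(ow$parameter["num df"]),
    df_within = unname(ow$parameter["denom df"]),
    p = unname(ow$p.value),
    group_means = means,
    group_sems = vapply(values, function(v) stats::sd(v) / sqrt(length(v)),
                        numeric(1)),
    ss_between = ss_between, ss_within = ss_within, ss_total = ss_total),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4f; df = %d, %d; P = %.4g\n",
              x$f_stat, x$df_between, x$df_within, x$p))
  invisible(x)
}

#' Phenoloxidase assay pipeline: traces to Vmax to group ANOVA
#'
#' Reads (or accepts) kinetic traces, extracts each sample's Vmax, and
#' compares group mean Vmax by one-way ANOVA. Samples flagged by
#' [extract_vmax()] (no sufficiently linear window) are excluded from the
#' ANOVA with a logged count; groups left with fewer than 2 usable samples
#' are dropped with a warning.
#'
#' @param traces Path to a long-format trace CSV (see [read_traces()]) or a
#'   list of [kinetic_trace()] objects.
#' @param group_map Optional data frame `sample_id`, `group` overriding the
#'   group carried by each trace; every sample must be mapped.
#' @param min_window,r2_threshold Passed to [extract_vmax()].
#' @return List with `vmax_table` (one row per sample: `sample_id`, `group`,
#'   `vmax`, `r_squared`, `flagged`), `anova` (an `anova_result`, or `NULL`
#'   if fewer than 2 usable groups remain), and `n_flagged`.
#' @export
po_pipeline <- function(traces, group_map = NULL, min_window = 20L,
                        r2_threshold = 0.99) {
  if (is.character(traces)) traces <- read_traces(traces)
  stopifnot(is.list(traces), length(traces) > 0L)
  if (!is.null(group_map)) {
    stopifnot(all(c("sample_id", "group") %in% names(group_map)))
    for (i in seq_along(traces)) {
      j <- match(traces[[i]]$sample_id, group_map$sample_id)
      if (is.na(j))
        stop("sample missing from group map: ", traces[[i]]$sample_id)
      traces[[i]]$group <- group_map$group[j]
    }
  }
  res <- lapply(traces, extract_vmax, min_window = min_window,
                r2_threshold = r2_threshold)
  tab <- do.call(rbind, lapply(res, function(r)
    data.frame(sample_id = r$sample_id, group = r$group, vmax = r$vmax,
               r_squared = r$r_squared, flagged = r$flagged,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  n_flagged <- sum(tab$flagged)
  if (n_flagged > 0L)
    message(n_flagged, " flagged sample(s) excluded from ANOVA")
  usable <- tab[!tab$flagged, , drop = FALSE]
  values <- split(usable$vmax, usable$group)
  small <- names(values)[lengths(values) < 2L]
  if (length(small) > 0L) {
    warning("group(s) with fewer than 2 usable samples dropped: ",
            paste(small, collapse = ", "))
    values <- values[lengths(values) >= 2L]
  }
  aov_res <- if (length(values) >= 2L) anova_oneway(values) else NULL
  list(vmax_table = tab, anova = aov_res, n_flagged = n_flagged)
}
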