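#' Treatment-group design of an immune-challenge cohort
#'
#' The seven-group design crossing antigen (none, sterile ringer, nylon
#' filament, heat-killed bacteria) with the life stage at which the challenge
#' was applied (larval, adult, or both for the double-injection procedural
#' control). Every [cohort_dataset()] group label must map to exactly one
#' (stage, antigen) combination from this table.
#'
#' @return A data frame with columns `group`, `stage`, `antigen`.
#' @export
group_design <- function() {
  data.frame(
    group   = c("Control", "PC1", "PC2", "NylonLarval", "NylonAdult",
                "BacteriaLarval", "BacteriaAdult"),
    stage   = c("none", "both", "larval", "larval", "adult", "larval", "adult"),
    antigen = c("none", "ringer", "ringer", "nylon", "nylon",
                "dead_bacteria", "dead_bacteria"),
    stringsAsFactors = FALSE
  )
}

cohort_group_levels <- function() group_design()$group
trace_group_levels  <- function() c("Bacteria", "Control", "Nylon", "Stab", "Water")

#' Construct a validated cohort dataset
#'
#' A cohort dataset is one row per individual: an opaque id, a treatment-group
#' label from [group_design()], the stage and antigen implied by the group, the
#' lifespan in days on a single declared time origin, and an event flag
#' (`TRUE` = death observed, `FALSE` = right-censored). Free-form metadata
#' (generator seed and parameters, provenance, the declared time origin) ride
#' along as an attribute and survive [write_cohort()] / [read_cohort()].
#'
#' Validation reports *all* offending rows, not only the first.
#'
#' @param records Data frame with columns `individual_id`, `group`,
#'   `lifespan_days`, `event`; `stage` and `antigen` are filled in from the
#'   group when absent and cross-checked when present.
#' @param metadata Named list of character scalars.
#' @return A `cohort` data frame (row order preserved) with a `metadata`
#'   attribute.
#' @export
cohort_dataset <- function(records, metadata = list()) {
  stopifnot(is.data.frame(records))
  required <- c("individual_id", "group", "lifespan_days", "event")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop_validation("missing column(s): ", paste(missing_cols, collapse = ", "))

  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  rec$individual_id <- as.character(rec$individual_id)
  rec$group <- as.character(rec$group)
  rec$lifespan_days <- as.numeric(rec$lifespan_days)
  rec$event <- as.logical(rec$event)

  design <- group_design()
  problems <- character(0)

  bad_group <- which(!(rec$group %in% design$group))
  if (length(bad_group) > 0L)
    problems <- c(problems, paste0(
      "unknown group label in row(s) ", paste(bad_group, collapse = ", "),
      " (", paste(unique(rec$group[bad_group]), collapse = ", "), ")"))

  bad_life <- which(!is.finite(rec$lifespan_days) | rec$lifespan_days <= 0)
  if (length(bad_life) > 0L)
    problems <- c(problems, paste0(
      "non-positive lifespan_days in row(s) ", paste(bad_life, collapse = ", ")))

  bad_event <- which(is.na(rec$event))
  if (length(bad_event) > 0L)
    problems <- c(problems, paste0(
      "missing/invalid event flag in row(s) ", paste(bad_event, collapse = ", ")))

  dup <- which(duplicated(rec$individual_id))
  if (length(dup) > 0L)
    problems <- c(problems, paste0(
      "duplicate individual_id in row(s) ", paste(dup, collapse = ", ")))

  idx <- match(rec$group, design$group)
  if (!"stage" %in% names(rec)) rec$stage <- design$stage[idx]
  if (!"antigen" %in% names(rec)) rec$antigen <- design$antigen[idx]
  known <- !is.na(idx)
  bad_stage <- which(known & rec$stage != design$stage[idx])
  if (length(bad_stage) > 0L)
    problems <- c(problems, paste0(
      "stage inconsistent with group in row(s) ", paste(bad_stage, collapse = ", ")))
  bad_ant <- which(known & rec$antigen != design$antigen[idx])
  if (length(bad_ant) > 0L)
    problems <- c(problems, paste0(
      "antigen inconsistent with group in row(s) ", paste(bad_ant, collapse = ", ")))

  if (length(problems) > 0L)
    stop_validation("invalid cohort records:\n  ", paste(problems, collapse = "\n  "))

  rec <- rec[, c("individual_id", "group", "stage", "antigen",
                 "lifespan_days", "event")]
  rownames(rec) <- NULL
  stopifnot(is.list(metadata))
  attr(rec, "metadata") <- lapply(metadata, as.character)
  class(rec) <- c("cohort", "data.frame")
  rec
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d individuals in %d group(s): %s\n",
              nrow(x), length(unique(x$group)),
              paste(names(table(x$group)), table(x$group), sep = "=",
                    collapse = ", ")))
  md <- attr(x, "metadata")
  if (length(md) > 0L)
    cat("metadata:", paste(names(md), unlist(md), sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Metadata attached to a cohort dataset
#' @param dataset A `cohort` object.
#' @return Named list of character scalars.
#' @export
cohort_metadata <- function(dataset) attr(dataset, "metadata") %||% list()

#' Read a cohort survival table from delimited text
#'
#' Expects a comma-separated file with a header row and (default) columns
#' `individual_id,group,stage,antigen,lifespan_days,event`; `dialect` renames
#' file columns to the standard ones. A companion `<path>.meta` file of
#' `key=value` lines, if present, is read back as metadata.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional named character vector `standard_name = file_name`
#'   remapping columns.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    stopifnot(!is.null(names(dialect)))
    for (std in names(dialect)) {
      file_col <- dialect[[std]]
      if (!file_col %in% names(raw))
        stop_validation("declared column not in file: ", file_col)
      names(raw)[names(raw) == file_col] <- std
    }
  }
  required <- c("individual_id", "group", "lifespan_days", "event")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop_validation("missing column(s): ", paste(missing_cols, collapse = ", "))

  meta <- list()
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    lines <- readLines(meta_path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
    meta <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  }
  cohort_dataset(raw, metadata = meta)
}

#' Write a cohort survival table to delimited text
#'
#' Writes the standard six-column CSV; non-empty metadata goes to a companion
#' `<path>.meta` file of `key=value` lines so that
#' `read_cohort(write_cohort(x))` is loss-free.
#'
#' @param dataset A [cohort_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  stopifnot(inherits(dataset, "cohort"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  md <- cohort_metadata(dataset)
  if (length(md) > 0L)
    writeLines(paste0(names(md), "=", unlist(md)), paste0(path, ".meta"))
  invisible(path)
}

#' Construct a kinetic absorbance trace
#'
#' One sample's timed absorbance readings from a microplate kinetic assay
#' (e.g. the L-DOPA phenoloxidase assay read every 15 s for 60 min). Times
#' must be strictly increasing; traces shorter than 12 readings are not
#' eligible for Vmax extraction.
#'
#' @param sample_id Opaque sample identifier.
#' @param group Assay group label, one of Bacteria, Control, Nylon, Stab, Water.
#' @param times_s Numeric vector of reading times in seconds, strictly
#'   increasing.
#' @param absorbance Numeric vector of optical densities, same length.
#' @return A `kinetic_trace` object.
#' @export
kinetic_trace <- function(sample_id, group, times_s, absorbance) {
  times_s <- as.numeric(times_s)
  absorbance <- as.numeric(absorbance)
  if (length(times_s) != length(absorbance))
    stop_validation("times and absorbance differ in length for sample ", sample_id)
  if (any(diff(times_s) <= 0))
    stop_validation("times not strictly increasing for sample ", sample_id)
  if (!group %in% trace_group_levels())
    stop_validation("unknown trace group: ", group)
  structure(list(sample_id = as.character(sample_id), group = as.character(group),
                 times_s = times_s, absorbance = absorbance),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace %s [%s]: %d readings, %.0f-%.0f s\n",
              x$sample_id, x$group, length(x$times_s),
              min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Read kinetic traces from a long-format CSV
#'
#' Expects columns `sample_id,group,time_s,absorbance`, one row per reading.
#' Rows are sorted by time within sample; samples with fewer than
#' `min_readings` readings are dropped with a warning.
#'
#' @param path Path to the long-format CSV.
#' @param min_readings Minimum readings for a trace to be kept (default 12).
#' @return Named list of [kinetic_trace()] objects, keyed by sample id.
#' @export
read_traces <- function(path, min_readings = 12L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "time_s", "absorbance")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop_validation("missing column(s): ", paste(missing_cols, collapse = ", "))
  key <- paste(raw$sample_id, raw$time_s, sep = "\r")
  if (anyDuplicated(key))
    stop_validation("duplicate (sample, time) pair(s): ",
                    paste(unique(raw$sample_id[duplicated(key)]), collapse = ", "))
  out <- list()
  for (sid in unique(raw$sample_id)) {
    sub <- raw[raw$sample_id == sid, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    if (nrow(sub) < min_readings) {
      warning("trace ", sid, " has ", nrow(sub),
              " reading(s), below the minimum of ", min_readings, "; excluded")
      next
    }
    grp <- unique(sub$group)
    if (length(grp) != 1L)
      stop_validation("sample ", sid, " maps to multiple groups")
    out[[sid]] <- kinetic_trace(sid, grp, sub$time_s, sub$absorbance)
  }
  out
}

#' Write kinetic traces to a long-format CSV
#' @param traces List of [kinetic_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr)
    data.frame(sample_id = tr$sample_id, group = tr$group,
               time_s = tr$times_s, absorbance = tr$absorbance,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
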