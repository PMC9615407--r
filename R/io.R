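# CSV readers/writers with documented headers, provenance comment
# blocks, and fail-fast row validation (a permissive mode drops bad rows
# and reports them).

provenance_lines <- function(what, meta = list()) {
  kv <- vapply(names(meta), function(k)
    sprintf("%s=%s", k, as.character(meta[[k]])), character(1))
  c(sprintf("# saerep %s", what),
    if (length(kv)) paste("#", kv))
}

write_table_with_provenance <- function(df, path, what, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(what, meta), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}

read_csv_skip_comments <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

row_problems <- function(keep, label, ids, permissive) {
  bad <- which(!keep)
  if (length(bad) == 0L) return(invisible(NULL))
  detail <- paste(utils::head(ids[bad], 5L), collapse = ", ")
  msg <- sprintf("%s in %d row(s): %s%s", label, length(bad), detail,
                 if (length(bad) > 5L) ", ..." else "")
  if (!permissive) stop(msg, call. = FALSE)
  warning(sprintf("dropping rows -- %s", msg))
  invisible(bad)
}

#' Write / read a cohort table
#'
#' The cohort CSV has one row per person with columns `id`, `age`,
#' `sex` (`male`/`female`), `time_at_risk` (days), `event` (0/1), and
#' optionally `condition`, `mm_count`, `medications`, `event_day`,
#' `true_hazard` and `has_<condition>` flags. Unknown columns are
#' preserved. Leading `#` lines carry provenance and are skipped on
#' read.
#'
#' @param cohort a cohort data frame.
#' @param path CSV path.
#' @param meta named list echoed into the provenance comment block.
#' @export
write_cohort <- function(cohort, path, meta = list()) {
  cfg <- attr(cohort, "config")
  if (!is.null(cfg) && is.null(meta$seed)) meta$seed <- cfg$seed
  write_table_with_provenance(as.data.frame(cohort), path, "cohort", meta)
}

#' @rdname write_cohort
#' @param permissive drop invalid rows with a warning instead of
#'   failing (default FALSE).
#' @return `read_cohort`: the validated cohort data frame.
#' @export
read_cohort <- function(path, permissive = FALSE) {
  df <- read_csv_skip_comments(path)
  require_columns(df, c("id", "age", "sex", "time_at_risk", "event"),
                  "cohort")
  if (nrow(df) == 0L) {
    warning("cohort file has a valid header but no rows")
    class(df) <- c("sae_cohort", "data.frame")
    return(df)
  }
  keep <- df$sex %in% c("male", "female")
  row_problems(keep, "malformed sex value", df$id, permissive)
  df <- df[keep, , drop = FALSE]
  keep <- is.finite(df$age) & df$age >= 0 & df$age <= 120 &
    is.finite(df$time_at_risk) & df$time_at_risk >= 0 &
    df$event %in% c(0, 1)
  row_problems(keep, "malformed age/time/event value", df$id, permissive)
  df <- df[keep, , drop = FALSE]
  if ("event_day" %in% names(df)) {
    keep <- is.na(df$event_day) |
      (df$event_day >= 0 & df$event_day <= df$time_at_risk + 1e-8)
    row_problems(keep, "event_day outside [0, time_at_risk]", df$id,
                 permissive)
    df <- df[keep, , drop = FALSE]
  }
  class(df) <- c("sae_cohort", "data.frame")
  df
}

#' Write / read an aggregate trial summary table
#'
#' One row per trial: `trial_id`, `condition`, `n_participants`,
#' `age_mean`, `age_sd` (may be NA), `age_min`, `age_max`,
#' `percent_female`, `followup_days`, `sae_count`. Per-arm rows live in
#' a separate arm table (`trial_id`, `arm`, `designation`, `n`,
#' `sae_count`, `followup_days`).
#'
#' @param summaries trial summary data frame.
#' @param path CSV path.
#' @param meta provenance entries.
#' @export
write_trial_summaries <- function(summaries, path, meta = list()) {
  write_table_with_provenance(summaries, path, "trial_summaries", meta)
}

#' @rdname write_trial_summaries
#' @param permissive drop invalid rows instead of failing.
#' @export
read_trial_summaries <- function(path, permissive = FALSE) {
  df <- read_csv_skip_comments(path)
  require_columns(df, c("trial_id", "condition", "n_participants",
                        "age_mean", "age_min", "age_max",
                        "percent_female", "followup_days", "sae_count"),
                  "trial summaries")
  if (nrow(df) == 0L) {
    warning("trial summary file has a valid header but no rows")
    return(df)
  }
  keep <- df$age_min <= df$age_max &
    df$age_mean >= df$age_min & df$age_mean <= df$age_max
  row_problems(keep, "age_min/age_mean/age_max ordering violated",
               df$trial_id, permissive)
  df <- df[keep, , drop = FALSE]
  keep <- df$percent_female >= 0 & df$percent_female <= 100 &
    df$sae_count >= 0 & df$n_participants > 0 & df$followup_days > 0
  row_problems(keep, "out-of-range summary value", df$trial_id, permissive)
  df[keep, , drop = FALSE]
}

#' Write / read individual participant data tables
#'
#' One CSV per trial in `dir`, named `<trial_id>.csv`, with columns
#' `trial_id`, `id`, `age`, `sex`, `arm`, `followup_days`, `sae_count`
#' and optionally `medications` / `mm_count` / `condition`.
#'
#' @param ipd_list list of per-trial participant tables.
#' @param dir directory (created if needed).
#' @param meta provenance entries.
#' @export
write_trial_ipd <- function(ipd_list, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ipd in ipd_list) {
    write_table_with_provenance(
      ipd, file.path(dir, paste0(ipd$trial_id[1], ".csv")),
      "trial_ipd", meta)
  }
  invisible(dir)
}

#' @rdname write_trial_ipd
#' @param permissive drop invalid rows instead of failing.
#' @return `read_trial_ipd`: named list of participant tables.
#' @export
read_trial_ipd <- function(dir, permissive = FALSE) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  out <- lapply(files, function(f) {
    df <- read_csv_skip_comments(f)
    require_columns(df, c("trial_id", "age", "sex", "followup_days",
                          "sae_count"), paste("trial IPD", basename(f)))
    keep <- df$sex %in% c("male", "female") & df$followup_days > 0 &
      df$sae_count >= 0
    row_problems(keep, sprintf("malformed IPD row in %s", basename(f)),
                 seq_len(nrow(df)), permissive)
    df[keep, , drop = FALSE]
  })
  names(out) <- vapply(out, function(d)
    as.character(d$trial_id[1] %||% NA_character_), character(1))
  out
}
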