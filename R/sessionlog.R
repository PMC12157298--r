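#' Summarize one wearing session
#'
#' Computes the aggregates the garment's companion interface logs per day:
#' total sitting time, how often the wearer changed sitting posture, and
#' how many reminders of each kind were delivered.
#'
#' Posture changes are counted on the debounced stream: runs shorter than
#' `debounce` seconds are discarded first (classifier jitter, momentary
#' shifts), then transitions between consecutive distinct labels are
#' counted.
#'
#' @param stream per-second classification data.frame (`t`, `posture`).
#' @param events reminder events emitted for the same session (see
#'   [run_session()]).
#' @param debounce minimum run length in seconds for a posture to count as
#'   held (default 3).
#' @param date session date (default today).
#' @return object of class `session_report`: list with `date`,
#'   `total_sitting_s`, `posture_changes`, `posture_reminders`,
#'   `sedentary_reminders`.
#' @export
summarize_session <- function(stream, events, debounce = 3,
                              date = Sys.Date()) {
  if (nrow(events) > 0 &&
      (min(events$t) < min(stream$t) || max(events$t) > max(stream$t)))
    stop("events fall outside the stream's time range")
  runs <- rle(stream$posture)
  keep <- runs$lengths >= debounce
  kept <- runs$values[keep]
  changes <- if (length(kept) > 1) sum(diff(kept) != 0) else 0L
  structure(list(
    date = as.character(date),
    total_sitting_s = sum(stream$posture != 0L),
    posture_changes = as.integer(changes),
    posture_reminders = sum(events$kind == "posture_change"),
    sedentary_reminders = sum(events$kind == "sedentary")
  ), class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("Session report —", x$date, "\n",
      sprintf("  sitting time:        %d s (%.1f min)\n",
              x$total_sitting_s, x$total_sitting_s / 60),
      sprintf("  posture changes:     %d\n", x$posture_changes),
      sprintf("  posture reminders:   %d\n", x$posture_reminders),
      sprintf("  sedentary reminders: %d\n", x$sedentary_reminders),
      sep = "")
  invisible(x)
}

#' Paired before/after intervention comparison
#'
#' Paired-sample t-test on per-subject counts from two wearing phases
#' (e.g. posture changes in daily clothing vs in the feedback garment).
#' The statistic is computed on the differences `before - after`, so more
#' activity in the after phase gives a negative t.
#'
#' @param before,after equal-length numeric vectors, paired by subject,
#'   length >= 2.
#' @return list with `t_statistic`, `p_value` (two-sided), `df`,
#'   `mean_difference`, `n_subjects` and `degenerate` (TRUE when the
#'   differences have zero variance, in which case no p-value is returned).
#' @examples
#' compare_phases(c(10, 12, 9, 11), c(12, 15, 10, 13))
#' @export
compare_phases <- function(before, after) {
  if (length(before) != length(after))
    stop("before and after must be paired vectors of equal length")
  n <- length(before)
  if (n < 2) stop("need at least 2 subject pairs")
  d <- before - after
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t_statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p_value = NA_real_, df = n - 1, mean_difference = mean(d),
                n_subjects = n, degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t_statistic = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
       df = n - 1, mean_difference = mean(d), n_subjects = n,
       degenerate = FALSE)
}

#' Append a session report to a history store
#'
#' History is an append-only JSON-lines file, one report per line.
#'
#' @param report a `session_report`.
#' @param store path to the history file (created if missing).
#' @return the store path, invisibly.
#' @export
persist_history <- function(report, store) {
  stopifnot(inherits(report, "session_report"))
  line <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE)
  con <- file(store, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(store)
}

#' Load session history
#'
#' Reads a JSON-lines history store; corrupt lines are skipped with a
#' warning rather than aborting the load.
#'
#' @param store path to the history file.
#' @return list of `session_report`s in file (chronological) order, with
#'   attribute `skipped` giving the number of unreadable lines.
#' @export
load_history <- function(store) {
  if (!file.exists(store)) return(structure(list(), skipped = 0L))
  lines <- readLines(store, warn = FALSE)
  lines <- lines[nzchar(lines)]
  skipped <- 0L
  out <- list()
  for (ln in lines) {
    rec <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    needed <- c("date", "total_sitting_s", "posture_changes",
                "posture_reminders", "sedentary_reminders")
    if (is.null(rec) || !all(needed %in% names(rec))) {
      skipped <- skipped + 1L
      next
    }
    out[[length(out) + 1L]] <- structure(rec[needed], class = "session_report")
  }
  if (skipped > 0)
    warning(skipped, " corrupt history line(s) skipped")
  structure(out, skipped = skipped)
}
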