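#' Read and write sensor-frame sample tables
#'
#' CSV dialect with header `t,participant,posture_code,sub_variant,c1,c2,c3,c4`.
#' The posture is stored as its numeric class code (the leg-crossed
#' sub-variant is kept in `sub_variant`, so acquisition-time information is
#' not lost by the on-disk encoding).
#'
#' @param frames sensor-frame data.frame as produced by
#'   [generate_dataset()].
#' @param path file path.
#' @return `write_samples()` returns `path` invisibly; `read_samples()`
#'   returns a sensor-frame data.frame.
#' @export
write_samples <- function(frames, path) {
  out <- data.frame(
    t = frames$t, participant = frames$participant,
    posture_code = posture_code(frames$posture),
    sub_variant = frames$sub_variant,
    c1 = frames$c1, c2 = frames$c2, c3 = frames$c3, c4 = frames$c4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("t", "participant", "posture_code", "sub_variant",
              "c1", "c2", "c3", "c4")
  if (!all(needed %in% names(x)))
    stop("sample table must have columns ", paste(needed, collapse = ","))
  data.frame(t = x$t, participant = as.character(x$participant),
             posture = posture_name(x$posture_code),
             sub_variant = x$sub_variant,
             c1 = x$c1, c2 = x$c2, c3 = x$c3, c4 = x$c4,
             stringsAsFactors = FALSE)
}

#' Read and write per-second classification streams
#'
#' Two interchangeable formats selected by file extension: JSON lines
#' (`.jsonl`/`.ndjson`; one `{"t": <int>, "posture": <int 0-6>}` object per
#' line) or two-column CSV (`t,posture`).
#'
#' @param stream data.frame with columns `t` and `posture`.
#' @param path file path.
#' @return `write_stream()` returns `path` invisibly; `read_stream()`
#'   returns the stream data.frame.
#' @export
write_stream <- function(stream, path) {
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    lines <- sprintf('{"t": %d, "posture": %d}',
                     as.integer(stream$t), as.integer(stream$posture))
    writeLines(lines, path)
  } else {
    utils::write.csv(stream[, c("t", "posture")], path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
    data.frame(t = vapply(recs, function(r) as.integer(r$t), integer(1)),
               posture = vapply(recs, function(r) as.integer(r$posture),
                                integer(1)))
  } else {
    x <- utils::read.csv(path)
    data.frame(t = as.integer(x$t), posture = as.integer(x$posture))
  }
}

#' Write reminder events as JSON lines
#'
#' One object per event:
#' `{"t":…, "kind":…, "posture":…, "freq_hz":…, "dur_s":…}` (posture null
#' for sedentary reminders).
#'
#' @param events event data.frame from [run_session()].
#' @param path file path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the event data.frame.
#' @export
write_events <- function(events, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    rec <- list(t = events$t[i], kind = events$kind[i],
                posture = if (is.na(events$posture[i])) NULL
                          else events$posture[i],
                freq_hz = events$freq_hz[i], dur_s = events$dur_s[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_events())
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    t = vapply(recs, function(r) as.integer(r$t), integer(1)),
    kind = vapply(recs, function(r) as.character(r$kind), character(1)),
    posture = vapply(recs, function(r)
      if (is.null(r$posture)) NA_integer_ else as.integer(r$posture),
      integer(1)),
    freq_hz = vapply(recs, function(r) as.numeric(r$freq_hz), numeric(1)),
    dur_s = vapply(recs, function(r) as.numeric(r$dur_s), numeric(1)))
}

#' Persist and restore min-max scaler parameters
#'
#' JSON of the form `{"c1": [min, max], "c2": …}`.
#'
#' @param scaler scaler as returned by [minmax_normalize()].
#' @param path file path.
#' @return `write_scaler()` returns `path` invisibly; `read_scaler()`
#'   returns the scaler list.
#' @export
write_scaler <- function(scaler, path) {
  obj <- stats::setNames(
    lapply(seq_along(scaler$min),
           function(j) c(scaler$min[[j]], scaler$max[[j]])),
    names(scaler$min))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  obj <- jsonlite::fromJSON(path)
  list(min = vapply(obj, `[`, numeric(1), 1),
       max = vapply(obj, `[`, numeric(1), 2))
}
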