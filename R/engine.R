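#' Default posture hazard tiers
#'
#' Three-level grading of the six sitting postures by physiological harm,
#' each with its own reminder interval: leg crossed is the most harmful
#' (serious, 5 min); back bent, forward, backward and the catch-all posture
#' are medium (10 min); upright sitting is the least harmful (low, 15 min).
#' Standing belongs to no tier. The tiers partition the sitting postures.
#'
#' @return named list of tiers, each `list(name, postures, window)` with
#'   `postures` as integer codes and `window` in seconds.
#' @export
default_tiers <- function() {
  list(
    serious = list(name = "serious", postures = 3L, window = 300L),
    medium = list(name = "medium", postures = c(2L, 4L, 5L, 6L),
                  window = 600L),
    low = list(name = "low", postures = 1L, window = 900L)
  )
}

#' Reminder engine configuration
#'
#' The "dynamic sitting" feedback rules: for each hazard tier, if any
#' single posture of that tier accounts for strictly more than
#' `trigger_fraction` of the per-second records in the tier's trailing
#' window, a posture-change reminder fires (the 70% threshold buffers
#' classifier noise and brief fidgeting). Independently, 45 minutes of
#' uninterrupted sitting of any kind triggers a sedentary reminder telling
#' the wearer to stand up. Posture-change reminders vibrate at 800 Hz for
#' 3 s; the sedentary reminder keeps the frequency but lasts 7 s so the two
#' cues are distinguishable.
#'
#' @param tiers hazard tiers, see [default_tiers()]; checked in the given
#'   order, most serious first.
#' @param trigger_fraction window share one posture must strictly exceed to
#'   fire (default 0.70).
#' @param sedentary_window seconds of uninterrupted sitting before the
#'   sedentary reminder (default 2700 s = 45 min).
#' @param posture_vibration,sedentary_vibration `c(freq_hz =, dur_s =)`.
#' @return object of class `engine_config`.
#' @export
engine_config <- function(tiers = default_tiers(), trigger_fraction = 0.70,
                          sedentary_window = 2700,
                          posture_vibration = c(freq_hz = 800, dur_s = 3),
                          sedentary_vibration = c(freq_hz = 800, dur_s = 7)) {
  if (trigger_fraction <= 0 || trigger_fraction >= 1)
    stop("trigger_fraction must be in (0, 1)")
  windows <- vapply(tiers, `[[`, numeric(1), "window")
  if (any(windows <= 0)) stop("tier windows must be positive")
  if (sedentary_window <= max(windows))
    stop("sedentary_window must exceed every tier window")
  tier_postures <- sort(unlist(lapply(tiers, `[[`, "postures")))
  if (!identical(as.integer(tier_postures), 1:6))
    stop("tiers must partition the six sitting postures (codes 1-6)")
  structure(list(tiers = tiers, trigger_fraction = trigger_fraction,
                 sedentary_window = sedentary_window,
                 posture_vibration = posture_vibration,
                 sedentary_vibration = sedentary_vibration),
            class = "engine_config")
}

#' Vibration parameters for a reminder kind
#'
#' @param kind `"posture_change"` or `"sedentary"`.
#' @param config an [engine_config()].
#' @return `c(freq_hz =, dur_s =)`.
#' @examples
#' vibration_for("posture_change")  # 800 Hz, 3 s
#' vibration_for("sedentary")       # 800 Hz, 7 s
#' @export
vibration_for <- function(kind, config = engine_config()) {
  switch(kind,
         posture_change = config$posture_vibration,
         sedentary = config$sedentary_vibration,
         stop("unknown reminder kind: ", kind))
}

#' Create a fresh engine state
#'
#' The state is an environment (reference semantics): [engine_step()]
#' mutates it in place, which keeps per-second streaming cheap. Each tier
#' keeps a ring buffer over its trailing window plus per-posture counts;
#' the sedentary timer counts the current uninterrupted sitting run.
#'
#' @param config an [engine_config()].
#' @return object of class `engine_state`.
#' @export
new_engine_state <- function(config = engine_config()) {
  st <- new.env(parent = emptyenv())
  st$last_t <- NA_integer_
  st$sitting_run <- 0L
  st$tiers <- lapply(config$tiers, function(tier) {
    e <- new.env(parent = emptyenv())
    e$buf <- integer(tier$window)
    e$head <- 1L
    e$n <- 0L         # current buffer occupancy (<= window)
    e$filled <- 0L    # ticks recorded since the last reset (capped at window)
    e$counts <- integer(7)
    e
  })
  class(st) <- "engine_state"
  st
}

#' Advance the engine by one per-second classification tick
#'
#' Appends the tick to every tier's trailing window, then checks tiers in
#' order (serious first): once a tier has a full window of records since
#' its last reset, it fires a posture-change reminder if any single posture
#' of the tier strictly exceeds `trigger_fraction` of the window, and its
#' trailing records are cleared so the countdown restarts. At most one
#' posture-change event is emitted per tick. Independently, any non-stance
#' tick extends the sitting run; reaching `sedentary_window` emits a
#' sedentary reminder and restarts the run timer, while a stance tick
#' resets it.
#'
#' @param state an `engine_state` (mutated in place).
#' @param t integer timestamp in seconds; must follow the previous tick by
#'   exactly 1 s.
#' @param posture posture code 0-6.
#' @param config the [engine_config()] the state was built for.
#' @return data.frame of emitted events (possibly 0 rows) with columns
#'   `t`, `kind`, `posture`, `freq_hz`, `dur_s`.
#' @export
engine_step <- function(state, t, posture, config = engine_config()) {
  t <- as.integer(t)
  posture <- as.integer(posture)
  if (is.na(posture) || posture < 0L || posture > 6L)
    stop("posture must be a code 0-6")
  if (!is.na(state$last_t) && t != state$last_t + 1L)
    stop("ticks must arrive in strict 1 s increments (got t = ", t,
         " after t = ", state$last_t, ")")
  state$last_t <- t

  events <- NULL
  idx <- posture + 1L
  for (te in state$tiers) {
    if (te$n == length(te$buf)) {
      old <- te$buf[te$head]
      te$counts[old + 1L] <- te$counts[old + 1L] - 1L
    } else te$n <- te$n + 1L
    te$buf[te$head] <- posture
    te$counts[idx] <- te$counts[idx] + 1L
    te$head <- if (te$head == length(te$buf)) 1L else te$head + 1L
    if (te$filled < length(te$buf)) te$filled <- te$filled + 1L
  }

  for (i in seq_along(config$tiers)) {
    tier <- config$tiers[[i]]
    te <- state$tiers[[i]]
    if (te$filled < tier$window) next
    cnts <- te$counts[tier$postures + 1L]
    if (max(cnts) > config$trigger_fraction * tier$window) {
      winner <- tier$postures[which.max(cnts)]
      v <- config$posture_vibration
      events <- rbind(events, data.frame(
        t = t, kind = "posture_change", posture = winner,
        freq_hz = unname(v["freq_hz"]), dur_s = unname(v["dur_s"])))
      te$counts[] <- 0L
      te$n <- 0L
      te$head <- 1L
      te$filled <- 0L
      break  # at most one posture-change reminder per tick
    }
  }

  if (posture == 0L) {
    state$sitting_run <- 0L
  } else {
    state$sitting_run <- state$sitting_run + 1L
    if (state$sitting_run >= config$sedentary_window) {
      v <- config$sedentary_vibration
      events <- rbind(events, data.frame(
        t = t, kind = "sedentary", posture = NA_integer_,
        freq_hz = unname(v["freq_hz"]), dur_s = unname(v["dur_s"])))
      state$sitting_run <- 0L
    }
  }

  if (is.null(events)) empty_events() else events
}

empty_events <- function() {
  data.frame(t = integer(0), kind = character(0), posture = integer(0),
             freq_hz = numeric(0), dur_s = numeric(0))
}

#' Run the engine over a whole classification stream
#'
#' Folds [engine_step()] over every tick of the stream.
#'
#' @param stream data.frame with columns `t` (integer seconds, strictly
#'   increasing by 1) and `posture` (codes 0-6), as produced by
#'   [generate_stream()].
#' @param config an [engine_config()].
#' @return list with `events` (data.frame in time order) and `state` (the
#'   final `engine_state`).
#' @examples
#' s <- generate_stream(data.frame(posture = 3, duration = 360))
#' run_session(s, engine_config())$events  # fires at t = 300
#' @export
run_session <- function(stream, config = engine_config()) {
  state <- new_engine_state(config)
  out <- vector("list", nrow(stream))
  k <- 0L
  for (i in seq_len(nrow(stream))) {
    ev <- engine_step(state, stream$t[i], stream$posture[i], config)
    if (nrow(ev) > 0) {
      k <- k + 1L
      out[[k]] <- ev
    }
  }
  events <- if (k > 0) do.call(rbind, out[seq_len(k)]) else empty_events()
  rownames(events) <- NULL
  list(events = events, state = state)
}

#' Recover the effective trigger threshold by bisection
#'
#' Executable check that the configured trigger fraction actually governs
#' firing: constructs windows of the tier's length containing a fraction
#' `f` of the tier's first posture (the remainder filled with a posture
#' from another tier), replays them through the engine, and bisects `f`
#' on the fire/no-fire boundary. Under the strict "more than" comparison
#' the recovered infimum equals the configured fraction.
#'
#' @param config an [engine_config()].
#' @param tier tier name (default `"serious"`).
#' @param tol bisection tolerance on `f` (default 1e-4).
#' @return the boundary fraction.
#' @examples
#' recover_trigger_threshold()  # 0.70 under the default config
#' @export
recover_trigger_threshold <- function(config = engine_config(),
                                      tier = "serious", tol = 1e-4) {
  tier_def <- config$tiers[[tier]]
  if (is.null(tier_def)) stop("unknown tier: ", tier)
  w <- tier_def$window
  target <- tier_def$postures[1]
  filler <- if (1L %in% tier_def$postures) 2L else 1L
  fires <- function(f) {
    k <- ceiling(f * w)
    stream <- data.frame(t = seq_len(w),
                         posture = c(rep(target, k), rep(filler, w - k)))
    ev <- run_session(stream, config)$events
    any(ev$kind == "posture_change" & ev$posture == target)
  }
  lo <- 0
  hi <- 1
  if (!fires(1)) stop("engine does not fire even on a pure window")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
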