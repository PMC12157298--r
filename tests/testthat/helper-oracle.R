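# Independent brute-force replay of the reminder rules, used to check the
# incremental ring-buffer engine. Re-derives every window count from prefix
# sums over the raw label sequence instead of maintaining running state.
oracle_run_session <- function(stream, config = engine_config()) {
  labels <- stream$posture
  n <- length(labels)
  # cs[t + 1, l + 1] = number of ticks with label l among ticks 1..t
  cs <- rbind(0, apply(vapply(0:6, function(l) as.integer(labels == l),
                              integer(n)), 2, cumsum))
  reset <- rep(0L, length(config$tiers))
  sit_run <- 0L
  ev <- list()
  for (i in seq_len(n)) {
    for (j in seq_along(config$tiers)) {
      tier <- config$tiers[[j]]
      w <- tier$window
      if (i - reset[j] >= w) {
        cnt <- cs[i + 1, tier$postures + 1] - cs[i + 1 - w, tier$postures + 1]
        if (max(cnt) > config$trigger_fraction * w) {
          winner <- tier$postures[which.max(cnt)]
          v <- config$posture_vibration
          ev[[length(ev) + 1L]] <- data.frame(
            t = stream$t[i], kind = "posture_change", posture = winner,
            freq_hz = unname(v["freq_hz"]), dur_s = unname(v["dur_s"]))
          reset[j] <- i
          break
        }
      }
    }
    if (labels[i] == 0L) {
      sit_run <- 0L
    } else {
      sit_run <- sit_run + 1L
      if (sit_run >= config$sedentary_window) {
        v <- config$sedentary_vibration
        ev[[length(ev) + 1L]] <- data.frame(
          t = stream$t[i], kind = "sedentary", posture = NA_integer_,
          freq_hz = unname(v["freq_hz"]), dur_s = unname(v["dur_s"]))
        sit_run <- 0L
      }
    }
  }
  if (length(ev) == 0) {
    dynsit:::empty_events()
  } else {
    out <- do.call(rbind, ev)
    rownames(out) <- NULL
    out
  }
}

# a classification stream of random postures, biased towards sitting
random_stream <- function(n, seed,
                          prob = c(0.05, 0.35, 0.2, 0.15, 0.1, 0.1, 0.05)) {
  set.seed(seed)
  data.frame(t = seq_len(n), posture = sample(0:6, n, replace = TRUE,
                                              prob = prob))
}
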