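test_that("constant streams fire at each tier's reminder interval", {
  cfg <- engine_config()
  crossed <- run_session(generate_stream(data.frame(posture = 3,
                                                    duration = 360)), cfg)
  expect_equal(crossed$events$t[1], 300)       # serious: 5 min
  expect_equal(crossed$events$kind[1], "posture_change")
  expect_equal(crossed$events$posture[1], 3)

  bent <- run_session(generate_stream(data.frame(posture = 2,
                                                 duration = 660)), cfg)
  pc <- bent$events[bent$events$kind == "posture_change", ]
  expect_equal(pc$t[1], 600)                   # medium: 10 min

  upright <- run_session(generate_stream(data.frame(posture = 1,
                                                    duration = 2700)), cfg)
  pc <- upright$events[upright$events$kind == "posture_change", ]
  expect_equal(pc$t, c(900, 1800, 2700))       # low: 15 min, reset after fire
  sed <- upright$events[upright$events$kind == "sedentary", ]
  expect_equal(sed$t, 2700)                    # sedentary: 45 min
})

test_that("standing produces no events and resets the sedentary run", {
  cfg <- engine_config()
  standing <- run_session(generate_stream(data.frame(posture = 0,
                                                     duration = 3000)), cfg)
  expect_equal(nrow(standing$events), 0)

  # one stance tick every 2699 s keeps the sitting run below 45 min forever
  n <- 8100
  stream <- data.frame(t = seq_len(n), posture = 1L)
  stream$posture[seq_len(n) %% 2699 == 0] <- 0L
  out <- run_session(stream, cfg)
  expect_equal(sum(out$events$kind == "sedentary"), 0)

  # any sitting mix with no stance fires the sedentary reminder at 45 min
  mix <- data.frame(t = seq_len(2700), posture = rep_len(1:6, 2700))
  out <- run_session(mix, cfg)
  expect_equal(out$events$t[out$events$kind == "sedentary"], 2700)
  # every individual posture stays at ~1/6 of each window: no posture event
  expect_equal(sum(out$events$kind == "posture_change"), 0)
})

test_that("alternating postures below the trigger fraction never fire", {
  stream <- data.frame(t = seq_len(1800),
                       posture = rep_len(c(1L, 2L), 1800))  # 50% < 70%
  out <- run_session(stream, engine_config())
  expect_equal(sum(out$events$kind == "posture_change"), 0)
})

test_that("window boundaries are honoured exactly at the trigger fraction", {
  cfg <- engine_config()
  # 100% leg crossed fires; 69% does not (strictly-more-than comparison)
  full <- data.frame(t = 1:300, posture = 3L)
  expect_equal(nrow(run_session(full, cfg)$events), 1)
  at69 <- data.frame(t = 1:300, posture = c(rep(3L, 207), rep(1L, 93)))
  expect_equal(sum(run_session(at69, cfg)$events$kind == "posture_change"), 0)
  at71 <- data.frame(t = 1:300, posture = c(rep(3L, 213), rep(1L, 87)))
  ev <- run_session(at71, cfg)$events
  expect_equal(ev$t[ev$kind == "posture_change"], 300)
})

test_that("bisection recovers the configured trigger threshold", {
  expect_equal(recover_trigger_threshold(engine_config(), "serious"),
               0.70, tolerance = 0.005)
  half <- engine_config(trigger_fraction = 0.5)
  expect_equal(recover_trigger_threshold(half, "serious"),
               0.50, tolerance = 0.005)
  # the same constant governs the other tiers
  expect_equal(recover_trigger_threshold(engine_config(), "medium"),
               0.70, tolerance = 0.005)
  expect_equal(recover_trigger_threshold(engine_config(), "low"),
               0.70, tolerance = 0.005)
  expect_error(recover_trigger_threshold(engine_config(), "extreme"),
               "unknown tier")
})

test_that("events carry the configured vibration parameters", {
  cfg <- engine_config()
  expect_equal(vibration_for("posture_change", cfg),
               c(freq_hz = 800, dur_s = 3))
  expect_equal(vibration_for("sedentary", cfg), c(freq_hz = 800, dur_s = 7))
  expect_error(vibration_for("melody", cfg), "unknown")
})

test_that("raising the trigger fraction never adds posture-change events", {
  for (seed in 1:5) {
    stream <- random_stream(2000, seed)
    lo <- run_session(stream, engine_config(trigger_fraction = 0.6))$events
    hi <- run_session(stream, engine_config(trigger_fraction = 0.8))$events
    expect_lte(sum(hi$kind == "posture_change"),
               sum(lo$kind == "posture_change"))
  }
})

test_that("no event precedes its governing window", {
  windows <- c(serious = 300, medium = 600, low = 900)
  for (seed in 6:9) {
    stream <- random_stream(2000, seed,
                            prob = c(0.02, 0.1, 0.1, 0.6, 0.08, 0.05, 0.05))
    ev <- run_session(stream, engine_config())$events
    pc <- ev[ev$kind == "posture_change", ]
    for (i in seq_len(nrow(pc))) {
      w <- if (pc$posture[i] == 3) 300 else if (pc$posture[i] == 1) 900 else 600
      expect_gte(pc$t[i], w)
    }
    expect_true(all(ev$t[ev$kind == "sedentary"] >= 2700))
  }
})

test_that("gapped or repeated timestamps are rejected", {
  cfg <- engine_config()
  st <- new_engine_state(cfg)
  engine_step(st, 1, 1, cfg)
  expect_error(engine_step(st, 3, 1, cfg), "1 s increments")
  expect_error(engine_step(st, 1, 1, cfg), "1 s increments")
  expect_error(engine_step(st, 2, 7, cfg), "0-6")
})

test_that("engine configuration invariants are enforced", {
  expect_error(engine_config(trigger_fraction = 1.2), "trigger_fraction")
  expect_error(engine_config(sedentary_window = 600), "exceed")
  tiers <- default_tiers()
  tiers$medium$postures <- c(2L, 4L, 5L)  # posture 6 unassigned
  expect_error(engine_config(tiers = tiers), "partition")
})

test_that("incremental engine matches the brute-force replay oracle", {
  for (seed in 1:10) {
    stream <- random_stream(1800, seed)
    expect_equal(run_session(stream, engine_config())$events,
                 oracle_run_session(stream, engine_config()))
  }
  # also under a stickier stream where tiers actually fire
  for (seed in 11:14) {
    set.seed(seed)
    labels <- rep(sample(0:6, 40, replace = TRUE,
                         prob = c(0.05, 0.2, 0.2, 0.35, 0.1, 0.05, 0.05)),
                  each = 120)[1:4000]
    stream <- data.frame(t = seq_along(labels), posture = labels)
    expect_equal(run_session(stream, engine_config())$events,
                 oracle_run_session(stream, engine_config()))
  }
})
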