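#' Default per-posture channel baselines
#'
#' Synthetic class-mean table for the four capacitance channels C1-C4, in
#' picofarads. No real capacitance magnitudes are published for this sensor
#' layout, so the table is constructed to satisfy the qualitative structure
#' observed on the garment:
#'
#' * channel C1 (centre of the dorsal width line) has by far the largest
#'   between-posture spread and is the most discriminative channel;
#' * every pair of posture classes is separated by at least 4 noise SDs on
#'   at least one channel, except (a) the left/right leg-crossed pair, whose
#'   means differ by at most `crossed_gap` on every channel (below the noise
#'   floor, which is why the two sub-variants are merged before
#'   classification), and (b) the catch-all `other` posture, which sits only
#'   2 noise SDs from its nearest neighbour on C1;
#' * values rise smoothly from standing (least back strain) towards the
#'   high-curvature postures.
#'
#' @return 8 x 4 numeric matrix, rows named by acquired type
#'   (see [acquired_types()]), columns `c1`-`c4`.
#' @export
default_class_means <- function() {
  m <- rbind(
    stance                      = c(30.0, 46.0, 42.0, 40.0),
    upright                     = c(40.0, 48.0, 43.5, 41.0),
    back_bent                   = c(52.0, 52.0, 45.0, 42.0),
    `leg_crossed/left_crossed`  = c(64.0, 56.0, 47.0, 43.0),
    `leg_crossed/right_crossed` = c(64.5, 56.4, 47.3, 43.2),
    forward                     = c(76.0, 60.0, 49.0, 44.0),
    backward                    = c(88.0, 64.0, 51.0, 45.0),
    other                       = c(90.0, 61.5, 52.5, 45.8)
  )
  colnames(m) <- c("c1", "c2", "c3", "c4")
  m
}

#' Simulator configuration
#'
#' Parameterization of the synthetic 4-channel signal model and the
#' acquisition protocol: `n_participants` wearers each hold every one of the
#' 8 acquired posture types for `duration_per_posture` seconds while the
#' controller samples at `sampling_rate` Hz. Each frame is
#' `scale_p * class_mean + noise`, where `scale_p ~ N(1, participant_scale_sd)`
#' is one multiplicative factor per participant (emulating amplitude
#' variation with height and weight) and the noise is i.i.d. Gaussian with
#' SD `noise_sd` per channel.
#'
#' @param n_participants number of simulated wearers (default 20).
#' @param sampling_rate samples per second (default 2 Hz).
#' @param duration_per_posture seconds each posture is held (default 30 s).
#' @param class_means 8 x 4 matrix of per-acquired-type channel baselines
#'   (pF); rows must be named as in [default_class_means()].
#' @param participant_scale_sd SD of the per-participant multiplicative
#'   amplitude factor (dimensionless, default 0.05).
#' @param noise_sd additive per-channel noise SD (pF, default 1).
#' @param crossed_gap maximum allowed per-channel difference between the
#'   left and right leg-crossed baselines (pF, default 0.5).
#' @param seed base RNG seed; participant i derives sub-seed `seed + i`.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 20, sampling_rate = 2,
                       duration_per_posture = 30,
                       class_means = default_class_means(),
                       participant_scale_sd = 0.05, noise_sd = 1,
                       crossed_gap = 0.5, seed = 42) {
  cfg <- structure(
    list(n_participants = n_participants, sampling_rate = sampling_rate,
         duration_per_posture = duration_per_posture,
         class_means = class_means,
         participant_scale_sd = participant_scale_sd, noise_sd = noise_sd,
         crossed_gap = crossed_gap, seed = seed),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  at <- acquired_types()
  keys <- acquired_key(at$posture, at$sub_variant)
  if (cfg$n_participants < 1) stop("invalid config: n_participants must be >= 1")
  if (cfg$sampling_rate <= 0) stop("invalid config: sampling_rate must be positive")
  if (cfg$duration_per_posture <= 0)
    stop("invalid config: duration_per_posture must be positive")
  if (cfg$participant_scale_sd < 0 || cfg$noise_sd < 0 || cfg$crossed_gap < 0)
    stop("invalid config: standard deviations must be non-negative")
  m <- cfg$class_means
  if (!is.matrix(m) || !all(keys %in% rownames(m)) || ncol(m) != 4)
    stop("invalid config: class_means must be an 8 x 4 matrix with acquired-type rownames")
  spread <- apply(m, 2, function(x) max(x) - min(x))
  if (any(spread[-1] >= spread[1]))
    stop("invalid config: channel c1 must have the strictly largest between-class spread")
  gap <- abs(m["leg_crossed/left_crossed", ] - m["leg_crossed/right_crossed", ])
  if (any(gap > cfg$crossed_gap))
    stop("invalid config: left/right leg-crossed means differ by more than crossed_gap")
  invisible(cfg)
}

# run expr with a private RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one participant's acquisition session
#'
#' Generates the full acquisition protocol for one wearer: each of the 8
#' acquired posture types held for `duration_per_posture` seconds at
#' `sampling_rate` Hz, in the fixed order of [acquired_types()], with time
#' running continuously from 0 across the whole session.
#'
#' @param config a [sim_config()].
#' @param participant participant identifier (character).
#' @param seed RNG seed for this session.
#' @return data.frame of sensor frames with columns `t`, `participant`,
#'   `posture`, `sub_variant`, `c1`-`c4`; `duration_per_posture *
#'   sampling_rate` rows per acquired type.
#' @examples
#' s <- generate_participant_session(sim_config(), "P01", seed = 1)
#' nrow(s)  # 480 under the default protocol
#' @export
generate_participant_session <- function(config, participant, seed) {
  validate_sim_config(config)
  n_per <- round(config$duration_per_posture * config$sampling_rate)
  at <- acquired_types()
  keys <- acquired_key(at$posture, at$sub_variant)
  n_total <- n_per * nrow(at)
  with_seed(seed, {
    scale_p <- stats::rnorm(1, mean = 1, sd = config$participant_scale_sd)
    means <- config$class_means[rep(keys, each = n_per), , drop = FALSE]
    noise <- matrix(stats::rnorm(n_total * 4, sd = config$noise_sd),
                    nrow = n_total, ncol = 4)
    values <- scale_p * means + noise
    data.frame(
      t = seq(0, by = 1 / config$sampling_rate, length.out = n_total),
      participant = participant,
      posture = rep(at$posture, each = n_per),
      sub_variant = rep(at$sub_variant, each = n_per),
      c1 = values[, 1], c2 = values[, 2], c3 = values[, 3], c4 = values[, 4],
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate the full multi-participant dataset
#'
#' Concatenates one acquisition session per participant; participant `i`
#' uses sub-seed `config$seed + i` so sessions are independent but the
#' whole dataset is reproducible from one seed.
#'
#' @param config a [sim_config()].
#' @return data.frame of sensor frames (see
#'   [generate_participant_session()]); `9600` rows under the defaults
#'   (20 participants x 8 types x 60 frames).
#' @export
generate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  sessions <- lapply(seq_len(config$n_participants), function(i) {
    generate_participant_session(config, sprintf("P%02d", i), config$seed + i)
  })
  do.call(rbind, sessions)
}

#' Simulate a per-second posture classification stream
#'
#' Emulates the recognition layer's output: one posture code per second
#' following a schedule of (posture, duration) blocks, with each tick
#' independently replaced by a uniformly random *other* code with
#' probability `misclassification_rate` (classifier noise).
#'
#' @param schedule data.frame with columns `posture` (codes 0-6 or names)
#'   and `duration` (positive integer seconds); or a list of
#'   `(posture, duration)` pairs.
#' @param misclassification_rate probability in `[0, 1)` that a tick's label
#'   is corrupted.
#' @param seed RNG seed.
#' @return data.frame with columns `t` (integer seconds, starting at 1) and
#'   `posture` (integer code), one row per second.
#' @examples
#' s <- generate_stream(data.frame(posture = 3, duration = 600))
#' nrow(s)  # 600 ticks, all leg_crossed
#' @export
generate_stream <- function(schedule, misclassification_rate = 0, seed = 1) {
  if (is.list(schedule) && !is.data.frame(schedule))
    schedule <- data.frame(posture = vapply(schedule, `[[`, numeric(1), 1),
                           duration = vapply(schedule, `[[`, numeric(1), 2))
  if (nrow(schedule) == 0) stop("empty schedule")
  if (any(schedule$duration <= 0) || any(schedule$duration != round(schedule$duration)))
    stop("schedule durations must be positive integers")
  if (misclassification_rate < 0 || misclassification_rate >= 1)
    stop("misclassification_rate must be in [0, 1)")
  codes <- posture_code(schedule$posture)
  labels <- rep(codes, times = schedule$duration)
  n <- length(labels)
  if (misclassification_rate > 0) {
    labels <- with_seed(seed, {
      hit <- stats::runif(n) < misclassification_rate
      if (any(hit)) {
        # uniform over the 6 codes other than the scheduled one
        offs <- sample.int(6, sum(hit), replace = TRUE)
        labels[hit] <- (labels[hit] + offs) %% 7L
      }
      labels
    })
  }
  data.frame(t = seq_len(n), posture = as.integer(labels))
}
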