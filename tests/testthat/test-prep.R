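test_that("validity filtering drops out-of-bounds and non-finite frames only", {
  bounds <- cbind(lo = c(0, 0, 0, 0), hi = c(100, 100, 100, 100))
  set.seed(5)
  good <- make_frames(runif(93, 10, 90))
  bad <- make_frames(c(runif(4, 150, 200), -5, NA, Inf))
  frames <- rbind(good, bad)[sample(100), ]
  out <- validate_samples(frames, bounds)
  expect_equal(nrow(out$frames), 93)
  expect_equal(out$dropped, 7)
  # order preserved among kept rows
  ok <- which(is.finite(frames$c1) & frames$c1 >= 0 & frames$c1 <= 100)
  expect_identical(out$frames$c1, frames$c1[ok])

  clean <- validate_samples(good, bounds)
  expect_identical(clean$frames, good)
  expect_equal(clean$dropped, 0)

  empty <- validate_samples(good[0, ], bounds)
  expect_equal(nrow(empty$frames), 0)
  expect_error(validate_samples(good, cbind(lo = c(1, 1, 1, 1),
                                            hi = c(0, 2, 2, 2))), "lo < hi")
})

test_that("label encoding merges sub-variants onto one leg-crossed code", {
  expect_equal(encode_labels(make_frames(1, "leg_crossed", "left_crossed")), 3L)
  expect_equal(encode_labels(make_frames(1, "leg_crossed", "right_crossed")), 3L)
  expect_equal(encode_labels(make_frames(1, "stance")), 0L)
  at <- acquired_types()
  codes <- encode_labels(at)
  expect_equal(sort(unique(codes)), 0:6)
  expect_error(encode_labels(make_frames(1, "slouching")), "slouching")
})

test_that("min-max normalization follows the training extrema exactly", {
  train <- dynsit:::new_dataset(
    cbind(c1 = c(2, 4, 6), c2 = c(0, 5, 10), c3 = c(1, 1, 1),
          c4 = c(-2, 0, 2)), labels = c(0L, 1L, 2L))
  test <- dynsit:::new_dataset(
    cbind(c1 = c(1, 8), c2 = c(5, 5), c3 = c(1, 2), c4 = c(0, 0)),
    labels = c(0L, 1L))
  out <- minmax_normalize(train, list(test))
  expect_equal(unname(out$train$features[, "c1"]), c(0, 0.5, 1))
  expect_true(all(out$train$features >= 0 & out$train$features <= 1))
  expect_true(all(out$train$features[1, c("c1", "c2")] == 0))
  expect_true(all(out$train$features[3, c("c1", "c2")] == 1))
  # constant channel maps to 0 everywhere
  expect_true(all(out$train$features[, "c3"] == 0))
  # held-out values outside the training range are not clipped
  expect_lt(out$others[[1]]$features[1, "c1"], 0)
  expect_gt(out$others[[1]]$features[2, "c1"], 1)
  expect_error(minmax_normalize(dynsit:::new_dataset(
    train$features[0, , drop = FALSE], integer(0))), "empty")
})

test_that("normalization is idempotent on its own training partition", {
  d <- as_dataset(generate_dataset(sim_config(n_participants = 2)))
  once <- minmax_normalize(d)
  twice <- minmax_normalize(once$train)
  expect_equal(twice$train$features, once$train$features)
  expect_true(all(once$train$features >= 0 & once$train$features <= 1))
})

test_that("per-participant normalization removes the amplitude factor exactly", {
  quiet <- sim_config(n_participants = 2, noise_sd = 0,
                      participant_scale_sd = 0.2, crossed_gap = 0.5)
  d <- as_dataset(generate_dataset(quiet))
  # multiplicative scale differs between wearers, so raw frames differ ...
  p1 <- d$features[d$participant == "P01" & d$labels == 1L, ]
  p2 <- d$features[d$participant == "P02" & d$labels == 1L, ]
  expect_false(isTRUE(all.equal(p1[1, ], p2[1, ])))
  # ... but per-participant min-max maps same-posture frames onto each other
  norm <- normalize_per_participant(d)
  q1 <- norm$features[norm$participant == "P01" & norm$labels == 1L, ]
  q2 <- norm$features[norm$participant == "P02" & norm$labels == 1L, ]
  expect_equal(q1[1, ], q2[1, ], tolerance = 1e-12)
})

test_that("stratified splitting is exact, disjoint and reproducible", {
  d <- as_dataset(generate_dataset(sim_config()))
  sp <- split_dataset(d, 0.8, seed = 3)
  expect_equal(nrow(sp$train$features), 7680)
  expect_equal(nrow(sp$test$features), 1920)
  expect_equal(sort(c(sp$train_idx, setdiff(seq_len(9600), sp$train_idx))),
               seq_len(9600))
  # per-class proportions within one sample of the target fraction
  for (cl in 0:6) {
    n_cl <- sum(d$labels == cl)
    n_tr <- sum(sp$train$labels == cl)
    expect_lte(abs(n_tr - 0.8 * n_cl), 1)
  }
  sp2 <- split_dataset(d, 0.8, seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_dataset(d, 0.8, seed = 4)
  expect_false(identical(sp$train_idx, sp3$train_idx))

  singleton <- dynsit:::new_dataset(cbind(c1 = 1:3, c2 = 1:3, c3 = 1:3,
                                          c4 = 1:3), c(0L, 0L, 1L))
  expect_error(split_dataset(singleton, 0.8), "2 members")
  expect_error(split_dataset(d, 1.2), "train_fraction")
})

test_that("validate-encode-normalize-split pipeline conserves sample counts", {
  cfg <- sim_config(n_participants = 2)
  frames <- generate_dataset(cfg)
  frames$c1[c(10, 500)] <- 1e6  # two implausible spikes
  v <- validate_samples(frames, default_bounds(cfg))
  expect_equal(nrow(v$frames) + v$dropped, nrow(frames))
  d <- as_dataset(v$frames)
  norm <- minmax_normalize(d)
  sp <- split_dataset(norm$train, 0.8, seed = 1)
  expect_equal(nrow(sp$train$features) + nrow(sp$test$features),
               nrow(frames) - 2)
})
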