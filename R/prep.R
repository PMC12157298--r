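#' Default validity bounds for sensor channels
#'
#' Per-channel plausibility limits derived from the simulator's class-mean
#' table: each channel's physical range (min to max baseline) widened by 50%
#' in value on both sides, i.e. `[0.5 * min, 1.5 * max]`, which comfortably
#' covers participant amplitude variation and sensor noise. Frames outside
#' these limits, or with non-finite values, are treated as invalid
#' acquisitions.
#'
#' @param config a [sim_config()] supplying the class-mean table.
#' @return 4 x 2 matrix with columns `lo`, `hi`, rows `c1`-`c4`.
#' @export
default_bounds <- function(config = sim_config()) {
  m <- config$class_means
  cbind(lo = 0.5 * apply(m, 2, min), hi = 1.5 * apply(m, 2, max))
}

#' Filter invalid sensor frames
#'
#' Drops frames with any non-finite channel value or any channel outside
#' the configured bounds; input order is preserved.
#'
#' @param frames sensor-frame data.frame (columns `c1`-`c4` at least).
#' @param bounds 4 x 2 matrix of `(lo, hi)` per channel
#'   (default [default_bounds()]).
#' @return list with `frames` (the kept rows) and `dropped` (count).
#' @export
validate_samples <- function(frames, bounds = default_bounds()) {
  if (!all(is.finite(bounds)) || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be finite with lo < hi per channel")
  if (nrow(frames) == 0) return(list(frames = frames, dropped = 0L))
  x <- as.matrix(frames[, c("c1", "c2", "c3", "c4")])
  ok <- rep(TRUE, nrow(x))
  for (j in 1:4) {
    ok <- ok & is.finite(x[, j]) & x[, j] >= bounds[j, 1] & x[, j] <= bounds[j, 2]
  }
  list(frames = frames[ok, , drop = FALSE], dropped = sum(!ok))
}

#' Encode posture labels as numeric codes
#'
#' Maps each frame's posture to its numeric class code 0-6. Both
#' leg-crossed sub-variants collapse onto code 3: their four-channel
#' signatures differ by less than the noise floor, so they are a single
#' class for recognition.
#'
#' @param frames sensor-frame data.frame with a `posture` column (names).
#' @return integer vector of codes, one per frame.
#' @export
encode_labels <- function(frames) {
  posture_code(frames$posture)
}

#' Build a labelled dataset from sensor frames
#'
#' @param frames sensor-frame data.frame.
#' @return object of class `posture_dataset`: list with `features`
#'   (n x 4 matrix, columns `c1`-`c4`), `labels` (integer codes),
#'   `participant`, `normalized` flag and `scaler` (NULL until fitted).
#' @export
as_dataset <- function(frames) {
  structure(
    list(features = as.matrix(frames[, c("c1", "c2", "c3", "c4")]),
         labels = encode_labels(frames),
         participant = frames$participant,
         normalized = FALSE, scaler = NULL),
    class = "posture_dataset"
  )
}

#' @export
print.posture_dataset <- function(x, ...) {
  cat("<posture_dataset> ", nrow(x$features), " samples, ",
      length(unique(x$labels)), " classes",
      if (isTRUE(x$normalized)) ", normalized" else "", "\n", sep = "")
  print(table(class_code = x$labels))
  invisible(x)
}

new_dataset <- function(features, labels, participant = NULL,
                        normalized = FALSE, scaler = NULL) {
  structure(list(features = features, labels = labels,
                 participant = participant, normalized = normalized,
                 scaler = scaler), class = "posture_dataset")
}

#' Min-max normalization fitted on the training partition
#'
#' Rescales each channel as `(x - min) / (max - min)` with the extrema
#' learned from `train` only and applied unchanged to any other partitions,
#' so every training value lands in `[0, 1]` while held-out values may fall
#' outside (no clipping: the map stays affine and invertible). A constant
#' channel maps to 0 everywhere. This removes inter-participant amplitude
#' differences that are shared across channels.
#'
#' @param train `posture_dataset` to fit the scaler on (non-empty).
#' @param others optional list of `posture_dataset`s to transform with the
#'   training scaler.
#' @return list with `train`, `others` (both normalized) and `scaler`
#'   (per-channel `list(min =, max =)`).
#' @export
minmax_normalize <- function(train, others = list()) {
  stopifnot(inherits(train, "posture_dataset"))
  if (nrow(train$features) == 0) stop("training partition is empty")
  mins <- apply(train$features, 2, min)
  maxs <- apply(train$features, 2, max)
  scaler <- list(min = mins, max = maxs)
  norm1 <- function(d) {
    f <- apply_scaler_matrix(d$features, scaler)
    new_dataset(f, d$labels, d$participant, normalized = TRUE, scaler = scaler)
  }
  list(train = norm1(train), others = lapply(others, norm1), scaler = scaler)
}

apply_scaler_matrix <- function(x, scaler) {
  span <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min, `-`)
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, span[nz], `/`)
  out[, !nz] <- 0
  out
}

#' Apply a previously fitted min-max scaler
#'
#' @param dataset a `posture_dataset`.
#' @param scaler per-channel extrema as returned by [minmax_normalize()].
#' @return normalized `posture_dataset`.
#' @export
apply_scaler <- function(dataset, scaler) {
  new_dataset(apply_scaler_matrix(dataset$features, scaler),
              dataset$labels, dataset$participant,
              normalized = TRUE, scaler = scaler)
}

#' Per-participant min-max normalization
#'
#' Alternative normalization granularity: each participant's frames are
#' rescaled with that participant's own channel extrema. This removes a
#' per-participant multiplicative amplitude factor exactly, at the cost of
#' needing per-wearer calibration at deployment; the global scaler of
#' [minmax_normalize()] is the default pipeline.
#'
#' @param dataset a `posture_dataset` with a non-NULL `participant` field.
#' @return normalized `posture_dataset`.
#' @export
normalize_per_participant <- function(dataset) {
  stopifnot(inherits(dataset, "posture_dataset"), !is.null(dataset$participant))
  f <- dataset$features
  for (p in unique(dataset$participant)) {
    idx <- dataset$participant == p
    sub <- f[idx, , drop = FALSE]
    sc <- list(min = apply(sub, 2, min), max = apply(sub, 2, max))
    f[idx, ] <- apply_scaler_matrix(sub, sc)
  }
  new_dataset(f, dataset$labels, dataset$participant, normalized = TRUE,
              scaler = NULL)
}

#' Stratified train/test split
#'
#' Partitions a dataset into disjoint, exhaustive train and test sets.
#' Under stratification each class contributes `round(n_class *
#' train_fraction)` training samples, so per-class proportions are within
#' one sample of the target fraction; sampling is seeded and reproducible.
#'
#' @param dataset a `posture_dataset`.
#' @param train_fraction proportion assigned to training (default 0.8).
#' @param stratified sample within classes (default TRUE).
#' @param seed RNG seed.
#' @return list with `train` and `test` (`posture_dataset`s) and
#'   `train_idx` (the training row indices).
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, stratified = TRUE,
                          seed = 1) {
  stopifnot(inherits(dataset, "posture_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- length(dataset$labels)
  train_idx <- with_seed(seed, {
    if (stratified) {
      counts <- table(dataset$labels)
      if (any(counts < 2))
        stop("stratified split needs >= 2 members per class")
      idx <- integer(0)
      for (cl in names(counts)) {
        rows <- which(dataset$labels == as.integer(cl))
        k <- round(length(rows) * train_fraction)
        k <- max(1L, min(k, length(rows) - 1L))
        idx <- c(idx, sample(rows, k))
      }
      sort(idx)
    } else {
      sort(sample.int(n, round(n * train_fraction)))
    }
  })
  take <- function(idx) new_dataset(
    dataset$features[idx, , drop = FALSE], dataset$labels[idx],
    if (!is.null(dataset$participant)) dataset$participant[idx],
    dataset$normalized, dataset$scaler)
  list(train = take(train_idx), test = take(setdiff(seq_len(n), train_idx)),
       train_idx = train_idx)
}
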