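#' Posture label set
#'
#' The seven-class label set used throughout the package: standing plus six
#' sitting postures. Left and right leg-crossed variants are acquired
#' separately but merged into the single `leg_crossed` class before
#' classification, because their four-channel signatures are nearly
#' indistinguishable.
#'
#' @return Named integer vector mapping posture name to numeric code 0-6.
#' @examples
#' posture_codes()
#' @export
posture_codes <- function() {
  c(stance = 0L, upright = 1L, back_bent = 2L, leg_crossed = 3L,
    forward = 4L, backward = 5L, other = 6L)
}

#' @rdname posture_codes
#' @export
posture_names <- function() names(posture_codes())

#' Convert between posture names and codes
#'
#' @param x posture names (character) or codes (integer 0-6).
#' @return `posture_code()` returns integer codes; `posture_name()` returns
#'   character names.
#' @examples
#' posture_code("leg_crossed")  # 3
#' posture_name(0)              # "stance"
#' @export
posture_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    bad <- !(x %in% 0:6)
    if (any(bad)) stop("unknown posture code(s): ",
                       paste(unique(x[bad]), collapse = ", "))
    return(x)
  }
  codes <- posture_codes()
  bad <- !(x %in% names(codes))
  if (any(bad)) stop("unknown posture name(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  unname(codes[x])
}

#' @rdname posture_code
#' @export
posture_name <- function(x) {
  x <- posture_code(x)
  posture_names()[x + 1L]
}

#' Acquired posture types
#'
#' The eight posture conditions recorded during acquisition: the seven
#' classes of [posture_codes()] with `leg_crossed` expanded into its left
#' and right sub-variants.
#'
#' @return data.frame with columns `posture` (class name) and `sub_variant`
#'   (`"left_crossed"`, `"right_crossed"` or `"none"`), 8 rows.
#' @export
acquired_types <- function() {
  data.frame(
    posture = c("stance", "upright", "back_bent", "leg_crossed",
                "leg_crossed", "forward", "backward", "other"),
    sub_variant = c("none", "none", "none", "left_crossed",
                    "right_crossed", "none", "none", "none"),
    stringsAsFactors = FALSE
  )
}

# internal key for one acquired type ("leg_crossed/left_crossed" etc.)
acquired_key <- function(posture, sub_variant) {
  ifelse(sub_variant == "none", posture, paste(posture, sub_variant, sep = "/"))
}
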