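# Internal helpers shared across modules.

# Factor level sets used throughout the trial schema.
at_groups <- c("SVI", "S")
at_postures <- c("uncrossed", "crossed")
at_conditions <- c("tactile_only", "auditory_only", "at_congruent", "at_incongruent")
at_sides <- c("left", "right")
at_modalities <- c("arm_hand", "eye_head", "both")

#' @noRd
# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Quantize times to the video frame grid
#'
#' Rounds times to the nearest multiple of one video frame. Coding was done
#' from video, so rated reaction times can only be resolved to the frame.
#'
#' @param x Numeric vector of times in seconds.
#' @param fps Frames per second of the video (default 25).
#' @return Numeric vector quantized to `1/fps` seconds.
#' @export
quantize_frames <- function(x, fps = 25) {
  round(x * fps) / fps
}

#' @noRd
# Derive a stream of sub-seeds from one master seed, staying within 32-bit
# integer range so set.seed() always accepts them.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max, n))
}

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}
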