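# Frame sequences: the unit every detector and editor consumes.

#' Construct a frame sequence
#'
#' A `frame_sequence` is an ordered list of 8-bit frames sharing one geometry,
#' together with a frame rate. Frames are integer matrices (grayscale,
#' height x width) or height x width x 3 integer arrays (RGB), values 0-255.
#' Frame indexing is 1-based throughout the public API: frame 1 is the static
#' reference frame, so the earliest possible motion onset is frame 2.
#'
#' @param frames list of frames (integer matrices or H x W x 3 arrays, 0-255).
#' @param fps frames per second; positive. Default 60, the usual recording
#'   rate for action-observation stimuli.
#' @return object of class `frame_sequence` with elements `frames`, `fps`,
#'   `width`, `height`.
#' @export
frame_sequence <- function(frames, fps = 60) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list of frames", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number", call. = FALSE)
  dims <- lapply(frames, frame_dims)
  ref <- dims[[1L]]
  same <- vapply(dims, function(d) identical(d, ref), logical(1L))
  if (!all(same))
    stop("all frames must share identical dimensions and channel count",
         call. = FALSE)
  frames <- lapply(frames, check_frame)
  structure(
    list(frames = frames, fps = as.numeric(fps),
         width = ref[["width"]], height = ref[["height"]]),
    class = "frame_sequence")
}

# height/width/channels of one frame, with validation
frame_dims <- function(frame) {
  if (is.matrix(frame))
    return(c(height = nrow(frame), width = ncol(frame), channels = 1L))
  if (is.array(frame) && length(dim(frame)) == 3L && dim(frame)[3L] %in% c(1L, 3L))
    return(c(height = dim(frame)[1L], width = dim(frame)[2L],
             channels = dim(frame)[3L]))
  stop("frame must be a matrix or an H x W x {1,3} array", call. = FALSE)
}

check_frame <- function(frame) {
  v <- as.vector(frame)
  if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 255))
    stop("frame values must be finite integers in [0, 255]", call. = FALSE)
  storage.mode(frame) <- "integer"
  frame
}

#' Number of frames in a sequence
#' @param seq a `frame_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  length(seq$frames)
}

#' @export
print.frame_sequence <- function(x, ...) {
  ch <- frame_dims(x$frames[[1L]])[["channels"]]
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %s, %g fps (%.3f s)\n",
              length(x$frames), x$width, x$height,
              if (ch == 1L) "grayscale" else "RGB",
              x$fps, length(x$frames) / x$fps))
  invisible(x)
}

#' Basic metadata of a video
#'
#' @param seq a `frame_sequence`.
#' @param video_id identifier string.
#' @return list with `video_id`, `n_frames`, `fps` and `duration_s`
#'   (= n_frames / fps).
#' @export
video_metadata <- function(seq, video_id = NA_character_) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  list(video_id = video_id, n_frames = n, fps = seq$fps,
       duration_s = n / seq$fps)
}

#' Convert a frame to grayscale
#'
#' 3-channel frames are combined with the ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114) and rounded half-up to integers; single-channel
#' frames pass through unchanged.
#'
#' @param frame integer matrix or H x W x {1,3} array, values 0-255.
#' @return integer matrix (height x width), values 0-255.
#' @export
to_grayscale <- function(frame) {
  d <- frame_dims(frame)
  frame <- check_frame(frame)
  if (d[["channels"]] == 1L) {
    if (is.matrix(frame)) return(frame)
    return(matrix(frame[, , 1L], nrow = d[["height"]]))
  }
  g <- 0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
  out <- matrix(round_half_up(g), nrow = d[["height"]])
  storage.mode(out) <- "integer"
  out
}

# round half away from zero is not needed; inputs are non-negative
round_half_up <- function(x) floor(x + 0.5)

#' Trim a sequence so motion starts at frame 2
#'
#' Drops the still frames preceding motion: the edited clip starts at the
#' frame *before* the onset frame, so that the onset lands on frame 2 and
#' frame 1 remains a valid static reference. Re-running onset detection on
#' the result yields onset 2 whenever the original motion persists.
#'
#' @param seq a `frame_sequence`.
#' @param onset_frame 1-based onset, `2 <= onset_frame <= n_frames(seq)`.
#' @return trimmed `frame_sequence` of length `n_frames - onset_frame + 2`.
#' @export
trim_to_onset <- function(seq, onset_frame) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  if (!is.numeric(onset_frame) || length(onset_frame) != 1L ||
      onset_frame != as.integer(onset_frame) || onset_frame < 2 || onset_frame > n)
    stop(sprintf("onset_frame must be an integer in [2, %d]", n), call. = FALSE)
  frame_sequence(seq$frames[(onset_frame - 1L):n], fps = seq$fps)
}

#' Merge automatic onsets with human-judged overrides
#'
#' Where a human observer disagrees with the frame-differencing output the
#' human judgment wins; the returned report lists every disagreement so the
#' correction rate can be audited.
#'
#' @param auto named numeric vector, video_id -> automatic onset frame.
#' @param manual named numeric vector, video_id -> human-judged onset frame
#'   (every onset >= 2; every name must exist in `auto`).
#' @return list with `onsets` (resolved named vector) and `disagreements`
#'   (data frame video_id / auto / manual, only rows where the two differ).
#' @export
resolve_onsets <- function(auto, manual = numeric(0)) {
  if (is.null(names(auto)) && length(auto) > 0)
    stop("'auto' must be a named vector keyed by video_id", call. = FALSE)
  if (length(manual) > 0) {
    if (is.null(names(manual)))
      stop("'manual' must be a named vector keyed by video_id", call. = FALSE)
    missing <- setdiff(names(manual), names(auto))
    if (length(missing) > 0)
      stop("manual override for unknown video_id: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (any(manual < 2, na.rm = TRUE))
      stop("manual onsets must be >= 2 (frame 1 is the reference)",
           call. = FALSE)
  }
  resolved <- auto
  resolved[names(manual)] <- manual
  dis <- names(manual)[manual != auto[names(manual)]]
  list(
    onsets = resolved,
    disagreements = data.frame(
      video_id = dis,
      auto = unname(auto[dis]),
      manual = unname(manual[dis]),
      stringsAsFactors = FALSE))
}
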