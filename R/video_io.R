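# Lossless frame-directory I/O. Clips are stored as directories of numbered
# PNG frames plus a small video.yaml carrying the frame rate, so threshold
# tests are never perturbed by a lossy codec.

#' Load a video from a frame-image directory
#'
#' Reads an ordered PNG frame directory (as written by [save_video()], or any
#' directory of frames whose lexicographic filename order is the presentation
#' order). The frame rate is taken from the directory's `video.yaml` when
#' present, else from `fps`, else 60.
#'
#' @param path directory of PNG frames.
#' @param fps fallback frames per second when the directory carries no
#'   metadata; default 60.
#' @return a [frame_sequence()].
#' @export
load_video <- function(path, fps = NULL) {
  if (!file.exists(path))
    stop("input path does not exist: ", path, call. = FALSE)
  if (!dir.exists(path)) {
    if (file.info(path)$size == 0)
      stop("input file is empty (zero bytes): ", path, call. = FALSE)
    stop("cannot decode '", path, "': container decoding is not supported; ",
         "supply a directory of PNG frames (see save_video)", call. = FALSE)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop("no PNG frames found in directory: ", path, call. = FALSE)
  frames <- lapply(files, read_png_frame)
  meta_path <- file.path(path, "video.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$fps)) fps <- meta$fps
  }
  if (is.null(fps)) fps <- 60
  frame_sequence(frames, fps = fps)
}

read_png_frame <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  out <- round(img * 255)
  if (length(dim(out)) == 3L && dim(out)[3L] == 1L)
    out <- matrix(out, nrow = dim(img)[1L])
  storage.mode(out) <- "integer"
  out
}

#' Save a video as a lossless frame-image directory
#'
#' Writes one 8-bit PNG per frame (`frame_0001.png`, ...) plus a `video.yaml`
#' with fps and geometry. The round trip through [load_video()] is
#' bit-exact.
#'
#' @param seq a [frame_sequence()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
save_video <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (length(seq$frames) == 0L)
    stop("cannot save an empty sequence", call. = FALSE)
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!ok && !dir.exists(path))
    stop("cannot create output directory: ", path, call. = FALSE)
  n <- length(seq$frames)
  width <- max(4L, nchar(as.character(n)))
  for (i in seq_len(n)) {
    f <- seq$frames[[i]] / 255
    file <- file.path(path, sprintf("frame_%0*d.png", width, i))
    png::writePNG(f, target = file)
  }
  yaml::write_yaml(
    list(fps = seq$fps, n_frames = n, width = seq$width, height = seq$height),
    file.path(path, "video.yaml"))
  invisible(path)
}

#' Read a human onset-override table
#'
#' CSV with columns `video_id` and `onset_frame` (1-based, all >= 2), used to
#' replace automatic onsets where a human observer disagreed.
#'
#' @param path CSV file.
#' @return named numeric vector video_id -> onset frame.
#' @export
read_onset_overrides <- function(path) {
  if (!file.exists(path))
    stop("override table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("video_id", "onset_frame")
  if (!all(need %in% names(tab)))
    stop("override table must have columns video_id, onset_frame",
         call. = FALSE)
  if (any(tab$onset_frame < 2))
    stop("override onsets must be >= 2 (frame 1 is the reference)",
         call. = FALSE)
  stats::setNames(as.numeric(tab$onset_frame), tab$video_id)
}

#' Write detected onsets to CSV
#'
#' @param onsets data frame with columns video_id, onset_frame, n_frames, fps.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_onsets <- function(onsets, path) {
  utils::write.csv(onsets, path, row.names = FALSE)
  invisible(path)
}
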