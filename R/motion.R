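# Frame-differencing motion-onset detector. Every frame is compared to the
# static initial frame on the grayscale; pixels differing by at least a fixed
# fraction of the intensity range form a binary change mask, whose connected
# regions are reduced to bounding boxes. Boxes smaller than a minimum area,
# or outside the vertical band occupied by the actor, are discarded as noise;
# the first frame with a surviving box is the frame of motion onset.

#' Motion-detection configuration
#'
#' @param threshold_fraction fraction of the full intensity range a pixel must
#'   change by to count as different; default 0.10 ("at least 10%"), i.e.
#'   |delta| >= 25.5, so integer |delta| >= 26 on 8-bit frames.
#' @param min_box_area minimum bounding-box area (w x h, pixels) a changed
#'   region must reach to count as motion; default 400. Rejects pixel-scale
#'   noise such as sensor flicker or small shadows.
#' @param roi_y inclusive `c(y_min, y_max)` vertical band (pixels, 1-based)
#'   that a box must overlap to count as actor motion, or `NULL` for the full
#'   frame height. Only the Y dimension is restricted.
#' @param reference_frame index of the static reference frame; default 1 and
#'   never updated (no running background model).
#' @return list of class `motion_config`.
#' @export
motion_config <- function(threshold_fraction = 0.10, min_box_area = 400,
                          roi_y = NULL, reference_frame = 1L) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  if (!is.numeric(min_box_area) || length(min_box_area) != 1L || min_box_area < 1)
    stop("min_box_area must be >= 1", call. = FALSE)
  if (!is.null(roi_y)) {
    if (length(roi_y) != 2L || any(roi_y < 1) || roi_y[1L] > roi_y[2L])
      stop("roi_y must be c(y_min, y_max) with 1 <= y_min <= y_max",
           call. = FALSE)
    roi_y <- as.integer(roi_y)
  }
  structure(
    list(threshold_fraction = threshold_fraction,
         min_box_area = as.numeric(min_box_area),
         roi_y = roi_y,
         reference_frame = as.integer(reference_frame)),
    class = "motion_config")
}

#' Binary change mask between a frame and the reference
#'
#' TRUE exactly where `|frame - reference| >= threshold_fraction * 255`;
#' ties count as changed ("at least").
#'
#' @param gray_frame,gray_reference single-channel integer matrices of equal
#'   dimensions.
#' @param threshold_fraction see [motion_config()].
#' @return logical matrix of the same dimensions.
#' @export
difference_mask <- function(gray_frame, gray_reference,
                            threshold_fraction = 0.10) {
  if (!is.matrix(gray_frame) || !is.matrix(gray_reference))
    stop("difference_mask expects single-channel matrices", call. = FALSE)
  if (!identical(dim(gray_frame), dim(gray_reference)))
    stop("frame and reference dimensions differ", call. = FALSE)
  abs(gray_frame - gray_reference) >= threshold_fraction * 255
}

#' Bounding boxes of changed regions
#'
#' Extracts one bounding box per 8-connected region of TRUE pixels and keeps
#' those with area `w * h >= min_box_area` whose vertical extent overlaps
#' `roi_y`. Boxes are returned top-to-bottom, then left-to-right.
#'
#' @param mask logical change mask (from [difference_mask()]).
#' @param config a [motion_config()].
#' @return data frame with columns `x`, `y` (1-based top-left corner), `w`,
#'   `h`, `area`; zero rows when nothing survives.
#' @export
motion_boxes <- function(mask, config = motion_config()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  empty <- data.frame(x = integer(0), y = integer(0), w = integer(0),
                      h = integer(0), area = numeric(0))
  if (!any(mask)) return(empty)
  lab <- label_components8(mask)
  idx <- which(lab > 0L)
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  comp <- lab[idx]
  y0 <- tapply(rows, comp, min); y1 <- tapply(rows, comp, max)
  x0 <- tapply(cols, comp, min); x1 <- tapply(cols, comp, max)
  boxes <- data.frame(x = as.integer(x0), y = as.integer(y0),
                      w = as.integer(x1 - x0 + 1L),
                      h = as.integer(y1 - y0 + 1L))
  boxes$area <- as.numeric(boxes$w) * boxes$h
  keep <- boxes$area >= config$min_box_area
  if (!is.null(config$roi_y))
    keep <- keep & (boxes$y <= config$roi_y[2L]) &
      (boxes$y + boxes$h - 1L >= config$roi_y[1L])
  boxes <- boxes[keep, , drop = FALSE]
  boxes <- boxes[order(boxes$y, boxes$x), , drop = FALSE]
  rownames(boxes) <- NULL
  boxes
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a small union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  H <- nrow(lab); W <- ncol(lab)
  for (dc in c(1L, -1L)) {  # down-right and down-left diagonals
    cr <- if (dc == 1L) 1:(W - 1L) else 2:W
    a <- lab[1:(H - 1L), cr, drop = FALSE]
    b <- lab[2:H, cr + dc, drop = FALSE]
    hit <- which(a > 0L & b > 0L & a != b)
    for (i in hit) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1L))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[out > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Detect the frame of motion onset
#'
#' For every frame from 2 to the end, compares the grayscale frame to the
#' grayscale static reference (frame 1 by default), extracts surviving motion
#' boxes, and reports the first frame with at least one survivor as the frame
#' of motion onset. The per-frame box count is logged for all frames so
#' detector behavior can be audited even after the onset.
#'
#' @param seq a [frame_sequence()] with at least 2 frames.
#' @param config a [motion_config()].
#' @param video_id identifier carried into the result.
#' @return list of class `onset_result`: `video_id`, `onset_frame` (1-based,
#'   `NA` if no frame ever qualifies), `log` (data frame `frame`, `n_boxes`
#'   covering frames 2..n), `config`.
#' @export
detect_motion_onset <- function(seq, config = motion_config(),
                                video_id = NA_character_) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(config, "motion_config"))
  n <- length(seq$frames)
  if (n < 2L)
    stop("onset detection needs at least 2 frames (got ", n, ")",
         call. = FALSE)
  ref <- to_grayscale(seq$frames[[config$reference_frame]])
  n_boxes <- integer(n - 1L)
  for (t in 2:n) {
    mask <- difference_mask(to_grayscale(seq$frames[[t]]), ref,
                            config$threshold_fraction)
    n_boxes[t - 1L] <- nrow(motion_boxes(mask, config))
  }
  hits <- which(n_boxes > 0L)
  structure(
    list(video_id = video_id,
         onset_frame = if (length(hits)) hits[1L] + 1L else NA_integer_,
         log = data.frame(frame = 2:n, n_boxes = n_boxes),
         config = config),
    class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  cat(sprintf("<onset_result> video %s: onset %s (frames checked: %d)\n",
              x$video_id,
              if (is.na(x$onset_frame)) "none" else x$onset_frame,
              nrow(x$log)))
  invisible(x)
}
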