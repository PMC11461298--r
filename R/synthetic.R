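# Seeded synthetic generators: videos with a known frame of motion onset,
# rating tables with a known confusion structure, and observer pools with
# known recognition frames. Everything is a pure function of (spec, seed),
# so the whole toolkit can be exercised and regression-tested without any
# external recordings.

#' Specification of a synthetic motion clip
#'
#' Emulates, at desk scale, the structure the detector assumes in real
#' stimulus recordings: a static (optionally textured) background, a single
#' moving region belonging to an actor band in Y, and a true motion onset
#' within the first frames of the clip. Distractor events model the usual
#' false-positive sources (small shadows, flicker) as sub-area or
#' sub-threshold changes.
#'
#' @param width,height frame geometry in pixels; default 200 x 200
#'   (full-scale stimuli are 720 x 1280; the generator is resolution-free).
#' @param n_frames clip length; default 100.
#' @param fps frame rate; default 60, the stimulus recording rate.
#' @param background_level constant background gray level (0-255).
#' @param background_noise_sd SD of i.i.d. Gaussian static texture added to
#'   the background once (quantized to 8-bit); 0 gives a flat background.
#'   The texture is static across frames, as real backgrounds are.
#' @param onset_frame true frame of motion onset (1-based, in
#'   `[2, n_frames]`); default 10. Real clips show onsets in frames 2-18.
#' @param patch_w,patch_h size of the moving patch; default 30 x 30
#'   (area 900 >= the default 400-px box-area floor).
#' @param patch_step intensity step of the patch over the background;
#'   default 120 (well above the 10% change threshold of 25.5 levels).
#' @param patch_xy optional `c(x, y)` top-left corner; default: seeded
#'   uniform placement inside `actor_band`.
#' @param trajectory `"appear"` (patch appears at onset and stays) or
#'   `"drift"` (appears at onset, then drifts `drift_px` per frame in X,
#'   bouncing off the frame edge).
#' @param drift_px horizontal speed for `"drift"`; default 2 px/frame.
#' @param actor_band inclusive `c(y_min, y_max)` band containing the patch;
#'   default full height.
#' @param distractors list of distractor events, each a list with `area`
#'   (pixels, drawn as a square), `step` (intensity step) and `period`
#'   (frames between flashes; 1 = every frame from frame 2 on).
#' @param seed integer seed.
#' @return list of class `synthetic_video_spec`.
#' @export
synthetic_video_spec <- function(width = 200, height = 200, n_frames = 100,
                                 fps = 60, background_level = 0,
                                 background_noise_sd = 0, onset_frame = 10,
                                 patch_w = 30, patch_h = 30, patch_step = 120,
                                 patch_xy = NULL, trajectory = c("appear", "drift"),
                                 drift_px = 2, actor_band = NULL,
                                 distractors = list(), seed = 1L) {
  trajectory <- match.arg(trajectory)
  if (onset_frame < 2 || onset_frame > n_frames)
    stop("onset_frame must lie in [2, n_frames]", call. = FALSE)
  if (is.null(actor_band)) actor_band <- c(1L, height)
  if (actor_band[1L] < 1 || actor_band[2L] > height ||
      actor_band[1L] > actor_band[2L])
    stop("actor_band must be c(y_min, y_max) within the frame", call. = FALSE)
  if (patch_w > width || patch_h > actor_band[2L] - actor_band[1L] + 1L)
    stop("patch does not fit inside the frame/actor band", call. = FALSE)
  if (!is.null(patch_xy)) {
    if (patch_xy[1L] < 1 || patch_xy[1L] + patch_w - 1L > width ||
        patch_xy[2L] < actor_band[1L] ||
        patch_xy[2L] + patch_h - 1L > actor_band[2L])
      stop("patch_xy places the patch outside the frame/actor band",
           call. = FALSE)
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_frames = as.integer(n_frames), fps = fps,
         background_level = background_level,
         background_noise_sd = background_noise_sd,
         onset_frame = as.integer(onset_frame),
         patch_w = as.integer(patch_w), patch_h = as.integer(patch_h),
         patch_step = patch_step, patch_xy = patch_xy,
         trajectory = trajectory, drift_px = as.integer(drift_px),
         actor_band = as.integer(actor_band), distractors = distractors,
         seed = as.integer(seed)),
    class = "synthetic_video_spec")
}

clip8 <- function(x) {
  x[x < 0] <- 0; x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Generate a synthetic motion clip with known ground truth
#'
#' Frames before the onset are identical (bit-identical when the texture SD
#' is 0 — the texture itself is static, so they are bit-identical in all
#' cases); from the onset frame onward the patch is present inside the actor
#' band. Identical specs give bit-identical sequences.
#'
#' @param spec a [synthetic_video_spec()].
#' @return list with `seq` (a [frame_sequence()]) and `truth` (list:
#'   `onset_frame`, `patch` = x/y/w/h/step, `seed`).
#' @export
make_motion_video <- function(spec) {
  stopifnot(inherits(spec, "synthetic_video_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  bg <- matrix(spec$background_level, spec$height, spec$width)
  if (spec$background_noise_sd > 0)
    bg <- bg + matrix(stats::rnorm(spec$height * spec$width,
                                   sd = spec$background_noise_sd),
                      spec$height, spec$width)
  bg <- clip8(round_half_up(bg))

  if (is.null(spec$patch_xy)) {
    x0 <- sample.int(spec$width - spec$patch_w + 1L, 1L)
    ymin <- spec$actor_band[1L]
    ymax <- spec$actor_band[2L] - spec$patch_h + 1L
    y0 <- ymin + sample.int(ymax - ymin + 1L, 1L) - 1L
  } else {
    x0 <- spec$patch_xy[1L]; y0 <- spec$patch_xy[2L]
  }

  dis <- lapply(spec$distractors, function(d) {
    side <- max(1L, round_half_up(sqrt(d$area)))
    list(side = side, step = d$step, period = max(1L, as.integer(d$period)),
         x = sample.int(spec$width - side + 1L, 1L),
         y = sample.int(spec$height - side + 1L, 1L))
  })

  dir <- 1L
  px <- x0
  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    f <- matrix(as.numeric(bg), spec$height, spec$width)
    if (t >= spec$onset_frame) {
      if (spec$trajectory == "drift" && t > spec$onset_frame) {
        nx <- px + dir * spec$drift_px
        if (nx < 1L || nx + spec$patch_w - 1L > spec$width) dir <- -dir
        px <- min(max(px + dir * spec$drift_px, 1L),
                  spec$width - spec$patch_w + 1L)
      }
      rows <- y0:(y0 + spec$patch_h - 1L)
      cols <- px:(px + spec$patch_w - 1L)
      f[rows, cols] <- f[rows, cols] + spec$patch_step
    }
    for (d in dis) {
      if (t >= 2L && ((t - 2L) %% d$period) == 0L) {
        rows <- d$y:(d$y + d$side - 1L)
        cols <- d$x:(d$x + d$side - 1L)
        f[rows, cols] <- f[rows, cols] + d$step
      }
    }
    frames[[t]] <- clip8(f)
  }
  list(seq = frame_sequence(frames, fps = spec$fps),
       truth = list(onset_frame = spec$onset_frame,
                    patch = list(x = x0, y = y0, w = spec$patch_w,
                                 h = spec$patch_h, step = spec$patch_step),
                    seed = spec$seed))
}

#' Specification of a synthetic rating table
#'
#' @param n_items number of videos; default 135, a full three-category,
#'   fifteen-object, three-angle stimulus set.
#' @param n_raters number of raters; default 51.
#' @param labels category labels; default Normal/How/What.
#' @param kernel k x k confusion kernel: `kernel[j, l]` is the probability
#'   of answering category l when the truth is j (rows sum to 1). Default
#'   0.9 on the diagonal, the remainder split evenly.
#' @param balanced if TRUE (default), truth labels are assigned in equal
#'   proportions; otherwise drawn uniformly.
#' @param seed integer seed.
#' @return list of class `synthetic_rating_spec`.
#' @export
synthetic_rating_spec <- function(n_items = 135, n_raters = 51,
                                  labels = c("Normal", "How", "What"),
                                  kernel = NULL, balanced = TRUE, seed = 1L) {
  k <- length(labels)
  if (k < 2) stop("need at least 2 categories", call. = FALSE)
  if (is.null(kernel)) {
    kernel <- matrix(0.1 / (k - 1), k, k)
    diag(kernel) <- 0.9
  }
  if (!is.matrix(kernel) || any(dim(kernel) != k) || any(kernel < 0) ||
      any(abs(rowSums(kernel) - 1) > 1e-8))
    stop("kernel must be k x k with non-negative rows summing to 1",
         call. = FALSE)
  structure(
    list(n_items = as.integer(n_items), n_raters = as.integer(n_raters),
         labels = labels, kernel = kernel, balanced = isTRUE(balanced),
         seed = as.integer(seed)),
    class = "synthetic_rating_spec")
}

#' Generate a synthetic rating table with known truth
#'
#' Truth labels are balanced (or uniform) over the categories; each response
#' is drawn from the confusion-kernel row of the item's truth, independently
#' per rater.
#'
#' @param spec a [synthetic_rating_spec()].
#' @return a [rating_matrix()] with a `truth` column.
#' @export
make_ratings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_rating_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)
  k <- length(spec$labels)
  truth <- if (spec$balanced)
    sample(rep(spec$labels, length.out = spec$n_items))
  else
    sample(spec$labels, spec$n_items, replace = TRUE)
  video_id <- sprintf("v%03d", seq_len(spec$n_items))
  rows <- expand.grid(rater = seq_len(spec$n_raters),
                      item = seq_len(spec$n_items))
  resp <- vapply(seq_len(nrow(rows)), function(i) {
    j <- match(truth[rows$item[i]], spec$labels)
    sample(spec$labels, 1L, prob = spec$kernel[j, ])
  }, character(1L))
  rating_matrix(
    data.frame(video_id = video_id[rows$item],
               rater_id = sprintf("r%03d", rows$rater),
               response = resp,
               truth = truth[rows$item],
               stringsAsFactors = FALSE),
    labels = spec$labels)
}

#' Build a pool of simulated observers, one per video
#'
#' @param true_frames named numeric vector video_id -> true recognition
#'   frame r.
#' @param guess_rate,lapse observer parameters, see [observer_model()].
#' @param seed base seed; each video gets a distinct derived seed.
#' @param Nframes optional named vector of clip lengths used to validate that
#'   each r lies within its video's frame range.
#' @return named list of [observer_model()]s, usable via
#'   [observer_responder()] as staircase responders.
#' @export
make_observer_pool <- function(true_frames, guess_rate = 1/3, lapse = 0,
                               seed = 1L, Nframes = NULL) {
  if (is.null(names(true_frames)) || any(!nzchar(names(true_frames))))
    stop("true_frames must be named by video_id", call. = FALSE)
  if (any(true_frames < 1))
    stop("every recognition frame must be >= 1", call. = FALSE)
  if (!is.null(Nframes)) {
    bad <- names(true_frames)[true_frames > Nframes[names(true_frames)]]
    if (length(bad) > 0)
      stop("recognition frame beyond clip length for: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_along(true_frames), function(i)
    observer_model(true_frames[[i]], guess_rate = guess_rate, lapse = lapse,
                   seed = seed + i))
  stats::setNames(out, names(true_frames))
}
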