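# End-to-end orchestration: detect onsets -> apply human overrides -> trim ->
# simulate the recognition staircase -> evaluate ratings, with every stage's
# parameters and the seed logged so a rerun reproduces identical outputs.

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file or a plain list. Missing detector values get the
#' standard defaults (threshold fraction 0.10, minimum box area 400 px,
#' 60 fps); all problems are collected and reported together.
#'
#' Recognized keys: `input` (directory of frame-image video directories),
#' `output` (directory, created on run), `seed`, `fps`,
#' `threshold_fraction`, `min_box_area`, `roi_y_min`, `roi_y_max`,
#' `overrides` (onset-override CSV), `true_frames` (CSV video_id, r_frame
#' enabling the staircase simulation), `guess_rate`, `lapse`,
#' `ratings` (ratings CSV enabling psychometric evaluation).
#'
#' @param config path to a YAML file, or a named list.
#' @return normalized list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  known <- c("input", "output", "seed", "fps", "threshold_fraction",
             "min_box_area", "roi_y_min", "roi_y_max", "overrides",
             "true_frames", "guess_rate", "lapse", "ratings")
  errs <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  defaults <- list(seed = 1L, fps = 60, threshold_fraction = 0.10,
                   min_box_area = 400, guess_rate = 1/3, lapse = 0)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$input))
    errs <- c(errs, "missing required key: input")
  else if (!dir.exists(config$input))
    errs <- c(errs, paste0("input directory does not exist: ", config$input))
  if (is.null(config$output))
    errs <- c(errs, "missing required key: output")
  if (config$threshold_fraction <= 0 || config$threshold_fraction >= 1)
    errs <- c(errs, "threshold_fraction must be in (0, 1)")
  if (config$min_box_area < 1)
    errs <- c(errs, "min_box_area must be >= 1")
  if (config$fps <= 0) errs <- c(errs, "fps must be > 0")
  if (config$lapse < 0 || config$lapse > 1)
    errs <- c(errs, "lapse must be in [0, 1]")
  if (config$guess_rate < 0 || config$guess_rate > 1)
    errs <- c(errs, "guess_rate must be in [0, 1]")
  if (xor(is.null(config$roi_y_min), is.null(config$roi_y_max)))
    errs <- c(errs, "roi_y_min and roi_y_max must be given together")
  if (!is.null(config$roi_y_min) && !is.null(config$roi_y_max) &&
      config$roi_y_max < config$roi_y_min)
    errs <- c(errs, "roi_y_max must be >= roi_y_min")
  for (k in c("overrides", "true_frames", "ratings"))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      errs <- c(errs, paste0(k, " file does not exist: ", config[[k]]))
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  config$seed <- as.integer(config$seed)
  structure(config, class = "run_config")
}

#' Run the full characterization pipeline
#'
#' Loads every frame-image video directory under `config$input`, detects
#' motion onsets, applies human overrides where given, trims each clip so
#' motion starts at frame 2, optionally runs a simulated recognition
#' staircase per trimmed clip (when `true_frames` supplies each video's true
#' recognition frame), and optionally evaluates a rating table. Writes
#' `onsets.csv`, `trimmed/<video_id>/`, `convergence.csv` and `report.json`
#' under `config$output`; reruns with the same config are byte-identical.
#'
#' @param config a [validate_config()] result, a list, or a YAML path.
#' @return the report list, invisibly.
#' @export
run_characterization <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- config$output
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  video_dirs <- sort(list.dirs(config$input, recursive = FALSE))
  if (length(video_dirs) == 0L)
    stop("stage detect-onset: no video directories under ", config$input,
         call. = FALSE)
  roi <- if (!is.null(config$roi_y_min))
    c(config$roi_y_min, config$roi_y_max) else NULL
  mcfg <- motion_config(threshold_fraction = config$threshold_fraction,
                        min_box_area = config$min_box_area, roi_y = roi)

  videos <- list(); onset_rows <- list()
  for (d in video_dirs) {
    id <- basename(d)
    seq <- tryCatch(load_video(d, fps = config$fps), error = function(e)
      stop("stage load: video ", id, ": ", conditionMessage(e),
           call. = FALSE))
    res <- detect_motion_onset(seq, mcfg, video_id = id)
    videos[[id]] <- seq
    onset_rows[[id]] <- data.frame(video_id = id,
                                   onset_frame = res$onset_frame,
                                   n_frames = n_frames(seq), fps = seq$fps)
  }
  onsets <- do.call(rbind, onset_rows)
  rownames(onsets) <- NULL

  auto <- stats::setNames(as.numeric(onsets$onset_frame), onsets$video_id)
  manual <- if (!is.null(config$overrides))
    read_onset_overrides(config$overrides) else numeric(0)
  resolved <- resolve_onsets(auto, manual)
  onsets$onset_frame <- as.integer(resolved$onsets[onsets$video_id])
  write_onsets(onsets, file.path(out, "onsets.csv"))

  trimmed <- list()
  trim_dir <- file.path(out, "trimmed")
  for (id in names(videos)) {
    onset <- resolved$onsets[[id]]
    if (is.na(onset)) next
    tr <- trim_to_onset(videos[[id]], onset)
    save_video(tr, file.path(trim_dir, id))
    trimmed[[id]] <- tr
  }

  convergence <- NULL
  if (!is.null(config$true_frames)) {
    tf <- utils::read.csv(config$true_frames, stringsAsFactors = FALSE)
    if (!all(c("video_id", "r_frame") %in% names(tf)))
      stop("stage staircase: true_frames needs columns video_id, r_frame",
           call. = FALSE)
    r <- stats::setNames(as.numeric(tf$r_frame), tf$video_id)
    use <- intersect(names(trimmed), names(r))
    Nf <- vapply(trimmed[use], n_frames, integer(1L))
    pool <- make_observer_pool(r[use], guess_rate = config$guess_rate,
                               lapse = config$lapse, seed = config$seed,
                               Nframes = Nf)
    conv_rows <- lapply(use, function(id) {
      res <- run_staircase(Nf[[id]], observer_responder(pool[[id]]),
                           video_id = id)
      data.frame(video_id = id, Nframe = Nf[[id]],
                 convergence_frame = res$convergence_frame,
                 n_iterations = res$n_iterations)
    })
    convergence <- do.call(rbind, conv_rows)
    rownames(convergence) <- NULL
    utils::write.csv(convergence, file.path(out, "convergence.csv"),
                     row.names = FALSE)
  }

  evaluation <- NULL
  if (!is.null(config$ratings))
    evaluation <- evaluate_ratings(read_ratings(config$ratings))

  report <- list(
    seed = config$seed,
    parameters = list(threshold_fraction = config$threshold_fraction,
                      min_box_area = config$min_box_area,
                      roi_y = roi, fps = config$fps,
                      guess_rate = config$guess_rate, lapse = config$lapse),
    n_videos = nrow(onsets),
    n_onsets_detected = sum(!is.na(onsets$onset_frame)),
    n_overridden = nrow(resolved$disagreements),
    onsets = onsets,
    disagreements = resolved$disagreements,
    convergence = convergence,
    evaluation = if (!is.null(evaluation)) list(
      mean_correct = evaluation$summary$mean_correct,
      mean_pct = evaluation$summary$mean_pct,
      kappa = evaluation$kappa$kappa,
      chance = evaluation$chance,
      t = if (!is.null(evaluation$chance_test)) evaluation$chance_test$t,
      d = if (!is.null(evaluation$chance_test)) evaluation$chance_test$d)
    else NULL)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}
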