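# Between-subject up-down staircase for locating the frame of action-category
# recognition. Each iteration is one naive participant's single response to a
# video played up to `played_frame` and then paused: a correct classification
# shortens the played segment by N frames on the next iteration, an error
# lengthens it by N, with
#
#     N = Nframe/2 * 2^(-(n - 2)/2.5)
#
# where Nframe is the clip length and n the (1-based) iteration number. The
# schedule is response-independent and stops once N < 1, when up-down
# reversals can no longer move a whole frame; the frame played at that final
# iteration is taken as the frame of category recognition.

#' Frame played on the first staircase iteration
#'
#' The first participant sees the clip up to the 50th percentile of its
#' frames (rounded half-up, clamped into the valid frame range).
#'
#' @param Nframe number of frames in the video (>= 2).
#' @return 1-based frame index.
#' @export
initial_played_frame <- function(Nframe) {
  check_Nframe(Nframe)
  min(max(round_half_up(0.5 * Nframe), 1), Nframe)
}

#' Staircase step size
#'
#' Evaluates `N = Nframe/2 * 2^(-(n - 2)/2.5)` for the step taken *into*
#' iteration `n`. The first adjustment (into iteration 2) therefore has
#' magnitude Nframe/2; every 2.5 iterations the step halves.
#'
#' @param Nframe number of frames in the video (>= 2).
#' @param n destination iteration (>= 2; no step precedes iteration 2).
#' @return real-valued step size in frames.
#' @export
step_size <- function(Nframe, n) {
  check_Nframe(Nframe)
  if (any(n < 2))
    stop("step_size is defined for n >= 2 (no step precedes iteration 2)",
         call. = FALSE)
  Nframe / 2 * 2^(-(n - 2) / 2.5)
}

check_Nframe <- function(Nframe) {
  if (!is.numeric(Nframe) || length(Nframe) != 1L || Nframe < 2 ||
      Nframe != as.integer(Nframe))
    stop("Nframe must be a single integer >= 2", call. = FALSE)
  invisible(Nframe)
}

#' Iteration at which the staircase converges
#'
#' The smallest iteration `n` whose step size drops below one frame, i.e. the
#' smallest integer `n > 2 + 2.5 * log2(Nframe/2)`. N is compared as a real
#' number; N = 1 exactly has not yet converged.
#'
#' @param Nframe number of frames in the video (>= 2).
#' @return iteration count n*.
#' @export
convergence_iteration <- function(Nframe) {
  check_Nframe(Nframe)
  n <- 2L
  while (step_size(Nframe, n) >= 1) n <- n + 1L
  n
}

#' Initial staircase state for one video
#'
#' @param Nframe number of frames (>= 2).
#' @param video_id identifier carried through the run.
#' @return list of class `staircase_state`: `video_id`, `Nframe`, `n`
#'   (current iteration), `played_frame`, and `history` (one row per
#'   iteration: `iteration`, `played_frame`, `step` — the real-valued step
#'   applied to enter that iteration, `NA` for the first — and `response`,
#'   filled in once the iteration's response is known).
#' @export
staircase_state <- function(Nframe, video_id = NA_character_) {
  played <- initial_played_frame(Nframe)
  structure(
    list(video_id = video_id, Nframe = as.integer(Nframe), n = 1L,
         played_frame = played,
         history = data.frame(iteration = 1L, played_frame = played,
                              step = NA_real_, response = NA)),
    class = "staircase_state")
}

#' Advance the staircase by one response
#'
#' Records the response at the current iteration and computes the frame for
#' the next one: the step `N` for the destination iteration is evaluated from
#' the printed schedule, rounded half-up to whole frames (only whole frames
#' can be played; N stays real-valued in the convergence test), subtracted
#' after a correct response and added after an error, and the result clamped
#' into `[1, Nframe]`.
#'
#' @param state a `staircase_state`.
#' @param correct logical: was the category classified correctly at the
#'   currently played frame?
#' @return updated `staircase_state` at iteration `n + 1`.
#' @export
next_state <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  n2 <- state$n + 1L
  stepN <- step_size(state$Nframe, n2)
  delta <- round_half_up(stepN)
  played2 <- state$played_frame + if (correct) -delta else delta
  played2 <- min(max(played2, 1), state$Nframe)
  hist <- state$history
  hist$response[hist$iteration == state$n] <- correct
  hist <- rbind(hist, data.frame(iteration = n2, played_frame = played2,
                                 step = stepN, response = NA))
  state$n <- n2
  state$played_frame <- played2
  state$history <- hist
  state
}

#' Run a full staircase for one video
#'
#' Starts at [initial_played_frame()] and performs
#' [convergence_iteration()]`(Nframe)` iterations, querying `responder` at
#' each iteration but the last (the final iteration's frame is the outcome;
#' no update follows it). The schedule length is fixed by `Nframe` alone,
#' never by the responses.
#'
#' @param Nframe number of frames in the video (>= 2).
#' @param responder function `played_frame -> logical(1)`, e.g. a human
#'   session bridge or [observer_responder()].
#' @param video_id identifier carried into the result.
#' @param n_iterations override for the stopping rule; default
#'   `convergence_iteration(Nframe)`.
#' @return list of class `convergence_result`: `video_id`,
#'   `convergence_frame`, `n_iterations`, `history`.
#' @export
run_staircase <- function(Nframe, responder, video_id = NA_character_,
                          n_iterations = NULL) {
  check_Nframe(Nframe)
  stopifnot(is.function(responder))
  n_total <- if (is.null(n_iterations)) convergence_iteration(Nframe)
             else as.integer(n_iterations)
  if (n_total < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  state <- staircase_state(Nframe, video_id)
  while (state$n < n_total) {
    correct <- tryCatch(responder(state$played_frame), error = function(e)
      stop(sprintf("responder failed at iteration %d (video %s): %s",
                   state$n, video_id, conditionMessage(e)), call. = FALSE))
    state <- next_state(state, isTRUE(correct))
  }
  structure(
    list(video_id = video_id, convergence_frame = state$played_frame,
         n_iterations = n_total, history = state$history),
    class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("<convergence_result> video %s: frame %d after %d iterations\n",
              x$video_id, x$convergence_frame, x$n_iterations))
  invisible(x)
}

#' Simulated observer with a recognition threshold
#'
#' Stands in for a naive human participant: category recognition switches on
#' at a true frame `r`. Shown at least `r` frames the observer answers
#' correctly with probability `1 - lapse`; shown fewer, they guess and are
#' right with probability `guess_rate` (1/3 for three categories). Responses
#' are drawn from a private seeded stream, so identical seeds give identical
#' response sequences regardless of other RNG use.
#'
#' @param r true recognition frame (1-based).
#' @param guess_rate probability of a correct guess below threshold;
#'   default 1/3.
#' @param lapse lapse rate above threshold; default 0.
#' @param seed integer seed of the observer's private stream.
#' @return object of class `observer_model`.
#' @export
observer_model <- function(r, guess_rate = 1/3, lapse = 0, seed = 1L) {
  stopifnot(is.numeric(r), length(r) == 1L, r >= 1,
            guess_rate >= 0, guess_rate <= 1, lapse >= 0, lapse <= 1)
  env <- new.env(parent = emptyenv())
  env$r <- as.integer(r)
  env$guess_rate <- guess_rate
  env$lapse <- lapse
  env$seed <- as.integer(seed)
  env$count <- 0L
  env$draws <- numeric(0)
  class(env) <- "observer_model"
  env
}

# i-th uniform of the observer's private stream; the cache is extended by
# regenerating from the seed, so the prefix never changes and the global RNG
# state is left untouched.
observer_draw <- function(model, i) {
  if (i > length(model$draws)) {
    need <- max(i, 2L * length(model$draws), 256L)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(model$seed)
    model$draws <- stats::runif(need)
  }
  model$draws[i]
}

#' Draw one response from a simulated observer
#'
#' @param model an [observer_model()].
#' @param played_frame frame up to which the clip was played (1-based).
#' @return logical: was the classification correct?
#' @export
simulate_observer <- function(model, played_frame) {
  stopifnot(inherits(model, "observer_model"))
  p <- if (played_frame >= model$r) 1 - model$lapse else model$guess_rate
  model$count <- model$count + 1L
  observer_draw(model, model$count) < p
}

#' Wrap an observer model as a staircase responder
#'
#' @param model an [observer_model()].
#' @return function `played_frame -> logical(1)` for [run_staircase()].
#' @export
observer_responder <- function(model) {
  force(model)
  function(played_frame) simulate_observer(model, played_frame)
}
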