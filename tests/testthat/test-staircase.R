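test_that("the first iteration plays up to the 50th percentile of frames", {
  expect_equal(initial_played_frame(300), 150)
  expect_equal(initial_played_frame(301), 151)  # 150.5 rounds half-up
  expect_equal(initial_played_frame(2), 1)
  expect_error(initial_played_frame(1), "Nframe")
})

test_that("step sizes follow the printed geometric schedule", {
  expect_equal(step_size(300, 2), 150)    # exponent zero
  expect_equal(step_size(300, 7), 37.5)   # 150 * 2^-2
  expect_equal(step_size(128, 17), 1)     # 64 * 2^-6; N = 1 not yet < 1
  expect_error(step_size(300, 1), "n >= 2")
  # halving property: N(n + 5) = N(n) / 4 exactly
  for (Nf in c(2, 128, 300, 360))
    for (n in 2:12)
      expect_equal(step_size(Nf, n + 5), step_size(Nf, n) / 4)
  # strict monotone decay
  steps <- step_size(300, 2:30)
  expect_true(all(diff(steps) < 0))
})

test_that("the schedule stops when the step drops below one frame", {
  expect_equal(convergence_iteration(2), 3)     # N(2)=1, N(3)=2^-0.4 < 1
  expect_equal(convergence_iteration(128), 18)  # N(17)=1 exactly
  expect_equal(convergence_iteration(360), 21)  # 2 + 2.5*log2(180) = 20.73
  expect_equal(convergence_iteration(300), 21)
  for (Nf in c(2, 50, 128, 300, 360)) {
    nstar <- convergence_iteration(Nf)
    expect_gte(step_size(Nf, nstar - 1), 1)
    expect_lt(step_size(Nf, nstar), 1)
  }
})

test_that("responses move the played frame by the rounded step, clamped", {
  s <- staircase_state(300, "v1")
  expect_equal(s$played_frame, 150)
  up <- next_state(s, FALSE)
  expect_equal(up$played_frame, 300)   # +150 clamped at Nframe
  down <- next_state(s, TRUE)
  expect_equal(down$played_frame, 1)   # -150 clamped at 1 (max(1, 150-150))
  # N(7) = 37.5 rounds half-up to 38
  s6 <- s; s6$n <- 6L; s6$played_frame <- 100L
  s6$history <- data.frame(iteration = 6L, played_frame = 100L,
                           step = NA_real_, response = NA)
  expect_equal(next_state(s6, TRUE)$played_frame, 100 - 38)
  expect_equal(next_state(s6, FALSE)$played_frame, 100 + 38)
  # history bookkeeping: one row per iteration, responses recorded
  expect_equal(up$history$iteration, 1:2)
  expect_false(up$history$response[1])
  expect_equal(nrow(up$history), up$n)
})

test_that("a full run follows a fixed, response-independent schedule", {
  always_yes <- run_staircase(300, function(p) TRUE)
  expect_equal(always_yes$convergence_frame, 1)      # monotone descent
  always_no <- run_staircase(300, function(p) FALSE)
  expect_equal(always_no$convergence_frame, 300)     # monotone ascent
  expect_equal(always_yes$n_iterations, convergence_iteration(300))
  expect_equal(always_no$n_iterations, always_yes$n_iterations)
  # played frame stays within [1, Nframe] along the whole trajectory
  set.seed(9)
  for (i in 1:10) {
    res <- run_staircase(300, function(p) stats::runif(1) < 0.5)
    expect_true(all(res$history$played_frame >= 1 &
                    res$history$played_frame <= 300))
    expect_equal(res$n_iterations, convergence_iteration(300))
  }
  # the stopping rule is overridable
  expect_equal(run_staircase(300, function(p) TRUE,
                             n_iterations = 3)$n_iterations, 3)
  expect_error(run_staircase(300, function(p) stop("boom"), "vX"),
               "iteration 1.*vX")
})

test_that("the engine matches an independent rule-by-rule simulator", {
  for (Nf in c(2, 50, 128, 300)) {
    for (r in unique(pmax(1, round(Nf * c(0.1, 0.4, 0.8))))) {
      respond <- function(p) p >= r
      mine <- run_staircase(Nf, respond)
      ref <- oracle_staircase(Nf, respond)
      expect_equal(mine$convergence_frame, ref$convergence_frame)
      expect_equal(mine$n_iterations, ref$n_iterations)
    }
  }
})

test_that("deterministic threshold observers are recovered within the bound", {
  for (r in seq(10, 290, 10)) {
    res <- run_staircase(300, function(p) p >= r)
    expect_lte(abs(res$convergence_frame - r), STAIRCASE_RECOVERY_BOUND)
  }
})

test_that("simulated observers respect threshold, guess rate and seed", {
  m <- observer_model(r = 50, lapse = 0, seed = 1)
  expect_true(all(vapply(1:50, function(i) simulate_observer(m, 50),
                         logical(1))))   # at/above threshold, no lapses
  expect_true(all(vapply(1:50, function(i) simulate_observer(m, 300),
                         logical(1))))
  # below threshold the long-run correct rate is the guess rate
  g <- observer_model(r = 1000, guess_rate = 1/3, seed = 7)
  hits <- mean(vapply(1:10000, function(i) simulate_observer(g, 10),
                      logical(1)))
  expect_lt(abs(hits - 1/3), 3 * sqrt((1/3) * (2/3) / 10000))
  # identical seeds give identical response streams
  a <- observer_model(r = 50, guess_rate = 1/3, lapse = 0.1, seed = 99)
  b <- observer_model(r = 50, guess_rate = 1/3, lapse = 0.1, seed = 99)
  played <- sample(1:100, 200, replace = TRUE)
  expect_identical(vapply(played, function(p) simulate_observer(a, p), logical(1)),
                   vapply(played, function(p) simulate_observer(b, p), logical(1)))
  # the private stream does not disturb the global RNG
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(simulate_observer(observer_model(5, seed = 3), 10))
  expect_identical(stats::runif(1), before)
})

test_that("observer-driven staircases reproduce exactly under a fixed seed", {
  run_once <- function() {
    pool <- make_observer_pool(c(v1 = 40, v2 = 90), guess_rate = 1/3,
                               lapse = 0.05, seed = 17)
    vapply(names(pool), function(id)
      run_staircase(300, observer_responder(pool[[id]]),
                    video_id = id)$convergence_frame, numeric(1))
  }
  expect_identical(run_once(), run_once())
})
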