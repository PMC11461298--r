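# Independent oracles, deliberately naive, kept apart from the package code
# paths they check.

# Brute-force 8-connected component finder: BFS flood fill with an explicit
# queue; returns one bounding box per component, ordered by (y, x).
oracle_flood_boxes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  boxes <- list()
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- matrix(c(r0, c0), ncol = 2)
    seen[r0, c0] <- TRUE
    y0 <- y1 <- r0; x0 <- x1 <- c0
    while (nrow(queue) > 0) {
      r <- queue[1, 1]; cc <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      y0 <- min(y0, r); y1 <- max(y1, r)
      x0 <- min(x0, cc); x1 <- max(x1, cc)
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W &&
            mask[rr, c2] && !seen[rr, c2]) {
          seen[rr, c2] <- TRUE
          queue <- rbind(queue, c(rr, c2))
        }
      }
    }
    boxes[[length(boxes) + 1]] <-
      data.frame(x = x0, y = y0, w = x1 - x0 + 1, h = y1 - y0 + 1,
                 area = (x1 - x0 + 1) * (y1 - y0 + 1))
  }
  if (length(boxes) == 0)
    return(data.frame(x = integer(0), y = integer(0), w = integer(0),
                      h = integer(0), area = numeric(0)))
  out <- do.call(rbind, boxes)
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Independent staircase simulator written straight from the procedure's
# rules, sharing no code with the package engine.
oracle_staircase <- function(Nframe, respond) {
  rhu <- function(x) floor(x + 0.5)
  stepf <- function(n) Nframe / 2 * 2^(-(n - 2) / 2.5)
  n <- 2
  while (stepf(n) >= 1) n <- n + 1
  nstar <- n
  played <- min(max(rhu(0.5 * Nframe), 1), Nframe)
  for (it in 1:(nstar - 1)) {
    ok <- respond(played)
    delta <- rhu(stepf(it + 1))
    played <- played + if (ok) -delta else delta
    played <- min(max(played, 1), Nframe)
  }
  list(convergence_frame = played, n_iterations = nstar)
}

# Recovery bound for the deterministic threshold responder at Nframe = 300,
# established once by running oracle_staircase exhaustively over all
# r in 1..300 (max |convergence - r| = 1) and frozen as a regression bound.
STAIRCASE_RECOVERY_BOUND <- 1

# small random logical mask
random_mask <- function(h, w, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w)
}

# quick gray test clip: patch of given intensity appearing at onset on a
# flat background, built directly (not via the package generator)
plain_clip <- function(n = 20, h = 100, w = 100, onset = 5, level = 120,
                       px = 10, py = 10, pw = 30, ph = 30, fps = 60) {
  frames <- lapply(seq_len(n), function(t) {
    f <- matrix(0L, h, w)
    if (t >= onset) f[py:(py + ph - 1), px:(px + pw - 1)] <- as.integer(level)
    f
  })
  frame_sequence(frames, fps = fps)
}
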