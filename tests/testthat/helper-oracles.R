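# Independent brute-force re-implementation of the reference-point scan.
# At every step it recomputes the full vector of distances from the current
# reference to all later points from scratch (no incremental state), finds
# the first local maximum under the strict-decrease / tie-extension rule,
# emits it and restarts from there. Used only as an oracle.
brute_segment <- function(trace, epsilon = 0) {
  xy <- cbind(trace$x, trace$y)
  fr <- trace$frame
  n <- nrow(xy)
  out <- list()
  ref <- 1L
  repeat {
    if (ref >= n) break
    idx <- (ref + 1L):n
    d <- sqrt((xy[idx, 1] - xy[ref, 1])^2 + (xy[idx, 2] - xy[ref, 2])^2)
    hit <- NA_integer_
    if (length(d) >= 2) {
      for (j in seq_len(length(d) - 1L)) {
        if (d[j + 1L] < d[j] && d[j] > epsilon) {
          hit <- j
          break
        }
      }
    }
    if (is.na(hit)) {
      dl <- d[length(d)]
      if (dl > epsilon) {
        out[[length(out) + 1L]] <- data.frame(
          ref_frame = fr[ref], max_frame = fr[n],
          max_distance = dl, trailing = TRUE
        )
      }
      break
    }
    i <- idx[hit]
    out[[length(out) + 1L]] <- data.frame(
      ref_frame = fr[ref], max_frame = fr[i],
      max_distance = d[hit], trailing = FALSE
    )
    ref <- i
  }
  do.call(rbind, out)
}

# Random 2D walk trace for property tests.
random_trace <- function(n, step_sd = 2) {
  tibble::tibble(
    frame = seq_len(n) - 1L,
    x = cumsum(rnorm(n, 0, step_sd)),
    y = cumsum(rnorm(n, 0, step_sd))
  )
}

# Sawtooth fixture used across examples: 1D x-motion 0,1,2,3,2,1,2.
sawtooth_trace <- function() {
  tibble::tibble(frame = 0:6, x = c(0, 1, 2, 3, 2, 1, 2), y = 0)
}

# Minimal landmark series holding one arm pose across n frames; the right
# chain is given explicitly, the left chain is laid out straight.
pose_series <- function(throat, r_shoulder, r_elbow, r_hand, n_frames = 1) {
  left <- list(
    throat = throat,
    left_shoulder = throat + c(-1, 0),
    left_elbow = throat + c(-2, 0),
    left_hand = throat + c(-3, 0)
  )
  pts <- c(left, list(
    right_shoulder = r_shoulder, right_elbow = r_elbow, right_hand = r_hand
  ))
  purrr::imap(pts, function(p, nm) {
    tibble::tibble(
      frame = seq_len(n_frames) - 1L, landmark = nm,
      x = p[1], y = p[2]
    )
  }) |> dplyr::bind_rows()
}
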