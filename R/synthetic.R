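#' Configuration for the synthetic motion-trace generator
#'
#' Describes a piecewise-linear 2D movement: a planned number of motion
#' segments, per-segment amplitudes (pixels) and durations (frames), a
#' folded von Mises distribution of heading changes at segment boundaries
#' (mean in degrees, 0 = straight continuation, 180 = reversal;
#' concentration kappa), and optional per-frame Gaussian positional jitter.
#'
#' Defaults emulate the hand-encoded speaker clips the measures were
#' designed for: a few dozen direction changes per clip, excursions of a
#' few tens of pixels lasting a handful of frames, and heading changes
#' biased towards reversals (gesturing is largely pendulum-like).
#'
#' @param n_segments Planned number of direction-change units (>= 1).
#' @param amplitude_mean,amplitude_sd Segment length distribution, pixels.
#' @param duration_mean,duration_sd Segment duration distribution, frames.
#' @param heading_mean Mean absolute heading change, degrees in (0, 180].
#' @param heading_kappa von Mises concentration (larger = tighter around
#'   `heading_mean`; `Inf` makes every change exactly `heading_mean`).
#' @param jitter_sd Per-frame, per-coordinate Gaussian noise, pixels.
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return A validated list of class `motion_config`.
#' @export
motion_config <- function(n_segments = 40, amplitude_mean = 50, amplitude_sd = 15,
                          duration_mean = 6, duration_sd = 2,
                          heading_mean = 120, heading_kappa = 4,
                          jitter_sd = 0, seed = 1L) {
  if (n_segments < 1) abort_parameter("n_segments must be >= 1")
  if (amplitude_mean <= 0) abort_parameter("amplitude_mean must be positive")
  if (duration_mean < 1) abort_parameter("duration_mean must be >= 1")
  if (jitter_sd < 0) abort_parameter("jitter_sd must be non-negative")
  if (heading_mean < 0 || heading_mean > 180) {
    abort_parameter("heading_mean must lie in [0, 180] degrees")
  }
  structure(
    list(
      n_segments = as.integer(n_segments),
      amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
      duration_mean = duration_mean, duration_sd = duration_sd,
      heading_mean = heading_mean, heading_kappa = heading_kappa,
      jitter_sd = jitter_sd, seed = as.integer(seed)
    ),
    class = "motion_config"
  )
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) {
    return((runif(n, -pi, pi) + mu + pi) %% (2 * pi) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

# Folded heading-change draw: absolute von Mises angle, degrees in [0, 180].
# kappa = Inf degenerates to a fixed change of exactly mean_deg.
fold_heading_deg <- function(n, mean_deg, kappa) {
  if (!is.finite(kappa)) {
    return(rep(mean_deg, n))
  }
  abs(rvonmises(n, mean_deg * pi / 180, kappa)) * 180 / pi
}

#' Generate a synthetic motion trace with planted structure
#'
#' Produces a piecewise-linear 2D path: per-segment amplitudes and
#' durations are drawn from the config, the heading rotates at every
#' segment boundary by a folded von Mises draw (random sign), intermediate
#' frames move linearly, and per-frame jitter is added last.
#'
#' Each direction change passes through a one-frame micro-recoil (a step
#' back of 1e-6 times the mean amplitude along the incoming heading),
#' mimicking the deceleration-reversal-acceleration a limb undergoes at a
#' turn. This guarantees the running distance from the current reference
#' point strictly decreases at every planted turn, so the reference-point
#' scan detects all planted boundaries regardless of how shallow the turn
#' is; without it, turns below 90 degrees would be geometrically invisible
#' to any distance-based detector.
#'
#' The planted ground truth is attached as `attr(trace, "planted")`: the
#' segment count, corner frames, per-segment velocities (chord length over
#' elapsed frames, the trailing recoil frame included) and the realized
#' heading-change draws in degrees. It is computed from the laid-down
#' geometry, independent of any downstream analysis.
#'
#' @param config A [motion_config()].
#' @return Tibble `frame, x, y` with attribute `planted`.
#' @export
#' @examples
#' trace <- generate_trace(motion_config(n_segments = 5, seed = 7))
#' attr(trace, "planted")$n_segments
generate_trace <- function(config) {
  stopifnot(inherits(config, "motion_config"))
  withr::with_seed(config$seed, {
    ns <- config$n_segments
    amp <- pmax(rnorm(ns, config$amplitude_mean, config$amplitude_sd),
      config$amplitude_mean * 0.05)
    dur <- pmax(round(rnorm(ns, config$duration_mean, config$duration_sd)), 1)
    theta <- if (ns > 1) {
      pmin(fold_heading_deg(ns - 1, config$heading_mean, config$heading_kappa), 180)
    } else {
      numeric(0)
    }
    sgn <- if (ns > 1) sample(c(-1, 1), ns - 1, replace = TRUE) else integer(0)
    heading <- runif(1, 0, 2 * pi)
    recoil <- 1e-6 * config$amplitude_mean

    pos <- c(0, 0)
    pts <- vector("list", sum(dur) + ns) # upper bound
    m <- 0L
    add <- function(p) {
      m <<- m + 1L
      pts[[m]] <<- p
    }
    add(pos)
    corner_rows <- integer(ns)
    corner_pos <- matrix(0, ns + 1, 2)
    corner_pos[1, ] <- pos
    for (s in seq_len(ns)) {
      u <- c(cos(heading), sin(heading))
      for (j in seq_len(dur[s])) add(pos + u * amp[s] * j / dur[s])
      pos <- pos + u * amp[s]
      corner_rows[s] <- m
      corner_pos[s + 1, ] <- pos
      if (s < ns) {
        add(pos - u * recoil)
        heading <- heading + sgn[s] * theta[s] * pi / 180
      }
    }
    xy <- do.call(rbind, pts[seq_len(m)])
    if (config$jitter_sd > 0) {
      xy <- xy + matrix(rnorm(2 * m, 0, config$jitter_sd), m, 2)
    }
    trace <- tibble::tibble(frame = seq_len(m) - 1L, x = xy[, 1], y = xy[, 2])
    chords <- sqrt(rowSums(diff(corner_pos)^2))
    corner_frames <- corner_rows - 1L # 0-based frames of the planted corners
    elapsed <- diff(c(0L, corner_frames)) # recoil frames included after the first
    attr(trace, "planted") <- list(
      n_segments = ns,
      corner_frames = corner_frames,
      amplitude = amp,
      duration = dur,
      velocity = chords / elapsed,
      heading_changes = theta
    )
    trace
  })
}

#' Generate a full 13-landmark stick-figure series
#'
#' Builds a complete landmark series around a base trajectory: head and
#' torso landmarks ride the base point at fixed offsets, the lectern
#' corners stay put, and the arms articulate. Each arm hangs off a
#' horizontal shoulder segment; its shoulder and elbow joint angles
#' oscillate sinusoidally around configurable means, so static body-part
#' angularity can be planted anywhere in its range.
#'
#' @param config A [motion_config()] driving the base trajectory, or `NULL`
#'   for a static figure.
#' @param n_frames Number of frames when `config` is `NULL`.
#' @param stimulus_id Id stored in the `stimulus_id` column.
#' @param flexion_mean,flexion_amplitude Elbow joint angle, degrees:
#'   oscillation midpoint and half-range (0 = arm fully extended).
#' @param shoulder_mean,shoulder_amplitude Shoulder joint angle, degrees.
#' @param period Oscillation period in frames.
#' @return Landmark tibble `stimulus_id, frame, landmark, x, y` with
#'   attribute `planted_bodypart`, the per-frame planted four-joint angle
#'   sum (mean of which is the ground-truth static angularity).
#' @export
generate_stickfigure_series <- function(config = NULL, n_frames = 50,
                                        stimulus_id = "synthetic",
                                        flexion_mean = 45, flexion_amplitude = 25,
                                        shoulder_mean = 15, shoulder_amplitude = 10,
                                        period = 40) {
  if (!is.null(config)) {
    base <- generate_trace(config)
  } else {
    base <- tibble::tibble(frame = seq_len(n_frames) - 1L, x = 0, y = 0)
  }
  t <- base$frame
  nf <- length(t)
  clamp <- function(a) pmin(pmax(a, 0), 180)
  # planted joint angles per frame (degrees); left arm in antiphase
  fx_r <- clamp(flexion_mean + flexion_amplitude * sin(2 * pi * t / period))
  fx_l <- clamp(flexion_mean + flexion_amplitude * sin(2 * pi * t / period + pi))
  sh_r <- clamp(shoulder_mean + shoulder_amplitude * sin(2 * pi * t / period + pi / 2))
  sh_l <- clamp(shoulder_mean + shoulder_amplitude * sin(2 * pi * t / period - pi / 2))

  rot <- function(ux, uy, deg) {
    a <- deg * pi / 180
    list(x = ux * cos(a) - uy * sin(a), y = ux * sin(a) + uy * cos(a))
  }
  arm <- function(side_sign, sh_deg, fx_deg) {
    # shoulder segment direction: throat -> shoulder, horizontal
    ux <- rep(side_sign, nf)
    uy <- rep(0, nf)
    # joints rotate the chain towards the body's lower half (image y grows
    # downwards); the right side bends clockwise, the left side mirrored
    upper <- rot(ux, uy, side_sign * sh_deg)
    lower <- rot(upper$x, upper$y, side_sign * fx_deg)
    list(upper = upper, lower = lower)
  }
  upper_len <- 30
  lower_len <- 28
  half_shoulder <- 25
  r <- arm(1, sh_r, fx_r)
  l <- arm(-1, sh_l, fx_l)

  bx <- base$x
  by <- base$y
  throat_x <- bx
  throat_y <- by - 40
  rs_x <- throat_x + half_shoulder
  rs_y <- throat_y
  ls_x <- throat_x - half_shoulder
  ls_y <- throat_y
  re_x <- rs_x + upper_len * r$upper$x
  re_y <- rs_y + upper_len * r$upper$y
  rh_x <- re_x + lower_len * r$lower$x
  rh_y <- re_y + lower_len * r$lower$y
  le_x <- ls_x + upper_len * l$upper$x
  le_y <- ls_y + upper_len * l$upper$y
  lh_x <- le_x + lower_len * l$lower$x
  lh_y <- le_y + lower_len * l$lower$y

  coords <- list(
    forehead = list(bx, by - 65),
    throat = list(throat_x, throat_y),
    left_ear = list(bx - 12, by - 60),
    right_ear = list(bx + 12, by - 60),
    left_shoulder = list(ls_x, ls_y),
    right_shoulder = list(rs_x, rs_y),
    left_elbow = list(le_x, le_y),
    right_elbow = list(re_x, re_y),
    left_hand = list(lh_x, lh_y),
    right_hand = list(rh_x, rh_y),
    navel = list(bx, by),
    lectern_left = list(rep(100, nf), rep(300, nf)),
    lectern_right = list(rep(540, nf), rep(300, nf))
  )
  out <- purrr::imap(coords, function(cc, nm) {
    tibble::tibble(
      stimulus_id = stimulus_id, frame = t, landmark = nm,
      x = cc[[1]] + 0 * t, y = cc[[2]] + 0 * t
    )
  }) |>
    dplyr::bind_rows() |>
    as_landmarks()
  attr(out, "planted_bodypart") <- fx_r + fx_l + sh_r + sh_l
  attr(out, "planted") <- attr(base, "planted")
  out
}

#' Configuration for the synthetic rater panel
#'
#' @param n_raters Panel size.
#' @param loading Target correlation (in expectation) between the planted
#'   stimulus feature and the stimulus-mean rating, in `[-1, 1]`.
#' @param noise_sd Per-rater Gaussian noise, rating-scale units.
#' @param rating_sd Spread of the latent stimulus-mean ratings on the
#'   -100..+100 scale.
#' @param scale_label Label stored in the `scale` column.
#' @param seed Integer seed.
#' @return A validated list of class `rater_config`.
#' @export
rater_config <- function(n_raters = 25, loading = 0.5, noise_sd = 30,
                         rating_sd = 30, scale_label = "takete_maluma",
                         seed = 1L) {
  if (abs(loading) > 1) abort_parameter("loading must lie in [-1, 1]")
  if (n_raters < 1) abort_parameter("n_raters must be >= 1")
  if (noise_sd < 0 || rating_sd < 0) abort_parameter("sd parameters must be non-negative")
  structure(
    list(
      n_raters = as.integer(n_raters), loading = loading,
      noise_sd = noise_sd, rating_sd = rating_sd,
      scale_label = scale_label, seed = as.integer(seed)
    ),
    class = "rater_config"
  )
}

#' Generate a rating panel correlated with a planted feature
#'
#' Stimulus-mean ratings are a linear map of the z-scored feature mixed
#' with independent noise so that their correlation with the feature is
#' `loading` in expectation; each rater's score adds Gaussian noise and is
#' clipped to the -100..+100 semantic-differential scale.
#'
#' @param features Tibble `stimulus_id, value` (>= 3 stimuli, nonzero
#'   variance), or a named numeric vector.
#' @param config A [rater_config()].
#' @return Long ratings tibble `rater_id, stimulus_id, scale, value`.
#' @export
generate_ratings <- function(features, config) {
  stopifnot(inherits(config, "rater_config"))
  if (is.numeric(features)) {
    features <- tibble::tibble(
      stimulus_id = names(features) %||% as.character(seq_along(features)),
      value = unname(features)
    )
  }
  features <- tibble::as_tibble(features)
  if (nrow(features) < 3) abort_data("need at least 3 stimuli")
  v <- features$value
  if (!all(is.finite(v)) || sd(v) == 0) {
    abort_data("feature values must be finite with nonzero variance")
  }
  withr::with_seed(config$seed, {
    ns <- nrow(features)
    z <- as.numeric(scale(v))
    latent <- config$loading * z +
      sqrt(1 - config$loading^2) * rnorm(ns)
    mu <- config$rating_sd * latent
    tidyr::expand_grid(
      rater_id = paste0("rater_", sprintf("%02d", seq_len(config$n_raters))),
      stimulus_id = features$stimulus_id
    ) |>
      dplyr::mutate(
        scale = config$scale_label,
        value = pmin(pmax(
          rep(mu, times = config$n_raters) + rnorm(ns * config$n_raters, 0, config$noise_sd),
          -100
        ), 100)
      )
  })
}

#' Configuration for the forced-choice observer simulation
#'
#' @param n_trials Total number of trials.
#' @param sensitivity Slope of the logistic choice rule on the z-scored
#'   feature difference between the two presented stimuli (0 = guessing).
#' @param seed Integer seed.
#' @return A validated list of class `choice_config`.
#' @export
choice_config <- function(n_trials = 460, sensitivity = 1, seed = 1L) {
  if (n_trials < 1) abort_parameter("n_trials must be >= 1")
  if (sensitivity < 0) abort_parameter("sensitivity must be non-negative")
  structure(
    list(
      n_trials = as.integer(n_trials), sensitivity = sensitivity,
      seed = as.integer(seed)
    ),
    class = "choice_config"
  )
}

#' Simulate two-alternative forced-choice trials
#'
#' Each trial presents one stimulus from the low-feature pool and one from
#' the high-feature pool (drawn uniformly, side assignment random) under a
#' word drawn uniformly from takete/maluma. The observer picks the
#' high-feature stimulus with probability `plogis(sensitivity * dz)` when
#' the word is takete and the low-feature stimulus with that probability
#' when the word is maluma, where `dz` is the z-scored feature difference
#' (high minus low, pooled scaling). A choice matching this predicted
#' word-to-motion mapping is recorded as correct.
#'
#' @param low,high Tibbles `stimulus_id, value` for the two pools, e.g. the
#'   two groups from [select_extremes()].
#' @param config A [choice_config()].
#' @return Trial tibble `trial_id, rater_id, word, low_stimulus,
#'   high_stimulus, chosen, correct` (ten trials per simulated rater).
#' @export
simulate_forced_choice <- function(low, high, config) {
  stopifnot(inherits(config, "choice_config"))
  low <- tibble::as_tibble(low)
  high <- tibble::as_tibble(high)
  if (nrow(low) < 1 || nrow(high) < 1) abort_data("both stimulus pools must be non-empty")
  pooled_sd <- sd(c(low$value, high$value))
  if (!is.finite(pooled_sd) || pooled_sd == 0) pooled_sd <- 1
  withr::with_seed(config$seed, {
    nt <- config$n_trials
    i_low <- sample.int(nrow(low), nt, replace = TRUE)
    i_high <- sample.int(nrow(high), nt, replace = TRUE)
    word <- sample(c("takete", "maluma"), nt, replace = TRUE)
    dz <- (high$value[i_high] - low$value[i_low]) / pooled_sd
    p_pred <- stats::plogis(config$sensitivity * dz)
    follows <- runif(nt) < p_pred # choice follows the predicted mapping
    chose_high <- ifelse(word == "takete", follows, !follows)
    tibble::tibble(
      trial_id = seq_len(nt),
      rater_id = paste0("rater_", sprintf("%02d", (seq_len(nt) - 1) %/% 10 + 1)),
      word = word,
      low_stimulus = low$stimulus_id[i_low],
      high_stimulus = high$stimulus_id[i_high],
      chosen = ifelse(chose_high, high$stimulus_id[i_high], low$stimulus_id[i_low]),
      correct = follows
    )
  })
}
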