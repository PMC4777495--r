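#' Segment a motion trace into direction-change units
#'
#' Scans the trace with a moving reference point. Starting from the first
#' frame, the Euclidean distance from the reference point to each successive
#' point is computed; when that running distance drops (strictly) below its
#' value at the previous frame, and the previous value exceeds `epsilon`, a
#' maximum is declared there. The maximum's frame becomes the new reference
#' point and the scan resumes. Ties (equal consecutive distances) extend the
#' scan, so a plateau peaks at its last frame. If the series ends while the
#' running distance still exceeds `epsilon`, the unfinished excursion is
#' emitted as a segment ending at the final frame and flagged `trailing`.
#'
#' Each emitted segment is one motion unit: an excursion away from the
#' current reference up to the frame of peak distance. The number of such
#' units is the quantity-of-motion measure; their distances and durations
#' feed the velocity measure.
#'
#' @param trace Tibble with columns `frame, x, y` (at least 2 rows).
#' @param epsilon Non-negative displacement threshold in pixels; excursions
#'   never exceeding it produce no segment. Default 0.
#' @return A tibble of class `angulate_segments` with one row per motion
#'   unit: `ref_frame`, `max_frame`, `max_distance` (pixels), `elapsed`
#'   (frames), `velocity` (pixels/frame), `trailing`. The threshold is kept
#'   in the `epsilon` attribute. Segments are chained: each `ref_frame`
#'   equals the previous row's `max_frame`.
#' @export
#' @examples
#' trace <- tibble::tibble(frame = 0:6, x = c(0, 1, 2, 3, 2, 1, 2), y = 0)
#' segment_maxima(trace)
segment_maxima <- function(trace, epsilon = 0) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || is.na(epsilon) || epsilon < 0) {
    abort_parameter("epsilon must be a single non-negative number")
  }
  trace <- tibble::as_tibble(trace)
  if (!all(c("frame", "x", "y") %in% names(trace))) {
    abort_format("trace must have columns frame, x, y")
  }
  n <- nrow(trace)
  if (n < 2) abort_data("trace must have at least 2 frames")
  fr <- trace$frame
  px <- trace$x
  py <- trace$y

  ref <- 1L
  refs <- integer(0)
  maxs <- integer(0)
  dist <- numeric(0)
  trail <- logical(0)
  d_to <- function(i, r) sqrt((px[i] - px[r])^2 + (py[i] - py[r])^2)
  i <- ref + 1L
  d_prev <- d_to(i, ref)
  while (i < n) {
    d_next <- d_to(i + 1L, ref)
    if (d_next < d_prev && d_prev > epsilon) {
      refs <- c(refs, ref)
      maxs <- c(maxs, i)
      dist <- c(dist, d_prev)
      trail <- c(trail, FALSE)
      ref <- i
      i <- ref + 1L
      d_prev <- d_to(i, ref)
    } else {
      i <- i + 1L
      d_prev <- d_next
    }
  }
  # i == n: d_prev is the distance from the current reference to the final
  # point; an unfinished excursion above threshold closes at end-of-series.
  if (d_prev > epsilon) {
    refs <- c(refs, ref)
    maxs <- c(maxs, n)
    dist <- c(dist, d_prev)
    trail <- c(trail, TRUE)
  }
  out <- tibble::tibble(
    ref_frame = fr[refs],
    max_frame = fr[maxs],
    max_distance = dist,
    elapsed = fr[maxs] - fr[refs],
    velocity = dist / (fr[maxs] - fr[refs]),
    trailing = trail
  )
  attr(out, "epsilon") <- epsilon
  class(out) <- c("angulate_segments", class(out))
  out
}

#' Number of motion units in a segmentation
#'
#' @param segments Result of [segment_maxima()].
#' @return Integer count of direction-change units (includes a trailing
#'   unfinished unit, if any).
#' @export
count_maxima <- function(segments) nrow(segments)

#' Per-unit velocity
#'
#' Distance covered by each motion unit divided by the frames it took.
#'
#' @param segments Result of [segment_maxima()].
#' @return Numeric vector, pixels per frame.
#' @export
segment_velocity <- function(segments) {
  segments$max_distance / (segments$max_frame - segments$ref_frame)
}

#' Average velocity across motion units
#'
#' @param segments Result of [segment_maxima()].
#' @return Mean of per-unit velocities (pixels/frame); `NA` when the trace
#'   produced no units, so that undefined values can never masquerade as 0.
#' @export
average_velocity <- function(segments) {
  if (nrow(segments) == 0) {
    return(NA_real_)
  }
  mean(segment_velocity(segments))
}

# Unsigned angle in degrees between 2D vectors a and b via the clamped
# normalised dot product. NA for a zero-length operand.
vec_angle_deg <- function(ax, ay, bx, by) {
  na <- sqrt(ax^2 + ay^2)
  nb <- sqrt(bx^2 + by^2)
  out <- rep(NA_real_, length(na))
  ok <- na > 0 & nb > 0
  cosv <- (ax[ok] * bx[ok] + ay[ok] * by[ok]) / (na[ok] * nb[ok])
  out[ok] <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  out
}

#' Turning angles between successive motion vectors
#'
#' The chain of reference points (the initial frame followed by each unit's
#' maximum) defines a sequence of motion vectors; each consecutive pair
#' subtends an unsigned angle: 0 deg means the motion continued straight,
#' 180 deg a full reversal. Pairs involving a zero-length vector are
#' dropped.
#'
#' @param segments Result of [segment_maxima()].
#' @param trace The trace that was segmented.
#' @return Numeric vector of angles in degrees (length at most
#'   `count_maxima(segments) - 1`); empty with fewer than 2 units.
#' @export
turning_angles <- function(segments, trace) {
  if (nrow(segments) < 2) {
    return(numeric(0))
  }
  ref_frames <- c(segments$ref_frame[1], segments$max_frame)
  idx <- match(ref_frames, trace$frame)
  if (anyNA(idx)) abort_data("segment frames not found in trace")
  vx <- diff(trace$x[idx])
  vy <- diff(trace$y[idx])
  m <- length(vx)
  ang <- vec_angle_deg(vx[-m], vy[-m], vx[-1], vy[-1])
  ang[!is.na(ang)]
}

#' Mean turning angle
#'
#' @param angles Numeric vector from [turning_angles()].
#' @return Arithmetic mean in degrees, `NA` on an empty vector.
#' @export
average_turn_angle <- function(angles) {
  if (length(angles) == 0) {
    return(NA_real_)
  }
  mean(angles)
}
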