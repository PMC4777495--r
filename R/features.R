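#' Motion feature vector(s) for one or more landmark series
#'
#' Composes the full measurement pipeline for each stimulus: aggregate the
#' topology's landmark set into a single motion trace, segment it into
#' direction-change units, and compute the four angularity measures:
#'
#' * `n_maxima` - number of motion units (quantity of motion),
#' * `avg_velocity` - mean per-unit velocity in pixels/frame,
#' * `avg_turn_angle` - mean unsigned angle between successive motion
#'   vectors, degrees,
#' * `avg_bodypart_angle` - mean per-frame sum of the four arm-chain joint
#'   angles, degrees.
#'
#' Measures that are undefined for a stimulus (no motion units, fewer than
#' two units, chain landmarks absent) are reported as `NA`, never as 0.
#'
#' @param series Landmark tibble; if a `stimulus_id` column is present each
#'   stimulus is processed separately.
#' @param topology A [skeleton_topology()].
#' @param epsilon Displacement threshold passed to [segment_maxima()].
#' @return Tibble with one row per stimulus:
#'   `stimulus_id, n_maxima, avg_velocity, avg_turn_angle,
#'   avg_bodypart_angle, n_frames, epsilon`.
#' @export
#' @examples
#' s <- generate_stickfigure_series(motion_config(n_segments = 4, seed = 1))
#' extract_features(s)
extract_features <- function(series, topology = skeleton_topology(), epsilon = 0) {
  series <- as_landmarks(series)
  if (!"stimulus_id" %in% names(series)) series$stimulus_id <- "stimulus"
  one <- function(df, id) {
    trace <- aggregate_trace(df, topology)
    n_frames <- nrow(trace)
    if (n_frames >= 2) {
      seg <- segment_maxima(trace, epsilon)
      n_max <- count_maxima(seg)
      vel <- average_velocity(seg)
      turn <- average_turn_angle(turning_angles(seg, trace))
    } else {
      n_max <- 0L
      vel <- NA_real_
      turn <- NA_real_
    }
    chain_ok <- all(unique(unlist(topology$chains)) %in% df$landmark)
    body <- if (chain_ok) average_bodypart_angle(df, topology) else NA_real_
    tibble::tibble(
      stimulus_id = id,
      n_maxima = as.integer(n_max),
      avg_velocity = vel,
      avg_turn_angle = turn,
      avg_bodypart_angle = body,
      n_frames = n_frames,
      epsilon = epsilon
    )
  }
  series |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::group_map(~ one(.x, .y$stimulus_id)) |>
    dplyr::bind_rows()
}

#' Write a feature table to CSV
#'
#' Undefined measures are written as empty fields.
#'
#' @param features Tibble from [extract_features()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, na = "", progress = FALSE)
  invisible(path)
}
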