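#' Static body-part angles per frame
#'
#' For each arm chain (throat -> shoulder -> elbow -> hand) two joint angles
#' are measured as unsigned turning angles between consecutive chain
#' segments: shoulder angle (shoulder segment vs upper arm) and elbow angle
#' (upper arm vs lower arm). 0 deg means the chain continues collinearly
#' (fully extended), 180 deg means it folds back on itself. The four angles
#' (two per side) are summed per frame; a larger sum means a more pointed,
#' angular posture.
#'
#' Chain segments of zero length make their angle undefined; such angles
#' contribute 0 to the sum and the frame is flagged `degenerate`.
#'
#' @param series Landmark tibble containing the chain landmarks.
#' @param topology A [skeleton_topology()].
#' @return Tibble with one row per frame: `frame`, the four joint angles
#'   (`right_shoulder_angle`, `right_elbow_angle`, `left_shoulder_angle`,
#'   `left_elbow_angle`, degrees), their sum `total` (0..720), and
#'   `degenerate`.
#' @export
bodypart_angles <- function(series, topology = skeleton_topology()) {
  series <- as_landmarks(series)
  chain_names <- unique(unlist(topology$chains))
  present <- unique(series$landmark)
  missing <- setdiff(chain_names, present)
  if (length(missing) > 0) {
    abort_data(paste0(
      "chain landmark(s) missing from series: ",
      paste(missing, collapse = ", ")
    ))
  }
  wide <- tidyr::pivot_wider(
    series[, c("frame", "landmark", "x", "y")],
    names_from = "landmark", values_from = c("x", "y")
  )
  chain_pair <- function(chain) {
    # direction vectors along the chain, then turning angles at the two
    # inner joints (shoulder, elbow)
    cx <- lapply(chain, function(l) wide[[paste0("x_", l)]])
    cy <- lapply(chain, function(l) wide[[paste0("y_", l)]])
    sx <- Map(function(a, b) b - a, cx[-4], cx[-1])
    sy <- Map(function(a, b) b - a, cy[-4], cy[-1])
    list(
      shoulder = vec_angle_deg(sx[[1]], sy[[1]], sx[[2]], sy[[2]]),
      elbow = vec_angle_deg(sx[[2]], sy[[2]], sx[[3]], sy[[3]])
    )
  }
  r <- chain_pair(topology$chains$right)
  l <- chain_pair(topology$chains$left)
  angles <- cbind(r$shoulder, r$elbow, l$shoulder, l$elbow)
  degenerate <- apply(is.na(angles), 1, any)
  angles[is.na(angles)] <- 0
  tibble::tibble(
    frame = wide$frame,
    right_shoulder_angle = angles[, 1],
    right_elbow_angle = angles[, 2],
    left_shoulder_angle = angles[, 3],
    left_elbow_angle = angles[, 4],
    total = rowSums(angles),
    degenerate = degenerate
  )
}

#' Average static body-part angle of a series
#'
#' Mean over frames of the per-frame four-joint angle sum, giving one
#' posture-angularity number per stimulus.
#'
#' @inheritParams bodypart_angles
#' @return Degrees (0..720).
#' @export
average_bodypart_angle <- function(series, topology = skeleton_topology()) {
  mean(bodypart_angles(series, topology)$total)
}
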