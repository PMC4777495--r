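#' Body landmark vocabulary
#'
#' The thirteen named landmarks tracked on a speaking figure: head and torso
#' points, both arms, and the two lectern corners that anchor the scene.
#' Coordinates follow the image convention (origin top-left, x to the right,
#' y downwards, units in pixels).
#'
#' @return Character vector of the canonical landmark names.
#' @export
body_landmarks <- function() {
  c(
    "forehead", "throat", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_hand", "right_hand", "navel", "lectern_left", "lectern_right"
  )
}

#' Skeleton topology: limb chains and the trace aggregation set
#'
#' Defines (a) the two arm chains used for the static body-part angle
#' (throat -> shoulder -> elbow -> hand on each side) and (b) the set of
#' landmarks whose coordinates are summed per frame into the single motion
#' trace. The default aggregation set (forehead, left shoulder, both hands)
#' captures head, torso and arm motion with little redundancy.
#'
#' @param aggregation Character vector of landmark names to sum into the
#'   motion trace.
#' @return An object of class `skeleton_topology`: a list with elements
#'   `chains` (named list of landmark chains) and `aggregation`.
#' @export
#' @examples
#' skeleton_topology()
skeleton_topology <- function(aggregation = c("forehead", "left_shoulder", "left_hand", "right_hand")) {
  chains <- list(
    right = c("throat", "right_shoulder", "right_elbow", "right_hand"),
    left = c("throat", "left_shoulder", "left_elbow", "left_hand")
  )
  if (anyDuplicated(aggregation)) {
    abort_parameter("aggregation set must not contain repeated landmarks")
  }
  structure(list(chains = chains, aggregation = aggregation),
    class = "skeleton_topology"
  )
}

#' @export
print.skeleton_topology <- function(x, ...) {
  cat("<skeleton_topology>\n")
  for (nm in names(x$chains)) {
    cat("  chain ", nm, ": ", paste(x$chains[[nm]], collapse = " -> "), "\n", sep = "")
  }
  cat("  aggregation: ", paste(x$aggregation, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a landmark series table
#'
#' Checks the invariants every landmark series must satisfy: columns
#' `frame`, `landmark`, `x`, `y` (an optional `stimulus_id` is kept), integer
#' non-negative frames, finite coordinates, no duplicated (frame, landmark)
#' key, and the same landmark set in every frame. Rows are returned sorted by
#' frame then landmark.
#'
#' @param series A data frame in long layout.
#' @return A validated tibble, sorted by frame.
#' @export
as_landmarks <- function(series) {
  series <- tibble::as_tibble(series)
  needed <- c("frame", "landmark", "x", "y")
  missing_cols <- setdiff(needed, names(series))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "landmark series is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!is.numeric(series$x) || !is.numeric(series$y)) {
    bad <- which(is.na(suppressWarnings(as.numeric(series$x))) |
      is.na(suppressWarnings(as.numeric(series$y))))
    abort_parse(paste0(
      "non-numeric coordinates in landmark series (first offending row: ",
      if (length(bad) > 0) bad[1] else NA, ")"
    ))
  }
  if (anyNA(series$x) || anyNA(series$y) ||
    any(!is.finite(series$x)) || any(!is.finite(series$y))) {
    bad <- which(!is.finite(series$x) | !is.finite(series$y))
    abort_parse(paste0("non-finite coordinates at row(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  if (!is.numeric(series$frame) || any(series$frame < 0) ||
    any(series$frame != floor(series$frame))) {
    abort_format("frame indices must be non-negative integers")
  }
  grouping <- intersect("stimulus_id", names(series))
  dup <- series |>
    dplyr::count(dplyr::across(dplyr::all_of(c(grouping, "frame", "landmark")))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_format(paste0(
      "duplicated (frame, landmark) entry: (",
      dup$frame[1], " ", dup$landmark[1], ")"
    ))
  }
  sets <- series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "frame")))) |>
    dplyr::summarise(
      sig = paste(sort(.data$landmark), collapse = "|"),
      .groups = "drop"
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$sig), .groups = "drop")
  if (any(sets$k > 1)) {
    abort_format("all frames must share the same landmark set")
  }
  dplyr::arrange(series, dplyr::across(dplyr::all_of(c(grouping, "frame", "landmark"))))
}

#' Read a landmark time series from CSV
#'
#' Two dialects are supported. The canonical long layout has columns
#' `frame,landmark,x,y` (one row per landmark per frame). The wide layout has
#' a `frame` column plus a `<landmark>_x`/`<landmark>_y` column pair per
#' landmark; it is converted to long on read.
#'
#' @param path Path to a CSV file.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param stimulus_id Optional id attached as a `stimulus_id` column;
#'   defaults to the file name without extension.
#' @return A validated landmark tibble with columns
#'   `stimulus_id, frame, landmark, x, y`, sorted by frame.
#' @export
read_landmarks <- function(path, dialect = c("long", "wide"), stimulus_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(stimulus_id)) {
    stimulus_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "long") {
    missing_cols <- setdiff(c("frame", "landmark", "x", "y"), names(raw))
    if (length(missing_cols) > 0) {
      abort_format(paste0(
        "landmark series is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ))
    }
  } else {
    if (!"frame" %in% names(raw)) abort_format("wide landmark CSV must have a 'frame' column")
    coord_cols <- setdiff(names(raw), "frame")
    if (!all(grepl("_(x|y)$", coord_cols))) {
      abort_format("wide landmark CSV columns must be named <landmark>_x / <landmark>_y")
    }
    raw <- tidyr::pivot_longer(raw, -"frame",
      names_to = c("landmark", ".value"),
      names_pattern = "^(.*)_([xy])$"
    )
  }
  raw$stimulus_id <- stimulus_id
  as_landmarks(raw[, c("stimulus_id", "frame", "landmark", "x", "y")])
}

#' Write a landmark series to CSV
#'
#' @param series Validated landmark tibble.
#' @param path Output file path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(series, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  series <- as_landmarks(series)
  out <- series[, c("frame", "landmark", "x", "y")]
  if (dialect == "wide") {
    out <- tidyr::pivot_wider(out,
      names_from = "landmark", values_from = c("x", "y"),
      names_glue = "{landmark}_{.value}"
    )
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Fill in skipped frames by linear interpolation
#'
#' Landmark encoding is often done at a reduced stride (every n-th frame);
#' this restores the full frame rate by interpolating each coordinate
#' linearly between consecutive keyframes. Keyframe values are preserved
#' exactly and no frame beyond the last keyframe is extrapolated.
#'
#' @param series Landmark tibble whose frames all lie on the stride grid
#'   (0, stride, 2*stride, ...).
#' @param stride Positive integer encoding step.
#' @return A landmark tibble at frame step 1.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   frame = c(0L, 3L), landmark = "forehead",
#'   x = c(0, 3), y = c(0, 0)
#' )
#' interpolate_stride(s, 3)
interpolate_stride <- function(series, stride) {
  if (!is.numeric(stride) || length(stride) != 1 || stride < 1 || stride != floor(stride)) {
    abort_parameter("stride must be a single integer >= 1")
  }
  series <- as_landmarks(series)
  if (any(series$frame %% stride != 0)) {
    off <- unique(series$frame[series$frame %% stride != 0])
    abort_format(paste0(
      "keyframes are not on the stride grid (stride ", stride, "): frame(s) ",
      paste(head(off, 5), collapse = ", ")
    ))
  }
  if (stride == 1) {
    return(series)
  }
  extra <- intersect("stimulus_id", names(series))
  interp_one <- function(df) {
    frames_out <- seq(min(df$frame), max(df$frame), by = 1L)
    if (nrow(df) == 1) {
      out <- df
    } else {
      out <- tibble::tibble(
        frame = frames_out,
        x = approx(df$frame, df$x, xout = frames_out)$y,
        y = approx(df$frame, df$y, xout = frames_out)$y
      )
      # keyframes bit-exact, untouched by the interpolation arithmetic
      key <- match(df$frame, out$frame)
      out$x[key] <- df$x
      out$y[key] <- df$y
    }
    out
  }
  out <- series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(extra, "landmark")))) |>
    dplyr::group_modify(~ interp_one(.x)) |>
    dplyr::ungroup()
  as_landmarks(out)
}

#' Collapse a landmark series into a single motion trace
#'
#' Sums the coordinates of the topology's aggregation set, per frame, into
#' one 2D time series representing overall body motion.
#'
#' @param series Landmark tibble (single stimulus).
#' @param topology A [skeleton_topology()].
#' @return A tibble with columns `frame, x, y` (one row per frame); the
#'   stimulus id, when present, is kept as an attribute `stimulus_id`.
#' @export
aggregate_trace <- function(series, topology = skeleton_topology()) {
  series <- as_landmarks(series)
  wanted <- topology$aggregation
  sub <- dplyr::filter(series, .data$landmark %in% wanted)
  per_frame <- dplyr::count(sub, .data$frame)
  bad <- per_frame$frame[per_frame$n < length(wanted)]
  all_frames <- unique(series$frame)
  bad <- union(bad, setdiff(all_frames, per_frame$frame))
  if (length(bad) > 0) {
    f <- sort(bad)[1]
    miss <- setdiff(wanted, sub$landmark[sub$frame == f])
    abort_data(paste0(
      "landmark '", miss[1], "' missing at frame ", f,
      " (required by the aggregation set)"
    ))
  }
  trace <- sub |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(x = sum(.data$x), y = sum(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$frame)
  if ("stimulus_id" %in% names(series)) {
    attr(trace, "stimulus_id") <- series$stimulus_id[1]
  }
  trace
}
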