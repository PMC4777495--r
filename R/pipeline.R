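#' Read a long ratings CSV
#'
#' Expected header: `rater_id,stimulus_id,scale,value` with values on the
#' -100..+100 semantic-differential scale.
#'
#' @param path CSV file path.
#' @return Validated ratings tibble.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  r <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("rater_id", "stimulus_id", "scale", "value")
  if (!all(needed %in% names(r))) {
    abort_format(paste0("ratings CSV must have columns ", paste(needed, collapse = ", ")))
  }
  if (!is.numeric(r$value)) abort_parse("ratings values must be numeric")
  if (any(abs(r$value) > 100, na.rm = TRUE)) {
    abort_data("rating values must lie in [-100, 100]")
  }
  tibble::as_tibble(r)
}

#' Read a forced-choice trials CSV
#'
#' Expected header:
#' `trial_id,rater_id,word,low_stimulus,high_stimulus,chosen,correct`.
#'
#' @param path CSV file path.
#' @return Validated trials tibble (`correct` coerced to logical).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  r <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("trial_id", "rater_id", "word", "low_stimulus", "high_stimulus", "chosen", "correct")
  if (!all(needed %in% names(r))) {
    abort_format(paste0("trials CSV must have columns ", paste(needed, collapse = ", ")))
  }
  if (!all(r$word %in% c("takete", "maluma"))) {
    abort_data("trial words must be 'takete' or 'maluma'")
  }
  r$correct <- as.logical(r$correct)
  tibble::as_tibble(r)
}

#' Compute motion features for a directory (or table) of landmark series
#'
#' The landmark stage of the pipeline: read every stimulus, optionally
#' restore skipped frames, aggregate, segment, measure. With a directory
#' input, each `*.csv` file is one stimulus (id = file name).
#'
#' @param landmarks Directory of long-dialect landmark CSVs, a single CSV
#'   path, or a landmark tibble.
#' @param epsilon Displacement threshold for [segment_maxima()].
#' @param stride If given, inputs are keyframes at this stride and are
#'   passed through [interpolate_stride()] first.
#' @param topology A [skeleton_topology()].
#' @param out_dir If given, `features.csv` is written there.
#' @return Feature tibble, one row per stimulus (see [extract_features()]).
#' @export
run_features <- function(landmarks, epsilon = 0, stride = NULL,
                         topology = skeleton_topology(), out_dir = NULL) {
  if (is.character(landmarks) && length(landmarks) == 1 && dir.exists(landmarks)) {
    files <- sort(list.files(landmarks, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0) abort_data(paste0("no stimuli: no CSV files in ", landmarks))
    series <- purrr::map(files, read_landmarks) |> dplyr::bind_rows()
  } else if (is.character(landmarks) && length(landmarks) == 1) {
    series <- read_landmarks(landmarks)
  } else {
    series <- as_landmarks(landmarks)
  }
  if (!is.null(stride)) series <- interpolate_stride(series, stride)
  features <- extract_features(series, topology = topology, epsilon = epsilon)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_features(features, file.path(out_dir, "features.csv"))
  }
  features
}

#' Rating-experiment analysis: reliability and correlation tables
#'
#' Reproduces the first experiment's battery. Per stimulus subset (raters
#' differ between subsets) and rating scale, the average-measure intraclass
#' correlation is computed; mean ratings are then pooled across subsets and
#' correlated - scale against scale, and motion measure against scale -
#' with Fisher-z intervals and two-sided p-values.
#'
#' @param ratings Ratings tibble (or CSV path) with columns
#'   `rater_id, stimulus_id, scale, value` and optionally `subset`.
#' @param features Feature tibble from [run_features()]/[extract_features()]
#'   (or CSV path). May be `NULL` to analyse ratings alone.
#' @param icc_variant `"ICC2k"` or `"ICC3k"`.
#' @param conf Confidence level.
#' @param out_dir If given, `icc_table.csv` and `correlations.csv` are
#'   written there.
#' @return List with tibbles `icc` (scale x subset reliability),
#'   `scale_cor` (scale-vs-scale correlations) and `measure_cor`
#'   (measure-vs-scale correlations, `NULL` without features).
#' @export
run_experiment1 <- function(ratings, features = NULL, icc_variant = c("ICC2k", "ICC3k"),
                            conf = 0.95, out_dir = NULL) {
  icc_variant <- match.arg(icc_variant)
  if (is.character(ratings)) ratings <- read_ratings(ratings)
  ratings <- tibble::as_tibble(ratings)
  if (is.character(features)) {
    features <- readr::read_csv(features, show_col_types = FALSE, progress = FALSE)
  }
  if (!"subset" %in% names(ratings)) ratings$subset <- "all"

  icc_tab <- ratings |>
    dplyr::group_by(.data$scale, .data$subset) |>
    dplyr::group_map(function(df, key) {
      fit <- icc_average(df[, c("rater_id", "stimulus_id", "value")],
        variant = icc_variant, conf = conf
      )
      dplyr::bind_cols(key, tidy(fit))
    }) |>
    dplyr::bind_rows()

  means <- mean_ratings(ratings)
  wide <- tidyr::pivot_wider(means[, c("stimulus_id", "scale", "mean_rating")],
    names_from = "scale", values_from = "mean_rating"
  )
  scales <- setdiff(names(wide), "stimulus_id")
  scale_cor <- if (length(scales) >= 2) {
    correlation_table(wide, scales, conf = conf)
  } else {
    NULL
  }

  measure_cor <- NULL
  if (!is.null(features)) {
    features <- tibble::as_tibble(features)
    only_r <- setdiff(wide$stimulus_id, features$stimulus_id)
    only_f <- setdiff(features$stimulus_id, wide$stimulus_id)
    if (length(only_r) > 0 || length(only_f) > 0) {
      abort_data(paste0(
        "stimulus ids do not match between ratings and features; ",
        "only in ratings: {", paste(head(only_r, 10), collapse = ", "), "}, ",
        "only in features: {", paste(head(only_f, 10), collapse = ", "), "}"
      ))
    }
    measures <- intersect(
      c("n_maxima", "avg_velocity", "avg_turn_angle", "avg_bodypart_angle"),
      names(features)
    )
    joined <- dplyr::inner_join(wide, features, by = "stimulus_id")
    measure_cor <- correlation_table(joined, measures, scales, conf = conf)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(icc_tab, file.path(out_dir, "icc_table.csv"), progress = FALSE)
    readr::write_csv(
      dplyr::bind_rows(
        if (!is.null(scale_cor)) dplyr::mutate(scale_cor, table = "scale_vs_scale"),
        if (!is.null(measure_cor)) dplyr::mutate(measure_cor, table = "measure_vs_scale")
      ),
      file.path(out_dir, "correlations.csv"),
      progress = FALSE
    )
  }
  list(icc = icc_tab, scale_cor = scale_cor, measure_cor = measure_cor)
}

#' Forced-choice experiment: extreme selection and binomial analysis
#'
#' Reproduces the second experiment's flow: rank stimuli on a motion
#' measure, keep the `k` lowest and `k` highest, and test forced-choice
#' accuracy against chance - overall and per word condition. Trials are
#' either supplied (real data) or simulated with [simulate_forced_choice()].
#'
#' @param features Feature tibble (or CSV path).
#' @param trials Trials tibble (or CSV path), or `NULL` to simulate.
#' @param k Stimuli per tail (default 10).
#' @param measure Ranking measure (default `"avg_velocity"`).
#' @param sim A [choice_config()], required when `trials` is `NULL`.
#' @param conf Confidence level.
#' @param out_dir If given, `forced_choice.csv` is written there.
#' @return List with `selection` (from [select_extremes()]), `trials`, and
#'   `choices` (the [analyze_choices()] table).
#' @export
run_experiment2 <- function(features, trials = NULL, k = 10,
                            measure = "avg_velocity", sim = NULL,
                            conf = 0.95, out_dir = NULL) {
  if (is.character(features)) {
    features <- readr::read_csv(features, show_col_types = FALSE, progress = FALSE)
  }
  selection <- select_extremes(features, k = k, measure = measure)
  if (is.null(trials)) {
    if (is.null(sim)) abort_parameter("either trials or a choice_config (sim) must be supplied")
    trials <- simulate_forced_choice(
      low = dplyr::filter(selection, .data$group == "low"),
      high = dplyr::filter(selection, .data$group == "high"),
      config = sim
    )
  } else if (is.character(trials)) {
    trials <- read_trials(trials)
  }
  choices <- analyze_choices(trials, conf = conf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(choices, file.path(out_dir, "forced_choice.csv"), progress = FALSE)
  }
  list(selection = selection, trials = tibble::as_tibble(trials), choices = choices)
}

#' Write a run manifest
#'
#' Records the configuration of a pipeline run (seed, epsilon, package
#' version, input identifiers) as a key-value text file so report files are
#' traceable. Deliberately timestamp-free: identical runs produce identical
#' manifests.
#'
#' @param path Output file path.
#' @param ... Named values to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  vals <- c(
    package = "angulate",
    version = as.character(utils::packageVersion("angulate")),
    list(...)
  )
  writeLines(paste0(names(vals), ": ", unlist(lapply(vals, paste, collapse = ","))), path)
  invisible(path)
}
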