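#' Per-stimulus mean ratings
#'
#' Averages semantic-differential scores across raters, per stimulus (and
#' per scale when a `scale` column is present).
#'
#' @param ratings Long tibble with columns `rater_id, stimulus_id, value`
#'   and optionally `scale`.
#' @return Tibble `stimulus_id[, scale], mean_rating, n_raters`.
#' @export
mean_ratings <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  needed <- c("rater_id", "stimulus_id", "value")
  if (!all(needed %in% names(ratings))) {
    abort_format(paste0(
      "ratings must have columns ",
      paste(needed, collapse = ", ")
    ))
  }
  if (nrow(ratings) == 0) abort_data("ratings table is empty")
  grp <- intersect(c("scale", "stimulus_id"), names(ratings))
  ratings |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean_rating = mean(.data$value),
      n_raters = dplyr::n_distinct(.data$rater_id),
      .groups = "drop"
    )
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation between two numeric vectors with the standard
#' normal-theory inference: two-sided p-value from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and a
#' confidence interval from the Fisher z-transform with standard error
#' `1 / sqrt(n - 3)`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `angulate_cor` with fields `r`, `n`, `df`,
#'   `ci_low`, `ci_high`, `p`, `conf`. Use [tidy()] for a one-row tibble.
#' @export
#' @examples
#' fit <- pearson_ci(c(1, 2, 3, 5), c(2, 4, 5, 9))
#' tidy(fit)
pearson_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) abort_parameter("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort_data("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_data("correlation undefined: an input has zero variance")
  }
  r <- cor(x, y)
  df <- n - 2
  if (abs(r) < 1) {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
  } else {
    p <- 0
  }
  z <- atanh(r)
  zcrit <- qnorm(1 - (1 - conf) / 2)
  ci <- if (n > 3) tanh(z + c(-1, 1) * zcrit / sqrt(n - 3)) else c(-1, 1)
  structure(
    list(
      r = r, n = n, df = df,
      ci_low = ci[1], ci_high = ci[2], p = p, conf = conf
    ),
    class = "angulate_cor"
  )
}

#' @export
print.angulate_cor <- function(x, ...) {
  cat(sprintf(
    "Pearson r(%d) = %.3f, %g%% CI [%.3f, %.3f], p = %.4g\n",
    x$df, x$r, 100 * x$conf, x$ci_low, x$ci_high, x$p
  ))
  invisible(x)
}

#' Pairwise correlation table
#'
#' Correlates every column in `x_vars` with every column in `y_vars` of a
#' wide per-stimulus table, reporting r, the Fisher-z interval and the
#' two-sided p-value per pair. With `y_vars = NULL`, the lower triangle of
#' `x_vars` against itself is reported.
#'
#' @param data Wide data frame, one row per stimulus.
#' @param x_vars,y_vars Character vectors of column names.
#' @param conf Confidence level.
#' @return Tibble `x, y, r, n, df, ci_low, ci_high, p`.
#' @export
correlation_table <- function(data, x_vars, y_vars = NULL, conf = 0.95) {
  data <- tibble::as_tibble(data)
  self <- is.null(y_vars)
  if (self) y_vars <- x_vars
  pairs <- tidyr::expand_grid(x = x_vars, y = y_vars)
  if (self) {
    ord <- match(pairs$x, x_vars) < match(pairs$y, x_vars)
    pairs <- pairs[ord, ]
  }
  purrr::pmap(pairs, function(x, y) {
    fit <- pearson_ci(data[[x]], data[[y]], conf = conf)
    dplyr::bind_cols(tibble::tibble(x = x, y = y), tidy(fit))
  }) |>
    dplyr::bind_rows()
}

# Two-way ANOVA mean squares of a complete targets x raters matrix.
rating_mean_squares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  list(
    n = n, k = k,
    msr = ss_row / (n - 1), # targets
    msc = ss_col / (k - 1), # raters
    mse = ss_err / ((n - 1) * (k - 1))
  )
}

ratings_to_matrix <- function(ratings) {
  if (is.matrix(ratings)) {
    m <- ratings
  } else {
    ratings <- tibble::as_tibble(ratings)
    if (!all(c("rater_id", "stimulus_id", "value") %in% names(ratings))) {
      abort_format("ratings must be a matrix or have columns rater_id, stimulus_id, value")
    }
    wide <- tidyr::pivot_wider(
      ratings[, c("stimulus_id", "rater_id", "value")],
      names_from = "rater_id", values_from = "value"
    )
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$stimulus_id
  }
  if (anyNA(m)) abort_data("rating matrix is incomplete (every rater must rate every stimulus)")
  if (nrow(m) < 2 || ncol(m) < 2) abort_data("need at least 2 stimuli and 2 raters")
  m
}

#' Average-measure intraclass correlation (Shrout-Fleiss)
#'
#' Reliability of the rater-mean rating from a complete two-way
#' (stimulus x rater) design. Two average-measure forms are supported:
#'
#' * `ICC2k` - two-way random effects, absolute agreement: raters are a
#'   random sample, rater mean differences count against reliability.
#' * `ICC3k` - two-way mixed effects, consistency: rater mean offsets are
#'   ignored.
#'
#' Confidence intervals follow the F-distribution constructions of Shrout &
#' Fleiss: the `ICC3k` bounds come directly from the targets-vs-residual F
#' ratio; the `ICC2k` bounds are the Spearman-Brown step-up of the
#' single-rater absolute-agreement bounds, which use a Satterthwaite
#' approximation for the denominator degrees of freedom.
#'
#' @param ratings Complete stimulus-by-rater matrix, or a long tibble with
#'   columns `rater_id, stimulus_id, value`.
#' @param variant `"ICC2k"` (default) or `"ICC3k"`.
#' @param conf Confidence level.
#' @return An object of class `angulate_icc` with the coefficient, interval,
#'   design size and the underlying mean squares. Use [tidy()] for a one-row
#'   tibble.
#' @export
icc_average <- function(ratings, variant = c("ICC2k", "ICC3k"), conf = 0.95) {
  variant <- match.arg(variant)
  m <- ratings_to_matrix(ratings)
  ms <- rating_mean_squares(m)
  n <- ms$n
  k <- ms$k
  alpha <- 1 - conf
  df_err <- (n - 1) * (k - 1)
  sb <- function(icc1) icc1 * k / (1 + icc1 * (k - 1))
  if (variant == "ICC3k") {
    icc <- (ms$msr - ms$mse) / ms$msr
    f <- ms$msr / ms$mse
    fl <- f / qf(1 - alpha / 2, n - 1, df_err)
    fu <- f * qf(1 - alpha / 2, df_err, n - 1)
    ci <- c(1 - 1 / fl, 1 - 1 / fu)
  } else {
    icc1 <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    icc <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
    if (ms$mse == 0) {
      # no residual variance: the rater-ratio F degenerates, and its
      # Satterthwaite df reduce to the k - 1 limit
      v <- k - 1
    } else {
      fj <- ms$msc / ms$mse
      vn <- df_err * (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
      vd <- (n - 1) * k^2 * icc1^2 * fj^2 +
        (n * (1 + (k - 1) * icc1) - k * icc1)^2
      v <- vn / vd
    }
    f_u <- qf(1 - alpha / 2, n - 1, v)
    f_l <- qf(1 - alpha / 2, v, n - 1)
    low1 <- n * (ms$msr - f_u * ms$mse) /
      (f_u * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    up1 <- n * (f_l * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_l * ms$msr)
    ci <- sb(c(low1, up1))
  }
  structure(
    list(
      icc = icc, variant = variant, ci_low = ci[1], ci_high = ci[2],
      n_targets = n, n_raters = k, conf = conf,
      msr = ms$msr, msc = ms$msc, mse = ms$mse
    ),
    class = "angulate_icc"
  )
}

#' @export
print.angulate_icc <- function(x, ...) {
  cat(sprintf(
    "%s = %.3f, %g%% CI [%.3f, %.3f] (%d stimuli, %d raters)\n",
    x$variant, x$icc, 100 * x$conf, x$ci_low, x$ci_high, x$n_targets, x$n_raters
  ))
  invisible(x)
}

#' Exact binomial test with Clopper-Pearson interval
#'
#' One-sided (greater) exact test of `k` successes in `n` trials against a
#' null success probability `p0`: the p-value is the exact upper-tail mass
#' `sum(dbinom(k:n, n, p0))`. The reported interval is the conventional
#' two-sided Clopper-Pearson interval for the observed proportion.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null probability, strictly between 0 and 1. Default 0.5
#'   (chance in a two-alternative forced choice).
#' @param conf Confidence level of the interval.
#' @return An object of class `angulate_binom` with `k, n, p_hat, p0,
#'   p_value, ci_low, ci_high, conf`. Use [tidy()] for a one-row tibble.
#' @export
#' @examples
#' binomial_exact(326, 460)
binomial_exact <- function(k, n, p0 = 0.5, conf = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
    k != floor(k) || n != floor(n) || k < 0 || n < 1 || k > n) {
    abort_parameter("need integers 0 <= k <= n with n >= 1")
  }
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 >= 1) {
    abort_parameter("p0 must lie strictly between 0 and 1")
  }
  p_value <- sum(dbinom(k:n, n, p0))
  alpha <- 1 - conf
  ci_low <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  ci_high <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  structure(
    list(
      k = k, n = n, p_hat = k / n, p0 = p0, p_value = p_value,
      ci_low = ci_low, ci_high = ci_high, conf = conf
    ),
    class = "angulate_binom"
  )
}

#' @export
print.angulate_binom <- function(x, ...) {
  cat(sprintf(
    "exact binomial: %d/%d = %.1f%%, %g%% CI [%.1f%%, %.1f%%], one-sided p = %.3g (p0 = %g)\n",
    x$k, x$n, 100 * x$p_hat, 100 * x$conf,
    100 * x$ci_low, 100 * x$ci_high, x$p_value, x$p0
  ))
  invisible(x)
}

#' Select extreme-group stimuli on a feature
#'
#' Ranks stimuli by a feature value and returns the `k` lowest and `k`
#' highest. Ties are resolved deterministically: the low tail is filled
#' first in ascending (value, stimulus id) order, the high tail from the
#' remaining stimuli in descending value order with ties broken by
#' ascending id, so the lexicographically smallest id wins at a tie cut and
#' `k = n/2` partitions all stimuli.
#'
#' @param features Tibble with a `stimulus_id` column and the feature
#'   column.
#' @param k Stimuli per tail.
#' @param measure Name of the feature column (default `"avg_velocity"`).
#' @return Tibble `stimulus_id, value, group` with `group` in
#'   `c("low", "high")`, low tail first.
#' @export
select_extremes <- function(features, k = 10, measure = "avg_velocity") {
  features <- tibble::as_tibble(features)
  if (!all(c("stimulus_id", measure) %in% names(features))) {
    abort_format(paste0("features must have columns stimulus_id and ", measure))
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k)) {
    abort_parameter("k must be a single integer >= 1")
  }
  defined <- features[is.finite(features[[measure]]), c("stimulus_id", measure)]
  names(defined) <- c("stimulus_id", "value")
  if (2 * k > nrow(defined)) {
    abort_parameter(paste0(
      "k = ", k, " requires ", 2 * k, " stimuli with defined ", measure,
      " but only ", nrow(defined), " are available"
    ))
  }
  asc <- dplyr::arrange(defined, .data$value, .data$stimulus_id)
  low <- asc[seq_len(k), ]
  rest <- asc[-seq_len(k), ]
  high <- rest |>
    dplyr::arrange(dplyr::desc(.data$value), .data$stimulus_id) |>
    head(k)
  dplyr::bind_rows(
    dplyr::mutate(low, group = "low"),
    dplyr::mutate(high, group = "high")
  )
}

#' Forced-choice accuracy analysis
#'
#' Summarises two-alternative forced-choice trials against chance: an exact
#' one-sided binomial test (null p0 = 0.5, alternative "scored higher than
#' chance") with a Clopper-Pearson interval, overall and within each word
#' condition.
#'
#' @param trials Tibble with columns `word` (`"takete"`/`"maluma"`) and
#'   `correct` (logical or 0/1: choice matched the predicted mapping of the
#'   word onto the fast/angular vs slow/round stimulus).
#' @param conf Confidence level.
#' @return A tibble of class `angulate_choices`, one row per condition
#'   (`overall`, then each word): `condition, k, n, p_hat, ci_low, ci_high,
#'   p_value, p0`.
#' @export
#' @examples
#' trials <- tibble::tibble(
#'   word = rep(c("takete", "maluma"), c(6, 4)),
#'   correct = c(1, 1, 1, 1, 0, 1, 1, 0, 1, 1)
#' )
#' analyze_choices(trials)
analyze_choices <- function(trials, conf = 0.95) {
  trials <- tibble::as_tibble(trials)
  if (!all(c("word", "correct") %in% names(trials))) {
    abort_format("trials must have columns word and correct")
  }
  if (nrow(trials) == 0) abort_data("trials table is empty")
  one <- function(cond, correct) {
    fit <- binomial_exact(sum(correct), length(correct), p0 = 0.5, conf = conf)
    dplyr::bind_cols(tibble::tibble(condition = cond), tidy(fit))
  }
  correct <- as.logical(trials$correct)
  out <- dplyr::bind_rows(
    one("overall", correct),
    trials |>
      dplyr::group_by(.data$word) |>
      dplyr::group_map(~ one(.y$word, as.logical(.x$correct))) |>
      dplyr::bind_rows()
  )
  class(out) <- c("angulate_choices", class(out))
  out
}
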