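# broom-style accessors for the fitted result objects

#' @export
tidy.angulate_cor <- function(x, ...) {
  tibble::tibble(
    r = x$r, n = x$n, df = x$df,
    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p
  )
}

#' @export
glance.angulate_cor <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, conf = x$conf)
}

#' @export
tidy.angulate_icc <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, icc = x$icc,
    ci_low = x$ci_low, ci_high = x$ci_high,
    n_targets = x$n_targets, n_raters = x$n_raters
  )
}

#' @export
glance.angulate_icc <- function(x, ...) {
  tibble::tibble(
    n_targets = x$n_targets, n_raters = x$n_raters, conf = x$conf,
    ms_targets = x$msr, ms_raters = x$msc, ms_residual = x$mse
  )
}

#' @export
tidy.angulate_binom <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, p_hat = x$p_hat,
    ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, p0 = x$p0
  )
}

#' @export
glance.angulate_binom <- function(x, ...) {
  tibble::tibble(n = x$n, p0 = x$p0, conf = x$conf)
}
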