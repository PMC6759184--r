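# broom-style accessors for fitted objects.

#' Tidy a harmonic fit
#'
#' @param x A `harmonic_fit` from [fit_harmonic()].
#' @param ... Unused.
#' @return One row per fitted series: `series`, `a`, `b`, `amplitude`,
#'   `phase_rad`, `rss`, plus the shared `tau_h`.
#' @export
tidy.harmonic_fit <- function(x, ...) {
  dplyr::mutate(x$coefficients, tau_h = x$tau_h)
}

#' @rdname tidy.harmonic_fit
#' @return `glance()`: one row with `tau_h`, `rss`, `n`, `n_series`.
#' @export
glance.harmonic_fit <- function(x, ...) {
  tibble(tau_h = x$tau_h, rss = x$rss, n = x$n,
         n_series = nrow(x$coefficients))
}
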