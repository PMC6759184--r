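# Small shared helpers: angle arithmetic, seed derivation, validation.

#' Wrap angles into (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector with each element reduced modulo 2*pi into
#'   `(-pi, pi]`.
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi)
  # %% maps exact multiples of 2*pi to 0; shift those to the upper bound
  y[y == 0] <- 2 * pi
  y - pi
}

#' Unwrap a phase trajectory
#'
#' Removes 2*pi jumps from a sampled angle sequence so that the result is a
#' continuous (cumulative) phase.
#'
#' @param x Numeric vector of angles in radians, sampled densely enough that
#'   successive true increments are below pi in magnitude.
#' @return Numeric vector, same length, unwrapped.
#' @export
unwrap_phase <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  jumps <- -round(d / (2 * pi)) * 2 * pi
  x + c(0, cumsum(jumps))
}

# Deterministic child seed from a master seed and a stream label.
# Keeps results reproducible while giving layers/channels distinct streams.
child_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(master) * 7919 + h * 104729 + 12345) %% .Machine$integer.max)
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

# Check a time vector is uniformly sampled; returns the step.
uniform_step <- function(times, tol = 1e-9) {
  if (length(times) < 2) abort("Need at least two time points.")
  d <- diff(times)
  if (max(d) - min(d) > tol * max(1, abs(mean(d)))) {
    abort("Time axis is not uniformly sampled.")
  }
  mean(d)
}

as_timeseries <- function(data) {
  if (is.data.frame(data)) {
    if (!all(c("time_h", "value") %in% names(data))) {
      abort("Time-series data frames need columns `time_h` and `value`.")
    }
    tibble(time_h = as.numeric(data$time_h), value = as.numeric(data$value))
  } else {
    abort("Expected a data frame with columns `time_h`, `value`.")
  }
}
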