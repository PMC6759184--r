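# Rhythm analysis: Hodrick-Prescott detrending, Lomb-Scargle period
# estimation, free-period harmonic fits, acrophases, pixel-wise period maps,
# bivariate KDE cluster counting and Student's-t period-histogram fits.

#' Analysis configuration for rhythm detection
#'
#' @param hp_lambda_coeff Coefficient of the Hodrick-Prescott smoothing rule
#'   `lambda = coeff * (24 h / dt)^4` (default 0.05).
#' @param period_range Periodogram search range in hours (default `c(4, 48)`).
#' @param n_periods Number of log-spaced periodogram grid points (default
#'   2000; resolves 23 h vs 24 h comfortably on 12-day records).
#' @param kde_n Bivariate KDE grid resolution per axis (default 200).
#' @param kde_bandwidth Kernel std in hours for the bivariate KDE; `NULL`
#'   uses Scott's rule per axis.
#' @param cluster_min_separation Minimum mode separation in hours (default 2).
#' @param cluster_prominence Modes below this fraction of the global KDE
#'   maximum are ignored (default 0.05).
#' @param noise_period_max Dominant periods below this bound (hours) are
#'   labelled non-circadian noise (default 20).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(hp_lambda_coeff = 0.05,
                            period_range = c(4, 48),
                            n_periods = 2000,
                            kde_n = 200,
                            kde_bandwidth = NULL,
                            cluster_min_separation = 2,
                            cluster_prominence = 0.05,
                            noise_period_max = 20) {
  stopifnot(length(period_range) == 2, period_range[1] > 0,
            period_range[1] < period_range[2])
  structure(list(
    hp_lambda_coeff = hp_lambda_coeff, period_range = period_range,
    n_periods = as.integer(n_periods), kde_n = as.integer(kde_n),
    kde_bandwidth = kde_bandwidth,
    cluster_min_separation = cluster_min_separation,
    cluster_prominence = cluster_prominence,
    noise_period_max = noise_period_max
  ), class = "analysis_config")
}

#' Hodrick-Prescott smoothing parameter for a sampling interval
#'
#' `lambda = coeff * (24 / dt)^4`, e.g. 16588.8 at `dt = 1` h.
#'
#' @param dt Sampling interval in hours.
#' @param coeff Rule coefficient (default 0.05).
#' @return Smoothing parameter (dimensionless).
#' @export
hp_lambda <- function(dt, coeff = 0.05) {
  assert_scalar_num(dt, "dt", positive = TRUE)
  coeff * (24 / dt)^4
}

# Solve the HP trend for a matrix of column signals: trend minimises
# ||y - g||^2 + lambda * ||D2 g||^2, i.e. (I + lambda t(D2) D2) g = y.
hp_trend_matrix <- function(Y, lambda) {
  n <- nrow(Y)
  if (n < 5) abort("Hodrick-Prescott filter needs at least 5 samples.")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  as.matrix(Matrix::solve(A, Y))
}

#' Hodrick-Prescott baseline detrending
#'
#' Removes the smooth HP trend computed with `lambda = 0.05 * (24/dt)^4`
#' (the coefficient is configurable) from a uniformly sampled series.
#'
#' @param data Data frame with columns `time_h`, `value`.
#' @param config An [analysis_config()].
#' @param lambda Optional explicit smoothing parameter overriding the rule.
#' @return Tibble `time_h`, `value` (detrended), `trend`.
#' @export
hp_detrend <- function(data, config = analysis_config(), lambda = NULL) {
  ts <- as_timeseries(data)
  dt <- uniform_step(ts$time_h)
  lambda <- lambda %||% hp_lambda(dt, config$hp_lambda_coeff)
  trend <- drop(hp_trend_matrix(matrix(ts$value, ncol = 1), lambda))
  tibble(time_h = ts$time_h, value = ts$value - trend, trend = trend)
}

# Classic tau-corrected Lomb-Scargle periodogram for a matrix of column
# signals sharing one time axis. Returns npix x nperiod power matrix,
# normalised by total variance per signal.
ls_power_matrix <- function(Y, times, periods) {
  Y <- sweep(Y, 2, colMeans(Y))
  omega <- 2 * pi / periods
  n <- length(times)
  Cm <- matrix(0, n, length(omega))
  Sm <- matrix(0, n, length(omega))
  for (j in seq_along(omega)) {
    w <- omega[j]
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    cj <- cos(w * (times - tau))
    sj <- sin(w * (times - tau))
    # pre-scale so the per-frequency normalisation folds into one product
    Cm[, j] <- cj / sqrt(sum(cj^2))
    Sm[, j] <- sj / sqrt(sum(sj^2))
  }
  YC <- crossprod(Y, Cm)   # npix x nperiod
  YS <- crossprod(Y, Sm)
  ss <- colSums(Y^2) / (n - 1)
  ss[ss == 0] <- Inf  # flat signals get zero power, not NaN
  0.5 * (YC * YC + YS * YS) / ss
}

period_grid <- function(config) {
  exp(seq(log(config$period_range[1]), log(config$period_range[2]),
          length.out = config$n_periods))
}

#' Lomb-Scargle periodogram
#'
#' Evaluates the classic tau-corrected, variance-normalised Lomb-Scargle
#' power on a log-spaced period grid.
#'
#' @param data Data frame with columns `time_h`, `value` (detrending
#'   recommended first).
#' @param config An [analysis_config()] (period range and grid size).
#' @return A `periodogram` tibble `period_h`, `power`, with attributes
#'   `dominant_period_h` and `peak_power`.
#' @export
ls_periodogram <- function(data, config = analysis_config()) {
  ts <- as_timeseries(data)
  if (nrow(ts) < 8) abort("Need at least 8 samples for a periodogram.")
  periods <- period_grid(config)
  P <- drop(ls_power_matrix(matrix(ts$value, ncol = 1), ts$time_h, periods))
  out <- tibble(period_h = periods, power = P)
  attr(out, "dominant_period_h") <- periods[which.max(P)]
  attr(out, "peak_power") <- max(P)
  class(out) <- c("periodogram", class(out))
  out
}

#' Dominant oscillation period
#'
#' @inheritParams ls_periodogram
#' @return The period (hours) of maximal Lomb-Scargle power within the
#'   configured range.
#' @export
dominant_period <- function(data, config = analysis_config()) {
  attr(ls_periodogram(data, config), "dominant_period_h")
}

#' Pixel-wise period map of a movie stack
#'
#' HP-detrends every pixel time series, then assigns each pixel the period
#' of maximal Lomb-Scargle power.
#'
#' @param movie A `movie_stack`.
#' @param config An [analysis_config()].
#' @return Tibble `row`, `col`, `period_h` aligned to the movie grid.
#' @export
pixelwise_period_map <- function(movie, config = analysis_config()) {
  Y <- movie_matrix(movie)
  lambda <- hp_lambda(movie$dt, config$hp_lambda_coeff)
  Y <- Y - hp_trend_matrix(Y, lambda)
  periods <- period_grid(config)
  P <- ls_power_matrix(Y, movie$times, periods)
  best <- periods[max.col(P, ties.method = "first")]
  d <- dim(movie$frames)
  tibble(row = rep(seq_len(d[2]), times = d[3]),
         col = rep(seq_len(d[3]), each = d[2]),
         period_h = best)
}

#' Count clusters in the bivariate period graph
#'
#' Forms a 2-D Gaussian kernel density estimate of paired per-pixel periods
#' (e.g. Bmal1 vs Per1) and counts well-separated local maxima: modes must
#' exceed `cluster_prominence` of the global maximum and be at least
#' `cluster_min_separation` hours apart (Chebyshev distance).
#'
#' @param periods_a,periods_b Equal-length period vectors (hours).
#' @param config An [analysis_config()].
#' @return Integer cluster count with attribute `modes`, a tibble of mode
#'   locations and heights.
#' @export
count_bivariate_clusters <- function(periods_a, periods_b,
                                     config = analysis_config()) {
  if (length(periods_a) != length(periods_b)) {
    abort("Paired period vectors must have equal length.")
  }
  if (length(periods_a) < 10) abort("Need at least 10 period pairs.")
  scott <- function(x) max(sd(x), 1e-3) * length(x)^(-1 / 6)
  bw <- config$kde_bandwidth %||% c(scott(periods_a), scott(periods_b))
  if (length(bw) == 1) bw <- rep(bw, 2)
  pad <- 3 * bw
  # MASS::kde2d interprets h/4 as the kernel std
  kd <- MASS::kde2d(periods_a, periods_b, h = 4 * bw, n = config$kde_n,
                    lims = c(min(periods_a) - pad[1], max(periods_a) + pad[1],
                             min(periods_b) - pad[2], max(periods_b) + pad[2]))
  z <- kd$z
  nr <- nrow(z); nc <- ncol(z)
  zp <- matrix(-Inf, nr + 2, nc + 2)
  zp[2:(nr + 1), 2:(nc + 1)] <- z
  is_max <- z >= zp[1:nr, 2:(nc + 1)] & z >= zp[3:(nr + 2), 2:(nc + 1)] &
    z >= zp[2:(nr + 1), 1:nc] & z >= zp[2:(nr + 1), 3:(nc + 2)] &
    z >= zp[1:nr, 1:nc] & z >= zp[1:nr, 3:(nc + 2)] &
    z >= zp[3:(nr + 2), 1:nc] & z >= zp[3:(nr + 2), 3:(nc + 2)]
  idx <- which(is_max & z > config$cluster_prominence * max(z),
               arr.ind = TRUE)
  modes <- tibble(period_a = kd$x[idx[, 1]], period_b = kd$y[idx[, 2]],
                  height = z[idx])
  modes <- dplyr::arrange(modes, dplyr::desc(.data$height))
  # greedy suppression of near-duplicate maxima (plateaus, KDE ripple)
  keep <- integer(0)
  for (i in seq_len(nrow(modes))) {
    if (!length(keep)) { keep <- i; next }
    d <- pmax(abs(modes$period_a[keep] - modes$period_a[i]),
              abs(modes$period_b[keep] - modes$period_b[i]))
    if (all(d >= config$cluster_min_separation)) keep <- c(keep, i)
  }
  out <- length(keep)
  attr(out, "modes") <- modes[keep, ]
  out
}

#' Harmonic (cosinor) fit with free period
#'
#' Least-squares fit of `a*cos(2*pi*t/tau) + b*sin(2*pi*t/tau)` with the
#' period free, by variable projection: for each candidate `tau` the linear
#' coefficients are profiled out with an exact linear solve, and `tau` is
#' optimised on a bracket around `period_init`. Derived amplitude
#' `A = sqrt(a^2 + b^2)` and phase `phi = atan2(b, a)`.
#'
#' @param data Data frame with columns `time_h`, `value` (detrended or
#'   mean-normalised), or a list of such data frames to fit with a shared
#'   period (one `a`, `b` pair per series).
#' @param period_init Initial period guess in hours.
#' @param period_bracket Relative search bracket around `period_init`
#'   (default `c(0.5, 1.5)`).
#' @param intercept Include a per-series intercept (default TRUE).
#' @return A `harmonic_fit` object; use [tidy()] / [glance()] to extract
#'   coefficients.
#' @export
fit_harmonic <- function(data, period_init = 24,
                         period_bracket = c(0.5, 1.5), intercept = TRUE) {
  series <- if (is.data.frame(data)) list(data) else data
  series <- purrr::map(series, as_timeseries)
  rss_at <- function(tau) {
    sum(purrr::map_dbl(series, function(s) {
      X <- cbind(cos(2 * pi * s$time_h / tau), sin(2 * pi * s$time_h / tau))
      if (intercept) X <- cbind(1, X)
      fit <- lm.fit(X, s$value)
      sum(fit$residuals^2)
    }))
  }
  lo <- period_init * period_bracket[1]
  hi <- period_init * period_bracket[2]
  # the RSS profile in tau is multimodal (aliases, harmonics): locate the
  # global basin on a coarse grid, then polish by golden section
  grid <- seq(lo, hi, length.out = 200)
  rss_grid <- vapply(grid, rss_at, numeric(1))
  i <- which.min(rss_grid)
  opt <- optimize(rss_at, grid[c(max(1, i - 1), min(length(grid), i + 1))],
                  tol = 1e-8)
  tau <- opt$minimum
  coefs <- purrr::imap_dfr(series, function(s, i) {
    X <- cbind(cos(2 * pi * s$time_h / tau), sin(2 * pi * s$time_h / tau))
    if (intercept) X <- cbind(1, X)
    fit <- lm.fit(X, s$value)
    cf <- fit$coefficients
    a <- cf[length(cf) - 1]; b <- cf[length(cf)]
    tibble(series = i, a = unname(a), b = unname(b),
           amplitude = sqrt(a^2 + b^2), phase_rad = atan2(b, a),
           rss = sum(fit$residuals^2))
  })
  structure(list(tau_h = tau, coefficients = coefs, rss = opt$objective,
                 n = sum(purrr::map_int(series, nrow))),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("<harmonic_fit> tau = %.4f h, %d series, RSS = %.4g\n",
              x$tau_h, nrow(x$coefficients), x$rss))
  invisible(x)
}

#' Acrophases (oscillation peak times)
#'
#' Finds local maxima, refines each by quadratic interpolation through the
#' three samples around it, enforces a minimum peak distance of half the
#' dominant period, and discards peaks within half a period of either record
#' boundary.
#'
#' @param data Data frame with columns `time_h`, `value` (detrended
#'   oscillatory input).
#' @param min_period Minimum peak spacing basis in hours; `NULL` uses the
#'   Lomb-Scargle dominant period.
#' @param edge_rule Drop peaks within half a period of the record boundary
#'   (default TRUE).
#' @param config An [analysis_config()] for the dominant-period fallback.
#' @return An `acrophase_series` tibble with column `peak_time_h`.
#' @export
find_acrophases <- function(data, min_period = NULL, edge_rule = TRUE,
                            config = analysis_config()) {
  ts <- as_timeseries(data)
  y <- ts$value; t <- ts$time_h
  n <- length(y)
  per <- min_period %||% dominant_period(ts, config)
  cand <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  # trough-level local maxima (noise ripple) are not acrophases
  cand <- cand[y[cand] > median(y)]
  if (!length(cand)) {
    out <- tibble(peak_time_h = numeric(0))
    class(out) <- c("acrophase_series", class(out))
    attr(out, "empty") <- TRUE
    return(out)
  }
  # enforce minimum distance, keeping taller peaks first
  cand <- cand[order(-y[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(t[kept] - t[i]) >= 0.5 * per)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  peaks <- vapply(kept, function(i) {
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom >= 0) return(t[i])  # flat/degenerate: keep the sample time
    delta <- 0.5 * (y0 - y2) / denom
    t[i] + delta * (t[i + 1] - t[i])
  }, numeric(1))
  if (edge_rule) {
    peaks <- peaks[peaks >= t[1] + per / 2 & peaks <= t[n] - per / 2]
  }
  out <- tibble(peak_time_h = sort(peaks))
  class(out) <- c("acrophase_series", class(out))
  out
}

#' Instantaneous periods from consecutive acrophases
#'
#' @param acros An `acrophase_series` (or data frame with `peak_time_h`).
#' @return Tibble `cycle`, `period_h` of first differences of peak times.
#' @export
instantaneous_periods <- function(acros) {
  pk <- acros$peak_time_h
  if (length(pk) < 2) abort("Need at least two acrophases.")
  tibble(cycle = seq_len(length(pk) - 1), period_h = diff(pk))
}

#' Student's-t fit to a period histogram
#'
#' Maximum-likelihood location/scale/df fit of a non-central Student's
#' t-distribution, preferred over a normal for its robustness to the heavy
#' tails that noise pixels contribute.
#'
#' @param periods Numeric vector of periods in hours (>= 30 values).
#' @return One-row tibble `location_h`, `scale_h`, `df`.
#' @export
fit_period_histogram <- function(periods) {
  periods <- periods[is.finite(periods)]
  if (length(periods) < 30) abort("Need at least 30 periods.")
  if (sd(periods) < 1e-12) abort("Degenerate (zero-variance) period sample.")
  fit <- suppressWarnings(
    MASS::fitdistr(periods, "t",
                   start = list(m = median(periods),
                                s = max(mad_scale(periods), 1e-3), df = 5),
                   lower = c(-Inf, 1e-6, 0.5))
  )
  est <- fit$estimate
  tibble(location_h = unname(est["m"]), scale_h = unname(est["s"]),
         df = unname(est["df"]))
}

mad_scale <- function(x) stats::mad(x)
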