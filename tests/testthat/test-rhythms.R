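test_that("Hodrick-Prescott rule, trends and linearity behave as specified", {
  expect_equal(hp_lambda(1), 16588.8)
  expect_equal(hp_lambda(2), 0.05 * 12^4)

  const <- tibble::tibble(time_h = 0:50, value = 3.7)
  expect_lt(max(abs(hp_detrend(const)$value)), 1e-9)

  ramp <- tibble::tibble(time_h = 0:200, value = 0.05 * (0:200))
  res <- hp_detrend(ramp)$value
  interior <- res[20:180]
  expect_lt(max(abs(interior)), 0.01 * diff(range(ramp$value)))

  # dense-matrix oracle for the HP normal equations
  y <- cumsum(rnorm(60))
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  lam <- 100
  trend_dense <- solve(diag(n) + lam * crossprod(D), y)
  got <- hp_detrend(tibble::tibble(time_h = seq_len(n), value = y),
                    lambda = lam)$trend
  expect_equal(got, as.numeric(trend_dense), tolerance = 1e-9)

  # linearity of the detrending operator
  x1 <- cosine_series(23, 240, 1, noise_sd = 0.2, seed = 1)
  x2 <- cosine_series(26, 240, 1, noise_sd = 0.2, seed = 2)
  both <- tibble::tibble(time_h = x1$time_h, value = x1$value + x2$value)
  expect_equal(hp_detrend(both)$value,
               hp_detrend(x1)$value + hp_detrend(x2)$value,
               tolerance = 1e-9)

  expect_error(hp_detrend(tibble::tibble(time_h = 1:3, value = 1:3)),
               "at least")
})

test_that("Lomb-Scargle dominant period finds tones and degrades gracefully", {
  grid_step <- 24 * (exp(log(48 / 4) / 1999) - 1)
  pure <- cosine_series(24, 288, 1)
  expect_lt(abs(dominant_period(pure) - 24), grid_step + 1e-9)

  pg <- ls_periodogram(pure)
  expect_true(all(pg$power >= 0))
  expect_equal(attr(pg, "dominant_period_h"), dominant_period(pure))

  # amplitude scaling and additive constants leave the dominant period alone
  scaled <- dplyr::mutate(pure, value = 5 * value + 11)
  expect_equal(dominant_period(hp_detrend(scaled)),
               dominant_period(hp_detrend(pure)))

  # all-zero input: flat (near-zero) power, no error
  flat <- tibble::tibble(time_h = 0:100, value = 0)
  expect_lt(max(ls_periodogram(flat)$power), 1e-10)

  # noisy 23 h tone at unit SNR: recovered within 0.5 h in >= 95% of seeds
  hits <- vapply(1:40, function(s) {
    noisy <- cosine_series(23, 288, 1, noise_sd = 1, seed = s)
    abs(dominant_period(hp_detrend(noisy)) - 23) < 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # pure noise: dominant periods pile up near the short-period edge
  short <- vapply(1:40, function(s) {
    set.seed(s + 500)
    noise <- tibble::tibble(time_h = 0:288, value = rnorm(289))
    dominant_period(hp_detrend(noise)) < 20
  }, logical(1))
  expect_gt(mean(short), 0.5)
})

test_that("free-period harmonic fit recovers coefficients, amplitude and phase", {
  y1 <- cosine_series(24, 240, 2)
  f1 <- fit_harmonic(y1, period_init = 24)
  td <- tidy(f1)
  expect_equal(f1$tau_h, 24, tolerance = 1e-4)
  expect_equal(td$a, 1, tolerance = 1e-4)
  expect_equal(td$b, 0, tolerance = 1e-4)
  expect_equal(td$amplitude, 1, tolerance = 1e-4)
  expect_equal(td$phase_rad, 0, tolerance = 1e-4)
  expect_equal(glance(f1)$n, nrow(y1))

  y2 <- tibble::tibble(time_h = y1$time_h,
                       value = sin(2 * pi * y1$time_h / 24))
  f2 <- fit_harmonic(y2, period_init = 24)
  expect_equal(tidy(f2)$phase_rad, pi / 2, tolerance = 1e-4)
  expect_equal(tidy(f2)$amplitude, 1, tolerance = 1e-4)

  # shared-period fit across phase-shifted copies equals the single fit
  base <- cosine_series(23.7, 240, 2)
  copies <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(ph) {
    tibble::tibble(time_h = base$time_h,
                   value = cos(2 * pi * base$time_h / 23.7 + ph))
  })
  shared <- fit_harmonic(copies, period_init = 24)
  expect_equal(shared$tau_h, fit_harmonic(copies[[1]], 24)$tau_h,
               tolerance = 1e-6)
  expect_equal(nrow(tidy(shared)), 3)
})

test_that("acrophases are located, spaced, edge-trimmed and differenced", {
  y <- cosine_series(24, 72, 0.5)
  pk <- find_acrophases(y)
  expect_equal(pk$peak_time_h, c(24, 48), tolerance = 1e-6)

  # 0.1 h sampling-time jitter: peaks still within 0.5 h of truth
  set.seed(4)
  tj <- seq(0, 240, by = 1)
  yj <- tibble::tibble(
    time_h = tj,
    value = cos(2 * pi * (tj + rnorm(length(tj), 0, 0.1)) / 24))
  pkj <- find_acrophases(yj, min_period = 24)
  truth <- seq(24, 24 * 9, by = 24)
  nearest <- vapply(pkj$peak_time_h,
                    function(p) min(abs(p - truth)), numeric(1))
  expect_lt(max(nearest), 0.5)

  # translation equivariance under a phase shift
  phi0 <- 0.8
  ys <- tibble::tibble(time_h = y$time_h,
                       value = cos(2 * pi * y$time_h / 24 - phi0))
  pks <- find_acrophases(ys)
  expect_equal(pks$peak_time_h, pk$peak_time_h + phi0 * 24 / (2 * pi),
               tolerance = 1e-3)

  expect_equal(instantaneous_periods(
    tibble::tibble(peak_time_h = c(0, 24, 48)))$period_h, c(24, 24))
  expect_error(instantaneous_periods(tibble::tibble(peak_time_h = 3)),
               "two")

  flatline <- tibble::tibble(time_h = 0:100, value = 0:100)
  expect_equal(nrow(suppressWarnings(find_acrophases(flatline,
                                                     min_period = 24))), 0)
})

test_that("Student's-t histogram fit recovers parameters robustly", {
  set.seed(77)
  x <- 24 + 0.3 * rt(2000, df = 5)
  fit <- fit_period_histogram(x)
  expect_lt(abs(fit$location_h - 24), 0.05)
  expect_lt(abs(fit$scale_h - 0.3), 0.05)

  expect_lt(abs(fit$location_h - median(x)), 0.05)

  # outliers move the t location less than the Gaussian mean
  xo <- c(x, rep(40, 60))
  fo <- fit_period_histogram(xo)
  expect_lt(abs(fo$location_h - 24), abs(mean(xo) - 24))

  expect_error(fit_period_histogram(rep(24, 100)), "Degenerate")
  expect_error(fit_period_histogram(rnorm(10)), "30")
})

test_that("bivariate KDE mode counting finds separated clusters symmetrically", {
  set.seed(10)
  # four well-separated synthetic clusters (the two-population pattern)
  a <- c(rnorm(300, 5, 1), rnorm(150, 23, 0.3), rnorm(150, 5, 1),
         rnorm(80, 23, 0.3))
  b <- c(rnorm(300, 5, 1), rnorm(150, 5, 1), rnorm(150, 24, 0.3),
         rnorm(80, 24, 0.3))
  n4 <- count_bivariate_clusters(a, b)
  expect_equal(as.integer(n4), 4)
  # symmetric under swapping the channels
  expect_equal(as.integer(count_bivariate_clusters(b, a)), 4)

  # two-cluster pattern (single-cell dissociation)
  a2 <- c(rnorm(400, 5, 1), rnorm(250, 23, 0.3))
  b2 <- c(rnorm(400, 5, 1), rnorm(250, 24, 0.3))
  expect_equal(as.integer(count_bivariate_clusters(a2, b2)), 2)

  # a degenerate point cloud is one cluster
  expect_equal(as.integer(count_bivariate_clusters(rep(24, 50),
                                                   rep(24, 50))), 1)
  expect_error(count_bivariate_clusters(1:5, 1:5), "10")
  expect_error(count_bivariate_clusters(1:20, 1:10), "equal length")
})
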