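# Shared fixture builders (all in code; no stored data).

cosine_series <- function(period = 24, duration_h = 288, dt = 1,
                          amplitude = 1, phase = 0, noise_sd = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_h, by = dt)
  y <- amplitude * cos(2 * pi * t / period + phase)
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  tibble::tibble(time_h = t, value = y)
}

# One-cell field for direct rendering tests.
single_cell_field <- function(x = 0.5, y = 0.5, channel = "bmal",
                              period = 24, phase = 0, intensity = 1,
                              layers = 1L) {
  out <- tibble::tibble(layer = as.integer(layers), cell = 1L, x = x, y = y,
                        channel = channel, period_h = period,
                        phase_rad = phase, intensity = intensity)
  class(out) <- c("cell_field", class(out))
  out
}

# Brute-force per-cell rasterisation oracle: independent of render_movie
# internals (no truncation; direct double loop over pixels).
brute_force_frame <- function(field, config, t) {
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  px <- (seq_len(nc) - 0.5) / nc
  py <- (seq_len(nr) - 0.5) / nr
  acc <- matrix(0, nr, nc)
  for (i in seq_len(nrow(field))) {
    w <- config$layer_attenuation^(field$layer[i] - 1)
    s <- cell_signal(field$intensity[i], field$period_h[i],
                     field$phase_rad[i], t)
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      d2 <- (px[cc] - field$x[i])^2 + (py[r] - field$y[i])^2
      acc[r, cc] <- acc[r, cc] + w * s * exp(-d2 / (2 * config$sigma_g^2))
    }
  }
  acc
}
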