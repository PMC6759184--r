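# Surrogate dual-reporter movie generation.
#
# In-silico time-lapse movies of a neuronal field expressing two
# bioluminescence reporters (Bmal1, Per1) are built under two null
# hypotheses: H0(1), every cell carries both reporters with different
# periods (dissociation within single cells), and H0(2), two disjoint
# half-populations each carry one reporter. Cells are uniform on the unit
# square, each emits a raised cosine, blobs are Gaussian with std sigma_g
# (fraction of the field width), M depth layers are superimposed with
# geometric attenuation, and white Gaussian observation noise is added per
# pixel, per frame, per channel.

#' Configuration for surrogate dual-reporter movies
#'
#' @param n_cells Cells per layer (see `n_is_per_layer`).
#' @param hypothesis `"H0_1"` (every cell carries both reporter signals) or
#'   `"H0_2"` (half the cells carry only the Bmal1 signal, half only Per1;
#'   odd counts split floor/ceiling).
#' @param period_bmal,period_per Reporter oscillation periods in hours
#'   (defaults 23 h and 24 h).
#' @param intensity Maximal single-cell intensity `I` (arbitrary units).
#' @param sigma_g Gaussian blob standard deviation as a fraction of the unit
#'   field width (default 0.0132, roughly one neuron diameter at the default
#'   grid).
#' @param sigma_n Observation noise standard deviation (a.u.).
#' @param dt Frame sampling interval in hours.
#' @param duration Recording length in days.
#' @param n_layers Number of superimposed depth layers `M` (default 3).
#' @param layer_attenuation Intensity retained per extra layer (default 0.5,
#'   i.e. weights 1, 0.5, 0.25).
#' @param grid_shape Integer `c(rows, cols)` of the pixel grid over the unit
#'   field.
#' @param phase_mode `"uniform"` draws each cell/channel initial phase
#'   i.i.d. uniform on `[0, 2*pi)`; `"common"` gives all cells phase 0.
#' @param n_is_per_layer If `TRUE` (default) each layer receives `n_cells`
#'   freshly drawn cells; if `FALSE`, `n_cells` total are split across layers.
#' @param seed Master RNG seed recorded in the config.
#' @return A validated `surrogate_config` list.
#' @export
surrogate_config <- function(n_cells = 150,
                             hypothesis = c("H0_1", "H0_2"),
                             period_bmal = 23,
                             period_per = 24,
                             intensity = 1,
                             sigma_g = 0.0132,
                             sigma_n = 1,
                             dt = 1,
                             duration = 12,
                             n_layers = 3,
                             layer_attenuation = 0.5,
                             grid_shape = c(128L, 128L),
                             phase_mode = c("uniform", "common"),
                             n_is_per_layer = TRUE,
                             seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  phase_mode <- match.arg(phase_mode)
  assert_scalar_num(n_cells, "n_cells", positive = TRUE)
  assert_scalar_num(period_bmal, "period_bmal", positive = TRUE)
  assert_scalar_num(period_per, "period_per", positive = TRUE)
  assert_scalar_num(sigma_g, "sigma_g", positive = TRUE)
  assert_scalar_num(sigma_n, "sigma_n", nonneg = TRUE)
  assert_scalar_num(dt, "dt", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(n_layers, "n_layers", positive = TRUE)
  if (layer_attenuation <= 0 || layer_attenuation > 1) {
    abort("`layer_attenuation` must lie in (0, 1].")
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape < 2)) {
    abort("`grid_shape` must be two integers >= 2.")
  }
  structure(
    list(
      n_cells = as.integer(n_cells), hypothesis = hypothesis,
      period_bmal = period_bmal, period_per = period_per,
      intensity = intensity, sigma_g = sigma_g, sigma_n = sigma_n,
      dt = dt, duration = duration, n_layers = as.integer(n_layers),
      layer_attenuation = layer_attenuation, grid_shape = grid_shape,
      phase_mode = phase_mode, n_is_per_layer = isTRUE(n_is_per_layer),
      seed = as.integer(seed)
    ),
    class = "surrogate_config"
  )
}

#' Raised-cosine single-cell reporter signal
#'
#' `s(t) = I/2 * (1 + cos(2*pi*t/tau + phi))`, bounded in `[0, I]`.
#'
#' @param intensity Maximal intensity `I`.
#' @param period Oscillation period `tau` in hours (> 0).
#' @param phase Initial phase `phi` in radians.
#' @param t Time(s) in hours.
#' @return Signal value(s), same length as `t`.
#' @export
cell_signal <- function(intensity, period, phase, t) {
  if (any(period <= 0)) abort("`period` must be > 0.")
  intensity / 2 * (1 + cos(2 * pi * t / period + phase))
}

#' Draw the cell field for a surrogate movie
#'
#' Places cells uniformly on the unit square, one independent draw per layer,
#' and assigns channels, periods and initial phases according to the
#' hypothesis. Under `H0_1` every cell gets one record per channel (same
#' position); under `H0_2` each cell carries exactly one channel.
#'
#' @param config A [surrogate_config()].
#' @param seed Optional override of `config$seed`.
#' @return A `cell_field` tibble with columns `layer`, `cell`, `x`, `y`,
#'   `channel` ("bmal"/"per"), `period_h`, `phase_rad`, `intensity`.
#' @export
place_cells <- function(config, seed = NULL) {
  stopifnot(inherits(config, "surrogate_config"))
  seed <- seed %||% config$seed
  n_layers <- config$n_layers
  if (config$n_is_per_layer) {
    n_per_layer <- rep(config$n_cells, n_layers)
  } else {
    base <- config$n_cells %/% n_layers
    extra <- config$n_cells %% n_layers
    n_per_layer <- base + (seq_len(n_layers) <= extra)
  }
  layers <- purrr::map(seq_len(n_layers), function(l) {
    n <- n_per_layer[l]
    if (n == 0) return(NULL)
    set.seed(child_seed(seed, paste0("layer", l)))
    x <- runif(n)
    y <- runif(n)
    if (config$hypothesis == "H0_1") {
      df <- tibble(
        layer = l, cell = rep(seq_len(n), each = 2), x = rep(x, each = 2),
        y = rep(y, each = 2),
        channel = rep(c("bmal", "per"), n),
        period_h = rep(c(config$period_bmal, config$period_per), n)
      )
    } else {
      n_bmal <- n %/% 2 + (n %% 2) * (l %% 2)  # floor/ceil alternating for odd n
      channel <- c(rep("bmal", n_bmal), rep("per", n - n_bmal))
      df <- tibble(
        layer = l, cell = seq_len(n), x = x, y = y, channel = channel,
        period_h = ifelse(channel == "bmal", config$period_bmal,
                          config$period_per)
      )
    }
    if (config$phase_mode == "uniform") {
      set.seed(child_seed(seed, paste0("phase", l)))
      df$phase_rad <- runif(nrow(df), 0, 2 * pi)
    } else {
      df$phase_rad <- 0
    }
    df$intensity <- config$intensity
    df
  })
  out <- dplyr::bind_rows(layers)
  class(out) <- c("cell_field", class(out))
  out
}

# Rasterise one layer/channel: returns npix x ntime matrix of pre-noise
# intensities. Blobs use a peak-preserving Gaussian (peak = instantaneous
# cell signal) truncated at 4 sigma.
rasterize_layer <- function(cells, times, grid_shape, sigma_g) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  npix <- nr * nc
  if (nrow(cells) == 0) {
    return(matrix(0, npix, length(times)))
  }
  # pixel centres in unit-field coordinates; x -> columns, y -> rows
  px <- (seq_len(nc) - 0.5) / nc
  py <- (seq_len(nr) - 0.5) / nr
  sigma_px <- sigma_g * nc
  if (sigma_px < 0.5) {
    warn("Gaussian kernel std below 0.5 pixel; blobs are under-resolved.")
  }
  # blob basis: npix x ncell (sparse-ish, built densely per cell patch)
  B <- matrix(0, npix, nrow(cells))
  halfwidth <- 4 * sigma_g
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x[i]; cy <- cells$y[i]
    ic <- which(abs(px - cx) <= halfwidth)
    ir <- which(abs(py - cy) <= halfwidth)
    if (!length(ic) || !length(ir)) next
    gx <- exp(-(px[ic] - cx)^2 / (2 * sigma_g^2))
    gy <- exp(-(py[ir] - cy)^2 / (2 * sigma_g^2))
    patch <- outer(gy, gx)  # rows x cols
    idx <- rep(ir, times = length(ic)) + (rep(ic, each = length(ir)) - 1L) * nr
    B[idx, i] <- B[idx, i] + as.vector(patch)
  }
  # signals: ncell x ntime
  S <- t(vapply(seq_len(nrow(cells)), function(i) {
    cell_signal(cells$intensity[i], cells$period_h[i], cells$phase_rad[i], times)
  }, numeric(length(times))))
  B %*% S
}

new_movie_stack <- function(frames, times, dt, channel) {
  structure(list(frames = frames, times = times, dt = dt, channel = channel),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> channel=%s, %d frames of %dx%d px, dt=%g h\n",
              x$channel, d[1], d[2], d[3], x$dt))
  invisible(x)
}

#' Render a cell field into dual-channel movie stacks
#'
#' Deposits each cell's instantaneous raised-cosine signal as a Gaussian blob
#' (std `sigma_g`, truncated at 4 sigma, peak equal to the signal),
#' superimposes the `M` layers with weights `1, a, a^2, ...`
#' (`a = layer_attenuation`), then adds i.i.d. Gaussian pixel noise per frame
#' and channel.
#'
#' @param field A `cell_field` tibble from [place_cells()].
#' @param config The matching [surrogate_config()].
#' @param seed Optional override of `config$seed` (noise stream).
#' @return A list with `movie_stack` elements `bmal` and `per`; each holds a
#'   `time x row x col` intensity array, `times` (hours) and `dt`.
#' @export
render_movie <- function(field, config, seed = NULL) {
  stopifnot(inherits(config, "surrogate_config"))
  seed <- seed %||% config$seed
  times <- seq(0, config$duration * 24, by = config$dt)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  npix <- nr * nc
  out <- list()
  for (ch in c("bmal", "per")) {
    acc <- matrix(0, npix, length(times))
    for (l in sort(unique(field$layer))) {
      cells <- dplyr::filter(field, .data$layer == l, .data$channel == ch)
      w <- config$layer_attenuation^(l - 1)
      if (nrow(cells)) {
        acc <- acc + w * rasterize_layer(cells, times, config$grid_shape,
                                         config$sigma_g)
      }
    }
    if (config$sigma_n > 0) {
      set.seed(child_seed(seed, paste0("noise-", ch)))
      acc <- acc + matrix(rnorm(length(acc), 0, config$sigma_n),
                          nrow(acc), ncol(acc))
    }
    frames <- aperm(array(acc, dim = c(nr, nc, length(times))), c(3, 1, 2))
    out[[ch]] <- new_movie_stack(frames, times, config$dt, ch)
  }
  out
}

#' Generate a surrogate dual-reporter movie
#'
#' Composes [place_cells()] and [render_movie()] under one master seed.
#'
#' @param config A [surrogate_config()].
#' @return List with elements `bmal`, `per` (movie stacks), `field` (the cell
#'   records) and `config`.
#' @export
generate_surrogate <- function(config) {
  field <- place_cells(config)
  movies <- render_movie(field, config)
  list(bmal = movies$bmal, per = movies$per, field = field, config = config)
}

#' Pixel time series from a movie stack
#'
#' @param movie A `movie_stack`.
#' @return Matrix `ntime x npix` (pixels in column-major row/col order).
#' @export
movie_matrix <- function(movie) {
  d <- dim(movie$frames)
  matrix(movie$frames, nrow = d[1], ncol = d[2] * d[3])
}

#' Write a movie stack as plain-text artefacts
#'
#' Writes a long-format CSV (`time_h,row,col,value`) and a YAML sidecar with
#' the generating configuration. Intended for small stacks; large movies are
#' better regenerated from their config.
#'
#' @param movie A `movie_stack`.
#' @param path Output CSV path; the sidecar gets extension `.yml`.
#' @param config Optional [surrogate_config()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie_stack <- function(movie, path, config = NULL) {
  d <- dim(movie$frames)
  df <- tidyr::expand_grid(time_h = movie$times, row = seq_len(d[2]),
                           col = seq_len(d[3]))
  # frames is time x row x col; expand_grid varies col fastest
  df$value <- as.vector(aperm(movie$frames, c(3, 2, 1)))
  readr::write_csv(df, path)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), sub("\\.csv$", ".yml", path))
  }
  invisible(path)
}
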