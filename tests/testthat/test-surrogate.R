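test_that("cell placement respects hypothesis, channels and determinism", {
  cfg1 <- surrogate_config(n_cells = 150, hypothesis = "H0_1", seed = 5)
  f1 <- place_cells(cfg1)
  # every cell carries a 23 h bmal and a 24 h per record at one position
  per_cell <- dplyr::summarise(
    dplyr::group_by(f1, layer, cell),
    n = dplyr::n(), chans = paste(sort(channel), collapse = "+"),
    pb = period_h[channel == "bmal"], pp = period_h[channel == "per"],
    one_pos = dplyr::n_distinct(x) == 1 && dplyr::n_distinct(y) == 1,
    .groups = "drop"
  )
  expect_true(all(per_cell$n == 2))
  expect_true(all(per_cell$chans == "bmal+per"))
  expect_true(all(per_cell$pb == 23) && all(per_cell$pp == 24))
  expect_true(all(per_cell$one_pos))
  expect_true(all(f1$x >= 0 & f1$x <= 1 & f1$y >= 0 & f1$y <= 1))

  cfg2 <- surrogate_config(n_cells = 2, hypothesis = "H0_2", seed = 5)
  f2 <- place_cells(cfg2)
  counts <- dplyr::count(f2, layer, channel)
  expect_true(all(counts$n == 1))  # exactly one of each per layer

  expect_identical(place_cells(cfg1), place_cells(cfg1))
  expect_false(identical(place_cells(cfg1),
                         place_cells(cfg1, seed = 6)))

  # H0_1 vs H0_2 at the same seed share positions, differ in assignment
  f2b <- place_cells(surrogate_config(n_cells = 10, hypothesis = "H0_2",
                                      seed = 9))
  f1b <- place_cells(surrogate_config(n_cells = 10, hypothesis = "H0_1",
                                      seed = 9))
  pos1 <- dplyr::distinct(f1b, layer, cell, x, y)
  pos2 <- dplyr::distinct(f2b, layer, cell, x, y)
  expect_equal(pos1, pos2)
})

test_that("single-cell signal is the raised cosine, bounded in [0, I]", {
  expect_equal(cell_signal(1, 24, 0, 0), 1)
  expect_equal(cell_signal(1, 24, 0, 12), 0, tolerance = 1e-12)
  t <- 5.75
  expect_equal(cell_signal(1, 23, pi / 2, t),
               1 / 2 * (1 + cos(2 * pi * t / 23 + pi / 2)))
  tt <- seq(0, 100, by = 0.1)
  s <- cell_signal(2.5, 23, 1.3, tt)
  expect_true(all(s >= 0 & s <= 2.5))
  expect_error(cell_signal(1, -2, 0, 0), "period")
})

test_that("rendering superimposes attenuated layers over a Gaussian blob", {
  cfg <- surrogate_config(n_cells = 1, sigma_n = 0, sigma_g = 0.05,
                          dt = 6, duration = 0.5, grid_shape = c(24L, 24L),
                          n_layers = 1, seed = 1)
  # single cell at centre, trough at t = 12 h (third frame)
  f <- single_cell_field(period = 24, phase = 0)
  mv <- render_movie(f, cfg)
  expect_equal(max(abs(mv$bmal$frames[3, , ])), 0, tolerance = 1e-12)
  expect_equal(dim(mv$bmal$frames), c(3, 24, 24))

  # three identical single-cell layers at attenuation 0.5: centre pixel
  # carries 1 + 0.5 + 0.25 times the single-layer value
  cfg3 <- surrogate_config(n_cells = 1, sigma_n = 0, sigma_g = 0.05,
                           dt = 24, duration = 1, grid_shape = c(25L, 25L),
                           n_layers = 3, layer_attenuation = 0.5, seed = 1)
  f3 <- dplyr::bind_rows(single_cell_field(layers = 1L),
                         single_cell_field(layers = 2L),
                         single_cell_field(layers = 3L))
  class(f3) <- c("cell_field", class(f3))
  mv3 <- render_movie(f3, cfg3)
  mv1 <- render_movie(single_cell_field(), cfg3)
  expect_equal(mv3$bmal$frames[1, 13, 13],
               1.75 * mv1$bmal$frames[1, 13, 13], tolerance = 1e-12)

  # frame mass matches an independent brute-force rasterisation
  cfg_m <- surrogate_config(n_cells = 3, hypothesis = "H0_1", sigma_n = 0,
                            sigma_g = 0.06, dt = 12, duration = 1,
                            grid_shape = c(20L, 20L), n_layers = 2,
                            seed = 11)
  fm <- place_cells(cfg_m)
  mv_m <- render_movie(fm, cfg_m)
  for (ti in c(1, 2)) {
    oracle <- brute_force_frame(
      dplyr::filter(fm, channel == "per"), cfg_m, mv_m$per$times[ti])
    got <- mv_m$per$frames[ti, , ]
    # the renderer truncates blobs at 4 sigma (tail value 3.4e-4 of peak)
    expect_lt(max(abs(got - oracle)), 5e-4 * max(1, max(oracle)))
  }
})

test_that("surrogate generation is deterministic, linear in intensity, and sized by duration", {
  cfg <- surrogate_config(n_cells = 4, duration = 1, dt = 1, sigma_n = 0.3,
                          grid_shape = c(16L, 16L), seed = 3)
  s1 <- generate_surrogate(cfg)
  s2 <- generate_surrogate(cfg)
  expect_identical(s1$bmal$frames, s2$bmal$frames)
  expect_identical(s1$per$frames, s2$per$frames)
  expect_equal(dim(s1$bmal$frames)[1], 25)  # 1 day at 1 h

  cfg12 <- surrogate_config(n_cells = 2, duration = 12, dt = 1,
                            grid_shape = c(8L, 8L), seed = 3)
  expect_equal(dim(generate_surrogate(cfg12)$per$frames)[1], 289)

  cfg0 <- surrogate_config(n_cells = 4, duration = 1, dt = 1, sigma_n = 0,
                           grid_shape = c(16L, 16L), seed = 3)
  cfg0x2 <- surrogate_config(n_cells = 4, duration = 1, dt = 1, sigma_n = 0,
                             intensity = 2, grid_shape = c(16L, 16L),
                             seed = 3)
  a <- generate_surrogate(cfg0)$bmal$frames
  b <- generate_surrogate(cfg0x2)$bmal$frames
  expect_equal(b, 2 * a, tolerance = 1e-12)
})

test_that("noise-free movies recover channel periods and the mean field", {
  cfg <- surrogate_config(n_cells = 3, hypothesis = "H0_1", sigma_n = 0,
                          duration = 12, dt = 1, grid_shape = c(32L, 32L),
                          n_layers = 1, seed = 21)
  sur <- generate_surrogate(cfg)
  covered <- apply(sur$bmal$frames, c(2, 3), max) > 0.2
  map_b <- pixelwise_period_map(sur$bmal)
  map_p <- pixelwise_period_map(sur$per)
  grid_step <- 24 * (exp(log(48 / 4) / 1999) - 1)
  cov_long <- tibble::tibble(row = rep(seq_len(32), times = 32),
                             col = rep(seq_len(32), each = 32),
                             on = as.vector(covered))
  mb <- dplyr::inner_join(map_b, cov_long, by = c("row", "col"))
  mp <- dplyr::inner_join(map_p, cov_long, by = c("row", "col"))
  expect_true(all(abs(mb$period_h[mb$on] - 23) < 2 * grid_step + 0.1))
  expect_true(all(abs(mp$period_h[mp$on] - 24) < 2 * grid_step + 0.1))

  # time-average of a noise-free single-layer stack is the phase-free mean
  # field (every blob at I/2)
  avg <- apply(sur$bmal$frames, c(2, 3), mean)
  field_b <- dplyr::filter(sur$field, channel == "bmal")
  field_half <- dplyr::mutate(field_b, phase_rad = 0,
                              intensity = intensity / 2)
  class(field_half) <- c("cell_field", class(field_half))
  mean_frame <- brute_force_frame(field_half, cfg, 0)
  expect_lt(max(abs(avg - mean_frame)), 0.012 * cfg$intensity)
})

test_that("blob broadening degrades the two-population cluster signature", {
  # with large kernels, neighbouring Bmal-only and Per-only cells overlap
  # within pixels and the H0(2) pattern collapses toward the H0(1) one:
  # the cluster count must not increase as sigma_g grows
  count_at <- function(sg) {
    cfg <- surrogate_config(n_cells = 150, hypothesis = "H0_2",
                            sigma_g = sg, seed = 2)
    sur <- generate_surrogate(cfg)
    as.integer(count_bivariate_clusters(
      pixelwise_period_map(sur$bmal)$period_h,
      pixelwise_period_map(sur$per)$period_h))
  }
  narrow <- count_at(0.0132)
  wide <- count_at(4 * 0.0176)
  expect_lte(wide, narrow)
})
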