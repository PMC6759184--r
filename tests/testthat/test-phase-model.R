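optimal <- phase_params()  # tau 24.38 / 24.68, K = 0.043 each, beta = 0.7 pi

test_that("free rotation, in-phase locking and rotational symmetry hold", {
  free <- phase_params(tau_p = 24, tau_r = 25, k = 0, beta = 0)
  tr <- integrate_phase(free, t_end = 48, dt_out = 0.1,
                        init = c(theta_p = 0.3, theta_r = -0.1))
  expect_equal(tr$theta_p, 0.3 + 2 * pi / 24 * tr$time_h, tolerance = 1e-6)
  expect_equal(tr$theta_r, -0.1 + 2 * pi / 25 * tr$time_h, tolerance = 1e-6)

  ident <- phase_params(tau_p = 24, tau_r = 24, k = 0.05, beta = 0)
  tr2 <- integrate_phase(ident, t_end = 600, dt_out = 0.5,
                         init = c(theta_p = 1.2, theta_r = 0))
  expect_lt(abs(tail(tr2$delta, 1)), 1e-6)

  # adding a constant to both initial phases translates the trajectory
  tr3 <- integrate_phase(optimal, t_end = 120, dt_out = 0.5,
                         init = c(theta_p = 0, theta_r = 0))
  tr4 <- integrate_phase(optimal, t_end = 120, dt_out = 0.5,
                         init = c(theta_p = 1, theta_r = 1))
  expect_equal(tr4$theta_p, tr3$theta_p + 1, tolerance = 1e-7)
  expect_equal(tr4$delta, tr3$delta, tolerance = 1e-7)
})

test_that("synchronisation ratio separates locking from phase slipping", {
  expect_equal(sync_ratio(phase_params(tau_p = 24, tau_r = 24, k = 0.01)), 0)
  expect_lt(sync_ratio(optimal), 1)
  unc <- sync_ratio(phase_params(tau_p = 24, tau_r = 25, k = 0))
  expect_true(is.infinite(unc))

  # locked case: simulated delta settles; slipping case: delta drifts
  tr <- integrate_phase(optimal, t_end = 1200, dt_out = 0.5)
  late <- tail(tr$delta, 200)
  expect_lt(diff(range(late)), 1e-8)

  slip <- phase_params(tau_p = 23.5, tau_r = 25.5, k = 0.01)
  expect_gt(sync_ratio(slip), 1)
  trs <- integrate_phase(slip, t_end = 1200, dt_out = 0.5)
  expect_gt(abs(tail(trs$delta, 1)), 2 * pi)  # keeps slipping
  expect_error(locked_state(slip), "synchroni")
})

test_that("locked state matches the closed form and the printed optimum", {
  ls <- locked_state(optimal)
  ks <- 2 * 0.043
  dw <- 2 * pi / 24.38 - 2 * pi / 24.68
  expect_equal(ls$delta_star, asin(dw / ks) - 0.7 * pi, tolerance = 1e-12)
  expect_equal(ls$omega_star, pi / 24.38 + pi / 24.68, tolerance = 1e-12)
  # harmonic-mean period approx 24.53 h and delta* approx -0.7 pi
  expect_equal(ls$tau_star, 24.53, tolerance = 2e-4)
  expect_equal(ls$delta_star / pi, -0.7, tolerance = 0.02)

  # vanishing detuning gives delta* = -beta exactly
  sym <- phase_params(tau_p = 24.5, tau_r = 24.5, k = 0.05, beta = 1.1)
  expect_equal(locked_state(sym)$delta_star, -1.1)

  # linearised relaxation rate near the fixed point is K_sigma cos(delta*+beta)
  pr <- pulse_relaxation(optimal, offset_h = 0.5, t_end = 120)
  resid <- abs(pr$offset_h)
  i1 <- 1000; i2 <- 6000
  rate <- -(log(resid[i2]) - log(resid[i1])) /
    (pr$time_h[i2] - pr$time_h[i1])
  expect_equal(rate, ks * cos(locked_state(optimal)$delta_star + 0.7 * pi),
               tolerance = 0.02)
})

test_that("isoclines invert the locked state and collapse at zero coupling", {
  kv <- c(0.005, 0.02, 0.043, 0.1)
  # sin(delta*+beta) = 0 case: all periods equal tau*
  iso0 <- isocline(-0.7 * pi, 0.7 * pi, 24.53, kv)
  expect_true(all(abs(iso0$tau_p - 24.53) < 1e-12))

  iso <- isocline(-0.7 * pi, 0.5 * pi, 24.53, kv)
  for (i in seq_along(kv)) {
    ls <- locked_state(phase_params(tau_p = iso$tau_p[i],
                                    tau_r = iso$tau_r[i], k = kv[i],
                                    beta = 0.5 * pi))
    expect_equal(ls$delta_star, -0.7 * pi, tolerance = 1e-10)
    expect_equal(ls$tau_star, 24.53, tolerance = 1e-10)
  }
  # K -> 0 limit: tip of the synchronisation triangle
  tip <- isocline(-0.7 * pi, 0.5 * pi, 24.53, 1e-9)
  expect_equal(tip$tau_p, 24.53, tolerance = 1e-6)
  expect_error(isocline(-0.7 * pi, -0.7 * pi + 2, 24.53, 0.05), "band")
})

test_that("jet-lag shift curves respond to z, K and coupling asymmetry", {
  null_prot <- zeitgeber("jetlag", z = 0.08, T = 24, jetlag_day = 16,
                         jetlag_shift = 0)
  jl0 <- suppressWarnings(simulate_jetlag(optimal, null_prot, n_post = 6))
  settled <- jl0[jl0$day > -5, ]  # past the initial entrainment transient
  expect_lt(max(abs(c(settled$shift_per_h, settled$shift_bmal_h))), 0.05)

  half_day <- function(jl, col) {
    post <- jl[jl$day > 0, ]
    post$day[which(post[[col]] >= 3)[1]]
  }
  run <- function(p, z) {
    prot <- zeitgeber("jetlag", z = z, T = 24, jetlag_day = 20,
                      jetlag_shift = 6)
    suppressWarnings(simulate_jetlag(p, prot, n_post = 20))
  }
  # Per re-entrains before Bmal-Rev, and both converge to the 6 h advance
  jl <- run(phase_params(k = 0.043), 0.08)
  expect_lt(half_day(jl, "shift_per_h"), half_day(jl, "shift_bmal_h"))
  expect_equal(tail(jl$shift_per_h, 1), 6, tolerance = 0.2)

  # stronger Zeitgeber accelerates the Per response
  h1 <- half_day(run(phase_params(k = 0.043), 0.05), "shift_per_h")
  h2 <- half_day(run(phase_params(k = 0.043), 0.10), "shift_per_h")
  expect_lte(h2, h1)

  # at fixed total coupling, pushing weight onto K_R (p up) slows Bmal-Rev
  hb <- vapply(c(0.3, 0.5, 0.7), function(p) {
    half_day(run(phase_params(k_total = 2 * 0.043, p = p), 0.08),
             "shift_bmal_h")
  }, numeric(1))
  expect_true(all(diff(hb) >= 0))
})

test_that("pulse relaxation follows the reduced phase-difference equation", {
  pr0 <- pulse_relaxation(optimal, offset_h = 0, t_end = 48)
  expect_lt(diff(range(pr0$delta)), 1e-9)

  pr <- pulse_relaxation(optimal, offset_h = 3, t_end = 24 * 10)
  expect_lt(attr(pr, "relax_time_h") / 24, 5)

  # relaxation accelerates with coupling strength
  times <- vapply(c(0.5, 1, 2) * 0.043, function(k) {
    attr(pulse_relaxation(phase_params(k = k), 3, 24 * 20), "relax_time_h")
  }, numeric(1))
  expect_true(all(diff(times) < 0))

  # an offset beyond the unstable fixed point goes the long way round
  expect_warning(pulse_relaxation(optimal, offset_h = 13, t_end = 24 * 30),
                 "long way")
})
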