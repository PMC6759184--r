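# Two-oscillator phase model of the interlocked Per and Bmal-Rev loops:
#
#   theta_P' = omega_P + K_R sin(theta_R - theta_P - beta) + Z(t)
#   theta_R' = omega_R + K_P sin(theta_P - theta_R + beta)
#
# with Z(t) = z sin(2*pi*t/T - theta_P + phi0) acting on the light-sensitive
# Per loop only. Under free run the phase difference obeys
#   d(dtheta)/dt = domega - (K_P + K_R) sin(dtheta + beta),
# locking iff |domega| < K_P + K_R, with locked frequency the coupling-
# weighted mean and locked difference arcsin(domega/K_sigma) - beta.

#' Parameters of the two-loop phase model
#'
#' Either give the per-direction strengths `k_p`, `k_r` directly, or a total
#' coupling `k_total` with asymmetry `p` (`k_r = p*k_total`,
#' `k_p = (1-p)*k_total`), or a symmetric per-direction `k`
#' (`k_p = k_r = k`).
#'
#' @param tau_p,tau_r Intrinsic periods of the Per and Bmal-Rev loops (hours).
#' @param k Symmetric per-direction coupling strength (rad/h).
#' @param beta Phase-offset parameter of the interaction function (radians).
#' @param k_p Strength of the Bmal-Rev -> Per... action on `theta_R` (rad/h);
#'   `k_p` multiplies the term driving the Bmal-Rev loop, `k_r` the term
#'   driving the Per loop.
#' @param k_r See `k_p`.
#' @param k_total,p Alternative parameterisation: total coupling and the
#'   asymmetry fraction `p` in `[0, 1]`.
#' @return A `phase_params` list with `omega_p`, `omega_r` precomputed.
#' @export
phase_params <- function(tau_p = 24.38, tau_r = 24.68, k = 0.043,
                         beta = 0.7 * pi, k_p = NULL, k_r = NULL,
                         k_total = NULL, p = NULL) {
  if (!is.null(k_total)) {
    stopifnot(!is.null(p), p >= 0, p <= 1)
    k_r <- p * k_total
    k_p <- (1 - p) * k_total
  }
  k_p <- k_p %||% k
  k_r <- k_r %||% k
  assert_scalar_num(tau_p, "tau_p", positive = TRUE)
  assert_scalar_num(tau_r, "tau_r", positive = TRUE)
  assert_scalar_num(k_p, "k_p", nonneg = TRUE)
  assert_scalar_num(k_r, "k_r", nonneg = TRUE)
  structure(list(tau_p = tau_p, tau_r = tau_r, k_p = k_p, k_r = k_r,
                 beta = beta, omega_p = 2 * pi / tau_p,
                 omega_r = 2 * pi / tau_r),
            class = "phase_params")
}

#' Zeitgeber (light input) protocol
#'
#' @param kind One of `"none"`, `"sinusoid"`, `"square"`, `"pulse"`,
#'   `"jetlag"`. `"jetlag"` is a sinusoid whose phase is advanced by
#'   `jetlag_shift` hours at `jetlag_day`.
#' @param z Forcing strength (dimensionless for the phase model, a.u./h for
#'   the gene models).
#' @param T Zeitgeber period in hours.
#' @param phi0 Zeitgeber phase offset in radians.
#' @param pulse_start,pulse_duration Pulse window in hours (`"pulse"` only).
#' @param jetlag_day Day of the schedule shift.
#' @param jetlag_shift Shift in hours; positive = advance.
#' @param photoperiod Fraction of the cycle with lights on (square wave).
#' @return A `zeitgeber` list.
#' @export
zeitgeber <- function(kind = c("none", "sinusoid", "square", "pulse",
                               "jetlag"),
                      z = 0, T = 24, phi0 = 0, pulse_start = 0,
                      pulse_duration = 9, jetlag_day = 10, jetlag_shift = 6,
                      photoperiod = 0.5) {
  kind <- match.arg(kind)
  assert_scalar_num(z, "z", nonneg = TRUE)
  assert_scalar_num(T, "T", positive = TRUE)
  if (kind == "pulse") assert_scalar_num(pulse_duration, "pulse_duration",
                                         positive = TRUE)
  structure(list(kind = kind, z = z, T = T, phi0 = phi0,
                 pulse_start = pulse_start, pulse_duration = pulse_duration,
                 jetlag_day = jetlag_day, jetlag_shift = jetlag_shift,
                 photoperiod = photoperiod),
            class = "zeitgeber")
}

# Zeitgeber phase offset including an advance after the jet-lag event.
zg_phase_offset <- function(protocol, t) {
  phi <- protocol$phi0
  if (protocol$kind == "jetlag") {
    phi <- phi + ifelse(t >= protocol$jetlag_day * 24,
                        2 * pi * protocol$jetlag_shift / protocol$T, 0)
  }
  phi
}

# Z(t) for the phase model (depends on theta_p through the forcing term).
phase_zeitgeber_term <- function(protocol, t, theta_p) {
  if (protocol$kind == "none" || protocol$z == 0) return(0)
  active <- TRUE
  if (protocol$kind == "pulse") {
    active <- t >= protocol$pulse_start &&
      t < protocol$pulse_start + protocol$pulse_duration
  }
  if (protocol$kind == "square") {
    # photoperiod-gated version of the sinusoidal drive
    active <- (t %% protocol$T) < protocol$photoperiod * protocol$T
  }
  if (!active) return(0)
  phi <- zg_phase_offset(protocol, t)
  protocol$z * sin(2 * pi * t / protocol$T - theta_p + phi)
}

#' Integrate the two-loop phase model
#'
#' Adaptive integration (deSolve, lsoda, rtol 1e-8 / atol 1e-10) with dense
#' output at `dt_out`.
#'
#' @param params A [phase_params()].
#' @param protocol A [zeitgeber()] (forcing acts on the Per loop only).
#' @param init Named vector `c(theta_p=, theta_r=)` in radians.
#' @param t_end End time in hours.
#' @param dt_out Output sampling interval in hours (default 0.01).
#' @return A tibble `time_h`, `theta_p`, `theta_r` (unwrapped radians) and
#'   `delta` (= theta_p - theta_r).
#' @export
integrate_phase <- function(params, protocol = zeitgeber("none"),
                            init = c(theta_p = 0, theta_r = 0),
                            t_end = 240, dt_out = 0.01) {
  stopifnot(inherits(params, "phase_params"), t_end > 0)
  deriv <- function(t, y, parms) {
    dp <- params$omega_p +
      params$k_r * sin(y[2] - y[1] - params$beta) +
      phase_zeitgeber_term(protocol, t, y[1])
    dr <- params$omega_r + params$k_p * sin(y[1] - y[2] + params$beta)
    list(c(dp, dr))
  }
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(y = unname(init[c("theta_p", "theta_r")]),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  tibble(time_h = sol[, 1], theta_p = sol[, 2], theta_r = sol[, 3],
         delta = sol[, 2] - sol[, 3])
}

#' Synchronisation ratio of the two loops
#'
#' `|omega_P - omega_R| / (K_P + K_R)`; the loops phase-lock iff this is
#' below 1.
#'
#' @param params A [phase_params()].
#' @return The ratio; `Inf` (with attribute `uncoupled = TRUE`) when the
#'   total coupling vanishes.
#' @export
sync_ratio <- function(params) {
  ks <- params$k_p + params$k_r
  dw <- abs(params$omega_p - params$omega_r)
  if (ks == 0) {
    out <- if (dw == 0) 0 else Inf
    attr(out, "uncoupled") <- TRUE
    return(out)
  }
  dw / ks
}

#' Locked state of the phase model
#'
#' Closed-form synchronised solution: common angular velocity
#' `omega* = (K_P omega_P + K_R omega_R)/(K_P + K_R)` and stable phase
#' difference `dtheta* = arcsin((omega_P - omega_R)/(K_P + K_R)) - beta`.
#'
#' @param params A [phase_params()].
#' @return One-row tibble `omega_star` (rad/h), `tau_star` (hours),
#'   `delta_star` (radians, in `[-beta - pi/2, -beta + pi/2]`).
#' @export
locked_state <- function(params) {
  r <- sync_ratio(params)
  if (!(r < 1)) {
    abort(paste0("Loops do not synchronise: |omega_P - omega_R|/(K_P + K_R)",
                 sprintf(" = %.3g >= 1.", r)))
  }
  ks <- params$k_p + params$k_r
  omega_star <- (params$k_p * params$omega_p + params$k_r * params$omega_r) / ks
  delta_star <- asin((params$omega_p - params$omega_r) / ks) - params$beta
  tibble(omega_star = omega_star, tau_star = 2 * pi / omega_star,
         delta_star = delta_star)
}

#' Isocline of constant locked phase difference
#'
#' For each coupling strength `K` (symmetric, per direction) finds the
#' period pair reproducing a target locked phase difference at a prescribed
#' common period: `omega_P = omega* + K sin(dtheta* + beta)`,
#' `omega_R = 2 omega* - omega_P`.
#'
#' @param delta_star Target locked phase difference in radians.
#' @param beta Interaction offset in radians; requires
#'   `|delta_star + beta| < pi/2`.
#' @param tau_star Common locked period in hours (default 24.53).
#' @param k_values Vector of symmetric coupling strengths (rad/h).
#' @return Tibble `k`, `tau_p`, `tau_r`; each row reproduces `delta_star`
#'   via [locked_state()].
#' @export
isocline <- function(delta_star, beta, tau_star = 24.53, k_values) {
  if (abs(delta_star + beta) >= pi / 2) {
    abort("Target outside the attainable band [-beta - pi/2, -beta + pi/2].")
  }
  omega_star <- 2 * pi / tau_star
  s <- sin(delta_star + beta)
  omega_p <- omega_star + k_values * s
  omega_r <- 2 * omega_star - omega_p
  if (any(omega_p <= 0) || any(omega_r <= 0)) {
    abort("Coupling too large: inverted frequencies on the isocline.")
  }
  tibble(k = k_values, tau_p = 2 * pi / omega_p, tau_r = 2 * pi / omega_r)
}

# ---- Acrophase-shift machinery shared by jet-lag protocols --------------

# Given acrophase times of an entrained oscillator, the Zeitgeber period T
# and the shift event time, return per-cycle phase shifts in hours
# (positive = advance), relative to the mean pre-shift entrained phase.
acrophase_shift_curve <- function(peak_times, T, t_shift, target_shift,
                                  n_ref = 5) {
  pre <- peak_times[peak_times < t_shift]
  post <- peak_times
  if (length(pre) < n_ref) abort("Not enough pre-shift cycles for a reference.")
  ref <- pre[(length(pre) - n_ref + 1):length(pre)]
  # mean entrained phase within the old Zeitgeber cycle (circular mean)
  ang <- 2 * pi * (ref %% T) / T
  phase0 <- atan2(mean(sin(ang)), mean(cos(ang))) * T / (2 * pi)
  raw <- phase0 - (post %% T)                  # advance positive
  shift <- wrap_pi(2 * pi * raw / T) * T / (2 * pi)
  # unwrap toward the target so shifts beyond T/2 are reported cumulatively
  if (abs(target_shift) > T / 2) {
    k <- round((target_shift - shift) / T)
    shift <- shift + k * T
  }
  tibble(day = (post - t_shift) / 24, shift_h = shift)
}

#' Jet-lag response of the phase model
#'
#' Entrains the model to a sinusoidal Zeitgeber, advances the Zeitgeber
#' phase by `jetlag_shift` hours at `jetlag_day`, and returns each loop's
#' per-cycle acrophase shift relative to its pre-shift entrained phase
#' (positive = advance; curves converge to the applied shift).
#'
#' @param params A [phase_params()].
#' @param protocol A [zeitgeber()] of kind `"jetlag"`.
#' @param n_post Days recorded after the shift (default 25).
#' @param dt_out Integration output step (hours).
#' @return Tibble `day`, `shift_per_h`, `shift_bmal_h` with attribute
#'   `entrained` (pre-shift acrophase drift < 0.05 h over 10 cycles).
#' @export
simulate_jetlag <- function(params, protocol, n_post = 25, dt_out = 0.05) {
  stopifnot(protocol$kind == "jetlag")
  t_shift <- protocol$jetlag_day * 24
  t_end <- t_shift + n_post * 24
  traj <- integrate_phase(params, protocol, t_end = t_end, dt_out = dt_out)
  curves <- purrr::map(c(per = "theta_p", bmal = "theta_r"), function(v) {
    peaks <- phase_acrophases(traj$time_h, traj[[v]])
    acrophase_shift_curve(peaks, protocol$T, t_shift, protocol$jetlag_shift)
  })
  # entrainment check on the Per loop before the shift
  prep <- curves$per[curves$per$day < 0, ]
  drift <- if (nrow(prep) >= 10) {
    diff(range(tail(prep$shift_h, 10)))
  } else NA_real_
  # the two loops' acrophases interleave in time; report both curves on the
  # Per acrophase days, interpolating the Bmal-Rev curve
  per <- curves$per
  bmal <- curves$bmal
  bmal_at <- approx(bmal$day, bmal$shift_h, xout = per$day, rule = 2)$y
  out <- tibble(day = per$day, shift_per_h = per$shift_h,
                shift_bmal_h = bmal_at)
  attr(out, "entrained") <- is.finite(drift) && drift < 0.05
  if (!isTRUE(attr(out, "entrained"))) {
    warn("Pre-shift entrainment criterion not met; curves still returned.")
  }
  out
}

# Acrophases of cos(theta): times where the unwrapped phase crosses 2*pi*k,
# located by linear inverse interpolation (phase is monotone in practice).
phase_acrophases <- function(times, theta) {
  ks <- seq(ceiling(min(theta) / (2 * pi)), floor(max(theta) / (2 * pi)))
  if (!length(ks)) return(numeric(0))
  vapply(ks, function(k) {
    target <- 2 * pi * k
    i <- which(theta[-length(theta)] <= target & theta[-1] > target)[1]
    if (is.na(i)) return(NA_real_)
    t0 <- times[i]; t1 <- times[i + 1]
    t0 + (target - theta[i]) / (theta[i + 1] - theta[i]) * (t1 - t0)
  }, numeric(1)) |> stats::na.omit() |> as.numeric()
}

#' Jet-lag RSS fitness landscape
#'
#' Scans a `(K, z)` grid: each `K` is mapped along the [isocline()] so the
#' locked phase difference is preserved, the jet-lag protocol is simulated,
#' and the residual sum of squares against a reference shift-curve table is
#' evaluated at the reference's sampling days (both loops).
#'
#' @param reference Data frame `day`, `shift_per_h`, `shift_bmal_h`.
#' @param k_values,z_values Grid axes (rad/h, dimensionless).
#' @param beta Interaction offset (radians).
#' @param delta_star Locked phase difference preserved along the isocline.
#' @param tau_star Common locked period (hours).
#' @param jetlag_shift,jetlag_day,T Protocol settings (hours / days / hours).
#' @param n_post Days recorded after the shift.
#' @return Tibble `k`, `z`, `rss`, `log_rss` with attribute `best`
#'   (the row minimising `rss`).
#' @export
rss_fitness <- function(reference, k_values, z_values, beta = 0.7 * pi,
                        delta_star = -0.7 * pi, tau_star = 24.53,
                        jetlag_shift = 6, jetlag_day = 15, T = 24,
                        n_post = 25) {
  if (!all(c("day", "shift_per_h", "shift_bmal_h") %in% names(reference))) {
    abort("Reference needs columns `day`, `shift_per_h`, `shift_bmal_h`.")
  }
  iso <- isocline(delta_star, beta, tau_star, k_values)
  grid <- tidyr::expand_grid(ik = seq_along(k_values), z = z_values)
  res <- purrr::pmap_dfr(grid, function(ik, z) {
    pars <- phase_params(tau_p = iso$tau_p[ik], tau_r = iso$tau_r[ik],
                         k = iso$k[ik], beta = beta)
    prot <- zeitgeber("jetlag", z = z, T = T, jetlag_day = jetlag_day,
                      jetlag_shift = jetlag_shift)
    sim <- suppressWarnings(
      simulate_jetlag(pars, prot, n_post = n_post)
    )
    per_at <- approx(sim$day, sim$shift_per_h, xout = reference$day,
                     rule = 2)$y
    bmal_at <- approx(sim$day, sim$shift_bmal_h, xout = reference$day,
                      rule = 2)$y
    rss <- sum((per_at - reference$shift_per_h)^2 +
                 (bmal_at - reference$shift_bmal_h)^2)
    tibble(k = iso$k[ik], z = z, rss = rss)
  })
  res$log_rss <- log10(pmax(res$rss, .Machine$double.xmin))
  attr(res, "best") <- res[which.min(res$rss), ]
  res
}

#' Relaxation of a perturbed phase difference
#'
#' Integrates the reduced phase-difference equation
#' `d(dtheta)/dt = domega - (K_P + K_R) sin(dtheta + beta)` from the locked
#' value plus an offset (given in hours, converted via the locked angular
#' velocity).
#'
#' @param params A [phase_params()] with `sync_ratio(params) < 1`.
#' @param offset_h Initial perturbation of the phase difference in hours.
#' @param t_end Integration time in hours.
#' @param dt_out Output step in hours.
#' @return Tibble `time_h`, `delta` (radians), `offset_h` (residual offset in
#'   hours, signed), with attributes `delta_star`, `relax_time_h` (first time
#'   the residual stays within 10% of the initial offset) and `long_way`
#'   (TRUE when the start lies beyond the unstable fixed point).
#' @export
pulse_relaxation <- function(params, offset_h = 3, t_end = 24 * 15,
                             dt_out = 0.01) {
  ls <- locked_state(params)
  offset0 <- offset_h * ls$omega_star
  ks <- params$k_p + params$k_r
  dw <- params$omega_p - params$omega_r
  # unstable fixed point of sin(delta + beta) = dw/ks
  delta_unstable <- pi - asin(dw / ks) - params$beta
  gap <- wrap_pi(delta_unstable - ls$delta_star)
  long_way <- abs(offset0) > abs(gap) && sign(offset0) == sign(gap)
  deriv <- function(t, y, parms) {
    list(dw - ks * sin(y + params$beta))
  }
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(y = ls$delta_star + offset0, times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  delta <- sol[, 2]
  res_h <- (delta - ls$delta_star) / ls$omega_star
  within <- abs(res_h) <= 0.1 * abs(offset_h)
  relax <- if (any(within)) {
    # first time after which the residual never leaves the band again
    ok <- rev(cumprod(rev(within))) == 1
    times[which(ok)[1]]
  } else NA_real_
  out <- tibble(time_h = times, delta = delta, offset_h = res_h)
  attr(out, "delta_star") <- ls$delta_star
  attr(out, "relax_time_h") <- relax
  attr(out, "long_way") <- long_way
  if (long_way) warn("Perturbation beyond the unstable fixed point; the phase difference relaxes the long way round.")
  out
}
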