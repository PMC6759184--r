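# Mean-field coupled Poincare amplitude-phase oscillators for the Per and
# Bmal-Rev loops:
#
#   dz_j/dt = (lambda_j (A_j - r_j) + i 2*pi/tau_j) z_j
#             + K e^{i phi} sum_{j in {P,R}} z_j ,    r_j = |z_j|,
#
# integrated in Cartesian coordinates, with the Zeitgeber
# Z(t) = z sin(2*pi*t/T + phi0) added to dx_P/dt only. Setting amp_r = 0
# turns the Bmal-Rev loop into a damped oscillator.

#' Parameters of the coupled Poincare oscillator pair
#'
#' @param lambda_p,lambda_r Radial relaxation rates (1/h).
#' @param amp_p,amp_r Limit-cycle amplitudes; `amp_r = 0` gives a damped
#'   Bmal-Rev loop.
#' @param tau_p,tau_r Intrinsic periods (hours).
#' @param k Mean-field coupling strength (1/h).
#' @param phi Coupling phase (radians; default `pi`).
#' @param include_self Include the oscillator's own term in the mean field,
#'   exactly as the complex equation is written (default TRUE); `FALSE`
#'   couples each oscillator to the other only.
#' @return A `poincare_params` list.
#' @export
poincare_params <- function(lambda_p = 0.1, lambda_r = 0.1, amp_p = 1,
                            amp_r = 1, tau_p = 24.38, tau_r = 24.68,
                            k = 0.005, phi = pi, include_self = TRUE) {
  assert_scalar_num(lambda_p, "lambda_p", positive = TRUE)
  assert_scalar_num(lambda_r, "lambda_r", positive = TRUE)
  assert_scalar_num(amp_p, "amp_p", nonneg = TRUE)
  assert_scalar_num(amp_r, "amp_r", nonneg = TRUE)
  assert_scalar_num(k, "k", nonneg = TRUE)
  structure(list(lambda_p = lambda_p, lambda_r = lambda_r, amp_p = amp_p,
                 amp_r = amp_r, tau_p = tau_p, tau_r = tau_r, k = k,
                 phi = phi, include_self = isTRUE(include_self)),
            class = "poincare_params")
}

# Zeitgeber for the Cartesian Poincare system: plain sinusoid (no state
# dependence), jet-lag advances its phase at the shift day.
poincare_zeitgeber_term <- function(protocol, t) {
  if (protocol$kind == "none" || protocol$z == 0) return(0)
  if (protocol$kind == "pulse") {
    if (t < protocol$pulse_start ||
        t >= protocol$pulse_start + protocol$pulse_duration) return(0)
  }
  phi <- zg_phase_offset(protocol, t)
  protocol$z * sin(2 * pi * t / protocol$T + phi)
}

#' Integrate the coupled Poincare oscillators
#'
#' @param params A [poincare_params()].
#' @param protocol A [zeitgeber()]; the forcing is added to `dx_P/dt`.
#' @param init Named vector `c(x_p=, y_p=, x_r=, y_r=)`.
#' @param t_end End time (hours).
#' @param dt_out Output step (hours; default 0.01).
#' @return Tibble `time_h`, `x_p`, `y_p`, `x_r`, `y_r`.
#' @export
integrate_poincare <- function(params, protocol = zeitgeber("none"),
                               init = c(x_p = 1, y_p = 0, x_r = 1, y_r = 0),
                               t_end = 240, dt_out = 0.01) {
  stopifnot(inherits(params, "poincare_params"), t_end > 0)
  wp <- 2 * pi / params$tau_p
  wr <- 2 * pi / params$tau_r
  cphi <- cos(params$phi); sphi <- sin(params$phi)
  deriv <- function(t, y, parms) {
    xp <- y[1]; yp <- y[2]; xr <- y[3]; yr <- y[4]
    rp <- sqrt(xp^2 + yp^2); rr <- sqrt(xr^2 + yr^2)
    # mean-field sums per oscillator
    if (params$include_self) {
      sx_p <- xp + xr; sy_p <- yp + yr
      sx_r <- sx_p;    sy_r <- sy_p
    } else {
      sx_p <- xr; sy_p <- yr
      sx_r <- xp; sy_r <- yp
    }
    zg <- poincare_zeitgeber_term(protocol, t)
    dxp <- params$lambda_p * (params$amp_p - rp) * xp - wp * yp +
      params$k * (cphi * sx_p - sphi * sy_p) + zg
    dyp <- params$lambda_p * (params$amp_p - rp) * yp + wp * xp +
      params$k * (sphi * sx_p + cphi * sy_p)
    dxr <- params$lambda_r * (params$amp_r - rr) * xr - wr * yr +
      params$k * (cphi * sx_r - sphi * sy_r)
    dyr <- params$lambda_r * (params$amp_r - rr) * yr + wr * xr +
      params$k * (sphi * sx_r + cphi * sy_r)
    list(c(dxp, dyp, dxr, dyr))
  }
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(y = unname(init[c("x_p", "y_p", "x_r", "y_r")]),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  tibble(time_h = sol[, 1], x_p = sol[, 2], y_p = sol[, 3],
         x_r = sol[, 4], y_r = sol[, 5])
}

#' Instantaneous phase and radius of Poincare trajectories
#'
#' @param traj Output of [integrate_poincare()].
#' @return `traj` with added columns `phase_p`, `phase_r` (unwrapped
#'   radians; `NA` where the radius falls below 1e-6) and `r_p`, `r_r`.
#' @export
extract_phase_amplitude <- function(traj) {
  out <- dplyr::mutate(
    traj,
    r_p = sqrt(.data$x_p^2 + .data$y_p^2),
    r_r = sqrt(.data$x_r^2 + .data$y_r^2),
    phase_p = unwrap_phase(atan2(.data$y_p, .data$x_p)),
    phase_r = unwrap_phase(atan2(.data$y_r, .data$x_r))
  )
  degenerate_p <- out$r_p < 1e-6
  degenerate_r <- out$r_r < 1e-6
  out$phase_p[degenerate_p] <- NA_real_
  out$phase_r[degenerate_r] <- NA_real_
  if (any(degenerate_p | degenerate_r)) {
    warn("Radius below 1e-6 at some samples; phase undefined there.")
  }
  out
}

#' Jet-lag response of the Poincare pair
#'
#' Entrains the pair to a sinusoidal Zeitgeber on `x_P`, shifts the
#' Zeitgeber phase at `jetlag_day`, and reports per-cycle acrophase shifts
#' of `x_P` and `x_R` (positive = advance).
#'
#' @param params A [poincare_params()].
#' @param protocol A [zeitgeber()] of kind `"jetlag"`.
#' @param n_post Days recorded after the shift.
#' @param dt_out Output step (hours).
#' @return Tibble `day`, `shift_per_h`, `shift_bmal_h`.
#' @export
simulate_jetlag_poincare <- function(params, protocol, n_post = 25,
                                     dt_out = 0.05) {
  stopifnot(protocol$kind == "jetlag")
  t_shift <- protocol$jetlag_day * 24
  traj <- integrate_poincare(params, protocol,
                             t_end = t_shift + n_post * 24, dt_out = dt_out)
  ph <- extract_phase_amplitude(traj)
  per_peaks <- phase_acrophases(ph$time_h, ph$phase_p)
  bmal_peaks <- phase_acrophases(ph$time_h, ph$phase_r)
  per <- acrophase_shift_curve(per_peaks, protocol$T, t_shift,
                               protocol$jetlag_shift)
  bmal <- acrophase_shift_curve(bmal_peaks, protocol$T, t_shift,
                                protocol$jetlag_shift)
  bmal_at <- approx(bmal$day, bmal$shift_h, xout = per$day, rule = 2)$y
  tibble(day = per$day, shift_per_h = per$shift_h, shift_bmal_h = bmal_at)
}

#' Symmetric detuning realising a target free-run phase difference
#'
#' For a coupling strength `k`, finds the symmetric period detuning `d`
#' (with `tau_p = tau_star - d`, `tau_r = tau_star + d`) at which the
#' free-running coupled pair locks with phase difference `delta_star`,
#' by bisection on simulated trajectories. The damped variant
#' (`amp_r = 0`) has its own, substantially larger, detuning line.
#'
#' @param k Mean-field coupling strength (1/h).
#' @param delta_star Target locked phase difference (radians).
#' @param tau_star Common reference period (hours, default 24.53).
#' @param amp_r Bmal-Rev amplitude (1 self-sustained, 0 damped).
#' @param phi Coupling phase (default `pi`).
#' @param lambda Radial relaxation rate for both oscillators (1/h).
#' @param interval Detuning search interval in hours.
#' @param t_end Free-run simulation length per evaluation (hours).
#' @return Detuning in hours, or `NA` when the target is not attained on
#'   the interval.
#' @export
poincare_detuning_for_delta <- function(k, delta_star = -0.7 * pi,
                                        tau_star = 24.53, amp_r = 1,
                                        phi = pi, lambda = 0.1,
                                        interval = c(0.05, 8),
                                        t_end = 1200) {
  delta_at <- function(d) {
    pp <- poincare_params(lambda_p = lambda, lambda_r = lambda,
                          amp_r = amp_r, tau_p = tau_star - d,
                          tau_r = tau_star + d, k = k, phi = phi)
    tr <- integrate_poincare(pp, t_end = t_end, dt_out = 0.2)
    ph <- extract_phase_amplitude(tr)
    tl <- tail(ph$phase_p - ph$phase_r, 1000)
    if (sd(tl) > 0.01) return(NA_real_)  # not locked
    wrap_pi(mean(tl)) - delta_star
  }
  # the self-sustained pair loses internal locking beyond roughly
  # d_max = K tau*^2 / (2 pi); the damped loop is slaved at any detuning
  ub <- if (amp_r > 0) {
    min(interval[2], 0.93 * k * tau_star^2 / (2 * pi))
  } else interval[2]
  grid <- seq(interval[1], ub, length.out = 10)
  vals <- vapply(grid, delta_at, numeric(1))
  ok <- which(is.finite(vals))
  if (length(ok) < 2) return(NA_real_)
  sgn <- sign(vals[ok])
  flip <- which(diff(sgn) != 0)
  if (!length(flip)) return(NA_real_)
  i1 <- ok[flip[1]]; i2 <- ok[flip[1] + 1]
  uniroot(delta_at, c(grid[i1], grid[i2]), f.lower = vals[i1],
          f.upper = vals[i2], tol = 1e-3)$root
}
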