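# Delayed-feedback gene circuits.
#
# Single-gene Per loop:
#   dP/dt = (v_P / (k_P + P(t - T_P)))^2 - d_P P + Z(t)
#
# Three-gene interlocked circuit (Per, Bmal1, RevErb):
#   dP/dt = (v_P/(k_P + P(t-T_P)))^2 * ((c_P + b_P B(t-T_B))/(c_P + B(t-T_B)))^2
#           - d_P P + Z(t)
#   dB/dt = (v_B/(k_B + R(t-T_R)))^2 - d_B B
#   dR/dt = ((v_R + b_R B(t-T_B))/(k_R + B(t-T_B)))^3 * (c_R/(P(t-T_P) + c_R))^3
#           - d_R R
#
# c_R sets how strongly Per represses RevErb transcription (large c_R = weak
# Per -> Bmal-Rev coupling); b_P sets the Bmal -> Per activation fold.
# Light acts as an additive Zeitgeber on dP/dt (square-wave LD cycles,
# jet-lag shifts, or rectangular pulses).

#' Parameters of the three-gene delayed feedback circuit
#'
#' Defaults are the nominal kinetic set: degradations `d_p = 0.25`,
#' `d_b = 0.26`, `d_r = 0.29` (1/h); activations `v_p = 1`, `v_b = 0.9`,
#' `v_r = 0.6`; half-max constants `k_p = 0.1`, `k_b = 0.05`, `k_r = 0.9`;
#' couplings `c_p = 0.1`, `c_r = 35`, `b_p = 1`, `b_r = 8`; delays
#' `delay_p = 8.333`, `delay_r = 1.52`, `delay_b = 3.652` (hours).
#'
#' @param d_p,d_b,d_r Degradation rates (1/h).
#' @param v_p,v_b,v_r Maximal activation strengths (a.u.).
#' @param k_p,k_b,k_r Half-maximal repression constants (a.u.).
#' @param c_p Bmal-activation half constant in the Per equation (a.u.).
#' @param c_r Per -> RevErb repression constant; large values weaken the
#'   Per -> Bmal-Rev coupling (a.u.).
#' @param b_p Bmal -> Per activation fold; `b_p = 1` switches that link off.
#' @param b_r Bmal -> RevErb activation fold (a.u.).
#' @param delay_p,delay_b,delay_r Explicit delays `T_P`, `T_B`, `T_R` (hours).
#' @return A `three_gene_params` list.
#' @export
three_gene_params <- function(d_p = 0.25, d_b = 0.26, d_r = 0.29,
                              v_p = 1, v_b = 0.9, v_r = 0.6,
                              k_p = 0.1, k_b = 0.05, k_r = 0.9,
                              c_p = 0.1, c_r = 35, b_p = 1, b_r = 8,
                              delay_p = 8.333, delay_b = 3.652,
                              delay_r = 1.52) {
  vals <- list(d_p = d_p, d_b = d_b, d_r = d_r, v_p = v_p, v_b = v_b,
               v_r = v_r, k_p = k_p, k_b = k_b, k_r = k_r, c_p = c_p,
               c_r = c_r, b_p = b_p, b_r = b_r, delay_p = delay_p,
               delay_b = delay_b, delay_r = delay_r)
  for (nm in names(vals)) assert_scalar_num(vals[[nm]], nm, positive = TRUE)
  structure(vals, class = "three_gene_params")
}

#' Zeitgeber protocol for the gene circuits
#'
#' @param kind `"none"`, `"square"` (LD cycles), or `"pulse"` (one
#'   rectangular light pulse).
#' @param z Additive Zeitgeber intensity on `dP/dt` (a.u./h).
#' @param T Zeitgeber period (hours).
#' @param photoperiod Lights-on fraction of the cycle (LD12:12 = 0.5).
#' @param jetlag_day Day of the schedule shift (square kind; `NA` = none).
#' @param jetlag_shift Shift in hours, positive = advance (one dark phase is
#'   shortened once).
#' @param pulse_start,pulse_duration Pulse window (hours).
#' @param pulse_variable Which rate equation receives the pulse (`"P"` or
#'   `"R"`).
#' @return A `dde_protocol` list.
#' @export
dde_protocol <- function(kind = c("none", "square", "pulse"), z = 0, T = 24,
                         photoperiod = 0.5, jetlag_day = NA,
                         jetlag_shift = 6, pulse_start = 0,
                         pulse_duration = 9, pulse_variable = c("P", "R")) {
  kind <- match.arg(kind)
  pulse_variable <- match.arg(pulse_variable)
  assert_scalar_num(z, "z", nonneg = TRUE)
  structure(list(kind = kind, z = z, T = T, photoperiod = photoperiod,
                 jetlag_day = jetlag_day, jetlag_shift = jetlag_shift,
                 pulse_start = pulse_start, pulse_duration = pulse_duration,
                 pulse_variable = pulse_variable),
            class = "dde_protocol")
}

# Additive light term at time t. The jet-lag advance moves the whole
# schedule earlier by `jetlag_shift` hours from the shift instant on.
dde_zeitgeber <- function(protocol, t) {
  if (protocol$kind == "none" || protocol$z == 0) return(0)
  if (protocol$kind == "pulse") {
    on <- t >= protocol$pulse_start &&
      t < protocol$pulse_start + protocol$pulse_duration
    return(if (on) protocol$z else 0)
  }
  tt <- t
  if (is.finite(protocol$jetlag_day) && t >= protocol$jetlag_day * 24) {
    tt <- t + protocol$jetlag_shift
  }
  on <- (tt %% protocol$T) < protocol$photoperiod * protocol$T
  if (on) protocol$z else 0
}

#' Delay-free steady state of the single-gene Per loop
#'
#' Root of `(v_P/(k_P + P))^2 = d_P * P`.
#'
#' @param params A [three_gene_params()] (only `v_p`, `k_p`, `d_p` used).
#' @return Steady-state `P` (a.u.).
#' @export
single_gene_steady_state <- function(params) {
  f <- function(P) (params$v_p / (params$k_p + P))^2 - params$d_p * P
  upper <- (params$v_p / params$k_p)^2 / params$d_p + 1
  uniroot(f, c(0, upper), tol = 1e-12)$root
}

# Delay-free steady state of the full circuit (delays collapse to the
# instantaneous values): fixed-point iteration with damping, refined by a
# final squared-residual polish.
three_gene_steady_state <- function(params) {
  p <- params
  P <- single_gene_steady_state(p); B <- 1; R <- 1
  for (i in 1:500) {
    Rn <- ((p$v_r + p$b_r * B) / (p$k_r + B))^3 * (p$c_r / (P + p$c_r))^3 / p$d_r
    Bn <- (p$v_b / (p$k_b + Rn))^2 / p$d_b
    Pn <- uniroot(function(x) {
      (p$v_p / (p$k_p + x))^2 * ((p$c_p + p$b_p * Bn) / (p$c_p + Bn))^2 -
        p$d_p * x
    }, c(0, 1e6), tol = 1e-12)$root
    if (max(abs(c(Pn - P, Bn - B, Rn - R))) < 1e-12) {
      P <- Pn; B <- Bn; R <- Rn; break
    }
    P <- 0.5 * P + 0.5 * Pn
    B <- 0.5 * B + 0.5 * Bn
    R <- 0.5 * R + 0.5 * Rn
  }
  c(P = P, B = B, R = R)
}

#' Integrate the single-gene Per loop
#'
#' Delay integration by deSolve's method of steps (`dede`), constant history
#' at the delay-free steady state unless supplied.
#'
#' @param params A [three_gene_params()].
#' @param protocol A [dde_protocol()].
#' @param t_end End time (hours).
#' @param dt_out Output step (hours, default 0.01).
#' @param rtol,atol Integrator relative/absolute tolerances (defaults 1e-6,
#'   1e-9).
#' @param history Constant history value on `[-T_P, 0]`; `NULL` uses the
#'   delay-free steady state raised by 20% (the steady state itself is an
#'   unstable equilibrium of the delay equation, so an exact start there
#'   never leaves it). Must be non-negative.
#' @return Tibble `time_h`, `value` (P), `zeitgeber` (additive light term).
#' @export
integrate_single_gene <- function(params, protocol = dde_protocol("none"),
                                  t_end = 480, dt_out = 0.01,
                                  history = NULL, rtol = 1e-6,
                                  atol = 1e-9) {
  history <- history %||% (1.2 * single_gene_steady_state(params))
  if (history < 0) abort("History must be non-negative.")
  p <- params
  deriv <- function(t, y, parms) {
    Plag <- if (t - p$delay_p <= 0) history else deSolve::lagvalue(t - p$delay_p)
    dP <- (p$v_p / (p$k_p + Plag))^2 - p$d_p * y[1] + dde_zeitgeber(protocol, t)
    list(dP)
  }
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::dede(y = history, times = times, func = deriv,
                       parms = NULL, rtol = rtol, atol = atol,
                       control = list(mxhist = 1e5))
  tibble(time_h = sol[, 1], value = sol[, 2],
         zeitgeber = vapply(sol[, 1], function(t) dde_zeitgeber(protocol, t),
                            numeric(1)))
}

#' Integrate the three-gene circuit
#'
#' @inheritParams integrate_single_gene
#' @param history Named vector `c(P=, B=, R=)` of constant history values;
#'   `NULL` uses the delay-free steady state with `P` raised by 20% (an
#'   exact start on the unstable equilibrium never leaves it).
#' @return A `gene_trajectory` tibble `time_h`, `P`, `B`, `R`,
#'   `zeitgeber`.
#' @export
integrate_three_gene <- function(params, protocol = dde_protocol("none"),
                                 t_end = 480, dt_out = 0.01,
                                 history = NULL, rtol = 1e-6,
                                 atol = 1e-9) {
  history <- history %||% (three_gene_steady_state(params) * c(1.2, 1, 1))
  if (any(history < 0)) abort("History must be non-negative.")
  p <- params
  pulse_on_R <- protocol$kind == "pulse" && protocol$pulse_variable == "R"
  deriv <- function(t, y, parms) {
    Plag <- if (t - p$delay_p <= 0) history[["P"]] else
      deSolve::lagvalue(t - p$delay_p, 1)
    Blag <- if (t - p$delay_b <= 0) history[["B"]] else
      deSolve::lagvalue(t - p$delay_b, 2)
    Rlag <- if (t - p$delay_r <= 0) history[["R"]] else
      deSolve::lagvalue(t - p$delay_r, 3)
    zg <- dde_zeitgeber(protocol, t)
    dP <- (p$v_p / (p$k_p + Plag))^2 *
      ((p$c_p + p$b_p * Blag) / (p$c_p + Blag))^2 - p$d_p * y[1] +
      (if (pulse_on_R) 0 else zg)
    dB <- (p$v_b / (p$k_b + Rlag))^2 - p$d_b * y[2]
    dR <- ((p$v_r + p$b_r * Blag) / (p$k_r + Blag))^3 *
      (p$c_r / (Plag + p$c_r))^3 - p$d_r * y[3] +
      (if (pulse_on_R) zg else 0)
    list(c(dP, dB, dR))
  }
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::dede(y = unname(history[c("P", "B", "R")]), times = times,
                       func = deriv, parms = NULL, rtol = rtol, atol = atol,
                       control = list(mxhist = 1e6))
  out <- tibble(time_h = sol[, 1], P = sol[, 2], B = sol[, 3], R = sol[, 4],
                zeitgeber = vapply(sol[, 1],
                                   function(t) dde_zeitgeber(protocol, t),
                                   numeric(1)))
  class(out) <- c("gene_trajectory", class(out))
  out
}

#' Free-running period of the three-gene circuit
#'
#' @param params A [three_gene_params()].
#' @param burn_cycles Cycles discarded as transient (default 10).
#' @param measure_cycles Cycles used for the estimate (default 10).
#' @param dt_out Output step (hours).
#' @return Mean peak-to-peak period of P (hours).
#' @export
free_running_period <- function(params, burn_cycles = 10,
                                measure_cycles = 10, dt_out = 0.05) {
  t_end <- (burn_cycles + measure_cycles + 2) * 24
  traj <- integrate_three_gene(params, dde_protocol("none"), t_end = t_end,
                               dt_out = dt_out)
  pk <- find_acrophases(tibble(time_h = traj$time_h, value = traj$P),
                        min_period = 20)
  pk <- pk$peak_time_h[pk$peak_time_h > burn_cycles * 24]
  if (length(pk) < 3) abort("Too few cycles to estimate a period.")
  mean(diff(pk))
}

# Acrophases of one gene from a trajectory (local maxima, quadratic refine).
gene_acrophases <- function(traj, gene, min_period = 20) {
  find_acrophases(tibble(time_h = traj$time_h, value = traj[[gene]]),
                  min_period = min_period)$peak_time_h
}

#' Jet-lag response of the gene circuits
#'
#' Entrains the circuit under square-wave LD cycles, advances the schedule
#' by `jetlag_shift` hours at `jetlag_day`, and returns per-gene per-cycle
#' acrophase shifts relative to the pre-shift entrained phase (positive =
#' advance).
#'
#' @param params A [three_gene_params()].
#' @param protocol A [dde_protocol()] of kind `"square"` with a finite
#'   `jetlag_day`.
#' @param model `"three_gene"` (default) or `"single_gene"`.
#' @param n_post Days recorded after the shift (default 25).
#' @param dt_out Output step (hours).
#' @return Tibble `day`, `shift_p_h` and, for the three-gene model,
#'   `shift_b_h`, `shift_r_h`; attribute `entrained` reports the pre-shift
#'   drift check (< 0.05 h over 10 cycles, tested within 30 cycles).
#' @export
simulate_jetlag_dde <- function(params, protocol, model = c("three_gene",
                                                            "single_gene"),
                                n_post = 25, dt_out = 0.05) {
  model <- match.arg(model)
  stopifnot(protocol$kind == "square", is.finite(protocol$jetlag_day))
  t_shift <- protocol$jetlag_day * 24
  if (t_shift < 12 * protocol$T) {
    abort("Place the jet-lag after at least 12 entrainment cycles.")
  }
  t_end <- t_shift + n_post * 24
  if (model == "single_gene") {
    ts <- integrate_single_gene(params, protocol, t_end = t_end,
                                dt_out = dt_out)
    traj <- tibble(time_h = ts$time_h, P = ts$value)
    genes <- "P"
  } else {
    traj <- integrate_three_gene(params, protocol, t_end = t_end,
                                 dt_out = dt_out)
    genes <- c("P", "B", "R")
  }
  curves <- purrr::map(genes, function(g) {
    pk <- gene_acrophases(traj, g)
    acrophase_shift_curve(pk, protocol$T, t_shift, protocol$jetlag_shift)
  })
  names(curves) <- genes
  pre <- curves$P[curves$P$day < 0, ]
  drift <- diff(range(tail(pre$shift_h, 10)))
  if (!is.finite(drift) || drift > 0.05) {
    abort("Entrainment not reached before the jet-lag (acrophase drift >= 0.05 h).")
  }
  out <- tibble(day = curves$P$day, shift_p_h = curves$P$shift_h)
  if (model == "three_gene") {
    out$shift_b_h <- approx(curves$B$day, curves$B$shift_h, xout = out$day,
                            rule = 2)$y
    out$shift_r_h <- approx(curves$R$day, curves$R$shift_h, xout = out$day,
                            rule = 2)$y
  }
  attr(out, "entrained") <- TRUE
  out
}

# Control-referenced per-cycle phase shifts after a pulse: each pulsed
# acrophase is compared with the nearest control acrophase (advance
# positive). Using actual control peaks, rather than an extrapolated
# periodic grid, cancels any residual limit-cycle transient shared by the
# two runs; shifts are unambiguous up to half a cycle.
pulse_shift_curve <- function(pulsed_peaks, control_peaks, pulse_start) {
  post <- pulsed_peaks[pulsed_peaks > pulse_start]
  shift <- vapply(post, function(p) {
    control_peaks[which.min(abs(control_peaks - p))] - p
  }, numeric(1))
  tibble(cycle = seq_along(post), day = (post - pulse_start) / 24,
         shift_h = shift)
}

#' Light-pulse response of the three-gene circuit
#'
#' Lets the circuit free-run to its limit cycle, applies a rectangular
#' additive pulse on `dP/dt` a fixed offset after a Per acrophase, and
#' compares the pulsed trajectory with an unpulsed control.
#'
#' @param params A [three_gene_params()].
#' @param z Pulse intensity (default 0.45 a.u./h).
#' @param pulse_duration Pulse length (hours, default 9).
#' @param offset_after_per_peak Pulse onset relative to the chosen Per
#'   acrophase (hours, default 2.3).
#' @param burn_cycles Free-run cycles before the pulse anchor (default 15).
#' @param post_days Days recorded after the pulse (default 30).
#' @param dt_out Output step (hours).
#' @return List with `trajectory` (pulsed run), `control`, `pulse_start`,
#'   and `shifts`, a tibble `gene`, `cycle`, `day`, `shift_h` of per-cycle
#'   acrophase shifts of P and B (positive = advance).
#' @export
simulate_light_pulse <- function(params, z = 0.45, pulse_duration = 9,
                                 offset_after_per_peak = 2.3,
                                 burn_cycles = 15, post_days = 30,
                                 dt_out = 0.05) {
  t_anchor <- burn_cycles * 24
  t_end <- t_anchor + (post_days + 4) * 24
  control <- integrate_three_gene(params, dde_protocol("none"),
                                  t_end = t_end, dt_out = dt_out)
  cpeaks <- gene_acrophases(control, "P")
  anchor <- max(cpeaks[cpeaks <= t_anchor])
  pulse_start <- anchor + offset_after_per_peak
  prot <- dde_protocol("pulse", z = z, pulse_start = pulse_start,
                       pulse_duration = pulse_duration, pulse_variable = "P")
  pulsed <- integrate_three_gene(params, prot, t_end = t_end,
                                 dt_out = dt_out)
  shifts <- purrr::map_dfr(c("P", "B"), function(g) {
    pc <- gene_acrophases(control, g)
    pp <- gene_acrophases(pulsed, g)
    dplyr::mutate(pulse_shift_curve(pp, pc, pulse_start), gene = g,
                  .before = 1)
  })
  list(trajectory = pulsed, control = control, pulse_start = pulse_start,
       shifts = shifts)
}

#' Phase response curve of the three-gene circuit
#'
#' For `n_phases` equally spaced pulse onsets across one free-running cycle,
#' applies a rectangular additive pulse on the stated variable and measures
#' the asymptotic phase shift against an unpulsed control (mean over the
#' last 5 recorded cycles, wrapped into half a period, advance positive).
#'
#' @param params A [three_gene_params()].
#' @param variable `"P"` or `"R"` (which rate equation receives the pulse).
#' @param z Pulse intensity (a.u./h).
#' @param pulse_duration Pulse length (hours, default 9).
#' @param n_phases Number of pulse onsets across the cycle (default 8).
#' @param burn_cycles Free-run cycles before the first onset (default 12).
#' @param post_days Days integrated after each pulse (default 25).
#' @param dt_out Output step (hours).
#' @return A `prc` tibble `pulse_phase_h` (onset after the reference Per
#'   acrophase) and `shift_h`.
#' @export
phase_response_curve <- function(params, variable = c("P", "R"), z = 0.43,
                                 pulse_duration = 9, n_phases = 8,
                                 burn_cycles = 12, post_days = 25,
                                 dt_out = 0.05) {
  variable <- match.arg(variable)
  t_anchor <- burn_cycles * 24
  t_end <- t_anchor + (post_days + 4) * 24
  control <- integrate_three_gene(params, dde_protocol("none"),
                                  t_end = t_end, dt_out = dt_out)
  cpeaks <- gene_acrophases(control, "P")
  anchor <- max(cpeaks[cpeaks <= t_anchor])
  tau <- mean(diff(cpeaks))
  phases <- seq(0, tau, length.out = n_phases + 1)[seq_len(n_phases)]
  shifts <- purrr::map_dbl(phases, function(ph) {
    prot <- dde_protocol("pulse", z = z, pulse_start = anchor + ph,
                         pulse_duration = pulse_duration,
                         pulse_variable = variable)
    pulsed <- integrate_three_gene(params, prot, t_end = t_end,
                                   dt_out = dt_out)
    sc <- pulse_shift_curve(gene_acrophases(pulsed, "P"), cpeaks,
                            anchor + ph)
    mean(tail(sc$shift_h, 5))
  })
  out <- tibble(pulse_phase_h = phases, shift_h = shifts)
  class(out) <- c("prc", class(out))
  out
}

#' Re-entrainment time from an acrophase-shift curve
#'
#' @param shifts Numeric vector of per-cycle shifts (hours), ordered in
#'   time.
#' @param target Target asymptotic shift (hours).
#' @param tolerance Convergence band as a fraction of `|target|`
#'   (default 0.1).
#' @param days Optional day stamps matching `shifts`; defaults to the cycle
#'   index.
#' @return First day after which the shift stays within the band for the
#'   rest of the record; `NA` (with a warning) when it never converges.
#' @export
reentrainment_time <- function(shifts, target, tolerance = 0.1,
                               days = seq_along(shifts) - 1) {
  band <- tolerance * abs(target)
  ok <- abs(shifts - target) <= band
  stays <- rev(cumprod(rev(ok))) == 1
  if (!any(stays)) {
    warn("Shift curve never settles into the convergence band.")
    return(NA_real_)
  }
  days[which(stays)[1]]
}
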