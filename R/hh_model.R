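#' Hodgkin-Huxley model parameters
#'
#' Constructs the parameter set of the single-compartment Hodgkin-Huxley
#' model in SI surface units (volts, A/cm^2, S/cm^2, F/cm^2). Defaults are
#' the classical squid-axon constants evaluated at 18.5 degrees C, the
#' configuration used to study how specific membrane capacitance limits
#' fast-spiking interneuron firing.
#'
#' @param Vr resting membrane potential (V).
#' @param E_Na,E_K,E_l sodium, potassium and leak reversal potentials (V).
#' @param Cm_specific specific membrane capacitance (F/cm^2).
#' @param G_K,G_Na,G_l maximal potassium, sodium and leak conductances
#'   (S/cm^2).
#' @param J_ext externally applied current density (A/cm^2).
#' @param T temperature (degrees C); all gating rates are scaled by
#'   `temperature_factor(T)`.
#' @param transposed_gates logical; if `TRUE` the potassium conductance uses
#'   m^4 and the sodium conductance n^3 h (a non-canonical gate assignment
#'   retained for comparison). Default `FALSE` uses the canonical
#'   g_K = G_K n^4, g_Na = G_Na m^3 h.
#'
#' @return An object of class `hh_params`.
#' @examples
#' p <- hh_params()
#' steady_state_gates(p$Vr, p)
#' @export
hh_params <- function(Vr = -0.065, E_Na = 0.050, E_K = -0.077, E_l = -0.0544,
                      Cm_specific = 1e-6, G_K = 36e-3, G_Na = 120e-3,
                      G_l = 0.3e-3, J_ext = 0.2e-4, T = 18.5,
                      transposed_gates = FALSE) {
  stopifnot(is.finite(Vr), is.finite(T), is.finite(J_ext))
  if (Cm_specific <= 0) stop("Cm_specific must be > 0")
  if (G_K <= 0 || G_Na <= 0 || G_l <= 0) stop("all conductances must be > 0")
  structure(list(Vr = Vr, E_Na = E_Na, E_K = E_K, E_l = E_l,
                 Cm_specific = Cm_specific, G_K = G_K, G_Na = G_Na, G_l = G_l,
                 J_ext = J_ext, T = T,
                 transposed_gates = isTRUE(transposed_gates)),
            class = "hh_params")
}

#' @export
print.hh_params <- function(x, ...) {
  cat("Hodgkin-Huxley parameters (single compartment)\n")
  cat(sprintf("  Vr = %g mV, E_Na = %g mV, E_K = %g mV, E_l = %g mV\n",
              x$Vr * 1e3, x$E_Na * 1e3, x$E_K * 1e3, x$E_l * 1e3))
  cat(sprintf("  Cm = %g uF/cm^2, G_K = %g, G_Na = %g, G_l = %g mS/cm^2\n",
              x$Cm_specific * 1e6, x$G_K * 1e3, x$G_Na * 1e3, x$G_l * 1e3))
  cat(sprintf("  J_ext = %g A/cm^2, T = %g C (phi = %.4f)%s\n",
              x$J_ext, x$T, temperature_factor(x$T),
              if (x$transposed_gates) ", transposed gates" else ""))
  invisible(x)
}

# parameter vector handed to the compiled integrator
.hh_par_vec <- function(p) {
  c(p$Vr, p$E_Na, p$E_K, p$E_l, p$Cm_specific, p$G_K, p$G_Na, p$G_l,
    p$J_ext, temperature_factor(p$T))
}

#' Temperature scaling factor for channel kinetics
#'
#' All six channel transition rates are multiplied by
#' phi = 3^((T - 6.3) / 10), a Q10 of 3 referenced to the 6.3 degrees C of
#' the original squid-axon measurements.
#'
#' @param T temperature (degrees C).
#' @return The dimensionless factor phi.
#' @examples
#' temperature_factor(6.3)   # 1
#' temperature_factor(18.5)  # ~3.82
#' @export
temperature_factor <- function(T) {
  stopifnot(is.finite(T))
  3^((T - 6.3) / 10)
}

#' Channel gating transition rates
#'
#' Evaluates the six voltage-dependent opening (alpha) and closing (beta)
#' rates of the n, m and h gates at membrane potential `V`, each scaled by
#' the temperature factor phi. Rates are expressed in 1/ms as functions of
#' the depolarization dV = (V - Vr) * 1000 in mV. The removable
#' singularities of alpha_n (dV = 10) and alpha_m (dV = 25) are replaced by
#' their analytic limits when the denominator magnitude falls below 1e-12.
#'
#' @param V membrane potential (V); may be a vector.
#' @param params an [hh_params()] object.
#' @return A list with components `alpha_n`, `beta_n`, `alpha_m`, `beta_m`,
#'   `alpha_h`, `beta_h` (1/ms), vectorized over `V`.
#' @export
gating_rates <- function(V, params = hh_params()) {
  stopifnot(all(is.finite(V)))
  phi <- temperature_factor(params$T)
  dV <- (V - params$Vr) * 1000

  ratio_lim <- function(num, den, limit) {
    out <- ifelse(abs(den) < 1e-12, limit, num / den)
    out
  }
  alpha_n <- phi * ratio_lim(0.10 - 0.01 * dV, exp(1 - 0.1 * dV) - 1, 0.1)
  beta_n  <- phi * 0.125 * exp(-dV / 80)
  alpha_m <- phi * ratio_lim(2.5 - 0.1 * dV, exp(2.5 - 0.1 * dV) - 1, 1.0)
  beta_m  <- phi * 4 * exp(-dV / 18)
  alpha_h <- phi * 0.07 * exp(-dV / 20)
  beta_h  <- phi / (exp(3.0 - 0.1 * dV) + 1)
  list(alpha_n = alpha_n, beta_n = beta_n,
       alpha_m = alpha_m, beta_m = beta_m,
       alpha_h = alpha_h, beta_h = beta_h)
}

#' Steady-state gating values
#'
#' The voltage-dependent equilibrium of each gate,
#' x_inf = alpha_x / (alpha_x + beta_x). The temperature factor cancels, so
#' the result is independent of `params$T`. At the resting potential of
#' -65 mV this returns (0.3177, 0.0529, 0.5961), the standard initial
#' condition of the model.
#'
#' @inheritParams gating_rates
#' @return A list with components `n`, `m`, `h`, vectorized over `V`.
#' @export
steady_state_gates <- function(V, params = hh_params()) {
  r <- gating_rates(V, params)
  list(n = r$alpha_n / (r$alpha_n + r$beta_n),
       m = r$alpha_m / (r$alpha_m + r$beta_m),
       h = r$alpha_h / (r$alpha_h + r$beta_h))
}

#' Time derivative of the Hodgkin-Huxley state
#'
#' Evaluates the right-hand side of the model: the membrane equation
#' dV/dt = (J_ext - J_Na - J_K - J_leak) / Cm with J_Na = G_Na m^3 h
#' (V - E_Na), J_K = G_K n^4 (V - E_K) and J_leak = G_l (V - E_l), plus the
#' three first-order gate relaxations dx/dt = alpha_x (1 - x) - beta_x x.
#'
#' @param state named list or vector with elements `V` (volts), `n`, `m`,
#'   `h`.
#' @param params an [hh_params()] object.
#' @return A list with `dV` (V/s) and `dn`, `dm`, `dh` (1/ms).
#' @export
hh_derivative <- function(state, params = hh_params()) {
  s <- as.list(state)
  stopifnot(s$n >= 0, s$n <= 1, s$m >= 0, s$m <= 1, s$h >= 0, s$h <= 1)
  r <- gating_rates(s$V, params)
  if (params$transposed_gates) {
    gK  <- params$G_K  * s$m^4
    gNa <- params$G_Na * s$n^3 * s$h
  } else {
    gK  <- params$G_K  * s$n^4
    gNa <- params$G_Na * s$m^3 * s$h
  }
  J_ion <- gNa * (s$V - params$E_Na) + gK * (s$V - params$E_K) +
    params$G_l * (s$V - params$E_l)
  list(dV = (params$J_ext - J_ion) / params$Cm_specific,
       dn = r$alpha_n * (1 - s$n) - r$beta_n * s$n,
       dm = r$alpha_m * (1 - s$m) - r$beta_m * s$m,
       dh = r$alpha_h * (1 - s$h) - r$beta_h * s$h)
}

#' Default initial state
#'
#' The resting state (-65 mV, n = 0.3177, m = 0.0529, h = 0.5961): the
#' steady-state gate values at rest, rounded to 4 decimals.
#'
#' @return Named numeric vector `c(V, n, m, h)`.
#' @export
hh_initial_state <- function() {
  c(V = -0.065, n = 0.3177, m = 0.0529, h = 0.5961)
}

#' Simulate the Hodgkin-Huxley model by forward Euler
#'
#' First-order (forward Euler) integration at a fixed step, by default 1
#' microsecond over 1 s. Gating variables are clipped to \[0, 1\] only when
#' the overshoot is below 1e-9; larger excursions or a non-finite membrane
#' potential abort with an error naming the offending step.
#'
#' @param params an [hh_params()] object.
#' @param initial numeric vector `c(V, n, m, h)`; default
#'   [hh_initial_state()].
#' @param duration simulated time (s).
#' @param dt integration step (s).
#' @param keep_gates logical; also record the gate trajectories.
#' @return An object of class `hh_trace`: list with `t` (s), `v` (V),
#'   optionally `n`, `m`, `h`, plus `dt`, `duration` and the parameters.
#' @examples
#' p <- hh_params(J_ext = 0.2e-4)
#' tr <- hh_simulate(p, duration = 0.05)
#' count_spikes_hh(tr)
#' @export
hh_simulate <- function(params = hh_params(), initial = hh_initial_state(),
                        duration = 1.0, dt = 1e-6, keep_gates = FALSE) {
  stopifnot(dt > 0, duration >= dt, length(initial) == 4)
  res <- .hh_euler_cpp(.hh_par_vec(params), as.numeric(initial), duration, dt,
                       params$transposed_gates, keep_gates)
  n <- length(res$v)
  out <- list(t = seq(0, by = dt, length.out = n), v = res$v,
              dt = dt, duration = duration, params = params)
  if (keep_gates) out[c("n", "m", "h")] <- res[c("n", "m", "h")]
  structure(out, class = "hh_trace")
}

#' @export
print.hh_trace <- function(x, ...) {
  cat(sprintf("HH trace: %d samples, dt = %g us, duration = %g ms\n",
              length(x$v), x$dt * 1e6, x$duration * 1e3))
  cat(sprintf("  V range [%.1f, %.1f] mV, %d spikes (> +20 mV peaks)\n",
              min(x$v) * 1e3, max(x$v) * 1e3, count_spikes_hh(x)))
  invisible(x)
}

#' Count action potentials in a simulated voltage trace
#'
#' A spike is a strict local maximum of the membrane potential exceeding
#' the threshold; flat-topped plateaus are counted once. With a 1000 ms
#' simulation the count equals the firing rate in Hz. By default the
#' 20 mV threshold is referenced to the resting potential - peaks count
#' when the depolarization dV = (V - Vr) x 1000 exceeds +20 mV - because
#' at the model's working temperature (18.5 C, phi = 3.82) action
#' potentials peak near +12 mV absolute, well short of an absolute +20 mV
#' criterion, while their rest-relative amplitude is ~77 mV. Set
#' `reference = "absolute"` for a threshold on the raw membrane potential.
#'
#' @param trace an `hh_trace` or a numeric voltage vector (V).
#' @param threshold peak threshold (V above the reference).
#' @param reference `"rest"` (default; threshold added to `Vr`) or
#'   `"absolute"`.
#' @param Vr resting potential (V) used when `reference = "rest"` and
#'   `trace` is a plain vector; ignored for an `hh_trace`, which carries
#'   its own parameters.
#' @return Integer spike count.
#' @export
count_spikes_hh <- function(trace, threshold = 0.020,
                            reference = c("rest", "absolute"), Vr = -0.065) {
  reference <- match.arg(reference)
  if (inherits(trace, "hh_trace")) Vr <- trace$params$Vr
  if (reference == "rest") threshold <- Vr + threshold
  v <- if (inherits(trace, "hh_trace")) trace$v else as.numeric(trace)
  stopifnot(all(is.finite(v)))
  if (length(v) < 3) return(0L)
  s <- sign(diff(v))
  nz <- which(s != 0)          # skipping zero-slopes counts plateaus once
  if (length(nz) < 2) return(0L)
  sn <- s[nz]
  k <- which(sn[-length(sn)] == 1 & sn[-1] == -1)
  if (!length(k)) return(0L)
  peaks <- v[nz[k] + 1]
  sum(peaks > threshold)
}

#' Firing-rate surface over capacitance and external current
#'
#' Simulates the model over a grid of specific membrane capacitances and
#' applied current densities and counts spikes in each run. Defaults
#' reproduce the published sweep: capacitance from 0.8 to 1.5 uF/cm^2 in
#' 0.01 steps (71 points) and current densities spanning 0.2e-4 to
#' 1.4e-2 A/cm^2.
#'
#' @param params an [hh_params()] object (its `Cm_specific` and `J_ext` are
#'   overridden by the grids).
#' @param cm_grid strictly increasing capacitance grid (F/cm^2).
#' @param jext_grid strictly increasing current-density grid (A/cm^2).
#' @param duration,dt simulation length and Euler step (s).
#' @param n_jext number of current points when `jext_grid` is not given.
#' @param threshold,reference spike-count threshold, see
#'   [count_spikes_hh()].
#' @return An object of class `firing_surface`: list with `cm_grid`,
#'   `jext_grid` and integer `rate` matrix (spikes per simulation,
#'   `length(cm_grid)` x `length(jext_grid)`).
#' @export
sweep_firing_surface <- function(params = hh_params(),
                                 cm_grid = seq(0.8e-6, 1.5e-6, by = 0.01e-6),
                                 jext_grid = NULL,
                                 duration = 1.0, dt = 1e-6, n_jext = 100,
                                 threshold = 0.020,
                                 reference = c("rest", "absolute")) {
  reference <- match.arg(reference)
  if (is.null(jext_grid)) jext_grid <- seq(0.2e-4, 1.4e-2, length.out = n_jext)
  stopifnot(all(diff(cm_grid) > 0), all(diff(jext_grid) > 0))
  thr <- if (reference == "rest") params$Vr + threshold else threshold
  rate <- .hh_sweep_cpp(.hh_par_vec(params), hh_initial_state(),
                        cm_grid, jext_grid, duration, dt,
                        params$transposed_gates, thr)
  structure(list(cm_grid = cm_grid, jext_grid = jext_grid, rate = rate,
                 duration = duration),
            class = "firing_surface")
}

#' @export
print.firing_surface <- function(x, ...) {
  cat(sprintf("Firing surface: %d Cm x %d J_ext points, max %d spikes/%g ms\n",
              length(x$cm_grid), length(x$jext_grid), max(x$rate),
              x$duration * 1e3))
  invisible(x)
}

#' Percent change in firing rate between two capacitances
#'
#' Reads (or linearly interpolates along Cm) the firing rate at a fixed
#' current density for a baseline and a scaled capacitance and returns
#' 100 * (rate_base - rate_scaled) / rate_base, so a positive value is a
#' firing-rate decrease. Raising the capacitance by the empirically observed
#' ~25% lowers the model's maximal rate by about 10%.
#'
#' @param surface a `firing_surface`.
#' @param cm_base,cm_scaled capacitances to compare (F/cm^2).
#' @param jext current density (A/cm^2); must be one of the grid points.
#' @return Percent decrease in firing rate (positive = slower firing).
#' @export
capacitance_effect <- function(surface, cm_base, cm_scaled, jext) {
  j <- which(abs(surface$jext_grid - jext) < 1e-12 * max(abs(surface$jext_grid)))
  if (length(j) != 1)
    stop("jext is not a grid point of the surface")
  rate_at <- function(cm) {
    col <- surface$rate[, j]
    if (cm < min(surface$cm_grid) || cm > max(surface$cm_grid))
      stop("cm outside the surface grid")
    approx(surface$cm_grid, col, xout = cm)$y
  }
  r0 <- rate_at(cm_base)
  r1 <- rate_at(cm_scaled)
  if (r0 == 0) stop("baseline firing rate is zero: effect undefined")
  100 * (r0 - r1) / r0
}
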