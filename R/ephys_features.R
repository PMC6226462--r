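#' Current-clamp step recording set
#'
#' Container for a current-step protocol: one voltage trace per injected
#' current, with shared timing metadata. The standard protocols are 15
#' hyperpolarizing steps of -100 pA (passive properties) and an ascending
#' series from -100 to 180 pA in 20 pA increments (input-output curve),
#' each step lasting 1000 ms.
#'
#' @param traces list of numeric voltage vectors (mV), one per step.
#' @param i_pa numeric vector of injected currents (pA), one per trace.
#' @param rate_khz sampling rate (kHz).
#' @param onset_ms time of step onset (ms from trace start).
#' @param step_ms step duration (ms).
#' @param meta optional list of extra metadata (e.g. generator ground
#'   truth).
#' @return An object of class `step_recording`.
#' @export
step_recording <- function(traces, i_pa, rate_khz = 10, onset_ms = 200,
                           step_ms = 1000, meta = list()) {
  stopifnot(is.list(traces), length(traces) == length(i_pa), rate_khz > 0,
            onset_ms > 0, step_ms > 0)
  structure(list(traces = traces, i_pa = as.numeric(i_pa),
                 rate_khz = rate_khz, onset_ms = onset_ms, step_ms = step_ms,
                 meta = meta),
            class = "step_recording")
}

#' @export
print.step_recording <- function(x, ...) {
  cat(sprintf("Current-step recording: %d steps (%g..%g pA), %g kHz, onset %g ms, step %g ms\n",
              length(x$traces), min(x$i_pa), max(x$i_pa), x$rate_khz,
              x$onset_ms, x$step_ms))
  invisible(x)
}

.time_ms <- function(rec, trace) (seq_along(trace) - 1) / rec$rate_khz

.step_window <- function(rec, trace) {
  t <- .time_ms(rec, trace)
  which(t >= rec$onset_ms & t < rec$onset_ms + rec$step_ms)
}

.baseline_window <- function(rec, trace) {
  t <- .time_ms(rec, trace)
  which(t < rec$onset_ms)
}

#' Resting membrane potential
#'
#' Mean of a zero-current baseline recording, stored signed (e.g. -65 mV).
#' Requires at least 100 ms of baseline; a drift larger than 5 mV between
#' the first and last fifth of the baseline raises an instability warning.
#'
#' @param v numeric voltage vector (mV) recorded at I = 0, or a
#'   `step_recording` whose pre-step baselines are pooled.
#' @param rate_khz sampling rate (kHz) when `v` is a plain vector.
#' @return Vm (mV, signed) with attribute `unstable` (logical).
#' @export
resting_potential <- function(v, rate_khz = 10) {
  if (inherits(v, "step_recording")) {
    rec <- v
    v <- unlist(lapply(rec$traces, function(tr) tr[.baseline_window(rec, tr)]))
    rate_khz <- rec$rate_khz
  }
  stopifnot(length(v) >= 100 * rate_khz)
  k <- max(1L, length(v) %/% 5)
  drift <- abs(mean(head(v, k)) - mean(tail(v, k)))
  out <- mean(v)
  attr(out, "unstable") <- drift > 5
  if (drift > 5) warning(sprintf("baseline drift %.2f mV exceeds 5 mV", drift))
  out
}

.steady_state_dv <- function(rec) {
  # steady-state deflection per step: mean of last 20% of the step minus
  # the pre-step baseline
  vapply(seq_along(rec$traces), function(i) {
    tr <- rec$traces[[i]]
    w <- .step_window(rec, tr)
    b <- .baseline_window(rec, tr)
    ss <- w[w >= w[1] + ceiling(0.8 * length(w))]
    mean(tr[ss]) - mean(tr[b])
  }, numeric(1))
}

#' Input resistance from hyperpolarizing steps
#'
#' Rin = mean steady-state voltage deflection / |I| across repeated equal
#' hyperpolarizing steps (nominally 15 steps of -100 pA). The steady state
#' is the mean over the last 20% of the step. A depolarizing step or a
#' spike-contaminated trace (any sample more than 15 mV above baseline) is
#' an error.
#'
#' @param rec a [step_recording()] of equal hyperpolarizing steps.
#' @return Rin (MOhm).
#' @export
input_resistance <- function(rec) {
  stopifnot(inherits(rec, "step_recording"))
  if (any(rec$i_pa >= 0)) stop("input_resistance expects hyperpolarizing steps")
  if (length(unique(rec$i_pa)) != 1)
    stop("all steps must have equal amplitude")
  for (tr in rec$traces) {
    b <- mean(tr[.baseline_window(rec, tr)])
    if (any(tr > b + 15)) stop("spike detected during hyperpolarizing step")
  }
  dv <- .steady_state_dv(rec)             # mV, negative
  mean(dv / rec$i_pa) * 1000              # mV/pA = GOhm -> MOhm
}

# small-sample corrected information criterion for an nls fit
.aicc <- function(fit, n) {
  k <- length(coef(fit)) + 1
  AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Membrane time constant and capacitance from the step relaxation
#'
#' Averages all hyperpolarizing traces, then fits the voltage relaxation
#' from 1 ms after step onset to step end with mono- and bi-exponential
#' decay models. The model with the lower small-sample-corrected
#' information criterion wins (ties go to the mono fit); tau is the slowest
#' fitted time constant and Cm = tau / Rin (so pF = ms / MOhm x 1000).
#'
#' @param rec a [step_recording()] of equal hyperpolarizing steps.
#' @param Rin input resistance (MOhm); computed from `rec` if missing.
#' @return List with `tau` (ms), `Cm` (pF), `Rin` (MOhm), `model`
#'   ("mono" or "bi") and `unreliable` (TRUE when tau exceeds half the step
#'   duration).
#' @export
membrane_capacitance <- function(rec, Rin = NULL) {
  stopifnot(inherits(rec, "step_recording"))
  if (is.null(Rin)) Rin <- input_resistance(rec)
  nmin <- min(lengths(rec$traces))
  avg <- rowMeans(vapply(rec$traces, function(tr) tr[seq_len(nmin)],
                         numeric(nmin)))
  t <- (seq_len(nmin) - 1) / rec$rate_khz
  sel <- t >= rec$onset_ms + 1 & t < rec$onset_ms + rec$step_ms
  tt <- t[sel] - rec$onset_ms
  vv <- avg[sel]

  v_inf <- mean(tail(vv, max(1, length(vv) %/% 5)))
  amp <- vv[1] - v_inf
  tau0 <- tt[which.min(abs((vv - v_inf) - amp * exp(-1)))]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- rec$step_ms / 20
  d <- data.frame(t = tt, v = vv)

  mono <- tryCatch(
    minpack.lm::nlsLM(v ~ a + b * exp(-t / tau), data = d,
                      start = list(a = v_inf, b = amp, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  bi <- tryCatch(
    minpack.lm::nlsLM(v ~ a + b1 * exp(-t / tau1) + b2 * exp(-t / tau2),
                      data = d,
                      start = list(a = v_inf, b1 = amp / 2, tau1 = tau0 / 5,
                                   b2 = amp / 2, tau2 = tau0 * 1.5),
                      lower = c(-Inf, -Inf, 1e-3, -Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(mono) && is.null(bi)) {
    # fallback: log-linear mono fit on the relaxing segment
    y <- (vv - v_inf) / amp
    ok <- y > 1e-3
    fitc <- stats::lm(log(y[ok]) ~ tt[ok])
    tau <- -1 / coef(fitc)[2]
    model <- "mono"
  } else if (!is.null(mono) && (is.null(bi) ||
                                .aicc(mono, nrow(d)) <= .aicc(bi, nrow(d)))) {
    tau <- coef(mono)[["tau"]]
    model <- "mono"
  } else {
    cf <- coef(bi)
    # the slowest component must carry real amplitude (same sign as the
    # overall relaxation, non-negligible size)
    taus <- c(cf[["tau1"]], cf[["tau2"]])
    amps <- c(cf[["b1"]], cf[["b2"]])
    keep <- abs(amps) > 0.05 * abs(sum(amps))
    if (!any(keep)) keep <- rep(TRUE, 2)
    tau <- max(taus[keep])
    model <- "bi"
  }
  list(tau = tau, Cm = tau / Rin * 1000, Rin = Rin, model = model,
       unreliable = tau > rec$step_ms / 2)
}

#' Plateau (steady-state) level of a firing depolarized step
#'
#' Median of the step-window voltage after excising 2 ms on either side of
#' candidate spike peaks, iterated once: a first pass uses the raw median
#' as the reference level, the second uses the cleaned median.
#'
#' @param v voltage (mV) restricted to the step window.
#' @param rate_khz sampling rate (kHz).
#' @param min_amp candidate-peak amplitude over the running level (mV).
#' @return Plateau level (mV).
#' @export
plateau_level <- function(v, rate_khz = 10, min_amp = 15) {
  level <- median(v)
  for (pass in 1:2) {
    idx <- .local_maxima(v)
    idx <- idx[v[idx] >= level + min_amp]
    if (!length(idx)) return(median(v))
    # excise 2 ms around each candidate peak, shrinking the halo when the
    # firing is so fast that +/- 2 ms would swallow the whole inter-spike
    # interval (fast-spiking cells exceed 250 Hz)
    halo_ms <- 2
    if (length(idx) > 1)
      halo_ms <- min(2, 0.4 * median(diff(idx)) / rate_khz)
    hw <- max(1, round(halo_ms * rate_khz))
    halo <- unique(unlist(lapply(idx, function(i)
      max(1, i - hw):min(length(v), i + hw))))
    if (length(halo) >= length(v)) break
    level <- median(v[-halo])
  }
  level
}

.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

#' Detect action potentials on a depolarized step
#'
#' A spike is a strict local maximum at least 15 mV above the steady-state
#' (inter-spike plateau) level, with detected peaks at least 1 ms apart
#' (the larger peak wins within the separation window).
#'
#' @param v voltage (mV) restricted to the step window.
#' @param rate_khz sampling rate (kHz).
#' @param steady_state_level plateau level (mV); estimated with
#'   [plateau_level()] when `NULL`.
#' @param min_amp qualifying deflection above the plateau (mV).
#' @param min_sep_ms minimum peak separation (ms).
#' @return Spike times (ms from window start), with attribute `level`.
#' @export
detect_spikes <- function(v, rate_khz = 10, steady_state_level = NULL,
                          min_amp = 15, min_sep_ms = 1) {
  if (is.null(steady_state_level))
    steady_state_level <- plateau_level(v, rate_khz, min_amp)
  idx <- .local_maxima(v)
  idx <- idx[v[idx] >= steady_state_level + min_amp]
  if (length(idx) > 1) {
    keep <- .enforce_separation(idx, v[idx], min_sep_ms * rate_khz)
    idx <- idx[keep]
  }
  out <- (idx - 1) / rate_khz
  attr(out, "level") <- steady_state_level
  out
}

# greedy by height: accept peaks tallest-first, rejecting any within min_gap
# samples of an accepted one
.enforce_separation <- function(idx, height, min_gap) {
  ord <- order(height, decreasing = TRUE)
  accepted <- logical(length(idx))
  for (k in ord) {
    if (!any(accepted & abs(idx - idx[k]) < min_gap)) accepted[k] <- TRUE
  }
  accepted
}

#' Threshold (rheobase) current from short-pulse responses
#'
#' Given spike/no-spike outcomes for 10 ms pulses of 2..200 pA in 2 pA
#' increments, returns the smallest current from which every larger current
#' also elicited a spike; cells that never reach such a point are assigned
#' 200 pA.
#'
#' @param i_pa pulse amplitudes (pA).
#' @param spiked logical vector, same length.
#' @param full_range amplitudes the protocol must cover (default
#'   `seq(2, 200, by = 2)`).
#' @return Threshold current (pA).
#' @export
threshold_current <- function(i_pa, spiked, full_range = seq(2, 200, by = 2)) {
  stopifnot(length(i_pa) == length(spiked))
  if (!all(full_range %in% i_pa)) stop("protocol incomplete: missing amplitudes")
  o <- order(i_pa)
  i_pa <- i_pa[o]; spiked <- as.logical(spiked[o])
  # smallest i such that all responses at >= i spiked
  persistent <- rev(cumprod(rev(spiked))) > 0
  if (!any(persistent)) return(max(full_range))
  i_pa[which(persistent)[1]]
}

#' Input-output (f-I) curve
#'
#' Spike count per current step using [detect_spikes()] on each step
#' window. With 1000 ms steps the count equals the firing rate in Hz.
#'
#' @param rec a [step_recording()] with ascending currents.
#' @return An object of class `fi_curve`: data.frame with `i_pa` and
#'   `n_spikes`.
#' @export
input_output_curve <- function(rec) {
  stopifnot(inherits(rec, "step_recording"))
  counts <- vapply(seq_along(rec$traces), function(i) {
    tr <- rec$traces[[i]]
    if (rec$i_pa[i] <= 0) return(0L)
    w <- .step_window(rec, tr)
    length(detect_spikes(tr[w], rec$rate_khz))
  }, integer(1))
  structure(data.frame(i_pa = rec$i_pa, n_spikes = counts),
            class = c("fi_curve", "data.frame"))
}

#' Maximal firing frequency over an ascending current series
#'
#' The peak spike count (in Hz for 1000 ms steps) over an ascending series
#' extending up to 500 pA. Flags saturation (the last two increments change
#' the count by at most 2) and depolarization block (the count falls after
#' its maximum).
#'
#' @param rec a [step_recording()] with ascending currents (1000 ms steps).
#' @return List with `max_hz`, `at_pa`, `saturated`, `block`, and the
#'   underlying `fi` curve.
#' @export
max_firing_frequency <- function(rec) {
  fi <- input_output_curve(rec)
  fi <- fi[order(fi$i_pa), ]
  k <- which.max(fi$n_spikes)
  n <- nrow(fi)
  saturated <- n >= 3 && all(abs(diff(tail(fi$n_spikes, 3))) <= 2)
  block <- k < n && any(fi$n_spikes[(k + 1):n] < fi$n_spikes[k])
  list(max_hz = fi$n_spikes[k] * 1000 / rec$step_ms, at_pa = fi$i_pa[k],
       saturated = saturated, block = block, fi = fi)
}

#' Extract all intrinsic properties of one cell
#'
#' Convenience wrapper running the full measurement battery on the
#' protocols of one recorded cell.
#'
#' @param passive a [step_recording()] of 15 x -100 pA steps.
#' @param io a [step_recording()] of the -100..180 pA series.
#' @param pulses data.frame with `i_pa`, `spiked` from the 10 ms pulse
#'   protocol (optional).
#' @param baseline_v zero-current baseline voltage vector (mV; optional).
#' @param rate_khz sampling rate of `baseline_v`.
#' @return One-row data.frame of properties (NA where the protocol was not
#'   supplied).
#' @export
extract_cell_properties <- function(passive, io = NULL, pulses = NULL,
                                    baseline_v = NULL, rate_khz = 10) {
  rin <- input_resistance(passive)
  cmfit <- membrane_capacitance(passive, rin)
  vm <- if (!is.null(baseline_v)) as.numeric(resting_potential(baseline_v, rate_khz)) else
    as.numeric(resting_potential(passive))
  thr <- if (!is.null(pulses)) threshold_current(pulses$i_pa, pulses$spiked) else NA_real_
  rate140 <- if (!is.null(io)) {
    fi <- input_output_curve(io)
    if (any(fi$i_pa == 140)) fi$n_spikes[fi$i_pa == 140] else NA_real_
  } else NA_real_
  data.frame(Vm_mV = vm, Rin_MOhm = rin, tau_ms = cmfit$tau,
             Cm_pF = cmfit$Cm, fit_model = cmfit$model,
             threshold_pA = thr, rate_140pA_hz = rate140)
}
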