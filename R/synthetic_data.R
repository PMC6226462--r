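#' Synthetic-data scenarios
#'
#' The generators in this module emit every input class the analysis
#' modules consume, with the planted ground truth attached, so that each
#' analysis can be validated by parameter recovery. Scenario defaults are
#' pinned to the published group means for sham, peritumoral (PTC) and
#' excitatory cells, so scenario names double as documentation.
#'
#' @name synthetic_scenarios
#' @keywords internal
NULL

.ephys_scenarios <- list(
  sham_fsn = list(R = 252.64, Cm = 30.11, Vm = -69.85, fmax = 406.62,
                  rheobase = 40, gain = 1.13, adapt = 1, threshold = 88,
                  tau2 = NA),
  ptc_fsn = list(R = 249.10, Cm = 43.84, Vm = -61.67, fmax = 210, rheobase = 50,
                 gain = 0.75, adapt = 1, threshold = 82, tau2 = NA),
  excitatory = list(R = 298.63, Cm = 73.93, Vm = -67.02, fmax = 40,
                    rheobase = 60, gain = 0.3, adapt = 1.06, threshold = 172,
                    tau2 = NA)
)

# passive RC response to a current step (mV), t in ms from trace start
.rc_response <- function(t, vm, i_pa, r_mohm, tau_ms, onset, dur, tau2 = NA) {
  dv <- i_pa * r_mohm / 1000
  v <- rep(vm, length(t))
  on <- t >= onset & t < onset + dur
  off <- t >= onset + dur
  if (is.na(tau2)) {
    v[on] <- vm + dv * (1 - exp(-(t[on] - onset) / tau_ms))
    v[off] <- vm + dv * (1 - exp(-dur / tau_ms)) * exp(-(t[off] - onset - dur) / tau_ms)
  } else {
    # equal-amplitude bi-exponential relaxation (two-compartment-like)
    relax <- function(tt) 1 - 0.5 * exp(-tt / tau_ms) - 0.5 * exp(-tt / tau2)
    v[on] <- vm + dv * relax(t[on] - onset)
    v[off] <- vm + dv * relax(dur) * (0.5 * exp(-(t[off] - onset - dur) / tau_ms) +
                                        0.5 * exp(-(t[off] - onset - dur) / tau2))
  }
  v
}

# planted spike times (ms within the step) for a firing step
.spike_times <- function(rate_hz, dur_ms, adapt) {
  if (rate_hz <= 0) return(numeric(0))
  if (adapt <= 1) {
    isi <- 1000 / rate_hz
    times <- seq(isi / 2, dur_ms, by = isi)
  } else {
    # adapting train: ISIs grow geometrically; first ISI set so the mean
    # rate over the step stays near rate_hz
    n <- max(1, round(rate_hz * dur_ms / 1000))
    isi1 <- dur_ms * (adapt - 1) / (adapt^n - 1)
    times <- cumsum(isi1 * adapt^(0:(n - 1)))
    times <- times[times < dur_ms]
  }
  times
}

# add stereotyped spike waveforms (Gaussian, ~0.25 ms sd) to a trace
.add_spikes <- function(v, t, spike_t, amp = 40, sd_ms = 0.25) {
  for (ts in spike_t) {
    w <- which(abs(t - ts) < 5 * sd_ms)
    v[w] <- v[w] + amp * exp(-(t[w] - ts)^2 / (2 * sd_ms^2))
  }
  v
}

#' Generate a full current-clamp recording set for one synthetic cell
#'
#' Produces the three step protocols used by the intrinsic-property
#' analyses - 15 hyperpolarizing -100 pA steps (passive properties), the
#' -100..180 pA input-output series, and an ascending max-frequency series
#' up to 500 pA - plus the 10 ms threshold-pulse outcomes and a
#' zero-current baseline. The voltage is a passive RC response with a
#' phenomenological thresholded spike process on top (spikes planted at the
#' scenario's f-I rate, non-adapting for fast-spiking cells, adapting for
#' excitatory cells), plus Gaussian noise.
#'
#' Scenario passive defaults are the published sham and peritumoral group
#' means: `sham_fsn` R = 252.64 MOhm, Cm = 30.11 pF, Vm = -69.85 mV, max
#' rate 406.62 Hz; `ptc_fsn` Cm = 43.84 pF, Vm = -61.67 mV; `excitatory`
#' R = 298.63 MOhm, Cm = 73.93 pF, adapting 15-40 Hz firing.
#'
#' @param scenario one of `"sham_fsn"`, `"ptc_fsn"`, `"excitatory"`.
#' @param seed RNG seed.
#' @param noise_sd voltage noise SD (mV).
#' @param rate_khz sampling rate (kHz).
#' @param overrides named list overriding scenario parameters
#'   (`R`, `Cm`, `Vm`, `fmax`, `rheobase`, `gain`, `adapt`, `threshold`,
#'   `tau2`).
#' @return List with `passive`, `io`, `maxf` ([step_recording()]s),
#'   `pulses` (data.frame `i_pa`, `spiked`), `baseline_v`, and `truth`
#'   (the planted parameters, including per-step planted spike counts).
#' @export
gen_step_recording <- function(scenario = c("sham_fsn", "ptc_fsn", "excitatory"),
                               seed = 1, noise_sd = 0.5, rate_khz = 10,
                               overrides = list()) {
  scenario <- match.arg(scenario)
  p <- .ephys_scenarios[[scenario]]
  p[names(overrides)] <- overrides
  tau <- p$R * p$Cm / 1000  # ms
  old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)

  onset <- 200; dur <- 1000; post <- 200
  t <- seq(0, onset + dur + post - 1 / rate_khz, by = 1 / rate_khz)
  f_of_i <- function(i_pa) {
    if (i_pa <= p$rheobase) 0 else min(p$fmax, p$gain * (i_pa - p$rheobase))
  }
  noise <- function() rnorm(length(t), 0, noise_sd)

  mk_trace <- function(i_pa, with_spikes = TRUE) {
    st <- numeric(0)
    firing <- with_spikes && i_pa > 0 && f_of_i(i_pa) > 0
    # on firing steps the steady depolarization is clamped near threshold
    # by the spike process rather than charging to the full passive I*R
    i_eff <- if (firing) min(i_pa, 20 * 1000 / p$R) else i_pa
    v <- .rc_response(t, p$Vm, i_eff, p$R, tau, onset, dur, p$tau2)
    if (firing) {
      st <- .spike_times(f_of_i(i_pa), dur, p$adapt)
      v <- .add_spikes(v, t, st + onset)
    }
    list(v = v + noise(), n_spikes = length(st))
  }

  passive_traces <- replicate(15, mk_trace(-100)$v, simplify = FALSE)
  passive <- step_recording(passive_traces, rep(-100, 15), rate_khz, onset, dur)

  io_i <- seq(-100, 180, by = 20)
  io_raw <- lapply(io_i, mk_trace)
  io <- step_recording(lapply(io_raw, `[[`, "v"), io_i, rate_khz, onset, dur)

  maxf_i <- c(seq(100, 500, by = 50))
  maxf_raw <- lapply(maxf_i, mk_trace)
  maxf <- step_recording(lapply(maxf_raw, `[[`, "v"), maxf_i, rate_khz, onset, dur)

  pulses <- data.frame(i_pa = seq(2, 200, by = 2))
  pulses$spiked <- pulses$i_pa >= p$threshold

  baseline_v <- p$Vm + rnorm(2000 * rate_khz, 0, noise_sd)

  list(passive = passive, io = io, maxf = maxf, pulses = pulses,
       baseline_v = baseline_v,
       truth = c(p, list(tau = tau, scenario = scenario, seed = seed,
                         noise_sd = noise_sd,
                         io_spikes = vapply(io_raw, `[[`, numeric(1), "n_spikes"),
                         maxf_spikes = vapply(maxf_raw, `[[`, numeric(1), "n_spikes"))))
}

#' Generate a WFA line profile with planted peaks and holes
#'
#' A closed-perimeter profile built as a sum of Gaussian bumps on a
#' baseline, with Gaussian noise. Holes are made by omitting bumps from a
#' regular lattice of candidate sites, so planted hole sizes are known.
#' Scenario defaults follow the published peak counts: `sham_profile`
#' plants 21 bumps (intact net), `ptc_profile` 10 (degraded net with
#' enlarged holes).
#'
#' @param scenario `"sham_profile"` or `"ptc_profile"`, or `NULL` to use
#'   `n_peaks` directly.
#' @param n_peaks number of planted bumps (overrides scenario default).
#' @param n_sites number of candidate bump sites on the perimeter.
#' @param perimeter_um path length (um).
#' @param amp bump amplitude (au) above baseline.
#' @param baseline baseline intensity (au).
#' @param snr amplitude-to-noise-SD ratio.
#' @param bump_sd_um bump width (Gaussian SD, um).
#' @param dx_um sample spacing (um).
#' @param seed RNG seed.
#' @return A [line_profile()] with attribute `truth`: list with planted
#'   `n_peaks`, `positions_um`, `gaps_um` (arc distances between
#'   consecutive planted bumps) and the generator settings.
#' @export
gen_line_profile <- function(scenario = c("sham_profile", "ptc_profile"),
                             n_peaks = NULL, n_sites = 21, perimeter_um = 47,
                             amp = 1000, baseline = 100, snr = 10,
                             bump_sd_um = 0.35, dx_um = 0.1, seed = 1) {
  if (is.null(n_peaks)) {
    scenario <- match.arg(scenario)
    n_peaks <- if (scenario == "sham_profile") 21 else 10
  } else scenario <- "custom"
  stopifnot(n_peaks >= 0, n_peaks <= n_sites)
  old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)

  pos <- seq(0, perimeter_um - dx_um, by = dx_um)
  sites <- (seq_len(n_sites) - 0.5) * perimeter_um / n_sites
  keep <- if (n_peaks > 0) sort(sample(n_sites, n_peaks)) else integer(0)
  centers <- sites[keep]
  v <- rep(baseline, length(pos))
  for (cu in centers) {
    d <- pmin(abs(pos - cu), perimeter_um - abs(pos - cu))  # circular distance
    v <- v + amp * exp(-d^2 / (2 * bump_sd_um^2))
  }
  v <- pmax(0, v + rnorm(length(pos), 0, amp / snr))
  prof <- line_profile(pos, v, closed = TRUE, perimeter = perimeter_um)
  gaps <- if (length(centers) >= 2)
    c(diff(centers), perimeter_um - (centers[length(centers)] - centers[1]))
  else numeric(0)
  attr(prof, "truth") <- list(scenario = scenario, n_peaks = n_peaks,
                              positions_um = centers, gaps_um = gaps,
                              amp = amp, baseline = baseline, snr = snr,
                              seed = seed)
  prof
}

.map_scenarios <- list(
  sham_map = list(neun = c(26.12, 26.12, 26.12), pv = c(2.6, 2.6, 2.6),
                  wfa = c(2.78, 2.78, 2.78)),
  gbm22_map = list(neun = c(9.25, 15.25, 19.06), pv = c(0.58, 0.77, 1.2),
                   wfa = c(0.87, 0.87, 1.48))
)

#' Generate a marker-labelled cell map with planted bin densities
#'
#' Draws an inhomogeneous Poisson point pattern whose intensity is
#' piecewise-constant over the tumor-distance bins, with PV cells as a
#' marked subset of NeuN and WFA assigned to ~80% of PV cells (plus extra
#' non-PV cells where the planted WFA density exceeds 0.8 x the PV
#' density). Defaults are the published per-0.01 mm^2 densities: sham
#' NeuN 26.12, PV 2.6, WFA 2.78 (uniform); the glioma-implanted scenario
#' has NeuN 9.25/15.25/19.06 and PV 0.58/0.77/1.2 across the 0-0.2,
#' 0.2-0.4 and 0.4-0.6 mm bins.
#'
#' The field is laid out with a vertical tumor border so that each
#' distance bin contains two full columns of 100 um boxes.
#'
#' @param scenario `"sham_map"` or `"gbm22_map"`.
#' @param seed RNG seed.
#' @param field_h_um field height (um); width is fixed by the bin layout.
#' @param intensities optional list with per-bin `neun`, `pv`, `wfa`
#'   densities overriding the scenario defaults.
#' @param wfa_pv_frac fraction of PV cells carrying WFA.
#' @return A [cell_map()] with attribute `truth` (planted intensities and
#'   layout). Sham maps have no border; implanted maps have a vertical
#'   border polyline.
#' @export
gen_cell_map <- function(scenario = c("sham_map", "gbm22_map"), seed = 1,
                         field_h_um = 1000, intensities = NULL,
                         wfa_pv_frac = 0.8) {
  scenario <- match.arg(scenario)
  lam <- if (is.null(intensities)) .map_scenarios[[scenario]] else intensities
  old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)

  box <- 100
  sham <- scenario == "sham_map"
  # implanted layout: col 1 tumor, col 2 border (polyline at x = 150),
  # cols 3..8 parenchyma at steps 1..6 -> bins 1..3 (two columns per bin)
  n_par_cols <- 6
  x_off <- if (sham) 0 else 2 * box
  width <- x_off + n_par_cols * box
  ny <- floor(field_h_um / box)

  rows <- list()
  for (col in seq_len(n_par_cols)) {
    bin <- ceiling(col / 2)            # steps 1-2 -> bin 1, etc.
    bin_i <- if (sham) 1 else bin
    for (row in seq_len(ny)) {
      x0 <- x_off + (col - 1) * box
      y0 <- (row - 1) * box
      n_neun <- rpois(1, lam$neun[bin_i])
      if (n_neun == 0) next
      d <- data.frame(x_um = runif(n_neun, x0, x0 + box),
                      y_um = runif(n_neun, y0, y0 + box))
      d$neun <- 1L
      d$pv <- as.integer(runif(n_neun) < lam$pv[bin_i] / lam$neun[bin_i])
      p_extra <- max(0, lam$wfa[bin_i] - wfa_pv_frac * lam$pv[bin_i]) /
        max(lam$neun[bin_i] - lam$pv[bin_i], 1e-9)
      d$wfa <- ifelse(d$pv == 1L,
                      as.integer(runif(n_neun) < wfa_pv_frac),
                      as.integer(runif(n_neun) < p_extra))
      rows[[length(rows) + 1]] <- d
    }
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_um = numeric(0), y_um = numeric(0), neun = integer(0),
               pv = integer(0), wfa = integer(0))
  border <- if (sham) NULL else
    data.frame(x_um = c(150, 150), y_um = c(0, ny * box))
  m <- cell_map(cells, c(0, width, 0, ny * box), border = border,
                tumor_side = 1)  # tumor left of the upward-directed border
  attr(m, "truth") <- list(scenario = scenario, seed = seed,
                           intensities = lam, wfa_pv_frac = wfa_pv_frac,
                           box_um = box, n_boxes_per_bin = 2 * ny)
  m
}

.gradient_scenario <- list(
  dqg = c(glioma = 1851.47, b1 = 1048.74, b2 = 848.61, b3 = 715.96,
          far = 669.96),
  wfa = c(glioma = 100, b1 = 372.65, b2 = 599.17, b3 = 849.07, far = 1282.73)
)

#' Generate a two-channel intensity field with opposing radial gradients
#'
#' Builds a synthetic image pair around a vertical tumor border: a
#' gelatinase-activity channel (`dqg`) that is highest over the glioma mass
#' and decays with distance, and a WFA channel rising with distance - the
#' published opposing gradients. Each 200 um distance bin has a constant
#' planted mean with Gaussian pixel noise. Defaults use the published bin
#' means (gelatinase 1851.47 in the glioma mass down to 669.96 au in
#' sham-like tissue; WFA 372.65 up to 1282.73 au).
#'
#' @param seed RNG seed.
#' @param px_um pixel size (um/px).
#' @param width_um,height_um field size (um).
#' @param border_x_um x position of the vertical tumor border (um).
#' @param noise_sd pixel noise SD (au).
#' @param levels list with named vectors `dqg` and `wfa` giving the glioma,
#'   per-bin (b1..b3) and far-field means (au).
#' @return List with matrices `dqg`, `wfa`, the `border` polyline,
#'   `px_um`, and `truth` (planted bin means). The border is directed
#'   upward with the tumor on its left, so the parenchyma is the negative
#'   side (`parenchyma_side = -1`).
#' @export
gen_gradient_image <- function(seed = 1, px_um = 2, width_um = 800,
                               height_um = 600, border_x_um = 100,
                               noise_sd = 30, levels = .gradient_scenario) {
  old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
  nc <- round(width_um / px_um); nr <- round(height_um / px_um)
  xs <- (seq_len(nc) - 0.5) * px_um
  dist <- xs - border_x_um        # signed distance, parenchyma at x > border
  bin_of <- findInterval(dist, c(0, 200, 400, 600)) # 0 = glioma, 4 = far
  mk <- function(lv) {
    mu <- lv[c("glioma", "b1", "b2", "b3", "far")][bin_of + 1]
    matrix(rep(mu, each = nr), nr, nc) + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  border <- data.frame(x_um = c(border_x_um, border_x_um),
                       y_um = c(0, height_um))
  list(dqg = mk(levels$dqg), wfa = mk(levels$wfa), border = border,
       px_um = px_um,
       truth = list(levels = levels, seed = seed, noise_sd = noise_sd))
}
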