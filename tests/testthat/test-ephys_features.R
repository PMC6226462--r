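rc_trace <- function(vm, i_pa, r_mohm, tau_ms, rate_khz = 10, onset = 200,
                     dur = 1000, post = 200) {
  t <- seq(0, onset + dur + post - 1 / rate_khz, by = 1 / rate_khz)
  dv <- i_pa * r_mohm / 1000
  v <- rep(vm, length(t))
  on <- t >= onset & t < onset + dur
  off <- t >= onset + dur
  v[on] <- vm + dv * (1 - exp(-(t[on] - onset) / tau_ms))
  v[off] <- vm + dv * (1 - exp(-dur / tau_ms)) *
    exp(-(t[off] - onset - dur) / tau_ms)
  v
}

passive_rec <- function(r_mohm = 250, tau_ms = 10, vm = -65, n = 15,
                        noise_sd = 0) {
  traces <- replicate(n, rc_trace(vm, -100, r_mohm, tau_ms) +
                        rnorm(14000, 0, noise_sd), simplify = FALSE)
  step_recording(traces, rep(-100, n))
}

test_that("resting potential: mean, noise, drift warning", {
  expect_equal(as.numeric(resting_potential(rep(-65, 2000))), -65)
  set.seed(1)
  v <- -65 + rnorm(10000, 0, 0.5)
  expect_equal(as.numeric(resting_potential(v)), -65, tolerance = 1e-3)
  drifting <- seq(-65, -55, length.out = 2000)
  expect_warning(resting_potential(drifting), "drift")
})

test_that("input resistance recovers Ohm's law exactly on noiseless cells", {
  expect_equal(input_resistance(passive_rec(250)), 250, tolerance = 1e-3)
  # linearity: doubling R doubles Rin
  expect_equal(input_resistance(passive_rec(500)) /
                 input_resistance(passive_rec(250)), 2, tolerance = 1e-6)
  # spike contamination is an error
  bad <- passive_rec(250)
  bad$traces[[3]][3000] <- 20
  expect_error(input_resistance(bad), "spike")
  expect_error(input_resistance(step_recording(list(rep(-65, 14000)), 100)),
               "hyperpolarizing")
})

test_that("membrane capacitance: tau = RC consistency and model selection", {
  rec <- passive_rec(250, tau_ms = 10)
  fit <- membrane_capacitance(rec)
  expect_equal(fit$tau, 10, tolerance = 0.01)
  expect_equal(fit$Cm, 40, tolerance = 0.01 * 40)      # pF = ms/MOhm * 1000
  expect_equal(fit$Cm * fit$Rin / 1000, fit$tau, tolerance = 1e-12)
  expect_equal(fit$model, "mono")

  # equal-amplitude bi-exponential relaxation: the slowest component wins
  t <- seq(0, 1399.9, by = 0.1)
  on <- t >= 200 & t < 1200
  v <- rep(-65, length(t))
  dv <- -25
  v[on] <- -65 + dv * (1 - 0.5 * exp(-(t[on] - 200) / 2) -
                         0.5 * exp(-(t[on] - 200) / 12))
  v[t >= 1200] <- -65 + dv
  rec2 <- step_recording(replicate(15, v, simplify = FALSE), rep(-100, 15))
  fit2 <- membrane_capacitance(rec2, Rin = 250)
  expect_equal(fit2$model, "bi")
  expect_equal(fit2$tau, 12, tolerance = 0.05)
})

test_that("spike detection: constructed trains and brute-force agreement", {
  rate <- 10
  t <- seq(0, 999.9, by = 1 / rate)
  plateau <- -45
  v <- rep(plateau, length(t))
  spikes <- seq(50, 950, length.out = 12)
  for (ts in spikes) v <- v + 25 * exp(-(t - ts)^2 / (2 * 0.25^2))
  expect_length(detect_spikes(v, rate), 12)
  expect_length(detect_spikes(rep(-65, 10000), rate), 0)

  # amplitude-decrementing train: only peaks >= 15 mV above plateau count
  amps <- seq(30, 5, length.out = 12)
  v2 <- rep(plateau, length(t))
  for (k in seq_along(spikes))
    v2 <- v2 + amps[k] * exp(-(t - spikes[k])^2 / (2 * 0.25^2))
  got <- detect_spikes(v2, rate, steady_state_level = plateau)
  expect_length(got, sum(amps >= 15))
  expect_equal(length(got), brute_force_peaks(v2, plateau + 15) -
                 sum(abs(amps - 15) < 1e-9))
})

test_that("threshold current implements the persistent-onset rule", {
  i <- seq(2, 200, by = 2)
  expect_equal(threshold_current(i, i >= 86), 86)
  # a lone early spike at 50 pA does not move the threshold forward
  sp <- i >= 86; sp[i == 50] <- TRUE
  expect_equal(threshold_current(i, sp), 86)
  expect_equal(threshold_current(i, rep(FALSE, length(i))), 200)
  expect_error(threshold_current(c(2, 4), c(TRUE, TRUE)), "incomplete")
  # randomized maps match the brute-force definition
  set.seed(42)
  for (rep_ in 1:25) {
    sp <- runif(length(i)) < 0.5
    expect_equal(threshold_current(i, sp), brute_force_threshold(i, sp))
  }
})

test_that("input-output curves separate fast-spiking from excitatory cells", {
  g_fsn <- gen_step_recording("sham_fsn", seed = 3)
  g_exc <- gen_step_recording("excitatory", seed = 3)
  fi_fsn <- input_output_curve(g_fsn$io)
  fi_exc <- input_output_curve(g_exc$io)
  expect_true(all(fi_fsn$n_spikes[fi_fsn$i_pa <= 0] == 0))
  n140_fsn <- fi_fsn$n_spikes[fi_fsn$i_pa == 140]
  n140_exc <- fi_exc$n_spikes[fi_exc$i_pa == 140]
  expect_gt(n140_fsn, 100)
  expect_true(n140_exc >= 10 && n140_exc <= 45)
  # counts recover the planted spike processes (+/- 1 edge spike)
  expect_true(all(abs(fi_fsn$n_spikes - g_fsn$truth$io_spikes) <= 1))
  expect_true(all(abs(fi_exc$n_spikes - g_exc$truth$io_spikes) <= 1))
})

test_that("spike counts are robust to resampling from 20 kHz to 10 kHz", {
  g20 <- gen_step_recording("sham_fsn", seed = 5, rate_khz = 20)
  fi20 <- input_output_curve(g20$io)
  g10 <- step_recording(lapply(g20$io$traces, function(tr)
    tr[seq(1, length(tr), by = 2)]), g20$io$i_pa, rate_khz = 10,
    onset_ms = g20$io$onset_ms, step_ms = g20$io$step_ms)
  fi10 <- input_output_curve(g10)
  expect_true(all(abs(fi20$n_spikes - fi10$n_spikes) <= 1))
})

test_that("maximal firing frequency: saturation plateau and block flag", {
  g <- gen_step_recording("sham_fsn", seed = 2)
  mf <- max_firing_frequency(g$maxf)
  expect_equal(mf$max_hz, max(g$truth$maxf_spikes), tolerance = 0.05)
  expect_true(mf$saturated)
  expect_false(mf$block)

  # depolarization block: counts rise then collapse
  blk <- g$maxf
  ord <- order(blk$i_pa)
  hi <- tail(ord, 2)
  blk$traces[hi] <- lapply(blk$traces[hi], function(tr) {
    b <- tr; b[] <- mean(tr[1:2000]); b  # flat: firing collapsed
  })
  mfb <- max_firing_frequency(blk)
  expect_true(mfb$block)
})

test_that("full extraction recovers generator ground truth", {
  g <- gen_step_recording("ptc_fsn", seed = 9, noise_sd = 0)
  props <- extract_cell_properties(g$passive, g$io, g$pulses, g$baseline_v)
  expect_equal(props$Rin_MOhm, g$truth$R, tolerance = 0.005)
  expect_equal(props$Cm_pF, g$truth$Cm, tolerance = 0.005)
  expect_equal(props$Vm_mV, g$truth$Vm, tolerance = 0.005)
  expect_equal(props$threshold_pA, g$truth$threshold)
})
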