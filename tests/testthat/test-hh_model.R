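test_that("temperature factor follows the Q10-of-3 law", {
  expect_equal(temperature_factor(6.3), 1)
  expect_equal(temperature_factor(16.3), 3)
  expect_equal(temperature_factor(18.5), 3^1.22)
})

test_that("gating rates at rest match hand-evaluated values", {
  p <- hh_params(T = 6.3)  # phi = 1
  r <- gating_rates(p$Vr, p)
  expect_equal(r$alpha_n, 0.1 / (exp(1) - 1), tolerance = 1e-12)
  expect_equal(r$beta_n, 0.125)
  expect_equal(r$alpha_m, 2.5 / (exp(2.5) - 1), tolerance = 1e-12)
  expect_equal(r$beta_m, 4)
  expect_equal(r$alpha_h, 0.07)
  expect_equal(r$beta_h, 1 / (exp(3) + 1), tolerance = 1e-12)
  # all rates scale with phi
  r2 <- gating_rates(p$Vr, hh_params(T = 16.3))
  for (nm in names(r)) expect_equal(r2[[nm]], 3 * r[[nm]], tolerance = 1e-12)
})

test_that("removable singularities are replaced by their analytic limits", {
  p <- hh_params(T = 6.3)
  r10 <- gating_rates(p$Vr + 0.010, p)        # dV = 10: alpha_n singular
  expect_equal(r10$alpha_n, 0.1, tolerance = 1e-9)
  r25 <- gating_rates(p$Vr + 0.025, p)        # dV = 25: alpha_m singular
  expect_equal(r25$alpha_m, 1.0, tolerance = 1e-9)
  # continuity: values just off the singular point agree with the limit
  eps <- 1e-7
  expect_equal(gating_rates(p$Vr + 0.010 + eps, p)$alpha_n, 0.1,
               tolerance = 1e-4)
  expect_equal(gating_rates(p$Vr + 0.025 - eps, p)$alpha_m, 1.0,
               tolerance = 1e-4)
})

test_that("steady-state gates reproduce the resting initial condition", {
  ss <- steady_state_gates(-0.065)
  expect_lt(abs(ss$n - 0.3177), 5e-5)   # agreement to 4 decimal places
  expect_lt(abs(ss$m - 0.0529), 5e-5)
  expect_lt(abs(ss$h - 0.5961), 5e-5)
})

test_that("steady-state gates are temperature invariant (phi cancels)", {
  V <- seq(-0.100, 0.060, by = 0.001)
  a <- steady_state_gates(V, hh_params(T = 6.3))
  b <- steady_state_gates(V, hh_params(T = 18.5))
  for (g in c("n", "m", "h"))
    expect_equal(a[[g]], b[[g]], tolerance = 1e-12)
})

test_that("the resting state is near-equilibrium of the membrane equation", {
  p <- hh_params(J_ext = 0)
  ss <- steady_state_gates(p$Vr, p)
  d <- hh_derivative(list(V = p$Vr, n = ss$n, m = ss$m, h = ss$h), p)
  expect_lt(abs(d$dV), 0.5)
  # gate derivatives vanish exactly at their steady states
  expect_equal(d$dn, 0, tolerance = 1e-12)
  expect_equal(d$dm, 0, tolerance = 1e-12)
  expect_equal(d$dh, 0, tolerance = 1e-12)
})

test_that("dV/dt scales as 1/Cm and gate assignment flag transposes conductances", {
  st <- list(V = -0.040, n = 0.4, m = 0.2, h = 0.5)
  d1 <- hh_derivative(st, hh_params(Cm_specific = 1e-6, J_ext = 1e-4))
  d2 <- hh_derivative(st, hh_params(Cm_specific = 2e-6, J_ext = 1e-4))
  expect_equal(d2$dV, d1$dV / 2, tolerance = 1e-12)

  pt <- hh_params(transposed_gates = TRUE)
  dt_ <- hh_derivative(st, pt)
  # hand evaluation of the literal (transposed) conductance lines
  gK <- pt$G_K * st$m^4
  gNa <- pt$G_Na * st$n^3 * st$h
  J_ion <- gNa * (st$V - pt$E_Na) + gK * (st$V - pt$E_K) +
    pt$G_l * (st$V - pt$E_l)
  expect_equal(dt_$dV, (pt$J_ext - J_ion) / pt$Cm_specific, tolerance = 1e-12)
})

test_that("with negligible conductances the membrane charges linearly at J/Cm", {
  p <- hh_params(G_K = 1e-300, G_Na = 1e-300, G_l = 1e-300, J_ext = 1e-6)
  tr <- hh_simulate(p, duration = 1e-3, dt = 1e-6)
  expected <- -0.065 + p$J_ext / p$Cm_specific * tr$t
  expect_equal(tr$v, expected, tolerance = 1e-6)
})

test_that("simulation honours the default initial condition and sample count", {
  tr <- hh_simulate(hh_params(J_ext = 0), duration = 0.01)
  expect_equal(length(tr$v), round(0.01 / 1e-6) + 1)
  expect_equal(tr$v[1], -0.065)
  # no drive: no spikes, V stays near rest
  expect_equal(count_spikes_hh(tr), 0L)
  expect_true(all(abs(tr$v + 0.065) < 0.010))
})

test_that("gating variables stay within [0, 1] throughout a driven simulation", {
  tr <- hh_simulate(hh_params(J_ext = 2e-5), duration = 0.05, keep_gates = TRUE)
  for (g in c("n", "m", "h")) {
    expect_true(all(tr[[g]] >= 0))
    expect_true(all(tr[[g]] <= 1))
  }
})

test_that("integration divergence raises an error naming the step", {
  p <- hh_params(J_ext = 1e-2)
  expect_error(hh_simulate(p, duration = 0.01, dt = 5e-4), "step")
})

test_that("spike counting matches constructed traces and the brute-force scan", {
  expect_equal(count_spikes_hh(rep(-0.065, 1000)), 0L)
  # seven parabolic peaks at +40 mV on a -65 mV baseline
  v <- rep(-0.065, 700)
  for (c0 in seq(50, 650, by = 100)) {
    k <- (c0 - 20):(c0 + 20)
    v[k] <- pmax(v[k], 0.040 - 2e-4 * (k - c0)^2)
  }
  expect_equal(count_spikes_hh(v, reference = "absolute"), 7L)
  expect_equal(count_spikes_hh(v, reference = "rest"), 7L)
  # plateau-topped peak counts once
  vp <- c(rep(-0.065, 5), rep(0.030, 4), rep(-0.065, 5))
  expect_equal(count_spikes_hh(vp, reference = "absolute"), 1L)

  tr <- hh_simulate(hh_params(J_ext = 2e-5), duration = 0.2)
  expect_equal(count_spikes_hh(tr),
               brute_force_peaks(tr$v, -0.065 + 0.020))
})

test_that("sweep surface has the printed capacitance grid and zero rates below rheobase", {
  expect_equal(length(seq(0.8e-6, 1.5e-6, by = 0.01e-6)), 71)
  surf <- sweep_firing_surface(cm_grid = c(1e-6, 1.2e-6),
                               jext_grid = c(1e-7, 2e-7), duration = 0.2)
  expect_true(all(surf$rate == 0))
  expect_equal(dim(surf$rate), c(2, 2))
})

test_that("capacitance_effect arithmetic and degenerate cases", {
  surf <- structure(list(cm_grid = c(1e-6, 1.25e-6),
                         jext_grid = c(1e-4, 2e-4),
                         rate = matrix(c(200L, 100L, 0L, 0L), 2, 2),
                         duration = 1),
                    class = "firing_surface")
  expect_equal(capacitance_effect(surf, 1e-6, 1e-6, 1e-4), 0)
  expect_equal(capacitance_effect(surf, 1e-6, 1.25e-6, 1e-4), 50)
  expect_error(capacitance_effect(surf, 1e-6, 1.25e-6, 2e-4), "zero")
})

test_that("Euler at 1 us matches the adaptive reference solver (short run)", {
  skip_if_not_installed("deSolve")
  p <- hh_params(J_ext = 2e-5)
  n_eul <- count_spikes_hh(hh_simulate(p, duration = 0.2))
  expect_lte(abs(n_eul - hh_reference_count(p, duration = 0.2)), 1)
})
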