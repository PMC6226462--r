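# independent oracles used across tests

# Hodgkin-Huxley right-hand side for deSolve (independent of the compiled
# Euler path: uses the package's rate functions but integrates with lsoda)
hh_rhs_desolve <- function(t, y, p) {
  r <- gating_rates(y[1], p)
  gK <- p$G_K * y[2]^4
  gNa <- p$G_Na * y[3]^3 * y[4]
  J <- gNa * (y[1] - p$E_Na) + gK * (y[1] - p$E_K) + p$G_l * (y[1] - p$E_l)
  list(c((p$J_ext - J) / p$Cm_specific,
         1000 * (r$alpha_n * (1 - y[2]) - r$beta_n * y[2]),
         1000 * (r$alpha_m * (1 - y[3]) - r$beta_m * y[3]),
         1000 * (r$alpha_h * (1 - y[4]) - r$beta_h * y[4])))
}

hh_reference_count <- function(params, duration = 1, out_dt = 2e-5) {
  sol <- deSolve::lsoda(hh_initial_state(), seq(0, duration, by = out_dt),
                        hh_rhs_desolve, params, rtol = 1e-8, atol = 1e-10)
  count_spikes_hh(sol[, 2], Vr = params$Vr)
}

# brute-force spike scan: every sample that is a strict two-sided local
# maximum above the absolute threshold
brute_force_peaks <- function(v, thr_abs) {
  n <- length(v)
  sum(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
        v[2:(n - 1)] > thr_abs)
}

# brute-force threshold-current rule: smallest amplitude from which every
# response at that amplitude or above spiked
brute_force_threshold <- function(i_pa, spiked, cap = 200) {
  o <- order(i_pa)
  i_pa <- i_pa[o]; spiked <- spiked[o]
  for (k in seq_along(i_pa)) {
    if (all(spiked[k:length(spiked)])) return(i_pa[k])
  }
  cap
}
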