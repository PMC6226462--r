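---
title: "Methods: perineuronal nets, membrane capacitance and fast-spiking firing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perineuronal nets, membrane capacitance and fast-spiking firing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Perineuronal nets (PNNs) are lattice-like extracellular-matrix coats around
parvalbumin-expressing fast-spiking interneurons (FSNs). In peritumoral
cortex, glioma-released proteases degrade PNNs; the cells that lose their
nets show a higher membrane capacitance and a lower maximal firing rate.
`pnncap` implements the computational side of that argument as a tested
pipeline: a biophysical model asking whether the measured capacitance change
is *sufficient* to explain the firing change, a minimal integrate-and-fire
comparison for evoked (synaptically driven) activity, and the measurement
procedures - patch-clamp feature extraction, PNN line-profile integrity
scoring, and peritumoral cell-density binning - applied to synthetic data
with known ground truth, since the study's raw recordings and images are not
deposited.

# The Hodgkin-Huxley module

## Model

A single compartment with sodium, potassium and leak conductances:

$$C_m \frac{dV}{dt} = J_{ext} - \bar g_{Na} m^3 h\,(V - E_{Na})
  - \bar g_K n^4\,(V - E_K) - g_l\,(V - E_l)$$

with first-order gate kinetics $dx/dt = \alpha_x(1-x) - \beta_x x$ for
$x \in \{n, m, h\}$. The rate functions are the classical squid-axon fits in
terms of the depolarization $dV = (V - V_r)\times 1000$ (mV), each
multiplied by the temperature factor $\phi = 3^{(T - 6.3)/10}$; at the
working temperature of 18.5 °C, $\phi \approx 3.82$. Parameters (SI surface
units): $V_r = -65$ mV, $E_{Na} = 50$ mV, $E_K = -77$ mV, $E_l = -54.4$ mV,
$C_m = 1\ \mu F/cm^2$, $\bar g_K = 36$, $\bar g_{Na} = 120$, $g_l = 0.3$
mS/cm². Integration is forward Euler at a 1 µs step from the resting state
$(-65\ \mathrm{mV}, 0.3177, 0.0529, 0.5961)$, which is the steady-state gate
configuration at rest (reproduced by `steady_state_gates(-0.065)`).

Two numerical details matter. The rate functions $\alpha_n$ and $\alpha_m$
have removable singularities (at $dV = 10$ and $25$ mV); they are replaced
by their analytic limits (0.1 and 1.0 times $\phi$) whenever the denominator
magnitude falls below $10^{-12}$. Gating variables are clipped to $[0,1]$
only for numerical overshoot below $10^{-9}$; anything larger, or a
non-finite voltage, aborts with an error naming the step, so divergence can
never masquerade as data.

## Gate assignment

Some descriptions of this model circulate with the potassium and sodium
activation gates transposed ($m^4$ for K, $n^3h$ for Na). The canonical
assignment $g_K = \bar g_K n^4$, $g_{Na} = \bar g_{Na} m^3 h$ is the default
here, and the resting initial condition proves it is the intended one: with
$n = 0.3177$ as the K activation gate the system is at equilibrium at
$-65$ mV, while under the transposed reading the same state is far from
equilibrium. The transposed variant remains available for comparison via
`hh_params(transposed_gates = TRUE)`.

## Spike counting and the threshold reference

Firing is quantified as the number of strict local voltage maxima above a
+20 mV threshold in a 1000 ms simulation. The threshold is referenced to
**rest** by default (a peak counts when $dV > 20$ mV, i.e. $V > -45$ mV):
at 18.5 °C the $\phi$-accelerated kinetics shrink the spike overshoot to
roughly +12 mV absolute, so an *absolute* +20 mV criterion would miss every
steady-state spike and the capacitance analysis would be undefined. Since
$dV$ in millivolts is the natural working variable of the rate equations,
the rest-referenced reading is the physically coherent one. The absolute
reading is available (`reference = "absolute"`).

## The capacitance sweep

`sweep_firing_surface()` simulates a (capacitance × current) grid -
0.8-1.5 µF/cm² in 0.01 steps (71 points) against current densities spanning
2×10⁻⁵ to 1.4×10⁻² A/cm² (100 linearly spaced points by default; the grid
density in the current direction is configurable). Firing is monotone
non-increasing in $C_m$ at fixed current (to ±1 spike of count
discretization). `capacitance_effect()` then compares two capacitances at
one current; at the current maximizing the baseline (1.00 µF/cm²) rate, a
rise to 1.25 µF/cm² - the empirically observed ~25% capacitance increase -
lowers the firing rate by about 10% (11.6% with the default grids), the
model's central quantitative prediction. Near the oscillatory bifurcation
the count is knife-edge sensitive (peak amplitudes hover at the threshold),
which is why the Euler-versus-adaptive-solver validation in the test suite
uses grid points away from that edge; on those points the 1 µs Euler counts
match `deSolve::lsoda` exactly.

# The integrate-and-fire module

For evoked activity at lower rates, two leaky integrate-and-fire neurons
identical except for membrane capacitance are driven by the same Poisson
input trains (matched seeds). Defaults describe a PNN-intact FSN using the
measured sham passive values: $C = 30$ pF, $R = 250$ MΩ ($\tau = 7.5$ ms),
rest $-70$ mV, threshold $-50$ mV, reset $-70$ mV, 2 ms refractory period.
Each input spike injects a fixed charge (0.25 pC), so the unitary
deflection is $1000\,w/C$ mV (~8.3 mV at 30 pF) and a *lighter* membrane
receives *larger* unitary deflections - exactly the mechanism under test. A
fixed-deflection mode (`fixed_dv`) is available to switch this coupling
off.

In this fluctuation-driven regime (roughly three coincident inputs within a
membrane time constant are needed to fire at baseline), reducing $C$ by 25%
increases output spike counts at both 40 and 100 Hz drive, and the
*relative* increase is strictly larger at 40 Hz, where firing is rarer and
more nonlinear. That ordering is the claim this module supports. The
literal percentage gains depend strongly on the (unpublished) synaptic
weight, threshold distance and input statistics of the original
point-and-click simulation and are not identifiable; our defaults give much
larger relative gains than the ~30/~50% originally quoted, with the same
ordering. The simulator itself is validated against the closed-form
constant-current rate
$1/(t_{ref} + \tau \ln\frac{IR' + V_{rest} - V_{reset}}{IR' + V_{rest} - V_{thresh}})$
(with $R' = R/1000$ in mV/pA) to within 2%.

# Patch-clamp feature extraction

The measurement conventions follow the standard current-clamp protocols:

* **Resting potential**: mean of ≥100 ms of zero-current baseline, stored
  signed; a >5 mV drift across the baseline raises an instability warning.
* **Input resistance**: 15 repetitions of a -100 pA, 1000 ms step;
  $R_{in} = \overline{\Delta V}/|I|$ with the steady state taken over the
  last 20% of the step. Spike contamination of a hyperpolarizing step is an
  error, not a warning.
* **Time constant and capacitance**: the 15 traces are averaged and the
  relaxation from 1 ms after step onset is fit with mono- and
  bi-exponential decays (Levenberg-Marquardt via `minpack.lm`); the model
  with the lower small-sample-corrected AIC wins, ties to mono, and the
  *slowest* time constant is used, with components carrying <5% of the
  total amplitude discarded as numerical ghosts. $C_m = \tau/R_{in}$
  (pF = ms/MΩ × 1000) holds by construction. A fallback log-linear fit
  covers non-convergence; $\tau$ exceeding half the step flags the result
  unreliable.
* **Spike detection**: a spike is a local maximum at least 15 mV above the
  steady-state (inter-spike plateau) level, peaks at least 1 ms apart. The
  plateau is the median of the step voltage after excising ~2 ms around
  candidate peaks, iterated once; for cells firing faster than ~250 Hz the
  excision half-width shrinks to 40% of the median inter-spike interval so
  that some plateau samples always survive.
* **Threshold current**: the smallest 10 ms pulse amplitude from which
  every larger amplitude also fired; cells never reaching such a point are
  assigned the protocol cap of 200 pA.
* **Input-output curve and maximal rate**: spike counts over the
  -100..180 pA series (20 pA increments, 1000 ms steps), and over an
  ascending series to 500 pA for the saturating maximal rate, with flags
  for saturation (last two increments change the count by ≤2) and
  depolarization block (count falls after its maximum).

# PNN integrity from line profiles

A fluorescence line profile along the cell perimeter shows peaks where
PNN-CSPG condensations sit and troughs at holes in the net. The score is
the number of strict local maxima above a threshold of 50% of the maximum
intensity, with hole sizes measured as arc distances between consecutive
qualifying peaks; on a closed perimeter the first and last samples are
adjacent, peaks wrap around, and the hole sizes tile the perimeter exactly.

Manual counting applies visual averaging that a raw `which.max` does not;
the deterministic surrogate is a 0.5 µm moving average before detection,
a minimum peak separation of 0.8 µm (one bump full-width-at-half-maximum),
and a threshold taken from the smoothed trace (the raw maximum is
noise-inflated at low signal-to-noise). A degeneracy guard refuses to count
"peaks" on a statistically flat profile: if the threshold fails to clear
the trace minimum by at least three noise standard deviations (noise
estimated robustly from successive sample differences), the profile is
reported as having zero peaks. These choices were validated on generated
profiles: planted counts of 5-25 peaks at signal-to-noise ≥5 are recovered
exactly in well over 95% of seeded profiles, and the intact-net (21 peaks)
versus degraded-net (10 peaks) scenario defaults are recovered exactly. The
50% fraction and all window parameters are configurable. The guard's known
limitation: a profile whose baseline offset exceeds half its peak-to-peak
range is declared flat - but on such a profile a half-of-maximum threshold
is itself meaningless.

ROI statistics use area-weighted pixel means (partially covered pixels
contribute proportionally), and distance-binned intensity mirrors drawing
concentric rings every 200 µm from the tumor border: pixels are assigned
their distance to the border polyline, random square ROIs (seeded, so
placements reproduce) are placed wholly inside each ring, and their means
averaged per ring.

# Cell-density binning

Cell coordinates with NeuN/PV/WFA marker flags are partitioned by a grid of
100 µm boxes; boxes crossed by the border polyline are *border* boxes (they
contain both glioma and parenchyma), boxes on the tumor side are *tumor*,
and each parenchymal box gets a distance equal to its Chebyshev box-step
count from the nearest border box times 0.1 mm, binned as 0-0.2, 0.2-0.4
and 0.4-0.6 mm (two box columns per bin for a straight border). Cells are
assigned to boxes half-open, so counts partition exactly. Densities are
per-box means (cells per 0.01 mm²), by default over all qualifying boxes,
with a seeded option to subsample 3-5 boxes per bin to mimic the per-slice
scoring variance of manual counting. Sham maps have no border; their single
pooled density is the reference for percent-of-sham normalization.

# The synthetic-data generators

Because no raw data are deposited, every analysis is validated by recovery
of planted ground truth. Generator defaults are pinned to the published
group means so scenario names double as documentation:

* `sham_fsn`: R = 252.64 MΩ, Cm = 30.11 pF, Vm = -69.85 mV, maximal rate
  406.62 Hz, non-adapting, >100 Hz at 140 pA (gain 1.13 Hz/pA above a
  40 pA rheobase, so the rate saturates by 400 pA as observed);
  `ptc_fsn`: Cm = 43.84 pF, Vm = -61.67 mV, slower ceiling;
  `excitatory`: R = 298.63 MΩ, Cm = 73.93 pF, adapting (geometrically
  lengthening intervals), 15-40 Hz at 140 pA. Traces are passive RC
  responses with stereotyped ~40 mV spike waveforms planted at the
  scenario's rate plus Gaussian noise (0.5 mV default); on firing steps
  the steady depolarization is clamped near threshold rather than charged
  to the full passive deflection, as in real cells. Spike generation is
  deliberately phenomenological - the mechanistic model lives in the HH
  module; the generator only needs protocol-level statistics.
* `sham_profile` / `ptc_profile`: 21 versus 10 Gaussian bumps on a 47 µm
  closed perimeter (bump SD 0.35 µm, amplitude-to-noise 10 by default),
  holes created by omitting bumps from a regular lattice of sites so
  planted hole sizes are known.
* `sham_map` / `gbm22_map`: inhomogeneous Poisson point patterns with
  piecewise-constant per-bin intensities (sham NeuN 26.12, PV 2.6, WFA
  2.78 per 0.01 mm²; implanted NeuN 9.25/15.25/19.06, PV 0.58/0.77/1.2,
  WFA 0.87/0.87/1.48), PV as a marked subset of NeuN and WFA on ~80% of
  PV cells plus extra non-PV carriers where the planted WFA density
  requires it.
* `gen_gradient_image`: two-channel field around a vertical border with
  opposing monotone gradients - gelatinase activity 1851 au over the
  glioma falling to 670, WFA rising 373 to 1283 au - piecewise constant
  per 200 µm bin with Gaussian pixel noise.

All generators restore the caller's RNG state and are bit-reproducible per
seed. What they do *not* emulate: correlated (1/f) recording noise,
electrode artifacts, bridge imbalance, true spike waveform dynamics,
anisotropic PNN morphology, confocal point-spread functions, or clustered
(non-Poisson) cell placement. Recovery on these generators therefore
demonstrates correctness of the measurement procedures, not robustness to
every failure mode of real recordings.

# Problem sizes and determinism

The test suite simulates 1000 ms of HH dynamics (10⁶ Euler steps) where the
claim demands it and 200 ms where only integrator agreement is being
checked; the capacitance-effect computation uses the full 100-point current
grid at the two capacitances of interest, and the monotonicity check spans
the full 71-point capacitance grid at six representative currents. The
integrate-and-fire comparison uses 50 matched seeds of 10 s each; peak
recovery uses 200 seeded profiles; density recovery uses single maps plus a
100-seed unbiasedness check. The HH module is deterministic (no RNG);
everything stochastic takes an explicit seed.
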