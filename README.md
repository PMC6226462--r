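# pnncap

Perineuronal nets (PNNs) — lattice-like extracellular-matrix coats around
parvalbumin-expressing fast-spiking interneurons (FSNs) — act as an
electrostatic insulator that lowers the specific membrane capacitance of
the cells they enclose, letting them fire at supra-physiological rates.
When glioma-released proteases degrade the nets, capacitance rises and
firing falls, weakening inhibition in peritumoral cortex. `pnncap` is an R
package for researchers studying this mechanism: it implements the
biophysical models and the quantification procedures as a reproducible,
tested pipeline, exercised end-to-end on seeded synthetic data with known
ground truth.

## What's inside

* **Hodgkin–Huxley capacitance sweep** (`hh_params()`, `hh_simulate()`,
  `sweep_firing_surface()`, `capacitance_effect()`): single-compartment
  model

  C_m dV/dt = J_ext − ḡ_Na m³h (V − E_Na) − ḡ_K n⁴ (V − E_K) − g_l (V − E_l),
  dx/dt = α_x(1 − x) − β_x x for x ∈ {n, m, h},

  with rates scaled by φ = 3^((T−6.3)/10), integrated by forward Euler at a
  1 µs step over a (capacitance × current) grid. Its central prediction: a
  25% rise in C_m (1.00 → 1.25 µF/cm²) lowers the maximal firing rate by
  about 10%.
* **Integrate-and-fire comparison** (`lif_params()`, `simulate_lif()`,
  `capacitance_comparison()`): two neurons identical except for C, driven
  by matched-seed Poisson trains; lowering C by 25% boosts evoked firing,
  proportionally more at 40 Hz than at 100 Hz drive.
* **Patch-clamp feature extraction** (`input_resistance()`,
  `membrane_capacitance()`, `detect_spikes()`, `threshold_current()`,
  `input_output_curve()`, `max_firing_frequency()`): intrinsic properties
  from current-step protocols — R_in = ΔV/I, τ from exponential fits with
  AICc model selection, C_m = τ/R_in.
* **PNN integrity scoring** (`count_wfa_peaks()`, `roi_mean_intensity()`,
  `radial_bin_intensity()`): peak counts above a 50%-of-maximum threshold
  along perimeter line profiles, hole sizes, ROI means and distance-binned
  intensities from a tumor border.
* **Cell-density binning** (`grid_boxes()`, `density_per_bin()`,
  `normalize_to_sham()`): marker-labelled cell maps gridded into 100 µm
  boxes, densities per 0.01 mm² in 0.2 mm distance bins, percent-of-sham
  normalization.
* **Synthetic-data generators** (`gen_step_recording()`,
  `gen_line_profile()`, `gen_cell_map()`, `gen_gradient_image()`): seeded,
  bit-reproducible inputs for every module, with planted ground truth
  attached for recovery testing.

See the methods vignette (`vignettes/pnn-capacitance-methods.Rmd`) for the
models, conventions and design choices in detail.

## Worked example

```r
library(pnncap)

# resting steady-state gates = the model's canonical initial condition
unlist(steady_state_gates(-0.065))
#>         n         m         h
#> 0.3176769 0.0529325 0.5961208

# capacitance effect on maximal firing
jext <- seq(0.2e-4, 1.4e-2, length.out = 100)
surf <- sweep_firing_surface(cm_grid = c(1.00e-6, 1.25e-6), jext_grid = jext)
j_star <- jext[which.max(surf$rate[1, ])]
capacitance_effect(surf, 1.00e-6, 1.25e-6, j_star)
#> [1] 11.58537        # percent decrease in firing rate

# recover intrinsic properties from a synthetic PNN-intact FSN
g <- gen_step_recording("sham_fsn", seed = 1)
rin <- input_resistance(g$passive)
membrane_capacitance(g$passive, rin)[c("tau", "Cm", "model")]
#> $tau
#> [1] 7.642729
#> $Cm
#> [1] 30.25347
#> $model
#> [1] "mono"

# PNN integrity: intact vs degraded nets
count_wfa_peaks(gen_line_profile("sham_profile", seed = 1))$peak_count
#> [1] 21
count_wfa_peaks(gen_line_profile("ptc_profile", seed = 1))$peak_count
#> [1] 10
```

The gate values are the steady states α/(α+β) at −65 mV; the 11.6%
figure is the model's firing-rate drop for the empirically observed
capacitance rise; the recovered R_in/τ/C_m match the generator's planted
sham values (252.64 MΩ, 7.61 ms, 30.11 pF) to well under 1%; and the peak
counts recover the planted intact (21) and degraded (10) net structures.

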