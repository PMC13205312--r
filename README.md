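# icgperf

Quantitative multimodal bowel perfusion imaging: hyperspectral imaging
(HSI) combined with indocyanine green fluorescence angiography (ICG-FA).

## The problem

Anastomotic leakage is one of the most serious complications of colorectal
resection, and insufficient perfusion at the transection site is a key risk
factor. Two intraoperative imaging modalities address it: HSI delivers a
reflectance spectrum per pixel (500–995 nm at 5 nm) from which static
tissue parameters (StO2, NIR perfusion index, organ haemoglobin index,
tissue water index, each 0–100) are derived, while ICG-FA shows dynamic
blood inflow after an intravenous fluorophore bolus. `icgperf` implements
the analysis stack needed to use both together and to check that they can
coexist:

- **ICG reconstruction from HSI.** ICG absorbs maximally near 805 nm.
  After administration, an ICG-mimicking absorption image is reconstructed
  from a hyperspectral cube as

  `recICG(x, y) = (1/5) * sum_{i = 790nm..810nm} d²R_S(x, y, λ_i) / dλ²`

  where `R_S` is the spectrally smoothed reflectance (Gaussian, σ = 4.44
  band units). The map is median filtered (7 × 7), normalised to its 99th
  percentile and clipped to [0, 1].
- **Inflow quantification.** Per circular ROI, the video intensity is
  normalised to the excitation-laser level (read off the on-screen
  indicator by normalized-cross-correlation template matching), smoothed
  with a 3-s moving average, and summarised by the background-noise
  maximum B (3–6 s window), the objective time to first fluorescence T0
  (first time the curve stays above B), the inflow slope (OLS over the
  segment of highest local slopes), and literature thresholds
  (slope < 2.1 units/s; T0 > 60 s / > 40 s).
- **Border localisation.** The perfusion transection border is the
  inflection of three line profiles drawn from the well-perfused side,
  estimated by a chord-based geometric construction robust to profile
  noise, calibrated to centimetres with a ruler annotation, and signed
  against the surgeon's clinical marker (negative = proximal).
- **Parameter shift and cohort statistics.** Pre/intra/post-ICG tissue
  index differences per perfusion class (descriptive), plus Shapiro–Wilk,
  paired Wilcoxon signed-rank, Spearman correlation and retrospective
  power (Δ = 0.5 cm, α = 0.05) at the cohort level.

Because no patient data is deposited, a first-class synthetic-data module
generates every input with known ground truth (absorption dip depth,
border position, T0/slope, laser profile, modality offsets), so the whole
stack is validated by parameter recovery.

## Worked example

```r
library(icgperf)

# a simulated intra-ICG cube with a perfusion border at column 80
sim <- simulate_cube(scenario_config(seed = 1))
rec <- reconstruct_icg(sim$cube)
median(rec$values[sim$truth$concentration > 0.95])   # 0.9934730
median(rec$values[sim$truth$concentration < 0.05])   # 0.0006314879

# inflow metrics for a simulated video (true T0 = 20.3 s, slope = 119.5)
si <- simulate_inflow_stack(scenario_config(seed = 2,
  inflow = list(t0_true_s = 20.3, slope_true = 119.5, plateau = NULL,
                rise_s = 12, shape = "ramp", frame_rate_hz = 5,
                duration_s = NULL, snr = 20,
                frame_height = 32L, frame_width = 48L)))
curve <- build_curve(si$stack, si$roi, si$indicator, si$bank)
inflow_metrics(curve)
#> <inflow_metrics> B = 1.70, T0 = 20.60 s, slope = 119.36 units/s, ttp = 22.00 s
```

The reconstructed map separates ICG-loaded from ICG-free tissue almost
perfectly (medians near 1 and 0), and the inflow estimates recover the
generator's truth to a fraction of a second and below 1% relative slope
error.

A thin CLI wraps the same functions (`exec/perfusion run-case`,
`run-cohort`, `simulate ...` after installation).

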