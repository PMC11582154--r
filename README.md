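# ivimdrift

Signal drift correction and intravoxel incoherent motion (IVIM) parameter
estimation for diffusion MRI (dMRI) of the brain.

## The problem

Brain dMRI signal drifts slowly over a scan — typically a couple of percent
per 5 minutes brain-wide, and above 5 %/5 min in frontal regions, with
opposite sign toward the cerebellum. Because diffusion protocols encode
information in small signal differences across b-values, any acquisition
order that correlates b-value with scan time converts this drift into
systematic parameter bias; a "mixed" order converts it into extra residual
variance instead. `ivimdrift` is for researchers who want to (a) correct
drift retrospectively from interspersed b = 0 volumes, (b) quantify what
drift does to IVIM estimates under different acquisition orders, and (c)
verify every step on synthetic phantoms where the truth is known.

## Models

**Drift corrections.** The b = 0 signal is modeled as a second-order
polynomial in acquisition index *n*, either globally
(`S(n | b_n = 0) = k_0 + k_1 n + k_2 n^2` fitted to the masked median),
voxelwise (one polynomial per voxel), or spatiotemporally
(`S(n; x,y,z | b_n = 0) = p_0(x,y,z) + p_1(x,y,z) n + p_2(x,y,z) n^2`, each
`p_i` a full second-order polynomial in space — 81 coefficients — fitted by
Tukey-bisquare robust regression after voxelwise normalization to the first
b = 0 volume). All data, at every b-value, are then divided by the fitted
field: `S_corr(n) = S(n) / fitted(n)`, normalized so the field is 1 at the
first b = 0 acquisition.

**IVIM estimators** (after geometric direction-averaging):

* *sIVIM* (3 b-values, closed form): `D = (ln S_1 − ln S_2)/(b_2 − b_1)`,
  `A = S_1 e^{b_1 D}`, `f = 1 − A/S_0`.
* *Diffusive* (10 b-values): bounded least squares of
  `S(b) = S_0((1−f) e^{−bD} + f e^{−bD*})`.
* *Ballistic* (flow-compensated + non-flow-compensated bipolar encodings):
  bounded least squares of
  `S(b,c) = S_0((1−f) e^{−bD} + f e^{−bD_b} e^{−c² v_d²})` with the blood
  diffusivity fixed at `D_b = 1.75 µm²/ms`.

The package also provides the acquisition-order simulation (reorder
drift-corrected data by ascending b, re-impose the drift at the new time
points), ROI drift metrics, test–retest repeatability summaries, and exact
permutation Friedman and Wilcoxon signed-rank tests.

## Worked example

```r
library(ivimdrift)

# 1. a brain-like phantom and the ten-b-value protocol
phantom <- make_phantom(c(16, 16, 8), seed = 1)
scheme  <- protocol_preset("diffusive")

# 2. noiseless signals, a known drift field, Rician noise at SNR 100
truth   <- forward_signal(phantom, scheme, "diffusive")
drift   <- make_drift_model(phantom, scheme,
                            drift = c(frontal = -5, inferior = 5))
sigma   <- median(phantom$maps$S0[phantom$mask]) / 100
series  <- add_noise(apply_drift(truth, drift), sigma, "rician", seed = 2)

# 3. frontal-ROI drift before and after spatiotemporal correction
roi       <- roi_mask(phantom, 1)
model     <- fit_spatiotemporal(series)
corrected <- apply_correction(series, model)
drift_first_last(series, roi)$drift_first_last     # -4.99  %/5min
drift_first_last(corrected, roi)$drift_first_last  # -0.19  %/5min

# 4. IVIM parameters in the frontal ROI
fit <- fit_diffusive(geometric_average(corrected))
median(fit$maps$D[roi], na.rm = TRUE)  # 0.808 um^2/ms (truth 0.805)
median(fit$maps$f[roi], na.rm = TRUE)  # 0.0422        (truth 0.0419)
```

The uncorrected series shows the injected −5 %/5 min frontal drift; the
81-coefficient spatiotemporal fit reduces it to −0.2 %/5 min, and the
drift-corrected diffusive fit recovers the phantom's frontal-ROI median
D and f to within a fraction of a percent at this noise level.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ivimdrift.R` (subcommands `simulate`, `correct`, `fit`, `stats`,
`run`); `run_pipeline()` executes the whole
simulate → correct → average → fit → summarize chain from a YAML config.

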