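# met2star

Quantitative comparison of **monopolar** and **bipolar** readout gradients
for T2\* mapping with multi-echo gradient-echo (GRE) sequences.

A monopolar train re-winds the readout gradient between echoes (fly-back
time $T_{fb}$), so all echoes share one polarity but the echo spacing is
long. A bipolar train alternates polarity, halving the spacing and roughly
doubling the number of echoes in a given TE range — at the price of
parity-dependent amplitude modulation between odd and even echoes. This
package provides the full simulation-and-estimation chain needed to
quantify that trade-off for people designing or analysing relaxometry
protocols:

- **Timing** — echo schedules
  $TE_n = T_{prep} + (2n-1)(T_{acq}/2 + T_{ramp}) + (n-1)T_{fb}$,
  acquisition window $\lceil N_x/BW \rceil$, echo counting within a TE
  range, and the bandwidth noise law $\sigma = \sigma_0\sqrt{BW/BW_0}$.
- **Simulation** — a five-region digital phantom (T2\* = 49/78/69/99/133 ms,
  T1 = 671/959/878/1134/1372 ms) imaged by the spoiled-GRE signal
  $s(TE_n) = M_0\frac{\sin\alpha(1-e^{-TR/T1})}{1-\cos\alpha\,e^{-TR/T1}}
  e^{-TE_n/T2^*}e^{i(\varphi_0+2\pi\Delta f TE_n)} + \varepsilon$,
  with Rician magnitude formation and noise-only background corners.
- **Estimation** — per-voxel maximum-likelihood fits of
  $\nu_n = A e^{-TE_n/T2^*}$ under the Rician distribution with known
  $\sigma$ (estimated from the Rayleigh background), plus iterative
  correction of odd/even amplitude modulation.
- **Precision prediction** — Fisher information / Cramér–Rao lower bound
  (CRLB) for the T2\* estimator under Rician or Gaussian noise, and
  calibration of $\sigma$ to a target precision.
- **Experiments** — sweep drivers over flip angle × TR, TE range, echo
  spacing and bandwidth that tabulate accuracy and precision for both
  readouts (`analysis/01…06_*.R` are thin drivers writing CSV tables to
  `results/`).

## Worked example

Calibrate the noise level so the monopolar reference protocol
(801 Hz/px: TE₁ = 3.84 ms, ΔTE = 2.92 ms, 97 ms TE range, α = 75°,
TR = 1200 ms) has a predicted T2\* standard deviation of 1.08 ms, then
simulate and fit the matched bipolar acquisition:

```r
library(met2star)

mono <- train_from_protocol(3.84, 2.92, "monopolar", te_max = 97)
bip  <- train_from_protocol(3.84, 1.47, "bipolar",   te_max = 97)
mono
#> <echo_train> 32 echoes, TE 3.84..94.36 ms, dTE 2.920 ms (monopolar)
bip
#> <echo_train> 64 echoes, TE 3.84..96.45 ms, dTE 1.470 ms (bipolar)

tissue <- tissue_params(m0 = 1, t1 = 878, t2_star = 69)
sigma0 <- calibrate_sigma(1.08, mono, tissue, acquisition_params(75, 1200))
round(sigma0, 6)
#> [1] 0.0128

# CRLB: the bipolar train, with twice the echoes, predicts ~1/sqrt(2) the std
round(crlb_t2star_std(bip, tissue, acquisition_params(75, 1200), sigma = sigma0), 3)
#> [1] 0.77

phantom <- build_default_phantom(240)
acq    <- acquisition_params(75, 1200, sigma = sigma0)
series <- simulate_series(phantom, acq, bip, seed = 1)

# noise from the Rayleigh background corners, then a voxelwise Rician fit
sigma_hat <- estimate_noise_background(series, corner_masks(phantom))$sigma
mask <- region_mask(phantom, 3)            # central region, true T2* = 69 ms
fit  <- fit_t2star_map(series, sigma = sigma_hat, mask = mask)
roi_stats(fit$t2_star, mask, crlb = 0.77, roi_id = 3)
#>   roi n_voxels mean_t2star std_t2star crlb_std low_n
#> 1   3     2188    69.00805  0.7794371     0.77 FALSE
```

The fitted region mean recovers the ground truth (69.01 vs 69 ms) and the
observed spread (0.78 ms over 2 188 voxels) sits on the CRLB prediction
(0.77 ms) — the Rician maximum-likelihood estimator is essentially
efficient at this SNR. The matching monopolar acquisition yields ~1.08 ms:
the bipolar readout is ~29 % ($\approx 1/\sqrt2$) more precise for the
same scan.

The methods vignette (`vignettes/readout-precision.Rmd`) documents the
models, the noise-anchoring choice, the fitting algorithm, and what the
simulations do and do not validate.

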