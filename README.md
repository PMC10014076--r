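# lectincap

Information-theoretic analysis of glycan–lectin signaling channels from
dose-indexed single-cell fluorescence data.

C-type lectin receptors (dectin-1, dectin-2, MINCLE, MCL, DC-SIGN) signal
glycan recognition to NF-κB, and in an NF-κB–GFP reporter line each
stimulant dose produces a broad, overlapping per-cell fluorescence
distribution rather than a clean on/off response. This package quantifies
how much information such a channel actually transmits, for researchers
analyzing flow-cytometry reporter assays (or any dose-indexed single-cell
readout).

Treating the dose series *x<sub>i</sub>* as the input alphabet and the
single-cell output *y* as the channel output, the joint probability on an
indexed rectangular grid is *P<sub>ij</sub> = w<sub>i</sub>
N<sub>ij</sub>/N<sub>i</sub>*, entropies follow in bits, and the mutual
information is *I<sub>xy</sub> = H<sub>x</sub> + H<sub>y</sub> −
H<sub>xy</sub>*. The **channel capacity** *C = max<sub>w</sub>
I<sub>xy</sub>* — computed with the Blahut–Arimoto algorithm on the
empirical conditional, bias-corrected by extrapolating subsampled
estimates to infinite sample size, with bootstrap confidence intervals —
is the headline statistic. Around it the package provides:

- **`flow_data`**: FCS 3.0/3.1 and CSV event readers, intensity transforms,
  sample-sheet-driven assembly into dose–response datasets, geometric-mean
  ± robust-SD population summaries, bead calibration of fluorescence to
  molecule counts.
- **`infocap`**: output binning, entropies/MI, `blahut_arimoto()`,
  `estimate_capacity()`, capacity-vs-maximum-dose curves, plateau-based
  bin-count selection.
- **`noise_power`**: decomposition into signal power (variance across doses
  of the per-dose mean), noise power (mean per-dose variance) and their
  ratio.
- **`dose_response`**: four-parameter logistic fits (EC50, Hill), EC50 fold
  changes, extra-sum-of-squares F test.
- **Synthetic generators**: a mixture reporter simulator emulating
  overlapping basal/activated log-normal populations, and a known-channel
  mode with analytically computable true capacity (`true_capacity()`) for
  validating the estimator.
- **`run_pipeline()`**: config-driven end-to-end runs with byte-reproducible
  tidy CSV outputs and a JSON manifest.

## Worked example

```r
library(lectincap)

# a synthetic reporter channel: 12 half-log doses, 1000 cells each,
# activation probability rising 0.05 -> 0.95 with dose
cfg <- mixture_reporter_config(n_cells_per_dose = 1000, seed = 1)
ds  <- simulate_mixture_reporter(cfg)

estimate_capacity(ds, n_bins = "auto", bias_correction = TRUE,
                  n_bootstrap = 50, seed = 1)
#> <capacity_estimate> 0.5548 bits [95% CI 0.5294, 0.6042]
#>   bins: 8 (effective 8); uncorrected 0.5655 bits

decompose(ds)
#> <noise_decomposition> signal 0.2032, noise 0.3123, SNR 0.6508

sm <- dose_response_summary(ds)   # geometric mean GFP per dose
fit_4pl(sm$dose, sm$response)
#> <dose_response_fit> EC50 3.6439, hill 0.9307, bottom 104.8, top 1407, RSS 15240
```

The channel transmits 0.55 bits: single cells resolve less than two dose
states reliably, despite a 13-fold dynamic range in mean GFP — the
signal-to-noise ratio below 1 (per-dose variance exceeding the variance of
the dose means) explains why. The uncorrected estimate is ~0.01 bits
higher, the finite-sample bias removed by the subsample extrapolation.

## The analysis workflow

`analysis/` contains the numbered drivers of the full study on the
synthetic cohort; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # cohort: strong + weak channel, 3 replicates
Rscript analysis/02_capacity.R      # per-replicate capacities + max-dose curves
Rscript analysis/03_noise.R         # signal/noise power, SNR comparison
Rscript analysis/04_dose_response.R # 4PL fits, EC50 fold change, F test
Rscript analysis/05_comparisons.R   # exact rank-sum comparisons
```

On the default cohort the strong channel (activation 0.05–0.95) carries
0.51–0.55 bits per replicate against 0.08–0.10 bits for the weak channel
(activation 0.30–0.70); the exact two-sided rank-sum p at n = 3 vs 3 is
0.1, the smallest attainable.

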