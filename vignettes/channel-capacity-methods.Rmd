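---
title: "Estimating channel capacity and noise of glycan-lectin signaling channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating channel capacity and noise of glycan-lectin signaling channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectincap)
```

## The problem and the model

C-type lectin receptors (dectin-1, dectin-2, MINCLE, MCL, DC-SIGN) read
glycan structures on microbial surfaces and signal to NF-kB. In an NF-kB-GFP
reporter line, pathway activation at a given stimulant dose is read out as a
per-cell fluorescence distribution. Those distributions are broad,
right-skewed, and overlap heavily between unstimulated and maximally
stimulated cells: the pathway is not an on/off switch, and no single summary
statistic (maximal MFI, EC50) captures how reliably a cell population can
tell doses apart.

Information theory gives the natural metric. Treat the dose series
$x_i$ as the input alphabet of a communication channel and the single-cell
output $y$ as its noisy output. Binning the output axis into cells $j$
produces a count grid $N_{ij}$; with an input distribution $w_i$, the joint
probability is

$$P_{ij} = w_i \, \frac{N_{ij}}{N_i},$$

from which marginal and joint Shannon entropies (bits) and the mutual
information $I_{xy} = H_x + H_y - H_{xy}$ follow. Mutual information depends
on the input distribution; its maximum over all distributions on the tested
dose set is the **channel capacity** — the number of bits about the dose
that one cell's output can carry, however the experimenter allocates input
probability. Capacities near 1 bit mean the population resolves roughly two
dose states; a capacity of 0.5 bits means even presence/absence is
unreliable at the single-cell level.

## The estimator, step by step

`estimate_capacity()` implements the full chain:

1. **Binning** (`bin_output()`). Output values (log10 fluorescence by
   default) are pooled across doses and cut into equal-frequency bins —
   pooled quantiles — with half-open intervals $[e_j, e_{j+1})$ and a
   closed last bin. Equal-frequency binning is robust to the decades-wide
   right tail of reporter GFP; equal-width binning is available for
   comparison. Duplicate quantile edges (heavily tied data) are collapsed
   and the effective bin count reported.
2. **Empirical conditional.** $\hat Q(j\mid i) = N_{ij}/N_i$. Output bins
   empty under every dose are dropped (they cannot carry information).
3. **Capacity maximization** (`blahut_arimoto()`). The Blahut-Arimoto
   alternating maximization is run on $\hat Q$. Each iteration evaluates
   the per-input divergences $d_i = D(Q_i \| q)$ against the current output
   marginal; $\max_i d_i$ and $\sum_i p_i d_i$ are the standard upper and
   lower capacity bounds, and iteration stops when they agree to the
   requested tolerance, so the result brackets the true optimum of the
   discretized channel. Maximizing over trial input distributions and
   Blahut-Arimoto optimize the same objective; the latter is deterministic
   and convergent, which is why it is used here.
4. **Finite-sample bias correction.** Plug-in information estimates are
   biased upward at finite cell numbers (spurious information of order
   (bins x doses)/N). The estimator re-runs steps 1-3 on random subsamples
   at fractions 0.5, 0.625, 0.75, 0.875 and 1.0 of the cells per dose (10
   repeats per fraction), fits a straight line of capacity against inverse
   total sample size, and reports the intercept — the extrapolation to
   infinite data. The fitted points are kept in `bias_curve` for
   inspection; the intercept is floored at zero.
5. **Bootstrap CI.** Cells are resampled with replacement within each dose
   and the (bias-corrected) estimate recomputed; the 2.5 and 97.5
   percentiles give the 95% interval. All resampling is driven by one seed
   and never perturbs the caller's RNG state.

### Choosing the bin count

The capacity of the discretized channel rises with bin count while real
information saturates, so the estimate is profiled over a candidate ladder
and `select_bin_count()` returns the smallest candidate within 0.02 bits of
the median across candidates — the start of the plateau. If the profile
spans more than 0.2 bits there is no plateau; a warning is raised and the
middle candidate is used. The default ladder is the doubling sequence
{8, 16, 32}: nested refinements measure the same partition at three
resolutions, whereas incommensurate counts (10 vs 15 vs 40) lay bin edges
at different positions relative to any strong modes in the pooled output
and can make the profile disagree for reasons unrelated to sample size —
on a perfectly separable four-cluster channel, counts not divisible by
four place an edge inside a cluster and lose a deterministic ~0.2 bits,
which is exactly the kind of artifact a plateau rule must not mistake for
signal.

### Numerical choices

- Entropies use the $0 \log 0 = 0$ convention throughout.
- The Blahut-Arimoto bounds-gap tolerance is 1e-9 bits when called
  directly and 1e-12 in `true_capacity()` (the analytic oracle for
  simulated channels). Inside the data estimator the tolerance is 1e-4
  bits: on near-flat empirical conditionals the gap closes only as
  O(1/iterations), and 1e-4 is far below the precision at which capacities
  are reported or compared.
- Capacity estimation requires at least 50 cells per dose and at least 2
  effective output bins; both are hard errors naming the offending dose.
- Ties at bin edges: half-open bins, right edge exclusive, except the last
  bin which is closed.

## The synthetic cohort

`simulate_mixture_reporter()` generates the statistical structure the
estimator assumes, with every parameter explicit. At dose $d$ each cell
independently activates with probability $p(d)$, a four-parameter logistic
in dose (floor $p_{\min}$, ceiling $p_{\max}$, half-max dose, Hill slope),
and draws its log10 output from the active or basal normal population. The
defaults — basal $10^{2.0}$ with 0.35 decades SD, active $10^{3.2}$ with
0.45 decades SD, $p$ from 0.05 to 0.95, twelve half-log-spaced doses
including an unstimulated control, 5000 cells per dose — give broad,
overlapping populations whose activated fraction, not position, encodes
the dose. Draws are made cell by cell in dose order, so a seed fully
determines a dataset.

What the generator does *not* emulate: instrument autofluorescence and
spillover, cell-cycle and size covariates, day effects between biological
replicates, and any temporal dynamics of NF-kB. Tests passing on this
cohort therefore validate the estimation machinery, not the biology of any
particular receptor; conclusions about real channels require the measured
data.

`simulate_known_channel()` is the oracle mode: the channel is an explicit
row-stochastic matrix, outputs are well-separated centers plus small
jitter, and `true_capacity()` gives the exact answer, so estimator error
is measurable. The test suite uses the binary-symmetric-channel family
(crossover 0, 0.11, 0.25, 0.5 — capacities 1, 0.500, 0.189, 0), a
separable 4-input identity channel, and a banded "staircase" channel for
the capacity-vs-maximum-dose curve.

## Signal and noise power

For per-dose means $\mu_i$ and variances $\sigma^2_i$ of the transformed
output, the package defines

$$P_{\mathrm{signal}} = \frac{1}{D} \sum_i (\mu_i - \bar\mu)^2, \qquad
  P_{\mathrm{noise}} = \frac{1}{D} \sum_i \sigma^2_i, \qquad
  \mathrm{SNR} = P_{\mathrm{signal}} / P_{\mathrm{noise}}.$$

Both powers are computed on the same log10 scale used for capacity so SNR
and capacity comparisons align; the across-dose variance is the population
(1/D) form by default with the sample (1/(D-1)) form available. Doses are
unweighted. A channel can fail to transmit either because the mean response
barely moves with dose (low signal power) or because per-dose variability
swamps it (high noise power); the decomposition separates the two.

## Dose-response fitting

`fit_4pl()` fits $y = \mathrm{bottom} + (\mathrm{top} -
\mathrm{bottom})/(1 + (\mathrm{EC}_{50}/x)^{h})$ by least squares,
parameterized internally in $\log_{10} \mathrm{EC}_{50}$. The unstimulated
control ($x = 0$) cannot enter a log-dose axis, but in this form its
prediction is the $h > 0$ limit, `bottom`, so the control anchors the lower
asymptote rather than being discarded. Initialization takes the asymptotes
from the response extremes and the EC50 from the dose nearest the
half-range crossing; a multi-start over Hill slopes {0.5, 1, 2} guards
against local minima. Bounds ($h \in [0.1, 10]$, EC50 within two decades of
the measured dose range) keep flat data from driving the midpoint to
infinity; a failed line search at a near-zero-RSS optimum is distinguished
from genuine non-convergence by a restart from the candidate solution.
The response variable defaults to the per-dose geometric mean of cell
fluorescence (arithmetic mean of the log10 outputs, back-transformed),
with the arithmetic mean of transformed values as the alternative.

EC50 differences between channels are tested with the extra-sum-of-squares
F test: the null model shares one EC50 between the two datasets (bottom,
top and Hill remain per-dataset; 7 parameters), the full model frees it
(8 parameters), and $F = (\mathrm{RSS}_0 - \mathrm{RSS}_1) /
(\mathrm{RSS}_1 / \mathrm{df}_1)$ with 1 and $n_a + n_b - 8$ degrees of
freedom.

## Comparisons across channels

The unit of comparison is the biological replicate: one capacity, SNR or
EC50 estimate per replicate, compared between channel groups by the
two-sided Wilcoxon rank-sum test. With 12 or fewer values in total and no
ties, the null distribution of the rank sum is enumerated exactly over all
$\binom{n_a+n_b}{n_a}$ assignments — at the n = 3-6 replicates typical of
these experiments the normal approximation is not trustworthy and exactness
is cheap. Larger groups use the normal approximation with midranks, tie
correction and continuity correction. No multiple-testing correction is
applied by default (comparisons are reported individually); a
Benjamini-Hochberg flag can be layered on top by the caller.

## Design decisions that were genuinely open

- **Input alphabet.** Capacity is maximized over distributions on the
  measured dose set (including the unstimulated control), not over a
  continuum: the experiment defines the channel's usable inputs.
- **Per-replicate estimation.** Replicates are estimated separately and
  compared, rather than pooled before estimation; pooling would average
  over day effects and hide replicate variability that the rank-sum
  comparisons need.
- **Noise coupling.** Noise power is inherently coupled to signal power in
  a mixture response (the between-population term $p(1-p)(\mu_a-\mu_b)^2$
  appears in both); no decoupling adjustment is attempted — the
  decomposition is reported as defined.
- **Gating.** No automatic gating or compensation is applied; an optional
  rectangular scatter gate is the only filter. Acquisition-side artifacts
  are assumed handled upstream.
- **Robust SD.** Population summaries report the geometric mean with a
  multiplicative robust SD, `exp(1.4826 * MAD(log v))` — the standard
  robust scale estimator on the log scale.

## Problem sizes used in the tests

The suite validates estimator accuracy at 5000 cells per input for the
binary-symmetric family (error below 0.03 bits), 2000 per input for the
separable channel, 1000 cells x 12 doses x 20 seeds for the independence
null (bias-corrected capacity below 0.05 bits in at least 19 of 20), 300
cells per input x 20 seeds for the staircase monotonicity check, and
100000 cells per dose for the closed-form mixture moments (within 1%).
These sizes were chosen so each check is decisive at its stated tolerance
while the whole suite stays fast enough to run routinely.

## Known limitations

- Binned plug-in estimation only; continuous (k-NN, kernel) mutual
  information estimators are out of scope, as is capacity of temporal
  response trajectories.
- The bias-correction line is a heuristic extrapolation; at very small
  cell numbers (near the 50-cell floor) the capacity-vs-1/N relation
  curves and the intercept can undershoot.
- The FCS reader covers list-mode FCS 3.0/3.1 with float, double or
  16/32-bit integer data and the gain/decades amplification keywords —
  the formats a modern benchtop cytometer writes — not the full breadth
  of the standard (no analysis segments, no multi-dataset files).
- The exact Wilcoxon enumeration is limited to 12 total observations;
  beyond that the corrected normal approximation is used.
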