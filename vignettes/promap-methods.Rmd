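---
title: "Model-based differential abundance analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based differential abundance analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(promap)
```

## The problem

Isobaric labeling (iTRAQ/TMT) quantifies thousands of proteins across
samples in a single MS run, but deciding which observed intensity changes
are real requires a model of technical and systematic error. Measurement
noise in these experiments is strongly intensity dependent: low-abundance
proteins show far noisier ratios than high-abundance ones. Many
approaches calibrate that noise from separate technical-replicate
experiments; `promap` instead estimates it directly from the two profiles
under comparison, treating the detected proteins as a mixture of
differential and non-differential ones and letting the
non-differential majority reveal the error distribution.

## Model

For protein $i$ with combined condition intensities $S_{i1}, S_{i2}$,

$$A_i = \tfrac12(\log_2 S_{i1} + \log_2 S_{i2}), \qquad
  M_i = \log_2 (S_{i1}/S_{i2}).$$

The null contribution of technical and systematic error to $M_i$ is
assumed to be $N(0, \sigma_i^2)$ with

$$\sigma_i^2 = \Psi(\theta, A_i) = \exp(\theta_1 + \theta_2 A_i),$$

a smooth, strictly positive, typically decreasing function of mean log2
intensity. Significance of a protein's change is the two-tailed normal
tail probability of $|M_i|$ under its own null variance, and
$Z_i = M_i/\sigma_i$ is standard normal under the null regardless of
intensity, which is what makes Z comparable across runs.

## Estimating the variance function

1. **Normalization.** Each profile's trimmed total excludes proteins
   whose intensity exceeds $Q_3 + L(Q_3-Q_1)$ ($L = 1.5$) in *either*
   profile; each profile is divided by (its trimmed total / mean trimmed
   total). Outliers are only excluded from the totals — they are still
   normalized and tested. Note that the normalized scale is anchored to
   the mean trimmed total, so rescaling one input profile rescales both
   normalized profiles by a common constant while leaving every M value
   unchanged.
2. **Sliding windows.** Proteins are ordered by $A$ and scanned by
   windows of `window_size = 400` proteins advancing by `step = 100`;
   the final window is anchored to the right edge so every protein is
   covered. Within a window the variance is treated as constant.
3. **QQ regression.** The window's $M$ values are ordered and paired
   with standard-normal quantiles at the complete-sample plotting
   positions $\hat p_i = (i-a)/(N-2a+1)$; ordinary least squares through
   the middle `middle_fraction = 0.5` of the pairs — the ratios assumed
   to be dominated by non-differential proteins — gives
   $M = \mu + \sigma\hat q$. The squared slope is the window's variance
   estimate, and the near-perfect linearity of the middle ranks
   (R² typically above 0.99) is the model's own diagnostic.
4. **Global fit.** The per-window variances are fitted against the
   windows' mean $A$ (over the selected proteins) by least squares on
   the exponential $\Psi$, giving $\hat\theta$.

```{r error-model}
sim <- simulate_pair(simulation_config(n_proteins = 5000,
                                       dep_fraction = 0, seed = 1))
res <- map_compare(sim$pair)
model <- attr(res, "variance_model")
model
plot(model)
```

### Plotting positions and censored subsets

`plotting_positions()` implements the Michael–Schucany product formula
for plotting positions of a censored ordered sample,

$$\hat p_i = \frac{N-a+1}{N-2a+1}\prod_{j\in\Omega,\,j\ge i}\frac{j-a}{j-a+1},$$

which telescopes to $(i-a)/(N-2a+1)$ for a complete sample. The formula
is built for right-censored data: applied to a *middle* rank subset it
assigns markedly asymmetric positions (for ranks 101–300 of 400 the
positions run from about 0.335 to 0.997), and a regression against those
quantiles would return a badly biased scale and visibly nonlinear fit.
The sliding-window regression therefore assigns positions over the
complete window sample and restricts only the *regression* to the middle
ranks; the product formula remains available, and exact, for genuinely
censored use cases. The constant $a = 0.3175$ is conventional for this
position family; it shifts all positions by a fraction of a rank and has
no measurable effect on the middle-rank slope, and it is exposed as
`qq_a` for sensitivity analysis.

### Weighting the exponential fit

The sampling error of a window's variance estimate is close to
proportional to its value (the middle-rank QQ slope has a relative SD of
about 6% at the default window size, independent of $A$), while the
variances themselves span orders of magnitude across the intensity
range. Unweighted least squares on the raw variance scale is then
determined almost entirely by the few lowest-intensity windows, and the
fitted curve extrapolates that handful of noisy values exponentially
across the rest of the range — in our validation simulations this
destabilized $\hat\theta$ enough to break the method's own type-I-error
calibration. The default fit therefore minimizes *relative* residuals
(inverse-squared-mean weights, computed as a Gamma GLM with log link),
the standard treatment when the coefficient of variation, not the
absolute error, is constant. `fit_variance_function(weighting =
"absolute")` provides the unweighted objective for comparison. The
reported fit R² is always computed on the raw variance scale.

### Degenerate windows and extrapolation

Windows with zero spread or non-positive middle-rank slope carry no
scale information; they are excluded from the fit with a warning, and
the run aborts if they exceed 20% of windows — data that degenerate are
not described by this error model. $\Psi$ is globally defined, so
variances for $A$ outside the windows' range are obtained by direct
exponential extrapolation; `predict()` reports when that happens.

### The stringent option

The window intercepts $\mu$ fluctuate around zero because global
normalization cannot remove all local bias. `map_compare(stringent =
TRUE)` absorbs this into the null by adding $\sigma^2_\mu$, the variance
of $\mu$ across all windows, to every protein's null variance; stringent
P-values are therefore never smaller than default ones.

## Diagnostics

`rescaled_qq_summary()` divides each window's ordered ratios by that
window's $\hat\sigma$ and summarizes the rescaled values per rank across
windows. Under the null the middle ranks lie on $y = x$; systematic
divergence at the extremes marks differential proteins, and its onset is
a visual check on whether `middle_fraction` is conservative enough. In a
technical-replicate comparison (no true changes) nearly the whole rank
range should follow the line.

```{r rescaled, fig.height = 4}
tech <- simulate_pair(simulation_config(n_proteins = 5000,
                                        technical_replicate = TRUE,
                                        seed = 2))
tres <- map_compare(tech$pair)
pts <- data.frame(protein_id = tres$protein_id, A = tres$A, M = tres$M)
plot_rescaled_qq(rescaled_qq_summary(pts, attr(tres, "variance_model")))
```

## Integration across runs

With $k$ replicate runs, each compared separately, a protein detected in
$k_i$ of them gets

- its best and second-best P-values (the second-best rule trades
  sensitivity for reproducibility: one lucky run cannot promote a
  protein);
- the Stouffer-style average $\hat Z_i = \sum_t Z_i^t/\sqrt{k_i}$, with a
  two-tailed standard-normal P-value and BH adjustment.

Proteins detected in a single run keep their best P and average Z but
have no second-best P; they are flagged by `k`, not dropped.

### FDR by model-based null resampling

`permutation_fdr()` estimates, for each observed value of the integrated
statistic, the expected fraction of false discoveries among proteins at
least as extreme. Null copies of the statistic are generated from the
error model's own null hypothesis over the observed detection pattern:
per round, every detected (protein, run) cell receives $Z^* \sim N(0,1)$
(average-Z statistic) or $P^* \sim U(0,1)$ (second-best P), and the
integrated statistic is recomputed. The estimate is (mean null
exceedance count)/(observed exceedance count), clipped to $[0,1]$ and
monotonized.

Two more obvious resampling designs were evaluated and rejected.
Per-run sign flips of $Z$ — the exact symmetry of the null — leave
$|Z|$ and hence every per-run P-value unchanged, so they cannot generate
a null for the second-best P at all; and for the average Z the flipped
copies of genuinely changed proteins re-align with probability
$2^{-(k-1)}$, contaminating the null's tail. Decoupling runs by
shuffling protein labels suffers the analogous contamination
quadratically in the differential fraction. In simulations with 10%
strong differential proteins both contaminated schemes overestimated the
FDR by 0.15–0.40 at thresholds where the realized false-discovery
proportion was zero, while model-based resampling tracks it closely and
still yields estimates near 1 on pure-null data. The trade-off is that
the null is only as good as the fitted error model — which holds equally
for the P-values themselves.

### Direction consistency

`consistency_score()` computes the fraction of differential proteins
whose direction of change matches an external direction reference (for
example mRNA translation changes from ribosome profiling), over the
proteins present in both; `filter_reference_directions()` prepares such
a reference by dropping log2 ratios of magnitude at or below a threshold
(default 0.2) and keeping signs only.

## The synthetic generator

`simulate_pair()`/`simulate_multi_run()` generate data with exactly the
structure the model assumes: $A \sim U(10, 25)$ (a wide, realistic
log2-intensity dynamic range), null $M \sim N(0, \exp(\theta_1 +
\theta_2 A))$ with defaults $\theta = (2.0, -0.4)$ (null ratio SD from
0.37 at the low-intensity end to 0.018 at the high end), a spiked
differential fraction of 0.1 with a fixed 1.5 log2-unit shift split
evenly between up- and down-regulation (so spiking does not bias the
trimmed-total normalization), three runs with independent per-run noise,
optional per-run dropout, and intensities back-solved to the raw scale
as $S_1 = 2^{A+M/2}$, $S_2 = 2^{A-M/2}$ so the MA transform returns the
drawn values exactly. `as_profile_table()` further splits each condition
between two reporter channels with channel sums preserved.

What the generator deliberately does **not** emulate: ratio compression
from co-isolation interference, peptide-level variation and rollup,
intensity-dependent missingness, or heavy-tailed outlier measurements.
Tests passing on these simulations therefore demonstrate internal
consistency of the estimation machinery — correct variance recovery,
calibrated type-I error and FDR when the model holds — not robustness to
every artifact of real spectra.

## Validation conditions and numerical choices

The package's statistical validation (see `tests/testthat/` and
`scripts/acceptance.R`) uses 5000 proteins per run with the defaults
above: 47 windows of 400 proteins, middle-50% regressions on 200 ranks,
1000 resampling rounds for FDR; the whole suite runs in well under a
minute on one core. Other numerical choices:

- middle-rank selection uses ranks $\lceil N(1-W)/2\rceil + 1$ through
  $N - \lceil N(1-W)/2\rceil$, guaranteeing symmetry; sorting ties are
  broken by $(A, M, \text{id})$ for reproducibility;
- windows require at least 20 proteins and 10 selected ranks;
- the Gamma-GLM fit iterates to a $10^{-10}$ convergence tolerance, with
  the two-window case solved in closed form;
- P-values are floored at the smallest positive double so `-log10`
  transforms stay finite;
- all simulation and resampling functions require an explicit seed.

## Known limitations

- The error model is global and smooth; local violations (e.g. a
  contaminant abundance stratum) surface only through the window
  diagnostics.
- With fewer proteins than `window_size` the model cannot be built;
  reduce the window at the cost of noisier local estimates.
- The second-best P requires detection in at least two runs; proteins
  detected once carry no reproducibility evidence.
- FDR estimates inherit any miscalibration of the fitted error model,
  particularly in the extreme tail.
- When the differential fraction approaches the selected middle
  fraction, the non-differential majority assumption inside windows
  weakens; inspect the rescaled-QQ diagnostic and consider a smaller
  `middle_fraction`.
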