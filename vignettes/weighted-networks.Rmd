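---
title: "Weight-preserving EEG network analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-preserving EEG network analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wnet)
```

This vignette is the package's account of its science: the estimators it
implements, the assumptions behind them, the parameters that matter, and
the places where the design was genuinely open and a choice had to be
made.

## The connectivity model

Sensor-level EEG connectivity is estimated with the weighted phase lag
index,

$$\mathrm{WPLI} = \frac{\left| E[\, \Im(X) \,] \right|}{E[\, |\Im(X)| \,]},$$

where $X$ is the complex cross-spectrum of a channel pair and $\Im$ its
imaginary part. Because a common source seen at two electrodes produces a
*zero-lag* (purely real) cross-spectrum, WPLI discounts exactly the
coupling most likely to be volume conduction, and weights each
observation by the magnitude of its imaginary part, which de-emphasizes
observations whose phase estimate is noisy. The index is 0 under lag-free
or phase-inconsistent coupling and 1 when a fixed nonzero lag is
maintained across all observations.

Cross-spectra come from a windowed Fourier transform on a 0.5 Hz grid
spanning each band — theta 4–7.5 Hz, alpha 8–13.5 Hz, beta 14–20.5 Hz.
The window at frequency $f$ spans $\mathrm{cycles}(f)/f$ seconds, with
the cycle count ramping linearly from 3 at the band's low edge to 10 at
its high edge (clipped to the epoch length); windows tile each 2 s epoch
at 50% overlap.

Two details are not fixed by the estimator's definition and are exposed
as configuration knobs:

* **Taper.** A Hann taper is applied in each window. Any smooth taper
  would do; Hann is the common default for windowed Fourier analysis and
  its choice only affects leakage, not the WPLI limits.
* **Pooling order.** The expectation $E[\cdot]$ is taken *jointly* over
  epochs, window positions and in-band frequency bins (`pool = "pooled"`,
  the default), rather than computing per-epoch WPLI values and averaging
  them. Joint pooling is the estimator-consistent reading of "computed
  over all epochs and averaged across time": the per-epoch variant is a
  different (positively biased at small samples) statistic, and is
  available as `pool = "per_epoch"` for sensitivity analysis.

When every imaginary part of a pair's observation set is numerically zero
(identical signals, or silent channels) the ratio is 0/0; the package
defines WPLI as 0 there, reading "no lagged coupling detectable" rather
than propagating `NaN`.

A consequence of the adaptive window rule worth knowing: at a band's low
edge the window is only 3 cycles long, so its spectral concentration is
poor. A strong constant-lag oscillation *outside* a band can leak a
genuinely constant-lag component into that band's short windows, and WPLI
— correctly — reports it. Band specificity in simulations should
therefore be read as *dominance* of the coupled band, not as exact zeros
elsewhere.

## Network construction

Weighted analyses operate on max-normalized matrices (every entry divided
by the matrix maximum), which removes group differences in overall
connectivity strength while preserving edge ranking. Proportional
thresholding retains the $k = \mathrm{round}(\mathrm{PT}/100 \cdot
n(n-1)/2)$ strongest edges over the grid PT = 3–60% in 1% steps — 58
levels. (A description of this design as "60 thresholding levels"
circulates; the 3–60 step-1 grid has 58, and the package follows the grid
as specified rather than silently reinterpreting it.) Rounding of $k$ is
half-up via R's `round`; edges tied exactly at the cut are admitted in
lowest-(row, column) order, so thresholding is fully deterministic.

Edge-distance profiles bin each edge by inter-electrode Euclidean
distance into four ranges — very short (<57 mm), short (57–114), long
(115–170), very long (171–227) — interpreted half-open on the right from
the printed integer boundaries, with the final range closed; distances
beyond 227 mm warn and fall into the last bin.

## Graph measures

* **Degree / strength**: row sums of the (binary or weighted) adjacency.
* **Clustering**: binary, the fraction of closed neighbour pairs;
  weighted, the geometric-mean triangle form
  $C_i = \sum_{j,h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3} / (k_i(k_i-1))$
  on max-normalized weights. This is the standard weighted generalization
  whose value reduces *exactly* to the binary coefficient when all
  surviving weights equal 1 — the "bridge invariant" that the test suite
  enforces for every measure.
* **Characteristic path length**: mean shortest-path distance over
  connected pairs; weighted edges map to lengths $1/w$ (strong coupling =
  proximity). Node pairs in different components are *excluded* from the
  average (with a reported count) rather than entering as infinities,
  which keeps L finite at the sparse end of the PT sweep. A fully
  disconnected graph is a degenerate input and errors.
* **Modularity**: Louvain optimization of Newman Q at resolution 1, best
  of 10 seeded restarts with node-order shuffling; the trivial one-module
  partition (Q = 0) is a floor. The seed is part of the API — modularity
  is the one measure whose optimizer is stochastic.
* **Surrogate normalization**: N-C and N-L divide C and L by their means
  over 50 degree-sequence-preserving rewired surrogates; for weighted
  graphs the surviving weights are additionally shuffled over the rewired
  topology. Small-worldness is $\sigma = \mathrm{N\text{-}C} /
  \mathrm{N\text{-}L}$. Both modes consume the random stream identically,
  so the bridge invariant holds exactly for the normalized measures too.
  If rewiring fails on a degenerate graph the package warns and falls
  back to weight-shuffle-only surrogates.

## Density dependence

Each measure is evaluated along the PT sweep; the companion scalar for
group tests is the mean across levels. Dependence on density is
quantified three ways:

1. **Spearman correlation** between pooled metric values and PT levels,
   with a permutation null (default 5,000 shuffles of values against
   levels); "significant" means outside the central 95% of the null. A
   phrasing of this criterion as "|ρ| < .025%" appears in the field; the
   package reads it as two-sided rejection at 2.5% per tail (α = .05).
   The headline correlation pools all groups and bands jointly; per-group
   curves are exposed for finer analysis.
2. **Power-law fits** `value = a·tᵇ + c` with `t = PT/100 ∈ (0, 1]`, by
   Levenberg–Marquardt least squares multi-started over the exponent grid
   {0.05, 0.25, 0.5, 1, 2} to avoid local minima; 95% CIs come from the
   linearized covariance, the convention of standard curve-fitting
   toolboxes (bootstrap CIs would be a drop-in alternative).
3. **The derivative-ratio criterion**: with binary fit $ft^g + h$ and
   weighted fit $mt^n + q$, the weighted curve depends less on density
   where $\frac{mnt^{n-1}}{fgt^{g-1}} < 1$. The ratio is $A\,t^{\,n-g}$
   with $A = mn/fg$, monotone in $t$, so the solution is the closed-form
   interval bounded by $t^* = A^{-1/(n-g)}$, on the side given by the
   sign of $n-g$; empty and full intervals are returned explicitly. With
   the published clustering coefficients (f = 0.8065, g = 0.6718,
   m = 0.9912, n = 0.06905) the boundary evaluates to 0.0323 (4 d.p.),
   i.e. the weighted measure is the steadier one on essentially the whole
   density range.

Whether density curves should be fit per subject or on group means is
genuinely open; the pipeline's default correlates pooled per-subject
curves and fits pooled mean curves, and both per-subject values and the
pooled curves are returned so either convention can be applied.

## Group statistics

Mean connectivity and averaged network measures are compared with
Kruskal–Wallis omnibus tests followed by two-tailed Mann–Whitney post
hocs under Holm–Bonferroni control (exact p for small untied samples,
normal approximation with tie/continuity correction otherwise — the exact
switch follows `wilcox.test`'s applicability rather than a hard n = 8).
Effects of group *across* threshold levels use the Mack–Skillings
statistic: observations are ranked within each block (PT level), group
rank sums are centred and variance-scaled per block, and the quadratic
form is referred to χ²(groups − 1). This reduces to Friedman's test at
one replicate per cell; the implementation is validated against a
within-block permutation oracle in the test suite. Balanced cell counts
(the package's use case) make the χ² reference exact in form; unbalanced
designs pass through the same formula with the per-group variance terms,
which is approximate.

The network-based statistic is re-implemented rather than wrapped: a
per-edge group statistic (one-way F for multi-group designs; one-tailed
pooled-variance t for two groups — F chosen where the toolbox convention
is ambiguous), a component-forming threshold (defaults 8 for F, 3.8 for
the post hoc t), connected components of the supra-threshold graph, and a
max-component-size (edge count) permutation null with the add-observed
convention $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$, so
no p can fall below $1/(n_{perm}+1)$. A Bonferroni family of 12 applies
to the post hoc NBS comparisons (α/12) when all pairwise contrasts are
run. A threshold admitting more than half of all edges triggers a
too-lenient warning.

Regional analyses gate on a two-way mixed ANOVA (region within subject ×
group between subjects, classical sums of squares, sphericity assumed —
with four regions a Greenhouse–Geisser correction would be stricter and
can be applied downstream); only a significant region × group interaction
opens the per-region rank tests. Clinical correlations are Spearman, per
group/band/measure/score, deliberately reported *uncorrected* and flagged
as such, with fewer than five pairs flagged unstable.

## Classification

The diagnostic harness is a 500-tree random forest under repeated
stratified cross-validation (6 folds × 10 repetitions by default). Class
imbalance is handled by random undersampling of the majority class within
each training fold — the simplest member of the resampling family, chosen
because the planted-effect recovery it must demonstrate does not hinge on
the resampler; class weighting can be substituted by disabling
undersampling. Out-of-fold probabilities are pooled for the ROC curve;
accuracy, F1, PPV, NPV and AUROC are aggregated per fold as mean ± sd.
The reported operating point maximizes Youden's J (sensitivity +
specificity − 1), ties broken toward higher specificity.

## What the synthetic cohorts are — and are not

The generator builds band-limited oscillatory signals: each coupled pair
shares a sinusoidal carrier (frequency jittered within the band per
epoch, random starting phase) with the second channel delayed by the
requested lag; each channel carries an independent same-band oscillator
at amplitude 1 − strength and white noise. This is the simplest signal
model whose phase structure WPLI provably detects, with analytic limits
(strength 1, zero noise, lag π/2 ⇒ WPLI = 1 exactly; strength 0 ⇒ no
systematic lag). Group effects are planted as per-band multiplicative
attenuation of coupling strengths, subject variability as a log-normal
multiplier (sd 0.15 by default), and clinical-score correlations by
Gaussian-copula mixing of the standardized coupling rank with noise
(target rank correlations are approached within about ±0.1, not
guaranteed).

What it does **not** emulate: volume conduction and field spread, 1/f
background spectra, artifacts (ocular, muscular), non-stationarity,
realistic head geometry (the layout is a Fibonacci cap on a 100 mm
sphere, which keeps all inter-electrode distances within the 227 mm
analysis ceiling), or any empirically calibrated effect size — the real
cohorts' per-edge effects are not published, so planted effects are free
parameters. Passing recovery tests therefore demonstrates that the
*pipeline* detects what was planted at the stated sizes, not that those
sizes match clinical data. Default sampling rate is 256 Hz (configurable);
simulations in the test suite run at 128 Hz, which is comfortably above
4× the highest band edge.

Scalp regions (frontal / lateral / central / posterior) are assigned from
electrode coordinates by an anterior/posterior/temporal-band quadrant
rule; "lateral" is the same region a temporal-lobe labelling would give.

## Numerical choices and problem sizes

Zero-denominator WPLI pairs return 0; asymmetric matrices beyond 1e-9 are
format errors on read; thresholding tie-breaks and k-rounding are as
above; power-law fits error only after all multi-starts fail, with the
collected diagnostics. All stochastic entry points take explicit seeds,
derive child seeds deterministically, and restore the caller's RNG state.

The validation suite runs its Monte-Carlo studies at deliberately modest
sizes — cohorts of 8–24 channels, 3–6 epochs, 10–15 subjects per group,
20-seed recovery loops, 50-seed null calibrations, 300–500 permutation
draws — sizes at which every planted effect in this vignette is
comfortably detectable and the whole suite stays inside a few minutes on
one core. The statistics scale unchanged to 128-channel, 5,000-permutation
analyses; only wall time grows.

## Known limitations

* Sensor-space only; no leakage correction or source modelling, so
  interpretation inherits all the usual caveats of scalp connectivity.
* The Mack–Skillings χ² reference is exact in form for balanced designs
  only (see above).
* The NBS edge statistic assumes exchangeability of subjects under the
  null; covariates are not supported.
* Weighted path lengths use 1/w; other monotone mappings (e.g. −log w)
  would change L's scale but not the package's qualitative contrasts.
* EDF import is not provided; recordings enter through the native text
  container or in memory.
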