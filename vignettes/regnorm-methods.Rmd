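---
title: "Methods: normalization assessment for two-channel regulation microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization assessment for two-channel regulation microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regnorm)
```

## The measurement model

A two-channel regulation microarray hybridizes a total-DNA input sample
(green, Cy3) against an immunoprecipitated sample (red, Cy5) that is
enriched for protein-bound or methylated DNA. For probe $i$ on array $j$,

$$M_{ij} = \log_2 \frac{R_{ij}}{G_{ij}}, \qquad
  A_{ij} = \tfrac12\left(\log_2 R_{ij} + \log_2 G_{ij}\right).$$

$M$ measures enrichment; its distribution is a mixture of an un-enriched
component (targets largely absent from the precipitate) and an enriched
component. The biologically meaningful quantity is a probe's *rank* in
that distribution — enrichment finders test whether a window of tiling
probes over-samples the upper quantile — so the package's quality metric
for a normalization is whether the two components remain separated after
it is applied.

Separation is scored as the ROC AUC between negative-control probes
(probes with no genomic target, measuring non-specific annealing and
background fluorescence; the negative class) and gene-promoter probes
(the positive class). `roc_auc()` computes the curve by a threshold sweep
and the AUC independently by the Mann–Whitney rank statistic with
half-credit for ties; the two routes must agree to $10^{-10}$ or the
function errors. This makes the AUC invariant under any strictly
increasing transform of the scores, which is exactly the invariance the
rank argument requires.

## The six normalization methods

* **LOWESS** (`lowess_normalize`): per array, a robust local regression of
  $M$ on $A$ is subtracted. Assumes $M$ is centred at zero at every
  intensity — false when enrichment correlates with intensity, which it
  does by construction (enriched probes gain red signal). The smoother is
  a local *quadratic* loess (`degree = 2`, bisquare `family = "symmetric"`,
  span 0.3, 4 robustifying iterations): a locally linear smoother carries
  curvature bias at the support boundary of order the bandwidth squared,
  which is visible against the ±0.02 per-decile detrending contract the
  package holds itself to; local quadratic removes it. For speed the fit
  uses an $A$-ordered thinned subset of at most 5000 probes and predicts
  at all probes; the subset always contains the extremes, so no
  extrapolation occurs.
* **Quantile, channels pooled** (`quantile_normalize`): all $2n$ channel
  log-intensity vectors are replaced rank-wise by the mean of same-rank
  values (limma's `normalizeQuantiles`). Afterwards every channel has an
  identical distribution — including red versus green, which erases the
  systematic red/green difference that *is* the enrichment signal.
* **VSN-style** (`vsn_normalize`): a calibrated generalized-log model,
  $h_c(x) = \mathrm{glog}_2((x - a_c)/b_c)$ per channel with
  $\mathrm{glog}_2(y) = \log_2(y + \sqrt{y^2 + 1})$. Parameters are
  estimated by trimmed Gaussian maximum likelihood: the squared deviations
  of transformed values from their across-channel mean are minimized over
  the majority subset of probes (least-trimmed-squares, 90 % retained by
  default), with the log-Jacobian of the transform in the objective. The
  Jacobian term is not optional: under plain least squares the objective
  is degenerate — flattening every transform ($b_c \to \infty$) drives the
  agreement criterion to zero. Optimization is block coordinate descent on
  a deterministic subsample (≤ 5000 probes, evenly spaced along the
  mean-intensity rank): each channel's $(a_c, \log b_c)$ is fitted against
  the leave-one-out mean of the other channels (which profiles the
  reference out exactly), followed by a joint common-mode step over a
  shared shift and rescaling of all transforms — a direction individual
  channel updates cannot explore because the reference follows them, yet
  the one that decides where the glog bends and hence whether variance is
  stabilized. The trimmed subset is frozen after ten sweeps so the
  alternation converges monotonically; iteration stops when the objective
  changes by less than $10^{-4}$ relative, beyond which the only movement
  is along a near-invariant common affine rescaling (the log-RSS and
  Jacobian terms cancel to first order) that leaves the normalized
  log-ratios unchanged up to a common scale. The estimator is labelled
  VSN-*style*: it is the same model class and majority-agreement
  assumption as variance stabilizing normalization, not a port of any
  reference implementation. Note the affine-glog family contains started
  logarithms ($\log_2(x + c)$, reached as $b \to 0$ with $a \to -\infty$
  jointly), so the reported $(a_c, b_c)$ are one representative of an
  equivalence class; only the fitted transform is identified.
* **T-quantile** (`tquantile_normalize`): quantile normalization within
  channel subgroups — once across all green channels, once across all red
  channels. Within-array, within-channel ranks are preserved exactly and
  the red/green difference survives, while between-array distribution
  differences (scanner gain, IP efficiency, intensity-dependent bias
  amplitude) are removed.
* **Tukey's biweight scaling** (`tbw_scale`): each array's $M$ vector is
  shifted by its Tukey biweight location — the bisquare-weighted mean
  iterated from the median, with weights $(1 - u^2)^2$ for
  $|u| < 1$, $u = (x - \hat\mu)/(c \cdot \mathrm{MAD})$, zero outside, so
  points far from the centre do not influence the estimate. Defaults
  $c = 5$, tolerance $10^{-6}$, at most 50 iterations; the MAD is the
  unscaled median absolute deviation about the initial median and is held
  fixed across iterations; a zero MAD returns the median. A per-array
  constant shift is rank-preserving, so per-array ROC curves are
  *identical* to the raw data's — exactly, not approximately. The combined
  (arrays pooled) ROC is identical only when the per-array constants
  coincide, since different shifts re-interleave the pooled ranks; the
  package therefore asserts the per-array identity exactly and tracks the
  combined AUC stochastically.
* **Peng's method** (`peng_normalize`): the centered $(A, M)$ cloud is
  rotated about its centroid so the major axis — estimated by total least
  squares, i.e. the first principal direction — is horizontal, then the
  rotated coordinates are detrended with the same robust loess. The
  rotation is recorded in the diagnostics. When enrichment itself tilts
  the cloud (enriched probes have both higher $M$ and higher $A$), the
  rotation mixes intensity into the log-ratio.

Quantile and T-quantile are idempotent to machine precision; all methods
preserve shape and produce finite output on finite input; these are
asserted in the test suite.

## The two-component mixture fit

`fit_two_component_mixture()` fits a two-component Gaussian mixture to a
log-ratio vector by EM, deterministically given its initialization
(component means at the 25th and 90th percentiles, both standard
deviations at the pooled value, equal weights). The log-likelihood is
checked to be non-decreasing at every step. Components are ordered so the
enriched one has the larger mean. A component standard deviation below
$10^{-6}$ aborts with an error (the data support fewer components); a fit
with a weight below 2 % or means closer than a tenth of the pooled
standard deviation is flagged `degenerate` rather than failed, since
one-component data is a legitimate input. The Gaussian shape is an
approximation: with partial-occupancy enrichment the enriched component is
left-skewed, and the fitted weight is then a slight underestimate of the
true enriched fraction (the overlap region is credited to the dominant
un-enriched component).

## The enrichment finder

`enrichment_pvalues()` implements the upper-quantile sliding-window test.
The threshold $t$ is the empirical `threshold_quantile` (default 0.95) of
the supplied log-ratios — computed per input vector, after normalization,
so only ranks matter. For each probe, the window holds all probes on the
same chromosome within half a window width (default window 1000 bp) of
its position; with $k$ of $n$ window probes above $t$ against $K$ of $N$
overall, the p-value is the one-sided, Yates-corrected $\chi^2$ test
(1 df) on the table $[[k, n-k], [K-k, (N-n)-(K-k)]]$, set to 1 whenever
$k/n \le K/N$. Single-probe windows get $p = 1$ and a flag. Regions are
maximal runs of probes with $p < \alpha$, merged across gaps smaller than
half the window (the merging gap is a convention, exposed as an
argument), reported as 0-based half-open intervals with counts at the
customary cut-offs 0.05 / 0.10 / 0.20 / 0.50. Because the test depends
only on threshold ranks, any strictly increasing transform of the
log-ratios — a per-array biweight shift in particular — leaves every
p-value unchanged; the suite asserts this identity directly.

No multiplicity correction is applied across probes: the finder reports
raw p-value cut-offs, and neighbouring windows share probes, so region
counts are descriptive, not error-controlled.

## What the synthetic generator emulates

`simulate_experiment()` generates two-channel experiments with known
ground truth. Its structure follows the physics of the assay:

* **Target abundance.** Each probe's genomic target has abundance
  $T = 2^{\mu + \varepsilon_i}$ with a probe-affinity effect
  $\varepsilon_i \sim N(0, \sigma_b)$ shared between channels and arrays
  (default $\mu = 10$, $\sigma_b = 1$, in log2 fluorescence units).
* **Background floor.** Both channels measure signal plus an additive
  background-fluorescence floor; negative-control probes have no target
  and measure the floor alone. The red floor sits lower than the green
  (default 2 log2 units): the IP pool contains far less total DNA, hence
  less non-specific material. Defaults: floor 2.5 log2 units below the
  target mean. With the floor disabled
  (`background_floor_drop = Inf`) the generator reduces to an exact
  shift model used by the closed-form tests.
* **Enrichment.** An un-enriched target is largely absent from the IP
  sample but not perfectly so: a non-specific retention fraction (default
  0.25) carries into the red channel. Enrichment interpolates
  geometrically between retention and the full IP gain
  `enrichment_shift` (default 2 log2 units), linear in the weight $w$ on
  the log scale. Promoter targets are enriched with probability
  `enriched_fraction`; each enriched target's occupancy (fraction of
  cells methylated / bound) is drawn from a Beta distribution (default
  Beta(2, 1)) — enrichment is not an all-or-nothing condition, and this
  is what gives the enriched component its continuous, partially
  overlapping shape. Tiling probes near a planted site receive
  $w = \mathrm{occupancy} \cdot e^{-d/L}$ with $d$ the distance to the
  site centre and $L$ the mean sonication fragment length (default
  600 bp): under Poisson fragmentation the probability that a fragment
  covering the site also covers the probe decays exponentially, giving
  the familiar peak shape. The exponential kernel is the simplest
  choice consistent with that argument — one parameter, monotone, exact
  in closed form for tests.
* **Technical bias.** Observed log-ratios are
  $M^{obs}_{ij} = s_j M_{ij} + t_j\, P(A_{ij} - \bar A) + o_j$ with a
  polynomial dye trend $P$ in centred $A$ (default
  $0.1 A_c - 0.03 A_c^2$, centring makes coefficients scale-free),
  per-array trend amplitude $t_j$, channel scale $s_j$ and offset $o_j$
  (log-normal / normal with sds 0.4, 0.15, 0.15), and per-array IP
  efficiency (log-normal, sd 0.15) scaling the enrichment gain itself.
  Scale and offset are monotone per array and cannot move a per-array
  AUC; trend amplitude and IP efficiency are the heterogeneities that do,
  and they are the ones a between-array normalization can remove.
  Intensities are back-computed from $(M^{obs}, A)$, so channel files
  carry the bias consistently.

Two presets fix the study conditions and differ only in
`enriched_fraction` and `n_planted_sites`: ChIP-like (0.02, 5 sites —
binding sites cover little of the genome, control and promoter densities
largely overlap, and the normalization methods perform comparably) and
MeDIP-like (0.35, 20 sites — a substantial methylated fraction, visible
separation, and strong divergence between methods). The default array is
promoter-centric (30,000 promoter, 8,000 tiling, 2,000 control probes; 8
arrays), matching the composition of promoter platforms where the
two-component structure is most pronounced.

What the generator does **not** emulate: probe sequence (no GC-content
effects on intensity or methylation probability — in real MeDIP data
methylation level and signal both correlate with CpG/GC density, which is
one documented way LOWESS introduces rather than removes bias), spatial
slide artifacts, scanner saturation, and correlated replicate structure
beyond shared probe effects. Passing tests therefore demonstrate that the
methods behave as designed under the stated statistical structure, not
that any particular real dataset will show effects of the same size.

## Numerical and design choices

* Coordinates are 0-based half-open internally and in BED output; GFF
  output and pair/annotation files are 1-based (converted on read/write).
* Non-positive raw intensities are rejected by default; an explicit flag
  floors them at 0.5 fluorescence units instead.
* Log base 2 throughout.
* Quantile tie handling averages ties (limma convention); the ROC uses
  Mann–Whitney half-credit, which makes identical class distributions
  score exactly 0.5.
* The biweight's tuning constant ($c = 5$) follows common usage for this
  estimator; the scale is the unscaled MAD so that the weights have the
  textbook form.
* EM stops on an absolute log-likelihood change below $10^{-8}$ or 500
  iterations.
* The enrichment window is defined in bp around the probe position, per
  chromosome; threshold quantile, window and merging gap are all exposed.
* Pipeline outputs (`run_comparison(..., out_dir = )`) contain no
  timestamps, so identical configuration and seed reproduce every report
  file byte-for-byte.

## Problem sizes in the shipped tests

Unit tests run on reduced conditions (hundreds to a few thousand probes,
1–6 arrays) with the same scientific defaults. The headline property —
T-quantile and Tukey's biweight scaling preserve component separation
while pooled quantile, LOWESS, VSN-style and Peng's method erode it, and
T-quantile additionally lowers the across-array AUC dispersion — is
exercised on 20 seeded MeDIP-like simulations at the full preset scale
(8 arrays × 40,000 probes, all six methods). Mixture recovery uses
10,000 draws from a 70/30 mixture; the enrichment finder's null
false-positive rate and planted-site recovery use 20 seeded replicates
each. `scripts/acceptance.R` re-runs the full-scale comparison and these
recoveries from a single command-line seed.

## Limitations

* The comparison is on replicate arrays of one condition; multi-condition
  designs normalize each condition separately (or jointly when
  differential enrichment is known to be rare), and that scoping is the
  caller's responsibility.
* The ROC metric needs annotated negative-control and promoter probes;
  platforms without control probes cannot be scored this way.
* The VSN-style estimator is a deliberate re-derivation of the calibrated
  glog model, not a reimplementation of any published tool's internals;
  conclusions about "VSN" from this package are conclusions about that
  model class.
* Mixture components are Gaussian; strongly skewed enriched components
  bias the fitted weight downward.
* Region counts are tool-convention-dependent (merging gap, window
  definition) and should be compared only within a fixed configuration.
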