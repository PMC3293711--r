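# regnorm

Normalization assessment for two-channel "regulation" microarrays —
ChIP-on-chip and MeDIP-on-chip.

## The problem

On a regulation microarray the two channels are not two conditions: the
green (Cy3) channel carries total input DNA and the red (Cy5) channel an
immunoprecipitated, *enriched* sample (protein-bound or methylated DNA).
The per-probe log-ratio `M = log2(red/green)` therefore measures
enrichment, and its distribution is a superposition of two components — an
**un-enriched** component from probes whose targets are largely absent from
the precipitate, and an **enriched** component. Everything downstream
(sliding-window enrichment finding, target calling) reads the *upper
quantile* of this distribution, so a normalization method is only
appropriate if it (i) makes arrays quantitatively comparable while (ii)
preserving the separation between the two components.

Popular transcriptomics normalizations assume the majority of probes are
unchanged between channels. On regulation arrays the channels differ by
construction, and methods built on that assumption can destroy the very
signal being measured. `regnorm` makes this failure measurable.

## What the package provides

* **Six normalization methods** behind a single interface
  (`normalize_experiment()`): LOWESS (`lowess_normalize`), pooled-channel
  quantile (`quantile_normalize`), VSN-style calibrated generalized-log
  (`vsn_normalize`), T-quantile — quantile normalization applied to the
  red and green channel groups separately (`tquantile_normalize`), Tukey's
  biweight scaling (`tbw_scale`, with the `tukey_biweight` location
  estimator), and Peng's MA-rotation method (`peng_normalize`).
* **A separation metric**: ROC curves and AUC between negative-control
  probes (negative class) and gene-promoter probes (positive class),
  per array and on combined data (`roc_auc`, `separation_report`), with the
  AUC computed both by threshold sweep and by the Mann–Whitney rank
  formula (the two must agree to 1e-10).
* **A two-component Gaussian mixture fit** of the log-ratio distribution by
  EM (`fit_two_component_mixture`).
* **An ACME-style enrichment finder**: sliding-window upper-quantile
  chi-square test (`enrichment_pvalues`), region calling at the usual
  p-value cut-offs (`call_regions`, `region_counts`).
* **A synthetic-data generator** (`simulate_experiment`) with known ground
  truth: two-component log-ratio structure, Poisson-fragmentation peak
  shapes on tiling probes, additive background-fluorescence floor,
  intensity-dependent dye trend, and per-array scale/offset/IP-efficiency
  jitter. Two presets ship as YAML configs: `chip_like_config()`
  (small enriched fraction) and `medip_like_config()` (substantial
  methylated fraction).
* **I/O**: NimbleGen-style pair files (`read_pair_files`,
  `write_experiment`), probe annotation TSV, GFF p-value tracks
  (`write_pvalue_gff`), BED region calls (`write_regions_bed`).
* **An end-to-end pipeline** (`run_comparison`): simulate → normalize with
  every method → score separation → find enriched regions → summarize.

## Worked example

```r
library(regnorm)
cmp <- run_comparison(medip_like_config(seed = 42))
print(cmp)
```

```
normalization comparison
combined control-vs-promoter AUC:
  tquantile  0.8990
  tbw        0.8953
  raw        0.8492  (unnormalized)
  lowess     0.5689
  quantile   0.4806
  vsn        0.4674
  peng       0.4590
across-array AUC sd:
  raw        0.0295
  lowess     0.0107
  quantile   0.0064
  vsn        0.0132
  tquantile  0.0231
  tbw        0.0295
  peng       0.0350
```

Reading the output: on MeDIP-like data (35 % of promoter targets
methylated) the raw control-vs-promoter AUC is 0.85 — the enriched
component clearly separates promoters from negative controls. T-quantile
and Tukey's biweight scaling *preserve* (here: improve, by removing
between-array jitter) that separation, while pooled quantile, LOWESS,
VSN-style and Peng's normalization collapse it toward chance (AUC ≈ 0.5):
they force the enriched channel onto the un-enriched reference
distribution and thereby spread un-enriched probes across the enriched
probes' dynamic range. Tukey's biweight scaling shifts each array by a
constant, so its per-array ROC curves equal the raw data's exactly; the
across-array AUC standard deviation shows why T-quantile is preferable —
as a between-array method it also makes the individual arrays more
comparable (sd 0.023 vs 0.030).

The comparison also runs the enrichment finder on the combined tiling
probes per method (`cmp$region_counts`, `cmp$site_recovery`): strongly
enriched planted sites are recovered under every normalization, mirroring
the fact that only moderately enriched regions are sensitive to the choice
of method.

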