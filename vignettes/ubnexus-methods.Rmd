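---
title: "ubnexus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ubnexus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ubnexus)
```

This vignette documents the statistical models, the synthetic-data
generators, the numerical conventions, and the design decisions behind the
package — the things a maintainer or reviewer would want written down.

## 1. Substrate nomination: the three evidence streams

### diGly ubiquitylome (`site_log2fc`, `flag_lost_ub`)

For every diGly site, replicate intensities are collapsed by arithmetic
mean per condition and the fold change is `log2((mean_KO + pc) /
(mean_WT + pc))` with a default pseudocount of 1 intensity unit to guard
zeros.  A protein "loses ubiquitylation" when at least one of its sites
has log2FC ≤ −0.5.

*Design note.* The |0.5| cutoff is interpreted on the **log2** scale (the
fold-change heatmaps this style of filter comes from are labelled in
log2 units); a linear-scale reading would be more permissive.  The cutoff
is an ordinary argument (`threshold`), so either convention can be run.

### IP enrichment (`g_test`, `fold_enrichment`, `call_interactors`,
`assemble_network`)

The G-test compares a protein's spectral counts in the bait IP and IgG
control runs to expectations proportional to the run depths
(`e_i = T_i (c_ip + c_igg) / (T_ip + T_igg)`), which is the standard
spectral-counting formulation and is robust to unequal sampling depth.
Conventions:

* no Williams or continuity correction (1 df; at very low counts the test
  is mildly anticonservative — a documented limitation);
* a pseudocount of 0.5 is used in the fold-enrichment ratio only, never in
  the G statistic;
* the significance box is raw `p < 0.05` and fold enrichment > 1.5,
  matching the volcano-style convention such scatter plots use; an
  optional `adjust = TRUE` gates the box on Benjamini–Hochberg q instead,
  since whether the original analysis corrected these p-values is not
  stated.

The interaction network is assembled from a *pre-scored* edge table
(node, node, confidence): edges below 0.7 ("medium confidence") are
dropped, nodes are restricted to the in-box interactors plus the bait, and
self-loops are removed.  The package never queries a remote database;
confidence scores are inputs.

### Context-dependent screen (`screen_gene_results`)

Guide counts are CPM-normalized per sample, per-guide log2 fold changes
(day 10 vs day 0, pseudocount 1) are averaged across replicates, and each
gene is tested with a two-tailed **paired** t-test across its
guide-matched fold changes in the two contexts.  The gene summary
statistic is the median guide fold change (robust to one bad guide).
Genes are classified by the context with the larger |median| and the sign
of that median (`enriched_sgFBXO11`, `depleted_sgCTRL`, …) when the BH
q-value (default; raw p optional) is below α.  Zero-variance paired
differences yield p = 1 with a `degenerate` flag rather than an error.
Robust rank aggregation (MAGeCK-style) is deliberately not reimplemented:
the paired-FC analysis is the defined statistic here.

### Integration (`build_profiles`, `nominate`)

Streams are outer-joined on a single protein/gene id namespace (an
explicit `id_map` table can harmonize ids; unmapped ids are reported,
never dropped).  A protein is nominated iff all three booleans hold.  The
rank score — the sum of per-stream z-scores of `−min site log2FC`, `G`,
and `|paired difference|` — is a package-defined composite used only for
ordering, since the selection itself is the intersection.

## 2. Proteome stage

Quantities are log2-transformed; proteins must be quantified in ≥ 50% of
the samples of at least one group; sample columns are median-centered.
Missing LFQ values stay missing — DIA missingness is informative absence,
so nothing is imputed and every test uses available values only.

* **Differential abundance**: per-protein two-sided Welch t-test, BH
  q-values, "significant" means raw `p < 0.05` and |log2FC| > 0.5 (the
  volcano convention; q is also reported).
* **PCA**: top 50% most-variable proteins, complete cases, centered
  singular-value decomposition.
* **Clustering**: top 400 proteins ranked by differential p-value, rows
  z-scored, distance `1 − Pearson r`, average linkage — the common
  defaults of the web clustering tools this emulates; both are exposed as
  arguments.
* **Network projection**: node log2FCs become vertex attributes; nodes
  missing from the differential results are flagged, not dropped; the
  summary is the mean over measured nodes.
* **GSEA** (`gsea_custom_set`): ranking metric is the Welch t statistic
  (the original ranking is unstated; this choice is exposed as the input
  ranking, so any metric can be supplied).  The null is **gene-label
  permutation** (random same-size sets), not sample permutation: with 6
  vs 13 samples, sample permutation has too few distinct relabelings.
  Defaults: 1000 permutations, mandatory seed.
* **Cross-omics correlation**: Pearson and Spearman on inner-joined fold
  changes.

## 3. Splicing stage

PSI is `I/(I+S)` per sample (undefined when `I+S = 0`); with
`length_normalize = TRUE` counts are first divided by the
inclusion/skipping form lengths.  Group differences use a binomial
likelihood-ratio test on **pooled** within-group counts against a shared
proportion, with ΔPSI the difference of mean per-sample PSIs.  The event
filter is FDR < 0.05 ∧ p < 0.05 ∧ |ΔPSI| > 0.15.

*Design note.* The hierarchical replicate model of rMATS is not
reproduced; the pooled LRT is a stated substitution because the in-scope
contribution is the threshold-based event selection, not the rMATS
likelihood.  Pooling ignores between-sample overdispersion, so its
p-values are anticonservative when samples within a group truly differ;
the synthetic generator draws samples from a shared group proportion,
where the pooled test is exact in distribution.

Expression quartile grouping assigns samples with percentile rank ≥ 0.75
(midranks for ties) to the high group and ≤ 0.25 to the low group,
following the upper-quartile-equals-high convention; an all-tied vector
returns empty groups with a degenerate flag.

## 4. Imaging stage

* **Segmentation**: global Otsu threshold on the DAPI channel, hole
  filling, connected components, minimum-area filter.
* **Compartments**: Otsu recomputed from the pixels *inside each ROI*
  ("relative" thresholding); bright ∪ dim partitions the ROI exactly.
* **Shape**: perimeter by the 4-direction Crofton estimate
  (`P = (π/8)(n_0 + n_90 + (n_45 + n_135)/√2)` with unit/diagonal line
  spacings); circularity `4πA/P²` clamped at 1 because the digital
  perimeter can underestimate slightly for small discs; Feret diameters by
  rotating calipers over the convex hull of pixel corners at 1° steps
  (worst-case width error ≈ `(1 − cos 0.5°) ≈ 4·10⁻⁵` relative).
* **Colocalization**: plain Pearson correlation over the pixels of each
  compartment mask; masks with < 3 pixels or zero variance give `NA`.
* **Intensity**: MFI and the *population* SD per nucleus (so a half/half
  two-level nucleus with levels a, b has SD = |a−b|/2 exactly).
  `relative_mfi()` divides by the control-group mean — the normalizer is a
  configuration choice because the original one is unstated.

Numerical conventions worth knowing: the Otsu criterion is flat across an
empty histogram gap between two well-separated modes, so the threshold is
taken at the **midpoint of the maximal plateau** (the ImageJ convention;
any point of the plateau induces the same segmentation).

## 5. Synthetic data: what it emulates, and what it does not

All generators draw from a single global seed expanded deterministically
into per-stream substreams (fixed offsets), so adding or re-running one
stream never changes another, and identical configurations are
bit-reproducible.

Error models follow the data types: log-normal intensities for peptide and
LFQ quantities, multinomial sampling at fixed run depth for spectral
counts, negative-binomial counts (variance `μ + φμ²`) for guides, binomial
junction counts at fixed event depth for splicing.  Missing LFQ values are
encoded as absent (`NA`), not zero.

Default study conditions: 800-protein universe; 1000 diGly sites over 200
proteins with 3 replicates per condition, planted KO effect −2 log2 and
replicate noise 0.3; IP/IgG depth 20,000 spectra with 25 planted
interactors at 8-fold enrichment; screen of 100 genes × 6 guides × 2
replicates at depth 500 with dispersion 0.05 and a ±1.5 log2 context
effect in 10 genes; LFQ proteome of 13 disease vs 6 healthy samples,
noise 0.5 log2, network nodes shifted −1 log2, 10% missingness; 200
splice events at depth 100 with 20 planted ΔPSI = +0.3 events; 192×192 px
nuclei with 3 elongated (14×7 px) bright objects in the control condition
versus 6 round (8×7 px) objects in the knockdown-like condition.  Two
proteins are planted as full-evidence substrates in all three nomination
streams; stream-specific positives are disjoint from the other streams by
construction, so the true full-evidence set is exactly the substrate pair.

What the generators do **not** emulate: peptide-level identification
noise, ratio compression, batch effects, correlated missingness in DIA,
guide off-target effects, overdispersion between splicing replicates,
optics (PSF, uneven illumination) in images.  Passing tests therefore
demonstrate correctness of the statistics and the pipeline plumbing under
the stated error models — not robustness to every artifact of real data.

At the default effect sizes the per-gene screen sensitivity is roughly
90–95%, so across arbitrary seeds an individual substrate occasionally
misses the q < 0.05 cut in the screen arm; the recovery fraction reported
by `scripts/acceptance.R` reflects this honestly rather than being forced
to 1.

## 6. Test design and problem sizes

The suite checks every statistical operator against an independent
brute-force oracle (Poisson/binomial likelihood routes for the LRTs,
first-principles Welch and BH step-up, a step-by-step GSEA walk plus
`fgsea::calcGseaStat`, naive O(n³) average-linkage agglomeration,
hull-free Feret projection and loop-based Crofton counting), at relative
tolerance 1e−9 on ≥ 20 random instances each.  Null calibration uses 500
replicate streams per test (protein/gene/event counts scaled to 20–60 per
replicate so the whole block runs in about two minutes) and requires the
empirical p < 0.05 rate to sit within 3 binomial standard errors of 0.05.
Recovery, geometry, determinism (byte-identical rerun reports) and
direction-of-effect checks run on the default configuration at fixed
seeds.

One genuine tie-break had to be made explicit: when the GSEA running sum
attains positive and negative extremes of exactly equal magnitude
(possible with rational increment coincidences), the positive extreme is
taken; the oracle encodes the same convention.

## 7. Known limitations

* The G-test and pooled binomial LRT rely on χ²(1) asymptotics; both are
  used at depths where the approximation is good (validated by the null
  calibration), but very low counts will misbehave.
* `in_box` uses raw p by default (figure convention); multiple-testing
  control is available but off.
* Cluster GO annotation, interaction-confidence scoring, and raw
  spectrum/read processing are out of scope: the pipeline starts at
  quantified tables and pre-scored edges.
* Images are 2-D single-nucleus fields; no 3-D stacks, deconvolution or
  learned segmentation.
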