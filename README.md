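# ubnexus

Multi-evidence nomination of ubiquitin-ligase substrates, and quantification
of how the resulting interactome is perturbed in a disease proteome.

## The problem

F-box proteins are the substrate receptors of SKP1–CUL1–F-box (SCF)
ubiquitin ligases; identifying which proteins an F-box protein actually
ubiquitylates is hard because no single assay is specific enough.  A robust
strategy combines three orthogonal evidence streams and nominates only the
proteins positive in all three:

1. **diGly ubiquitylome** — sites whose ubiquitylated-peptide intensity
   drops on ligase knockout (log2 fold change KO/WT ≤ −0.5) mark proteins
   that *lose ubiquitylation*;
2. **co-IP enrichment** — proteins whose spectral counts in a bait IP
   exceed the IgG control (G-test *p* < 0.05 and fold enrichment > 1.5)
   are *physical interactors*;
3. **context-dependent CRISPR screen** — genes whose guide fold changes
   (day 10 colonies vs day 0, counts-per-million normalized) differ
   between control and ligase-depleted contexts (two-tailed paired *t*
   test across the 6 guides per gene) show a *ligase-dependent fitness
   effect*.

The package implements each stream, the triple-intersection nomination,
and the downstream consequences: differential analysis of a label-free
(LFQ/DIA) protein quantity matrix with PCA, correlation-distance
hierarchical clustering, fold-change projection onto the interaction
network and permutation GSEA of the interactome as a custom gene set;
exon-inclusion (PSI) analysis of junction counts with a pooled binomial
likelihood-ratio test and the (FDR < 0.05, *p* < 0.05, |ΔPSI| > 0.15)
event filter; and confocal-style nuclear image quantification (per-ROI
Otsu masking, object circularity 4πA/P², Feret aspect ratio
minFeret/maxFeret, compartmental Pearson colocalization, per-nucleus
intensity statistics).

Every input stream can be simulated with planted ground truth
(`sim_config()` + `gen_*()`), so the full pipeline is testable end to end
without any external data.

## Core statistics

* **G-test** on spectral counts: with run depths `T_ip`, `T_igg` and
  expected counts `e_i = T_i (c_ip + c_igg) / (T_ip + T_igg)`,
  `G = 2 Σ c_i ln(c_i / e_i)` (zero-count terms contribute 0), referred to
  χ²(1).
* **Paired screen statistic**: per-gene paired *t* on guide-matched log2
  fold changes between contexts, Benjamini–Hochberg across genes.
* **GSEA**: weighted Kolmogorov–Smirnov running sum; `ES` is the signed
  maximum deviation, `NES = ES / mean|ES_null|` over same-sign gene-label
  permutations, `p = (1 + #{|ES_null| ≥ |ES|}) / (n_perm + 1)`.
* **PSI**: `I / (I + S)` from inclusion/skipping junction counts
  (optionally length-normalized), group difference by binomial LRT on
  pooled proportions.
* **Shape**: circularity `4πA/P²` with a Crofton (4-direction) perimeter
  estimate; aspect ratio from rotating-calipers Feret diameters at 1°
  steps.

## Worked example

```r
library(ubnexus)
cfg    <- run_config(seed = 1, outdir = "ubnexus_out")
report <- run_all(cfg)
print(report)
```

```
ubnexus run report
seed: 1
counts:
  sites_flagged          120
  proteins_lost_ub       31
  interactors_called     32
  network_nodes          32
  network_edges          45
  genes_classified       10
  proteins_significant   46
  events_passing         20
  nuclei_quantified      40
interactome GSEA: ES=-0.9568 NES=-2.8506 p=0.000999
network mean log2FC: -0.9641
nominated substrates: P0163, P0102
```

Reading the report: 120 diGly sites pass the |log2FC| ≥ 0.5 filter,
collapsing to 31 proteins that lose ubiquitylation (20 planted, the rest
noise-driven); 32 proteins fall in the IP significance box and survive the
0.7-confidence network cut; 10 screen genes are context dependent; the
triple intersection nominates exactly the two planted full-evidence
substrates.  In the simulated patient proteome the interactome nodes are
coherently down (mean log2FC −0.96) and GSEA of the interactome gene set
gives a strongly negative normalized enrichment score with the smallest
p-value 1000 permutations can produce.  20 splice events pass the
ΔPSI filter (all planted), and 40 nuclei are segmented and quantified.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ubnexus.R", package="ubnexus"))')" \
    simulate --seed 1 --outdir sim_out
```

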