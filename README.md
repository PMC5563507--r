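# tfregnet

Inference and analysis of transcription-factor (TF) regulatory networks
from ChIP-seq peak sets and knockout RNA-seq differential expression —
the integrative approach used to map how AP-1 factors such as JunB,
BATF and Fosl2 stabilize the Th17 T-cell program while restraining Th1
and Treg alternatives. The package is for computational biologists who
have, per TF, a called peak set (narrowPeak/BED) and a
knockout-versus-wild-type DE table (gene, log2FC, p, FDR), and want the
explicit direct/indirect activation/repression network plus the
standard downstream summaries.

## What it computes

For each TF, every gene significant in the knockout contrast
(FDR < 0.05, Benjamini–Hochberg) becomes a network edge with

- **mode** — ACT if expression decreased in the knockout
  (log2FC < 0, KO-vs-WT orientation), REP if increased;
- **directness** — DIRECT if ≥ 1 ChIP-seq peak *summit* lies within
  W = 5 kb of the gene body (0-based half-open coordinates, inclusive
  threshold), INDIRECT otherwise, with a curated manual-DIRECT override
  for validated distal targets (default: Ifng, Irf8, Tbx21 for JunB).

Around the network it provides:

- **pCRMs** — pooled peaks transitively merged (≥ 1 shared base) into
  putative cis-regulatory modules with per-TF occupancy vectors,
  k-means-binned into 8 clusters for heatmaps; co-occupancy venn counts
  and differential-binding summaries (fold change ≥ 2, p < 0.01, by
  co-bound subtype and sign quadrant);
- **TF-pair analyses** — quadrant concordance over co-significant
  genes, the four cooperative-regulation groups (ACT:ACT ... REP:REP),
  and their net effect on subset-contrast expression;
- **pre-ranked GSEA** — top-100 p-value-sorted subset signatures, the
  rank metric s = −log10(p) · sign(log2FC), the weighted
  Kolmogorov–Smirnov enrichment score, and a gene-set permutation null
  (10,000 permutations, plus-one corrected, p never 0);
- **a synthetic-data generator** — plants a ground-truth network
  (directness, modes, effect sizes, signature membership) and writes
  the exact input formats, so every stage is validated against known
  truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
bundled synthetic benchmark (3 TFs × 200 genes, seed 42; also shipped
pre-generated under `inst/extdata/fixture/`):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_map_peaks.R
Rscript analysis/03_build_network.R
Rscript analysis/04_pcrm_clusters.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_full_pipeline.R
```

`03_build_network.R` prints:

```
Regulatory network: 172 edges, 124 genes, 3 TFs
        DIRECT ACT DIRECT REP INDIRECT ACT INDIRECT REP
  BATF          14         13           17           13
  Fosl2         20          8           20           10
  JunB          15         13           16           13
Recovery vs planted truth: precision 0.994, recall 0.950, F1 0.972; mode acc 1.000, directness acc 1.000
JunB vs BATF: 67% concordant over 15 co-significant genes
  JunB:BATF ACT:ACT  n=  6 median Th17/Th0 log2FC +1.94
```

i.e. the inferred edge set recovers the planted network at 99%
precision / 95% recall (the shortfall is exactly the planted targets
whose Beta(0.01, 1) p-values miss FDR significance, plus BH's designed
false-discovery allowance — see the methods vignette), and every
recovered edge has the correct mode and directness. `05_enrichment.R`
shows the expected global shifts on the JunB-knockout ranking:

```
  Th17_vs_Th0_up     ES -0.623 NES -1.340 p 0.0191 (leading edge 20/100)
  Th17_vs_Th1_down   ES +0.789 NES +1.694 p 2e-04 (leading edge 22/100)
```

the Th17 signature is depleted (down in the knockout) while
Th1-preferential genes are enriched among upregulated genes — the
repression-release pattern the network encodes. `06_full_pipeline.R`
reruns everything from one configuration and verifies the 16 output
files are hash-identical across runs.

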