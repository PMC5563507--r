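---
title: "Methods: regulatory-network inference from ChIP-seq and knockout differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-network inference from ChIP-seq and knockout differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfregnet)
```

# The problem

A transcription factor's (TF) functional targets can be read out from two
complementary experiments: knockout-versus-wild-type RNA-seq says *which*
genes depend on the TF and in which direction, and ChIP-seq says *where*
the TF binds. `tfregnet` integrates the two into an explicit regulatory
network, of the kind used to dissect the AP-1 factor circuitry (JunB,
BATF, Fosl2, ...) that stabilizes the Th17 CD4^+^ T-cell program against
Th1 and Treg alternatives. The same machinery applies to any panel of TFs
with knockout differential-expression (DE) tables and called peak sets.

The package is organised as a pipeline of small, separately testable
stages — peak–gene association, edge classification, cis-regulatory
module (pCRM) construction and occupancy clustering, TF-pair summaries,
and pre-ranked gene set enrichment — plus a synthetic-data generator that
plants a known network so every stage can be validated end to end.

# The network model

For each TF, every gene that is significantly differential in the
knockout contrast (FDR $< \alpha$, strictly; Benjamini–Hochberg adjusted,
$\alpha = 0.05$ by default) becomes one edge, labelled on two independent
axes:

* **Mode.** With the knockout-versus-wild-type orientation, a gene whose
  expression *decreases* in the knockout (log~2~FC $< 0$) is an
  **activation** (ACT) target; one that increases is a **repression**
  (REP) target. A significant gene with log~2~FC exactly 0 has no defined
  mode and is excluded with a warning rather than arbitrarily assigned.
  A configuration flag flips tables supplied in the opposite orientation.
* **Directness.** A target is **DIRECT** when at least one ChIP-seq peak
  summit lies within $W = 5\,000$ bp of the gene body (transcription
  start to end), **INDIRECT** otherwise. A curated list of
  manually-promoted DIRECT edges (by default Ifng, Irf8 and Tbx21 for
  JunB — loci whose validated regulatory elements sit outside the window)
  overrides the peak requirement but never the significance requirement.

One edge is kept per (TF, gene) pair regardless of how many peaks
support it; the peak count is retained as an edge attribute.

## Peak–gene association

A peak is associated with a gene when its *summit* falls within $W$
bases up- or downstream of the gene body. Coordinates are BED-convention
0-based half-open throughout; the distance of a summit $s$ to a body
$[b_s, b_e)$ is $0$ inside the body, $b_s - s$ upstream and $s - b_e + 1$
downstream, and the threshold is inclusive ($d \le W$), the common
annotation-tool convention. The window is symmetric, so strand is carried
but ignored by the arithmetic. Two deliberate uniformity choices:

* The summit rule is applied everywhere, including DIRECT-target
  classification, rather than mixing summit- and edge-based distances.
* A summit near two overlapping genes associates with both — the rule
  has no uniqueness clause, and nearest-gene collapsing would silently
  drop real regulatory assignments.

The implementation is a windowed `GenomicRanges::findOverlaps()` sweep;
tests require exact agreement with an all-pairs brute-force scan,
including both $d = W$ boundaries, so the index is an optimisation with
no semantic content.

## TF-pair summaries

Given two TFs, common targets split into four cooperative-regulation
groups (ACT:ACT, ACT:REP, REP:ACT, REP:REP). The *net effect* of a pair
on subset identity is the distribution of subset-contrast log~2~FC (e.g.
Th17 vs Th0) over each group's members that are significant in that
contrast. *Quadrant concordance* between two knockout contrasts is
computed over genes significant in **both** tables (the stricter of the
two possible denominators, matching the co-significant "both datasets"
reading), with zero-log~2~FC genes excluded so the four sign-quadrant
fractions sum to one.

# pCRMs and occupancy clustering

Pooled peaks from all TFs are transitively merged on the $\ge 1$-base
overlap rule: every chain of overlapping peaks becomes one putative
cis-regulatory module, so each input peak belongs to exactly one module.
Occupancy is a binary TF vector per module (a signal mode substitutes
max peak score for heatmap shading but never drives clustering unless
requested).

Modules are binned into $k = 8$ occupancy clusters by k-means. The
original binning tool for such heatmaps is not re-used and its exact
algorithm is unspecified; k-means on the occupancy matrix is the
simplest faithful reading, isolated behind one function, and cluster
membership is therefore validated only against synthetic benchmarks
(planted archetypes), not against any published figure. Determinism and
row-order invariance are enforced by canonically sorting rows before
clustering under a fixed seed, with 25 restarts keeping the best-inertia
solution (fewer restarts were observed to strand k-means in local optima
on noisy binary data); clusters are relabelled in decreasing size order.

Differential-binding statistics are **inputs** (DiffBind/edgeR-style
region tables); the package only flags regions co-bound by a reference
TF ($\ge 1$ base overlap) and summarises, per co-occupancy subtype, the
percentage of regions with fold change $\ge 2$ and $p < 0.01$, split by
sign quadrant (the signed, per-quadrant reading), alongside a volcano
export with the p-value capped at $10^{-25}$.

# Signatures and pre-ranked GSEA

A subset signature is the top $n = 100$ up- (or down-) regulated genes
sorted ascending by **raw** p-value — not FDR, and with no additional
significance filter, the minimal reading of "top 100 sorted by p-value";
both choices are overridable. Ties on p break by larger |log~2~FC|, then
lexicographic gene id, so signatures are deterministic.

The per-gene ranking metric is $s_g = -\log_{10}(p_g)\cdot
\mathrm{sign}(\log_2\mathrm{FC}_g)$. A p-value of exactly 0 is capped at
$|s| = 320$, just below where double-precision $-\log_{10}$ underflows,
keeping the ordering finite and deterministic.

The enrichment score is the standard weighted Kolmogorov–Smirnov running
sum: at a member of the set, increment by $|s_i|^w / \sum_{\mathrm{hits}}
|s|^w$; at a non-member, decrement by $1/(N - N_h)$; the score is the
maximum-magnitude signed deviation (first extremum on ties). $w = 0$
recovers the classic unweighted KS statistic — verified against an
independent naive implementation — and $w = 1$ is the conventional
"weighted" setting. The degenerate set covering the whole universe is
rejected.

The null model is **gene-set permutation** — random sets of equal size
drawn from the ranked universe — the only permutation scheme coherent
for pre-ranked input (sample permutation needs expression matrices).
With `nperm` draws,

$$p = \frac{1 + \#\{\text{same-signed null } |ES| \ge |ES_{obs}|\}}
           {1 + \#\{\text{same-signed nulls}\}},$$

plus-one corrected so p is never reported as 0, with minimum reportable
value $1/(\mathrm{nperm}+1)$ — below $10^{-4}$ at the default
`nperm = 10000`, matching the "$p < 10^{-4}$" reporting convention for
sets that exceed every null. NES divides the observed score by the mean
|null score| of the same sign. Numerical identity with the Java GSEA
tool is not claimed (its tie handling and NES internals differ); the
contract is the formulae above, validated against exhaustive enumeration
on a small universe ($N = 8$, $|S| = 3$, all 56 subsets).

# The synthetic-data generator

`truth_spec()` / `generate_dataset()` plant a ground-truth network and
emit the exact formats the pipeline reads (narrowPeak, BED6, DE TSVs):

* **Genome.** Gene bodies (2–20 kb) placed uniformly with gaps
  $\ge 2W$, so every generated summit maps to at most one gene and
  recovery metrics stay interpretable; ambiguous overlapping-gene
  geometry is exercised by a dedicated fixture instead.
* **Edges.** Per TF, `n_targets` genes sampled with planted directness
  (`frac_direct`) and mode (`frac_act`); knockout effect sizes are
  lognormal magnitudes (meanlog 0.7, sdlog 0.5 — |log~2~FC| centred
  near 2, typical of strong TF dependencies) signed by mode.
* **DE tables.** True targets draw $p \sim \mathrm{Beta}(a, 1)$; the
  single shape parameter interpolates from near-certain significance
  ($a \to 0$) to the null ($a = 1$). Non-targets are null:
  $p \sim U(0,1)$, log~2~FC $\sim N(0, 0.1)$. The FDR column is exactly
  `bh_adjust()` of the p column.
* **Peaks.** Each DIRECT edge receives one peak (configurable) with its
  summit uniform in $[b_s - W, b_e + W)$, then peaks drop independently
  at `peak_dropout`; decoy peaks land beyond $W$ of every body and can
  never create a DIRECT call.
* **Subset structure.** Activation targets are planted as
  subset-upregulated (and repression targets as downregulated) in the
  Th17-vs-Th0 and Th17-vs-Th1 contrasts at rate `signature_overlap`
  (default 0.8), so pair-mode net-effect and subset-preference summaries
  have known expected signs.

The bundled benchmark (200 genes, 3 TFs — JunB, BATF, Fosl2 — 60
targets each, $a = 0.01$, no dropout, seed 42) ships under
`inst/extdata/fixture/` and is byte-identical to regeneration.

What the generator does **not** emulate: read-level noise, peak-shape
signal, correlated genes, dispersion estimation, or any dependence
between DE tables beyond shared planted targets. Passing tests therefore
demonstrate that the *analysis logic* recovers planted structure under
the stated statistical model, not that the model captures all features
of real sequencing data.

## A statistical note on "perfect" recovery

At the fixture's $a = 0.01$, a true target's p-value exceeds 0.05 with
probability $1 - 0.05^{0.01} \approx 0.03$, so a handful of the ~180
planted edges are expected to miss FDR significance in any realisation;
and Benjamini–Hochberg at FDR 0.05 *by design* admits a small number of
uniform-null false discoveries once many true positives are present.
Exactly-perfect precision and recall is therefore the $a \to 0$ limit
combined with an edge-definition that ignores the FDR procedure's own
false-discovery allowance — not a property any finite-$a$ realisation
can guarantee. The fixture realises precision ≈ 0.99 and recall ≈ 0.95
with mode and directness accuracy 1.0 on the recovered edges; the
validation suite asserts the exact-recovery claim where it is stated and
documents this gap rather than relaxing the generator.

# Numerical and degenerate-input choices

* Coordinates 0-based half-open everywhere; adjacency is not overlap.
* Chromosome names are opaque strings; disjoint peak/annotation
  namespaces raise an error (association) or warning (co-occupancy)
  rather than being silently "repaired".
* Readers fail fast: malformed coordinates, out-of-range p/FDR,
  duplicate ids and summit offsets outside their peak are errors naming
  the offending line or column.
* All writers are byte-deterministic (`%.15g` numeric formatting, fixed
  column order, sorted rows), so pipeline reruns are hash-identical and
  diffs are meaningful in review.
* Empty pair-mode groups are reported with $n = 0$ and an explicit empty
  flag, never dropped; an empty inferred network reports precision as
  NaN with a degeneracy flag.

# Validation problem sizes

The test suite runs at deliberately desk-scale sizes: 50 random
instances (≤ 500 peaks × ≤ 100 genes) for mapping-oracle equivalence;
1,000 single-peak DIRECT edges for dropout relabelling; 1,000
co-significant genes for concordance; 4,000 modules × 7 TFs for the
clustering benchmark (adjusted Rand index ≥ 0.9 at 5% bit-flip noise);
10,000 permutations for the GSEA floor; the full suite completes in
well under a minute. `scripts/acceptance.R` recomputes the same
quantities from scratch at the same sizes.

# Known limitations

* Published overlap/concordance percentages from the real datasets
  (e.g. the JunB/BATF concordance or JunD/cJun peak overlaps) require
  the deposited sequencing data and are not reproduced here; the
  package validates the machinery on planted truth only.
* k-means occupancy clusters are a visualisation binning, not a
  statistical model of co-occupancy; membership near cluster boundaries
  is seed-stable but not biologically sharp.
* Differential-binding and differential-expression statistics are
  consumed, never re-estimated; garbage tables in, garbage networks out.
* The GSEA p-value resolution is bounded by the same-signed null count,
  which is roughly half of `nperm` for sign-balanced rankings.
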