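---
title: "Methods: identifying and integrating GLI1/GLI2 binding regions"
author: "glicistrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and integrating GLI1/GLI2 binding regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glicistrome)
```

## The analysis

Excessive Hedgehog signalling in chondrocytes drives enchondroma and
chondrosarcoma, with the GLI transcription factors as its effectors.
`glicistrome` implements, as a reusable and fully testable pipeline, the
in-silico workflow used to characterise the GLI1/GLI2 cistrome in
neoplastic chondrocytes: ChIP-seq style coverage is normalised and
background-corrected, enrichment regions are called and filtered, the two
fractions are partitioned into unique and co-occupied binding regions, and
the resulting region sets are integrated with CTCF occupancy, human–mouse
conservation, and differential gene expression. Every input can be
simulated with known ground truth, so each stage is verifiable by
planted-parameter recovery rather than by eye.

## Coverage model and peak calling

A coverage track stores per-base signal as run-length encoded vectors plus
the sequencing library size. Three operations prepare it for calling:

* **Normalisation** rescales to counts per million: every value is
  multiplied by $10^6/\text{library size}$. The scaling law
  $\mathrm{norm}(k\cdot\text{reads})/k = \mathrm{norm}(\text{reads})$ is a
  tested invariant.
* **Control subtraction** computes per-base $\max(0, \text{TF} -
  \text{IgG})$ between normalised tracks; output is bounded by
  $[0, \text{TF}]$.
* **Enrichment-region detection** takes maximal runs above a background
  threshold, prunes isolated runs narrower than `min_run` (5 bp), merges
  runs separated by less than the 250-bp bandwidth — approximately the
  size of sonicated chromatin fragments — and discards merged regions
  narrower than 50 bp. The summit is the leftmost position attaining the
  region maximum (a deterministic tie-break), and the intensity is the
  value at the summit.

Two points here were genuinely open design choices. First, the pre-merge
pruning of sub-`min_run` runs: without it, isolated one-base Poisson
excursions act as stepping stones during bandwidth merging and chain
distant regions together once the background rate is non-trivial, which
ruins summit recovery; pruning first is what the minimum-width filter is
for. Second, the background threshold: the parameter-free `"auto"` setting
uses the genome-wide mean of non-zero subtracted values. That is a
sensible default on genome-scale data where enriched bases are rare, but
on the compact simulated genome (50 kb with ~20% of bases under planted
peaks) the non-zero mean is dominated by signal and suppresses
low-intensity peaks. The simulation configuration therefore passes an
explicit threshold of 2.0 counts/million, a few standard deviations above
the residual noise left by subtracting two Poisson(0.1) tracks.

### Peak selection

Selection retains a called peak if it meets *any* of three criteria:
(a) summit intensity above the mean plus one sample standard deviation of
its fraction's peak intensities; (b) at least 1 bp of overlap with a
conserved element; (c) a peak of the other fraction within 250 bp. Reasons
are recorded per peak. On Normal intensities the mean-plus-one-SD rule
retains the upper tail $1-\Phi(1)\approx 15.9\%$, which the test suite
checks on synthetic intensities drawn from the per-fraction parameters
(mean 206.8, SD 120.6 and mean 89.0, SD 62.0).

## MATCH matrix-similarity scoring

Motif screening uses the TRANSFAC MATCH matrix-similarity score. For a
frequency matrix $f(i,b)$ with information vector
$I(i)=\sum_b f(i,b)\ln(4f(i,b))$ (taking $0\ln 0 = 0$),

$$\mathrm{MSS} = \frac{\mathrm{Current}-\mathrm{Min}}{\mathrm{Max}-\mathrm{Min}},
\qquad \mathrm{Current}=\sum_i I(i)\,f(i, b_i),$$

with Min and Max substituting the per-position minimal and maximal
frequencies. Conventions, each of which is a documented choice: natural
logarithms and no pseudocounts (zero-frequency bases contribute nothing to
$I$ and can drive Min to 0); a zero-information matrix (all-N) scores
every window 1; windows containing non-ACGT characters are skipped, not
errors; threshold comparisons are strict (`score > 0.65` for "match score
above 65%"). Only the matrix-similarity score is computed — the original
MATCH core-similarity pre-filter is omitted because a single score
threshold is all the analysis requires. Matrices are built from IUPAC
consensus strings (each position splits frequency equally over its allowed
bases); the default GLI matrix is the canonical consensus `GACCACCCA` and
the CTCF matrix is `CCMMYYCHHGGTGG`, both replaceable in the
configuration.

Both strands are scanned at every offset (reverse-strand scores via the
reverse complement), and per-peak motif presence is assessed in
`[summit - 250, summit + 250)`. Scan correctness is established by
exhaustive enumeration against a naive reimplementation for all $4^L$
windows of matrices up to length 6, and by 100% recovery of planted
consensus instances at threshold 0.95.

## Interval algebra

All region comparisons use one primitive: *within distance $d$*, defined
as edge-to-edge gap $\le d$ with overlap counting as distance 0 (the
weakest reading of "within a 250-bp genomic distance"; a summit-based mode
would be stricter and is intentionally not the default). Exact boundary
semantics are pinned by tests: a 250-bp gap qualifies at $d=250$, a 251-bp
gap does not.

* **Co-occupancy partition.** The union of both fractions' selected peaks
  is clustered by single linkage at gap $\le d$; clusters containing both
  fractions become one co-occupied ("GIS") record spanning the cluster,
  and the remaining peaks stay fraction-unique. The partition is disjoint
  and exhaustive, and is checked against an $O(n^2)$ union-find oracle.
  Reporting GIS as clusters (not pairs) mirrors counting co-occupied
  *regions*; pair counting would differ whenever several peaks chain.
* **CTCF co-localisation** intersects each partition class with the CTCF
  set at $d$, yielding the sets l (fraction-1-unique), k
  (fraction-2-unique) and n (co-occupied), with per-class percentages.
* **Conservation binning.** Every mouse region (pre-lifted Gli1/Gli3
  sets, the Gli3 set first filtered by intensity $> 3.0$ — a cutoff that
  keeps the upper $1-\Phi(-0.96)\approx 83\%$ of a Normal(5.4, 2.5)
  intensity distribution) receives a membership vector over
  $\{hG1, hG2, mG1, mG3\}$. Bin `p` is mouse-Gli1-specific and `q`
  mouse-Gli3-specific (no human flag); the remaining combinations get
  letters from `r` onwards in a fixed lexicographic order. Twelve
  combinations are possible, so the letters run `r`–`z` plus `zz`; the
  letters are labels only.

Percentages in all reports are computed as $100\,n/d$ rounded half-up to
one decimal, so that, e.g., 3,943 of 5,304 gives 74.3.

## Expression integration

Differential expression is called per gene by a Welch two-sample t-test on
log2 values, with a 1.5-fold change threshold and $\alpha = 0.05$ by
default and no multiple-testing correction (Benjamini–Hochberg is
available via the `adjust` argument). The 1.5-fold cutoff is the common
microarray convention for this comparison; the choice of test is an
assumption and is therefore configurable.

A gene's regulatory neighbourhood spans from the end of the nearest
upstream gene body to the start of the nearest downstream gene body,
always containing the gene's own body and clipped to the chromosome. "Two
nearest neighbour genes up- and downstream" is read as one neighbour per
side (two in total); a two-per-side reading is available via
`neighbors_per_side = 2`. Intergenic regions are deliberately shared:
a binding region between two genes labels both, because each gene's
neighbourhood includes the whole intergenic span.

Labelled differentially expressed genes are partitioned into the seven
non-empty subsets of $\{G1, G2, GIS\}$ (letters a–g in a fixed order:
a = G1 only, b = G2 only, c = G1+G2, d = GIS only, e = G1+GIS, f = G2+GIS,
g = all three) and into seven conservation sets: mouse-only (b' = mouse
Gli1, c' = mouse Gli3, f' = both), human-only (e'), and human–mouse
common targets (a', d', g'). The d' pattern — mouse Gli3 plus human
GLI1/GLI2 binding — is the classic conserved-common-target configuration
(SMAD7 is a well-known Hh-responsive gene with exactly this profile).
Assigning e' to human-only conserved binding is this package's choice and
makes the seven sets a true partition.

The ΔΔCt helper implements the comparative threshold-cycle method:
$\Delta C_t = C_t(\text{target}) - \overline{C_t}(\text{controls})$,
$\Delta\Delta C_t = \Delta C_t - \overline{\Delta C_t}(\text{carrier})$,
fold change $2^{-\Delta\Delta C_t}$.

## What the simulator emulates — and what it does not

The synthetic-data module generates every pipeline input with recorded
ground truth:

* **Genome**: i.i.d. bases at a chosen GC fraction (41% by default, the
  human genome-wide value). Real genomes have repeats, CpG structure and
  composition heterogeneity; none of these are modelled, so motif
  false-positive rates on real sequence will differ.
* **Coverage**: homogeneous Poisson background (0.1 reads/bp) plus, per
  planted peak, a flat-top triangular bump of total width 250 bp (the
  fragment length) whose plateau (width 1/10 of the fragment length)
  equals the planted intensity. The flat top makes the expected summit
  unambiguous to within ±12 bp. Planted intensities are drawn from the
  per-fraction Normal parameters above, rejection-truncated below 5
  coverage units so that every peak exceeds ten times the background rate
  — the signal-to-noise regime the recovery guarantees refer to. Real
  ChIP background is neither homogeneous nor Poisson (mappability,
  chromatin accessibility), so the recovery rates demonstrated here bound
  ideal-case behaviour only.
* **Truth layout**: peak loci sit on a grid with 1,200-bp spacing so that
  distinct loci can never merge at the 250-bp bandwidth; a planted
  fraction (0.3) of fraction-2 peaks is placed within 250 bp of a
  *distinct* fraction-1 partner. Distinct partners matter: sampling
  partners with replacement deflates cluster counts through collisions
  and would make the planted fraction unrecoverable by construction.
* **Motifs**: consensus instances are written into the sequence at 42% of
  truth loci (rounded to a whole count: with 34 distinct loci under the
  default peak layout this is 14 instances, a planted fraction of 14/34).
  Coincidental instances elsewhere are scrubbed above the scan threshold,
  so the planted positions are the complete ground truth.
* **Expression**: control replicates $\sim N(8, 0.15)$ and treated
  replicates shifted by planted log2 fold changes of ±1.5 (ten noise SDs,
  so recovery is expected to be exact); four replicates per group, the
  size of the original microarray comparison.
* **Region sets**: CTCF, conserved-element and mouse sets are generated
  with controlled proximity fractions to the truth loci; mouse intensity
  scores are drawn from the printed Normal parameters (mean 3.1/SD 1.4
  for Gli1, mean 5.4/SD 2.5 for Gli3) rather than resampled from data,
  which reproduces the ">3.0 keeps over 75%" property analytically.
  Placement is uniform; no clustered or distance-law spacing beyond the
  near/far dichotomy is modelled.

Problem sizes in the tests (50-kb genome, 40 planted peaks, 30 genes,
around 200 randomised oracle instances with up to 2,000 regions) were
chosen so the full suite demonstrates every recovery property at
desk scale; all of them are configuration values, and nothing in the
implementation depends on them.

## Numerical and degenerate-input conventions

* Summit ties and group letters are broken deterministically (leftmost;
  fixed lexicographic orders).
* `intensity_filter` requires at least two peaks (SD undefined
  otherwise); if all intensities are equal the SD is zero and nothing
  exceeds mean + SD, so nothing is retained.
* `subtract_control` demands identical chromosome name sets but pads
  differing lengths with zeros.
* Coordinates are 1-based closed inside R (the GRanges convention) and
  0-based half-open in every BED/bedGraph file written or read.
* All randomness flows from one root seed; each simulation stage derives
  its own stream, so repeated runs are byte-identical, which the suite
  checks on the emitted reports.

## Known limitations

Peak calling is deliberately simple thresholded run-merging: no local
background model, no statistical enrichment p-values, no duplicate-read or
fragment-shift handling. Genome-scale peak inventories (tens of thousands
of regions per fraction) depend strongly on the data set and caller, so
this implementation emulates the structure of such analyses on synthetic
data rather than reproducing any particular inventory.
liftOver is not reimplemented;
mouse regions must arrive in human coordinates. De novo motif discovery,
GO enrichment and microarray preprocessing are out of scope.
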