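# glicistrome

Unique and overlapping GLI1/GLI2 binding regions in neoplastic
chondrocytes, as a tested and reusable R pipeline.

Excessive Hedgehog (Hh) signalling drives cartilage tumours, and the GLI
transcription factors are its effectors. Characterising the GLI1/GLI2
cistrome means answering four linked questions: where does each factor
bind (ChIP-seq enrichment regions), which regions are unique to one factor
versus co-occupied (G1BR / G2BR / GIS), how do those regions relate to
chromatin architecture and evolution (CTCF co-localisation, human–mouse
conservation), and which differentially expressed genes do they plausibly
regulate (gene-neighbourhood assignment). `glicistrome` implements that
whole chain for researchers in regulatory genomics who want each step as
an explicit, testable operation rather than a one-off script — and pairs
it with a synthetic-data module that generates every input with known
ground truth, so the pipeline's recovery behaviour is demonstrable without
any external download.

## The core operations

* **Coverage → peaks.** Counts-per-million normalisation
  (×10⁶/library size), per-base IgG subtraction max(0, TF − IgG), and
  enrichment-region detection by thresholded run-merging with a 250-bp
  bandwidth, leftmost-maximum summits, and summit intensities.
* **Three-criteria selection.** A peak is kept if its intensity exceeds
  the fraction mean + 1 SD, or it overlaps a conserved element, or a peak
  of the other fraction lies within 250 bp.
* **MATCH motif scoring.** The TRANSFAC matrix-similarity score
  MSS = (Current − Min)/(Max − Min) with Current = Σᵢ I(i)·f(i, bᵢ) and
  information weights I(i) = Σ_b f(i,b)·ln(4 f(i,b)); IUPAC-consensus
  matrices, both strands, strict thresholds (">65%" ⇒ score > 0.65).
* **Interval algebra.** Edge-gap "within 250 bp" joins, single-linkage
  co-occupancy partition (G1-only / G2-only / GIS), CTCF sets l/k/n,
  mouse Gli3 intensity filter (> 3.0), and conservation bins over
  {hG1, hG2, mG1, mG3} membership.
* **Expression integration.** Welch-test DEG calling (1.5-fold, p < 0.05),
  regulatory neighbourhoods bounded by the nearest flanking gene bodies,
  region-to-gene assignment, the 7-group (a–g) and conservation-set
  (a'–g') DEG classifications, and the ΔΔCt fold change 2^(−ΔΔCt).

## Worked example

```r
library(glicistrome)

res <- run_pipeline(default_config(seed = 1))
r <- res$report
```

Under the default configuration (50-kb synthetic genome, 20 planted peaks
per fraction at a planted co-occupancy of 0.3, planted motifs at 42% of
loci, 30 genes with 8 planted expression effects), the run prints, via the
report:

```
peaks detected  GLI1: 20   GLI2: 20
peaks selected  GLI1: 9    GLI2: 9
partition       G1-only: 3  G2-only: 3  GIS: 6
CTCF sets       l: 1  k: 2  n: 2
mouse Gli3 kept: 105 of 120 (87.5%)
DEG up: 5  down: 3
binding groups  a:0 b:1 c:1 d:2 e:1 f:1 g:0
```

Reading this: all 40 planted peaks were detected (recall 1.0); selection
then kept the 18 peaks meeting at least one of the three criteria; the
partition found 6 co-occupied loci — the planted 0.3 of the GLI2 fraction
— leaving 3 unique peaks per fraction among the selected; 105 of 120
simulated mouse Gli3 regions survive the >3.0 intensity cutoff (87.5%,
consistent with the Normal(5.4, 2.5) intensity model, whose analytic
retention is 83%); and all 8 planted expression effects are recovered and
distributed over the binding groups. Percentages everywhere use half-up
rounding to one decimal:

```r
percentage(3943, 5304)   # 74.3
percentage(1204, 1407)   # 85.6
```

Running with an output directory (`run_pipeline(cfg, outdir = "out")`)
writes the genome (FASTA), subtracted coverage (bedGraph), selected peaks
and partition (BED6+), per-gene classifications (TSV) and the summary
report (`report.tsv`, `report.json`); repeated runs under one seed are
byte-identical. A thin command-line wrapper is installed at
`inst/scripts/glicistrome-run.R`.

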