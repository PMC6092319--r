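# zoopipe

Dual-marker DNA metabarcoding analysis of mesozooplankton communities, as
an R package plus a scripted analysis workflow. It is written for marine
molecular ecologists who profile zooplankton with a COI fragment (~313 bp)
and the 18S V9 region (~138 bp) and need the whole chain — read QC,
taxonomic assignment, MOTU inference, marker combination, diversity,
non-indigenous-species screening and comparison against microscopy — as
tested, reproducible code rather than a one-off pipeline of shell tools.

## What it computes

* **Read QC** — exact-tag demultiplexing, forward-primer matching with ≤ 3
  IUPAC-aware mismatches, trimming, and retention of reads with mean
  Phred > 20 and length ≥ 200 bp (COI) / 100 bp (18S).
* **Assignment** — per-read naive LCA over all references with global-alignment
  identity ≥ t (identity = matches / alignment columns; match +1, mismatch
  −1, gap −2). A stepwise sweep (1% grid) counts newly assigned reads and
  phylum-ambiguous reads per threshold; the *phylum-conflict cutoff* — the
  lowest t at which no read's hit set spans two phyla — sets the metazoan
  extraction threshold.
* **MOTUs** — global dereplication, de-novo two-parent chimera removal,
  greedy centroid clustering at 90/95/97(/99)% levels, and LULU curation
  (84% match, 0.95 co-occurrence, min ratio 1) with exact read-count
  conservation.
* **Combination** — 18S counts scaled by the depth weight
  round(COI total / 18S total, 1) with per-cell ceiling of non-zero
  products, sample-set intersection minus explicit drops, and COI priority
  for taxa retrieved by both markers.
* **Diversity** — Hill numbers q = 0 (Chao1 asymptote,
  rarefaction/extrapolation) and q = 2 (unbiased Gini–Simpson) with
  bootstrap CIs; square-root Bray–Curtis, NMDS, Ward (`ward.D2`)
  clustering with multiscale-bootstrap node support (BP and AU), and a
  SIMPER whose per-taxon contributions sum exactly to the mean
  between-group dissimilarity.
* **Screening** — NIS detection across 90/95/97% stringencies, per-station
  relative abundances, morphology-vs-molecular record reconciliation, and
  ind m⁻³ conversion from net geometry.
* **Synthetic communities** — a generator producing reference databases
  with exact layered divergences (phylum/species/reference), log-normal
  site abundances on a coastal–offshore gradient, reads with substitution
  errors, chimeras, contaminants and marker dropouts, plus ground truth
  for every read — so the full pipeline is testable offline.

## Worked example

The default configuration is a two-marker, 12-station synthetic design
with a designed coastal/offshore gradient:

```r
library(zoopipe)
out <- run_pipeline(default_config(seed = 1, out_dir = "results/pipeline"))
```

which logs, stage by stage:

```
[simulate] sites=12 reads=6450
[qc] COI in=4800 assigned=4800 retained=4800
[qc] 18S in=1650 assigned=1650 retained=1650
[assign] COI cutoff=85 metazoan_reads=4546
[assign] 18S cutoff=86 metazoan_reads=1568
[cluster] COI reads=4546 motus_pre_lulu=56 motus=24
[cluster] 18S reads=1568 motus_pre_lulu=167 motus=24
[combine] weight=2.9 taxa=24 samples=11
[diversity] stress=1e-04 overall_dissimilarity=0.6662
[screening] nis_detected=1 reconciliation_records=263
```

Reading those numbers: the phylum-conflict cutoffs (85%/86%) sit above the
70% implied by the 30% inter-phylum divergence because chimeric reads are
genuine cross-phylum mosaics; LULU pulls the error-inflated MOTU tables
(56 and 167) back to the 24 simulated species for both markers; the
combined matrix keeps 24 taxa on the 11 stations sequenced by both markers
(one 18S dropout); the two designed site classes separate with NMDS stress
≈ 0 and class-node bootstrap support 1.0, with a coastal-vs-offshore
SIMPER average dissimilarity of 66.6%; and the one planted NIS is
recovered at the highest (97%) stringency.

The `analysis/` directory holds the same workflow at the full study design
(46 stations, 12 offshore) as numbered narrative scripts — run in order
from the repository root:

```sh
Rscript analysis/01_simulate.R    # reference DBs, communities, libraries
Rscript analysis/02_readqc.R     # demultiplex + quality filter
Rscript analysis/03_assign_sweep.R
Rscript analysis/04_cluster_curate.R
Rscript analysis/05_combine.R
Rscript analysis/06_diversity.R
Rscript analysis/07_screening.R
```

Each writes its tables under `results/analysis/` and prints what it found.

## Documentation

`vignettes/methods.Rmd` describes the models and estimators, the
synthetic-data design (what it emulates and what it deliberately does
not), every numerical convention and boundary decision, and known
limitations.
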