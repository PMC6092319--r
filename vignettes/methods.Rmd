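---
title: "Dual-marker zooplankton metabarcoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-marker zooplankton metabarcoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoopipe)
```

`zoopipe` implements a complete dual-marker (mitochondrial COI and nuclear
18S V9) metabarcoding analysis for mesozooplankton communities: read
demultiplexing and quality control, similarity-threshold taxonomic
assignment with a naive lowest-common-ancestor (LCA) rule, an operational
barcoding-gap determination, taxonomy-free MOTU inference with chimera
removal and LULU curation, combination of the two marker matrices into one
taxon table, alpha and beta diversity, non-indigenous-species (NIS)
screening, and reconciliation of molecular records against morphological
identifications. Because real sequencer output and GenBank snapshots are
large, private or unstable, the package ships a synthetic-community
generator that reproduces the statistical structure these methods assume,
so every stage is exercised and tested end-to-end on data with known truth.

This vignette documents the models, every tunable that matters, the
numerical conventions, and where the design was genuinely open, the choice
made and why.

## Sequence identity and assignment

All similarity thresholds rest on one identity definition: global
(Needleman–Wunsch) alignment with match +1, mismatch −1, gap −2, and

$$\mathrm{identity} = \frac{\text{matching columns}}{\text{all alignment columns}},$$

so gap columns count against identity and the measure is symmetric. Under
this scoring, two gaps (−4) are always worse than the at most two
mismatches they could replace (−2), so the optimal alignment of two
equal-length sequences is gap-free; equal-length pairs are therefore scored
by direct position-wise comparison, which is exact, and batch comparisons
use a one-hot matrix-product formulation of the same quantity. The
accelerated hit search adds a lossless k-mer prefilter (a reference sharing
fewer k-mer positions than the count–distance bound implies cannot reach
the threshold), and the test suite asserts bit-identical hit sets between
the accelerated and full-scan routes.

A read's assignment at threshold $t$ is the LCA of the full ranked lineages
of *all* references with identity $\ge t$ — the naive rule, with no
top-percent hit window (none is applied by default; the semantics of the
tool chain being emulated are unstated on this point, and all-hits is the
conservative reading). Thresholds live on a 1% grid and are compared with
$\ge$: a 95% threshold admits identity exactly 0.95.

The stepwise sweep assigns the read set at every threshold from 100% down
to 70% (COI) or 80% (18S) and records, per step, cumulative assigned reads
and the number of reads whose hit set spans more than one phylum. The
**phylum-conflict cutoff** — the lowest threshold at which no read is
ambiguous at phylum rank — is the marker's operational limit for
phylum-level discrimination; reads whose LCA at that cutoff lies inside
Metazoa pass the metazoan filter. Because hit sets nest as the threshold
rises, cumulative counts are monotone and the conflict indicator is a step
function; both are asserted as properties.

Assigned taxa are categorized against a regional checklist: `PRESENT` when
listed, `NIS` when on the non-indigenous list (NIS wins over PRESENT, since
an established NIS is usually also on the regional list),
`PLAUSIBLE_MISID` when absent but a congener is listed, `ERRONEOUS`
otherwise. Erroneous rows and rows with exactly one read *summed over all
samples* are dropped — "singleton" is a global, not per-sample, notion
here.

## MOTU inference and LULU curation

Reads are pooled and dereplicated globally; ordering everywhere is by
decreasing abundance with lexicographic sequence tie-breaks, so the
clustering is deterministic without seeds. The de-novo chimera detector is
a deliberately simplified two-parent model: a unique sequence is flagged
when two candidate parents (each at least twice its abundance) explain it
under a single-breakpoint prefix/suffix model strictly better than the best
single parent, with both segments at ≥ 99% identity — no three-way
alignments and no abundance-skew score. Greedy centroid clustering then
joins each unique to the first centroid with identity at or above the
clustering level ("clustering at 97%" joins at identity ≥ 0.97), else
founds a new MOTU.

LULU curation uses the published defaults (minimum centroid match 84%,
minimum relative co-occurrence 0.95, minimum parent/daughter abundance
ratio 1 as the minimum over daughter-positive samples), since the study
design being reproduced states none; daughters are visited in ascending
abundance and merged into the best qualifying parent until a fixpoint.
Read counts are conserved exactly through dereplication, clustering and
curation; chimera removal is the only count-reducing step and reports what
it removed.

One regime observation worth keeping in mind: LULU assumes erroneous MOTUs
are *low-abundance satellites* of their parent. That holds when the
per-read error rate is small relative to the clustering radius (e.g. 1%
errors against a 3–5% radius). If errors are comparable to the radius, a
species' read cloud fragments into several *comparable-abundance* clusters
whose per-sample ratios dip below 1, and LULU — by design — leaves them
unmerged. The synthetic defaults (1% substitution error) sit in the regime
the method targets.

## Combining the two markers

The two assignment matrices (COI at 95%, 18S at 97%) are merged on the
stations common to both markers, minus any explicit drop list for known
amplification failures. 18S counts are scaled by the sequencing-depth
weight — the ratio of post-QC read totals rounded to one decimal — and
non-zero products are rounded *up* per cell (zeros stay zero), keeping the
matrix integral and its zero structure intact; whether the original
analysis ceiled per cell or per row is unstated, and per-cell is the
declared convention here. Taxa retrieved by both markers keep the COI row
verbatim (COI priority); row provenance is recorded. Expert polishing is
reproduced as an auditable decisions table (`keep`/`drop`/`rename`) rather
than as hidden edits.

## Diversity

Alpha diversity uses two Hill numbers. For q = 0, observed richness, the
Chao1 asymptote ($S_{obs} + f_1^2/2f_2$, bias-corrected
$S_{obs} + f_1(f_1-1)/2$ when $f_2 = 0$) and size-based
rarefaction/extrapolation: exact hypergeometric interpolation below the
sample size and the standard $f_0$-based exponential extrapolation above
it; the curve passes through $(n, S_{obs})$ by construction and is checked
against exhaustive subsample enumeration at small n. For q = 2, the
Gini–Simpson index with the minimum-variance unbiased estimator
$1 - \sum x_i(x_i-1)/n(n-1)$. Standard errors come from multinomial
resampling of the bootstrap-augmented community (observed frequencies
scaled by the Turing coverage estimate, $\lceil f_0 \rceil$ unseen taxa
sharing the remaining mass); 200 replicates by default for intervals.

Beta diversity is Bray–Curtis on square-root transformed counts (per-cell
square root, no renormalization — the transformation convention of the
SIMPER lineage being followed), ordinated with NMDS (Kruskal stress-1,
vegan's engine, 20 random starts) and clustered with Ward linkage on
squared dissimilarities (`ward.D2`). Node stability uses the multiscale
bootstrap: taxa are resampled with replacement at relative scales 0.5–1.4,
1,000 replicates per scale; BP is the scale-1 node frequency and AU comes
from the z-regression $\Phi^{-1}(1-BP_r) = v\sqrt{r} + c/\sqrt{r}$,
$AU = 1 - \Phi(v - c)$, fitted on non-degenerate scales only and falling
back to BP (with a warning) when fewer than three scales are informative.
SIMPER decomposes each between-group pair's Bray–Curtis denominator-wise,
so per-taxon contributions sum to the mean between-group dissimilarity at
machine precision — asserted in the tests, with vegan's implementation as
an independent cross-check. SIMPER runs on the same transformation as the
distance matrix; running it untransformed while clustering on transformed
data would decompose a different quantity.

## The synthetic-community generator

The generator is first-class, tested code, and its defaults are the study
conditions: 46 stations with 12 offshore, amplicons of 313 bp (COI) and
138 bp (18S V9), inter-phylum / inter-species / intra-species pairwise
divergences of 0.30 / 0.10 / 0.01, log-normal per-taxon station abundances
(meanlog 3, sdlog 1.2), a composition gradient between the coastal and
offshore classes, substitution errors at 1% per base, 2% chimeric reads
(single breakpoint uniform in the middle 50% of the amplicon, parents the
station's two most abundant taxa), 5% non-metazoan contaminants (matching
the ~5–8% non-metazoan read fractions such surveys report), and
marker-specific dropouts (COI station 16; 18S stations 43 and 46). Read
depths default to 400 (COI) and 150 (18S) per station: real surveys run
1–2 orders of magnitude deeper, but depth enters these methods only through
sampling noise, and these sizes keep the full analysis and test suite in
the minutes range; they are this package's choice of problem size.

Divergences are realized *by construction* rather than by a stochastic
substitution process. Each phylum mutates a dedicated block of
$k_{phy} = (D_p - D_s)L/2$ positions from a common root, each species
$k_{sp} = (D_s - D_i)L/2$ positions, each reference $k_{ref} = D_iL/2$,
with position sets drawn disjointly (globally disjoint when the budget fits
the amplicon; per-phylum disjoint otherwise). Pairwise distances are then
deterministic sums of layer contributions — intra-species $2k_{ref}$,
congeneric $2(k_{sp}+k_{ref})$, cross-phylum $2(k_{phy}+k_{sp}+k_{ref})$ —
so the minimum cross-phylum divergence, which is what the conflict cutoff
responds to, does not wander below its design value through mutation-overlap
accidents. The cutoff-recovery simulations run with chimeras disabled:
a chimera of two cross-phylum parents is a genuine mosaic at ~50%/50%
composition and legitimately conflicts at ~$1 - D_p/2$ identity, which
masks the divergence-to-cutoff mapping being calibrated. With that
calibration, the recovered cutoff equals $100(1-D_p)$ exactly across
seeds; with chimeras on, the cutoff rises into the mosaic range, which is
the realistic behaviour the end-to-end pipeline shows.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: indels and homopolymer length errors (the
dominant Ion Torrent failure mode; the identity machinery handles unequal
lengths, but no error model produces them), PCR amplification bias and
primer-mismatch dropout, chimeras with more than one breakpoint,
reference databases with wrong or incomplete lineages, and realistic
taxonomic breadth (dozens of species, not thousands). Conclusions about
threshold placement on real data still require real reference databases.

## The default pipeline configuration

`default_config()` is a 12-station positive control (six per class) with
gradient strength 0.9, designed so the two site classes separate
decisively in the Ward tree (class-node BP ≥ 0.9 is the design goal of
this control). The full-design analysis under `analysis/` instead uses the
generator's study-condition gradient of 0.6; there the ordination and the
top dendrogram split still recover the classes, but taxa-resampling
support for the class nodes is low (BP ≈ 0.1 at 24 taxa) — a useful
reminder that a clean mean separation and bootstrap robustness over taxa
are different claims, and that 24 taxa is a small resampling universe.

## Numerical conventions and degenerate inputs

* Mean-quality filtering is strict (mean Phred exactly 20 fails, matching
  the "> 20" contract); length filtering is inclusive (exactly 200/100 bp
  pass). Tags match exactly; primers tolerate ≤ 3 IUPAC-aware mismatches;
  both read orientations are tried and reads are reoriented forward.
* The per-sample mean read count divides by an explicit divisor: all
  collected stations or successfully amplified stations differ whenever a
  station fails, and both conventions are exposed rather than guessed.
* Readers reject malformed input (with line numbers for FASTQ) instead of
  coercing; writers round-trip through their paired readers.
* Empty communities yield empty read sets, not errors; empty hit sets are
  unassigned, not errors; conflicts at the sweep's top threshold make the
  cutoff undefined and raise an error.
* All stochastic operations take explicit seeds; a single pipeline seed
  fans out to stage seeds by stable tag hashing, and identical configs
  reproduce identical artifact checksums.

## Known limitations

Chimera detection is a simplified uchime-style model and will miss
multi-breakpoint or low-ratio chimeras. The AU approximation degrades for
nodes whose support is degenerate at most scales (it falls back to BP).
NMDS is restarted, not globally optimized. The LULU implementation is
quadratic in MOTU count, appropriate for the problem sizes here but not
for de-novo tables with tens of thousands of MOTUs.
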