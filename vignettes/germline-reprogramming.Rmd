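---
title: "Methylome reprogramming and piRNA signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome reprogramming and piRNA signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`germreprog` analyses staged whole-genome bisulfite (WGBS) and small RNA
sequencing experiments of germ-cell specification: the global gain of CpG
methylation as pluripotent cells prime, its genome-wide erasure in
PGC-like cells, the regions that deviate from that wave, and the piRNA
hallmarks of transposon control. This vignette is the package's account of
the statistical models, the tunable parameters, the synthetic data the
tests run on, and the design choices made where the design was open.

```{r setup, eval = FALSE}
library(germreprog)
```

## Coordinates and quantitation

All internal coordinates are 0-based half-open; Bismark coverage files
(1-based inclusive) are shifted on read, and CpGs are keyed by the
plus-strand C. Strand-merged counts are assumed merged upstream, matching
coverage-file semantics. The percent column of call files is never
trusted; fractions are always recomputed from the raw call counts.

Probe methylation is **weighted**: over the covered CpGs of a probe,

$$\hat{m} = \frac{\sum_i \text{meth}_i}{\sum_i (\text{meth}_i + \text{unmeth}_i)},$$

so CpGs are weighted by their coverage. This matches the pooled
"all calls over all instances" definition used for repeat classes and is
applied uniformly; `quantify_probes(weighted = FALSE)` instead averages
per-CpG fractions, for comparison. Probes covered by fewer than `min_cpg`
CpGs in a sample are missing, not zero (default 10 for the 20-kb
genome-wide probes, 1 elsewhere). Tiling probes drop the trailing partial
window rather than truncating it, so probe length is constant; 50-CpG
probes span consecutive blocks of CpGs shared across all compared samples
(union of covered positions), so probe definitions are identical between
stages, and the final partial block is dropped.

Feature definitions follow the standard Ensembl-style conventions:
promoters are the 1 kb upstream of the TSS (strand-aware); a CGI promoter
contains or lies within 250 bp of a CGI; intergenic is the complement of
gene bodies only (promoters are not subtracted — the feature list is
interpreted literally). Metagene profiles use 1-kb windows at 500-bp steps
across 5-kb flanks and a gene body scaled to `body_bins` = 40 equal bins —
enough resolution to be smooth at typical gene lengths without starving
individual bins of CpGs; genes shorter than `body_bins` bp are skipped
with a message.

## The background model of demethylation

The genome does not demethylate uniformly, so "retains more methylation
than expected" must be defined against the genome-wide trend, not a fixed
threshold. `fit_background()`:

1. takes each probe's methylation at the start and end of a transition
   (e.g. primed EpiLC to late PGCLC);
2. bins probes by **start** methylation into equal-occupancy bins
   (default `n_bins` = 20, at least `min_bin_n` = 50 probes per bin; bins
   are merged or reduced with a message when probes are scarce, and ties
   may collapse bins — a single bin is allowed for degenerate input);
3. within each bin, keeps the empirical distribution of the methylation
   **change** (end − start), with its median and MAD.

Modelling the change rather than the raw end level removes the residual
start-methylation trend inside a bin: a genome-wide uniform shift then has
zero scale in every bin and flags nothing, which is the behaviour one
wants from a trend model. `call_outliers()` scores each probe's change
against its bin with two interchangeable p-values:

* `method = "empirical"` (default): the add-one-smoothed two-sided rank
  probability $p = \min\!\big(1, 2\min(\#\{v \le x\}, \#\{v \ge x\})/(n+1)\big)$
  over the bin's $n$ members. It is distribution-free and exactly
  calibrated — under the null the flagged fraction at $\alpha$ is
  $\alpha$ by construction — but its smallest attainable value is
  $2/(n+1)$, and any real outliers sitting in the bin occupy the extreme
  ranks and mask each other.
* `method = "zscore"`: a robust normal approximation
  $z = (x - \mathrm{median})/(1.4826\,\mathrm{MAD})$. The median and MAD
  tolerate a substantial fraction of true outliers in the bin, and the
  continuous p-values support Benjamini–Hochberg correction.

The default report uses raw p < 0.05 (`correction = "none"`), which
reproduces the classic scatter-band view. For **discovery** of
demethylation-resistant escapees we recommend `method = "zscore",
correction = "bh"`: with a contaminated bin the rank-based p cannot
separate a bulk of escapees from each other (their p-values scale like
their within-bin rank, which no FDR line can cross), while the robust z
keeps near-full sensitivity at controlled FDR. Probes are classed
`higher`/`lower` only when the (adjusted) p is below `alpha` *and* the
change lies above/below the bin median; whether a one- or two-sided test
and any correction best matches historical practice is not decidable from
the method descriptions this package follows, so both are exposed and the
choice is explicit in every call.

## Trajectory clustering and enrichment

`kmeans_trajectories()` clusters probes by their methylation trajectory
(fraction scale, unstandardised — absolute levels are meaningful here).
The implementation is Lloyd's algorithm from k-means++ starts, best of
`n_restarts` = 25 by within-cluster sum of squares, fully deterministic
given the seed; an emptied cluster is re-seeded from the point farthest
from its centroid, and clusters are reported in descending size order so
labels are stable. k = 7 is the default, the number of kinetic classes one
expects genome-wide (global trend, CGI-low, resistant, gene-body-shifted,
erasure-like, and intermediate shapes). Probes overlapping repeats are
excluded before clustering (they are analysed separately at the class
level).

Cluster (or outlier-set) composition is tested with
`enrich_features()`: the percentage of group probes overlapping a feature
class versus the genome-wide percentage, the log2 ratio, and a
hypergeometric upper-tail p (drawing the group from the probe universe).
A class absent from the universe yields a missing ratio rather than an
infinity. ChIP tracks are overlaid as reads-per-kb-per-million scores per
probe with a top-decile "enriched" label (ties at the threshold are all
included): the overlay is continuous in origin, and a decile cut is the
smallest additional assumption that yields set statistics.

## Repeat expression

Repeat instances within 2 kb of any gene body (inclusive; overlap counts)
are removed before expression quantitation, so genic transcription does
not masquerade as TE expression. Distance is measured to the transcript
span, the plainest reading of "near an annotated gene". Class RPKM is
count / (total class length in kb × library size in millions); overlaps
are strand-blind, and a read overlapping several classes contributes one
count to each (never fractionally split — the simplest consistent reading
of class-pooled counting). The library size is supplied by the caller (all
mapped reads by convention).

## piRNA signatures

Sequential exclusion (remove rRNA, then miRNA, then assign to repeats,
then genes) is emulated by a single hierarchical labelling pass —
rRNA > miRNA > piRNA gene > repeat > gene > unannotated — which yields
the identical partition given interval annotations and drops the aligner
dependency. "Uniquely mapped" is honoured via the BED score flag.

The ping-pong profile counts opposite-strand read pairs by their 5'-5'
spacing $d = p^- - p^+ + 1$ (1..30 nt), each read pair once, unweighted by
multiplicity; the histogram can be reported as counts per million pairs.
The signature statistic is the z-score of the 10-nt bin against the other
bins as empirical null, $z_{10} = (c_{10} - \bar c_{d\ne10})/s_{d\ne10}$ —
standard field practice where only the histogram shape is of interest.
The 5' composition matrix covers ±30 nt around the 5' end (position +1 is
the read's first nucleotide; minus-strand reads are reverse-complemented),
with positions truncated at chromosome ends excluded from normalisation.

## The synthetic data generator

`simulation_config()` fixes the emulated study conditions; a single seed
makes every output bit-for-bit reproducible. Defaults: two 5-Mb
chromosomes; CpG density 4/kb, tenfold inside CGIs (≈40,000 CpGs);
region-class genome shares cgi 2%, young TE 5%, old TE 13%, gene body
30%, imprinted DMR 1%, intergenic 49%; four stages with class mean
methylation

| class | naive | epilc | pgclc_early | pgclc_late |
|---|---|---|---|---|
| CGI | 0.05 | 0.05 | 0.05 | 0.05 |
| young TE | 0.35 | 0.80 | 0.75 | 0.70 |
| old TE | 0.30 | 0.70 | 0.45 | 0.25 |
| gene body | 0.32 | 0.68 | 0.45 | 0.22 |
| imprinted DMR | 0.50 | 0.50 | 0.35 | 0.05 |
| intergenic | 0.30 | 0.65 | 0.40 | 0.18 |

i.e. a global naive≈0.30 → primed≈0.65 gain and stepwise PGCLC decline,
resistant young TEs, CGIs low throughout, DMRs at the imprinted 50% until
late erasure. These are generator settings chosen to mimic the biology's
shape, not measurements. Per region and stage a latent level is drawn
from a beta distribution around the class mean (precision 50 — realistic
probe-to-probe dispersion); per CpG, coverage is negative-binomial
(mean 10, size 5, a typical WGBS depth profile) and methylated calls are
binomial at the latent level.

Small RNA reads: 10% rRNA background, 25% miRNA-like (22–23 nt from
hairpin loci), 60% piRNA-like (24–31 nt from TE instances), remainder
gene-derived. Primary piRNA 5' positions are chosen so the genomic base
under the 5' end is U with probability 0.8 — the bias is real sequence
bias, not an overwritten letter. A configured fraction (0.3) of piRNA
reads are slicer-paired secondaries whose 5' end sits opposite nucleotide
10 of a primary guide; the 10-nt 5'-5' overlap is therefore an *emergent*
property the statistic must detect, not something encoded in the
statistic. Chromosome sequence is a CG-free random backbone with CG
planted at every CpG, so CpG truth is exact; base composition is
otherwise unrealistic (a documented non-goal), which is why composition
checks only use the planted 5' identity.

What passing tests on this generator do **not** show about real data:
bisulfite conversion failure, M-bias, strand-unmerged calls, CHH/CHG
contexts, multi-mapping ambiguity beyond a Bernoulli unique flag, and
realistic sequence composition are all absent. The tests certify the
statistics and their calibration, not robustness to those artefacts.

## Numerical choices and degenerate inputs

* Empirical p-values use add-one smoothing and cap at 1; all-tied bins
  give p = 1 (nothing is surprising in a degenerate bin).
* A bin with zero MAD under `method = "zscore"` assigns p = 1 at the
  median and effectively 0 elsewhere.
* Quantile ties in binning collapse bins with a message; fewer than
  2 × `min_bin_n` usable probes is an error.
* k-means ties in assignment go to the first centroid; restart ties keep
  the first restart; size ties in relabelling keep the original order.
* Classes/probes with zero covered CpGs are missing, never zero.
* Chromosome-boundary positions are excluded from composition
  normalisation; secondaries that would extend beyond a chromosome are
  dropped by the generator.

## Problem sizes used in the checks

The bundled test-and-acceptance runs use a 10-Mb genome (~47,000 CpGs)
for oracle equivalence of the quantitation; 10 × 4,000 probes for null
calibration; 4,000 probes with 5% planted escapees (+0.35 offset, noise
sd 0.05) for recovery; 700 probes over 7 planted archetypes for
clustering; 5,000 small RNA reads for the ping-pong and 5'U checks; and a
2 × 200-kb pipeline run repeated twice for byte-level determinism. These
sizes give the Monte-Carlo assertions comfortable margins while keeping
the whole suite fast on a single core.

## Known limitations

Non-CpG methylation, 5hmC, per-read epialleles, HMM/regression DMR
callers, ChIP peak calling, piRNA cluster discovery and phasing
signatures are out of scope. The background model is a marginal,
per-probe test: it does not borrow strength across neighbouring probes,
and spatial correlation of methylation will make raw p < 0.05 calls
cluster along the genome.
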