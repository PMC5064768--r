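# germreprog

Epigenetic resetting in the germline is one of the two genome-wide waves of
DNA demethylation in mammalian development: pluripotent cells acquire high
CpG methylation on priming, and primordial germ cells (PGCs, or their in
vitro counterparts, PGC-like cells) then erase most of it — except for CpG
islands that were never methylated, young transposable elements (IAP, SVA)
that resist erasure, and imprinted control regions that sit near 50%
methylation until they are finally demethylated. `germreprog` implements
the downstream analysis of such staged whole-genome bisulfite and small
RNA experiments as a tidyverse-style R package: every user-facing function
takes a data frame and returns a tibble, fitted objects have
`tidy()`/`glance()`/`augment()` methods, and each result type has a
ggplot2 `autoplot()`/`plot_*()`.

## What it computes

* **Probe methylation quantitation.** Fixed-width tiling probes (20-kb
  genome-wide, 2-kb for clustering) and fixed-CpG-count probes (50 CpGs)
  with weighted methylation: pooled methylated calls over all calls,
  masking probes below a minimum covered-CpG count (default 10 for the
  20-kb probes).
* **Feature summaries.** Exons, introns, CGI/non-CGI promoters (promoter =
  1 kb upstream of the TSS; CGI promoter = CGI within 250 bp), promoter
  and non-promoter CGIs, intergenic space, imprinted DMR panels by parent
  of origin, repeat classes, and 1-kb/500-bp metagene profiles over 5-kb
  flanks and scaled gene bodies.
* **Background model of demethylation.** Probes are binned by starting
  methylation (equal occupancy); within each bin the empirical
  distribution of the methylation change is the expectation. Probes whose
  change is significantly above the trend (p < 0.05) are
  demethylation-resistant "escapees"; below, hyper-demethylated. Empirical
  rank p-values (exactly calibrated) or robust z p-values (median/MAD,
  recommended with Benjamini-Hochberg for escapee discovery).
* **Trajectory k-means.** Seven clusters of 2-kb probes across stages
  (k-means++ starts, best of 25 restarts, deterministic under a seed) with
  hypergeometric feature enrichment per cluster, plus ChIP read-count
  overlay and gene-body methylation-expression correlation.
* **Repeat expression.** Repeat instances within 2 kb of a gene removed,
  then class-level RPKM (count / total class kb / library millions).
* **piRNA signatures.** Hierarchical read classification
  (rRNA > miRNA > piRNA gene > repeat > gene), length spectra (piRNA
  24-31 nt vs miRNA 22-23 nt), 5' nucleotide composition (+/-30 nt; 5'U
  bias), and the ping-pong 5'-5' overlap profile with its z-score at
  10 nt.
* **Synthetic data generator.** A seeded simulator of all of the above —
  region classes with planted kinetics, binomial CpG calls under
  negative-binomial coverage, slicer-paired small RNA reads — so the whole
  pipeline is testable without external data.

## Worked example

```r
library(germreprog)
library(dplyr)

cfg  <- simulation_config(seed = 42, chrom_sizes = c(chr1 = 1e6, chr2 = 1e6))
sim  <- simulate_genome_and_annotation(cfg)
meth <- simulate_methylomes(cfg, sim)

# global methylation over 20-kb probes covered by >= 10 CpGs
probes <- make_probes(sim$genome, mode = "tiling", width = 20000)
quantify_probes(probes, meth$calls, min_cpg = 10) |>
  group_by(sample) |>
  summarise(global_meth = round(mean(meth_fraction, na.rm = TRUE), 3))
#>   sample      global_meth
#> 1 naive             0.278
#> 2 epilc             0.595
#> 3 pgclc_early       0.386
#> 4 pgclc_late        0.203
```

The global wave is visible: ~0.28 in naive cells, ~0.60 after priming,
stepping down to ~0.20 in late PGC-like cells. Escapees against the
primed-to-late transition:

```r
p50   <- make_probes(sim$genome, calls = meth$calls, mode = "cpg_count", n_cpg = 50)
mm50  <- quantify_probes(p50, meth$calls)
model <- fit_background(mm50, "epilc", "pgclc_late")
out   <- call_outliers(model, method = "zscore", correction = "bh")
table(out$class)
#> higher     ns
#>      5    184
autoplot(model, calls = out)   # start-vs-end scatter, escapees in red
```

The five `higher` probes retain methylation above the genome-wide
demethylation trend — in this simulation, the planted young-TE regions.
The imprinted DMR panel sits near 50% before erasure:

```r
dmr_methylation(sim$dmrs, meth$calls) |> filter(panel == "combined")
#>   sample      panel    meth_fraction total_calls
#> 1 naive       combined         0.462         883
#> 2 epilc       combined         0.480         805
#> 3 pgclc_early combined         0.326         767
#> 4 pgclc_late  combined         0.032         813
```

And the ping-pong signature of slicer-paired piRNA reads:

```r
smr <- simulate_smrna(cfg, sim)
cls <- classify_reads(smr$reads, list(rRNA = sim$rrna, miRNA = sim$mirna,
                                      "repeat" = sim$repeats))
glance(pingpong_profile(cls))
#>     z10 total_pairs modal_overlap
#> 1  441.         934            10
```

An excess of exactly 10-nt 5'-5' overlaps (z10 = 441, modal bin 10 nt) is
the diagnostic of ping-pong piRNA amplification.

The whole pipeline, from simulation to TSV outputs with a manifest:

```r
run_germreprog("all", outdir = "out", seed = 1)
```

or from the shell via the bundled wrapper
`inst/cli/germreprog all --outdir out --seed 1`.

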