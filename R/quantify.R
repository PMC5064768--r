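# Probe-level methylation quantitation. The default ("weighted") statistic
# pools raw calls: sum(meth) / sum(meth + unmeth) over the covered CpGs of a
# probe, weighting each CpG by its coverage. The unweighted alternative
# averages per-CpG fractions. Probes covered by fewer than min_cpg CpGs in
# a sample are reported as missing for that sample.

#' Quantify methylation over a probe set
#'
#' @param probes probe tibble from [make_probes()] (or any interval tibble
#'   with a `probe_id` column)
#' @param calls long CpG call tibble (`sample`, `chrom`, `pos`, `meth`,
#'   `unmeth`), one or more samples
#' @param min_cpg minimum covered CpGs for a probe/sample value (default 1)
#' @param weighted pool raw calls (default) or average per-CpG fractions
#' @return long tibble (`probe_id`, `sample`, `meth_fraction`,
#'   `total_calls`, `covered_cpgs`); `meth_fraction` is `NA` below `min_cpg`
#' @export
quantify_probes <- function(probes, calls, min_cpg = 1, weighted = TRUE) {
  if (is.null(probes) || nrow(probes) == 0) abort("empty probe set")
  if (min_cpg < 1) abort("min_cpg must be >= 1")
  if (!"probe_id" %in% names(probes)) {
    probes <- probes %>%
      mutate(probe_id = paste0(chrom, ":", start, "-", end), .before = 1)
  }
  samples <- unique(calls$sample)
  pgr <- as_granges0(probes)
  out <- map_dfr(samples, function(s) {
    cs <- calls %>% filter(sample == s)
    hits <- GenomicRanges::findOverlaps(cpg_granges(cs), pgr,
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    agg <- tibble(
      probe = si,
      meth = cs$meth[qi],
      unmeth = cs$unmeth[qi],
      frac = ifelse(cs$meth[qi] + cs$unmeth[qi] > 0,
                    cs$meth[qi] / (cs$meth[qi] + cs$unmeth[qi]), NA_real_)
    ) %>%
      group_by(probe) %>%
      summarise(
        sum_meth = sum(meth), sum_unmeth = sum(unmeth),
        covered = sum(meth + unmeth > 0),
        mean_frac = mean(frac, na.rm = TRUE),
        .groups = "drop"
      )
    res <- tibble(
      probe_id = probes$probe_id, sample = s,
      meth_fraction = NA_real_, total_calls = 0L, covered_cpgs = 0L
    )
    res$total_calls[agg$probe] <- as.integer(agg$sum_meth + agg$sum_unmeth)
    res$covered_cpgs[agg$probe] <- as.integer(agg$covered)
    frac <- if (weighted) {
      ifelse(agg$sum_meth + agg$sum_unmeth > 0,
             agg$sum_meth / (agg$sum_meth + agg$sum_unmeth), NA_real_)
    } else {
      ifelse(is.nan(agg$mean_frac), NA_real_, agg$mean_frac)
    }
    res$meth_fraction[agg$probe] <- frac
    res$meth_fraction[res$covered_cpgs < min_cpg] <- NA_real_
    res
  })
  out
}

#' Pivot a long methylation matrix to wide (probes x samples)
#' @param mm long tibble from [quantify_probes()]
#' @param value column to spread (default `meth_fraction`)
#' @return wide tibble, one row per probe
#' @export
meth_matrix_wide <- function(mm, value = "meth_fraction") {
  mm %>%
    select(probe_id, sample, all_of(value)) %>%
    pivot_wider(names_from = sample, values_from = all_of(value))
}
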