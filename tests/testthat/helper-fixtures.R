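# Fixtures and independent oracles shared across test files. Oracles are
# deliberately naive (loops, exhaustive enumeration, closed forms) and
# never reuse the package's interval machinery.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

tiny_genome <- function(len = 50000L, chroms = "chr1") {
  tibble(chrom = chroms, length = rep(as.integer(len), length(chroms)))
}

# long methylation matrix from a probes x samples matrix of fractions
mm_from_matrix <- function(M, probe_ids = NULL) {
  probe_ids <- probe_ids %||% paste0("p", seq_len(nrow(M)))
  tidyr::pivot_longer(
    tibble::as_tibble(M) |> mutate(probe_id = probe_ids, .before = 1),
    -probe_id, names_to = "sample", values_to = "meth_fraction"
  ) |>
    mutate(total_calls = 100L, covered_cpgs = 50L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random CpG call table on one or more chromosomes
random_calls <- function(n, genome, samples = "s1", seed = 1,
                         max_cov = 20) {
  withr::with_seed(seed, {
    purrr::map_dfr(samples, function(s) {
      purrr::map_dfr(seq_len(nrow(genome)), function(i) {
        pos <- sort(sample.int(genome$length[i] - 2L, n)) - 1L
        cov <- sample.int(max_cov, n, replace = TRUE)
        meth <- rbinom(n, cov, runif(n))
        tibble(sample = s, chrom = genome$chrom[i], pos = pos,
               meth = as.integer(meth), unmeth = as.integer(cov - meth))
      })
    })
  })
}

# brute-force probe quantitation: per probe, linear scan over all CpGs
oracle_quantify <- function(probes, calls, min_cpg = 1) {
  purrr::map_dfr(unique(calls$sample), function(s) {
    cs <- calls[calls$sample == s, ]
    purrr::map_dfr(seq_len(nrow(probes)), function(i) {
      sel <- cs$chrom == probes$chrom[i] &
        cs$pos >= probes$start[i] & cs$pos < probes$end[i]
      m <- sum(cs$meth[sel]); u <- sum(cs$unmeth[sel])
      covered <- sum(sel & (cs$meth + cs$unmeth > 0))
      tibble(probe_id = probes$probe_id[i], sample = s,
             meth_fraction = if (covered >= min_cpg && m + u > 0)
               m / (m + u) else NA_real_,
             total_calls = m + u, covered_cpgs = covered)
    })
  })
}

# exhaustive interval overlap test (>= 1 bp), all pairs
oracle_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# gap distance between two intervals on the same chromosome (0 if overlap)
oracle_gap <- function(s1, e1, s2, e2) {
  if (s1 < e2 && s2 < e1) return(0)
  if (s2 >= e1) s2 - e1 else s1 - e2
}

# exact hypergeometric upper tail by direct summation of choose() terms
oracle_hyper_upper <- function(k, K, N, n) {
  i <- seq.int(k, min(K, n))
  if (length(i) == 0) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
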