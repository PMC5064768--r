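# Feature enrichment of a probe group against the probe universe:
# percentage overlap in the group vs genome-wide, log2 ratio, and a
# hypergeometric upper-tail p-value.

#' Feature enrichment of a probe group
#'
#' For each feature class, counts the probes overlapping the class (>= 1 bp)
#' in the group and in the whole universe, and tests over-representation
#' with the hypergeometric upper tail (drawing `|group|` probes from the
#' universe, of which `K` overlap the class).
#'
#' @param group character vector of probe ids (must be a subset of the
#'   universe)
#' @param probes the probe universe tibble (`probe_id`, `chrom`, `start`,
#'   `end`)
#' @param features interval tibble with a `feature_class` column (or a
#'   named list of such tibbles, which are row-bound)
#' @return tibble (`feature_class`, `n_group`, `k_group`, `pct_group`,
#'   `n_universe`, `K_universe`, `pct_universe`, `log2_ratio`, `p_hyper`);
#'   `log2_ratio` is `NA` when the universe percentage is zero
#' @export
enrich_features <- function(group, probes, features) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- bind_rows(features)
  }
  if (length(group) == 0) abort("empty probe group")
  if (!all(group %in% probes$probe_id)) {
    abort("group contains probe ids not present in the universe")
  }
  N <- nrow(probes)
  n_g <- length(group)
  in_group <- probes$probe_id %in% group
  map_dfr(unique(features$feature_class), function(cl) {
    iv <- features %>% filter(feature_class == cl)
    ov <- overlaps_any(probes, iv)
    K <- sum(ov)
    k <- sum(ov & in_group)
    pct_u <- 100 * K / N
    pct_g <- 100 * k / n_g
    tibble(
      feature_class = cl,
      n_group = n_g, k_group = k, pct_group = pct_g,
      n_universe = N, K_universe = K, pct_universe = pct_u,
      log2_ratio = if (K == 0) NA_real_ else log2((k / n_g) / (K / N)),
      p_hyper = phyper(k - 1, K, N - K, n_g, lower.tail = FALSE)
    )
  })
}
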