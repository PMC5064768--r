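# ChIP read-count overlay on a probe universe: a length- and depth-
# normalised score per probe plus a top-quantile "enriched" label.

#' Overlay ChIP signal on probes
#'
#' With read intervals, counts reads per probe and normalises to
#' reads-per-kb-per-million (RPKM-like). With a pre-computed `score`
#' column, sums the score of overlapping intervals and applies the same
#' length/total normalisation. Probes at or above the `top_quantile` of
#' the score distribution are labelled enriched; ties at the threshold are
#' all included.
#'
#' @param probes probe tibble
#' @param chip interval tibble of reads, or intervals with a `score` column
#' @param top_quantile quantile defining "enriched" (default 0.9)
#' @return probes with added `chip_score` and `chip_enriched` columns
#' @export
overlay_chip <- function(probes, chip, top_quantile = 0.9) {
  if (nrow(chip) == 0) abort("zero total chip signal")
  weights <- if ("score" %in% names(chip)) chip$score else rep(1, nrow(chip))
  total <- sum(weights)
  if (total <= 0) abort("zero total chip signal")
  hits <- overlap_pairs(probes, chip)
  raw <- rep(0, nrow(probes))
  if (nrow(hits) > 0) {
    agg <- tibble(q = hits$q, w = weights[hits$s]) %>%
      group_by(q) %>% summarise(w = sum(w), .groups = "drop")
    raw[agg$q] <- agg$w
  }
  kb <- (probes$end - probes$start) / 1e3
  score <- raw / (kb * total / 1e6)
  thr <- quantile(score, top_quantile, names = FALSE, type = 7)
  probes %>% mutate(chip_score = score, chip_enriched = score >= thr)
}
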