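# Repeat-class expression: gene-proximity exclusion followed by RPKM per
# repeat class. RPKM = count / (total class length in kb x library size in
# millions), mirroring standard repeat-level RNA-seq quantitation.

#' Remove repeat instances near annotated genes
#'
#' Drops every repeat instance whose interval lies within `distance_bp` of
#' any gene body (overlap counts as within), so genic transcription does
#' not contaminate repeat-specific expression.
#'
#' @param repeats repeat instance tibble
#' @param genes gene model tibble
#' @param distance_bp exclusion distance in bp (default 2000, inclusive)
#' @return the filtered repeat tibble
#' @export
exclude_near_genes <- function(repeats, genes, distance_bp = 2000) {
  if (nrow(repeats) == 0 || nrow(genes) == 0) return(repeats)
  bodies <- genes %>% transmute(chrom, start = tx_start, end = tx_end)
  d <- GenomicRanges::distanceToNearest(
    as_granges0(repeats), as_granges0(bodies), ignore.strand = TRUE)
  dist <- rep(NA_real_, nrow(repeats))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  repeats[is.na(dist) | dist > distance_bp, ]
}

#' Repeat-class expression as RPKM
#'
#' Overlaps are non-directional (strand ignored). A read overlapping
#' instances of several classes contributes one count to each such class;
#' within one class a read is counted once.
#'
#' @param reads interval tibble of mapped RNA-seq reads (BED6-like)
#' @param repeats filtered repeat instance tibble (`feature_class`)
#' @param library_size total mapped reads of the library
#' @return tibble (`repeat_class`, `n_reads`, `length_bp`, `library_size`,
#'   `rpkm`)
#' @export
repeat_rpkm <- function(reads, repeats, library_size) {
  if (nrow(repeats) == 0) abort("empty repeat list")
  if (library_size <= 0) abort("library_size must be > 0")
  hits <- overlap_pairs(reads, repeats)
  counts <- tibble(read = hits$q,
                   repeat_class = repeats$feature_class[hits$s]) %>%
    distinct() %>%
    count(repeat_class, name = "n_reads")
  repeats %>%
    group_by(repeat_class = feature_class) %>%
    summarise(length_bp = sum(end - start), .groups = "drop") %>%
    left_join(counts, by = "repeat_class") %>%
    mutate(
      n_reads = as.integer(ifelse(is.na(n_reads), 0L, n_reads)),
      library_size = library_size,
      rpkm = n_reads / ((length_bp / 1e3) * (library_size / 1e6))
    ) %>%
    select(repeat_class, n_reads, length_bp, library_size, rpkm) %>%
    arrange(repeat_class)
}
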