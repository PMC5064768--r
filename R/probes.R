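# Probe construction. Two modes mirror standard WGBS practice:
#   tiling     - fixed-width windows tiled along each chromosome; trailing
#                partial windows are dropped so probe length stays constant
#   cpg_count  - windows spanning consecutive blocks of exactly n_cpg CpGs
#                (the final partial block is dropped)

#' Build a genomic probe set
#'
#' @param genome genome index tibble (`chrom`, `length`)
#' @param calls CpG call tibble; required for `mode = "cpg_count"`, where
#'   windows are defined on the union of CpG positions across all samples
#'   present so probe definitions are shared between samples
#' @param mode `"tiling"` or `"cpg_count"`
#' @param width,step tiling window width and step in bp (step defaults to
#'   width, i.e. non-overlapping consecutive probes)
#' @param n_cpg number of consecutive CpGs per probe in `cpg_count` mode
#' @param exclude optional interval tibble; probes overlapping any exclusion
#'   interval by >= 1 bp are dropped
#' @return tibble (`probe_id`, `chrom`, `start`, `end`) with attributes
#'   `mode` and `params`
#' @examples
#' g <- tibble::tibble(chrom = "chr1", length = 50000L)
#' make_probes(g, mode = "tiling", width = 20000)
#' @export
make_probes <- function(genome, calls = NULL, mode = c("tiling", "cpg_count"),
                        width = 20000, step = width, n_cpg = 50,
                        exclude = NULL) {
  mode <- match.arg(mode)
  validate_genome(genome)
  if (mode == "tiling") {
    if (width <= 0 || step <= 0) abort("width and step must be > 0")
    probes <- map_dfr(seq_len(nrow(genome)), function(i) {
      len <- genome$length[i]
      if (len < width) return(NULL)
      starts <- seq.int(0L, len - width, by = step)
      tibble(chrom = genome$chrom[i], start = as.integer(starts),
             end = as.integer(starts + width))
    })
    params <- list(width = width, step = step)
  } else {
    if (is.null(calls)) abort("cpg_count mode requires `calls`")
    if (n_cpg <= 0) abort("n_cpg must be > 0")
    pos_tbl <- calls %>% distinct(chrom, pos) %>% arrange(chrom, pos)
    probes <- pos_tbl %>%
      group_by(chrom) %>%
      group_modify(function(d, key) {
        n_full <- nrow(d) %/% n_cpg
        if (n_full == 0) return(tibble(start = integer(), end = integer()))
        idx <- seq_len(n_full * n_cpg)
        blk <- rep(seq_len(n_full), each = n_cpg)
        tibble(start = tapply(d$pos[idx], blk, min),
               end = tapply(d$pos[idx], blk, max) + 1L) %>%
          mutate(start = as.integer(start), end = as.integer(end))
      }) %>%
      ungroup()
    params <- list(n_cpg = n_cpg)
  }
  check_chroms(probes, genome)
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(probes) > 0) {
    probes <- probes[!overlaps_any(probes, exclude), ]
  }
  probes <- probes %>%
    arrange(chrom, start) %>%
    mutate(probe_id = paste0(chrom, ":", start, "-", end), .before = 1)
  attr(probes, "mode") <- mode
  attr(probes, "params") <- params
  probes
}
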