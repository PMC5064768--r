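# Gene models from BED12. Exons are reconstructed from blockSizes /
# blockStarts; TSS/TES are strand-aware accessors derived from tx bounds.

#' Read gene models from a BED12 file
#'
#' @param path BED12 file
#' @param genome optional genome index for chromosome validation
#' @return tibble with columns `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` and a list-column `exons` of tibbles (`start`, `end`),
#'   0-based half-open
#' @export
read_gene_models <- function(path, genome = NULL) {
  raw <- read_token_table(path, n_min = 12)
  if (length(raw) == 0 || nrow(raw) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), tx_start = integer(),
                  tx_end = integer(), exons = list()))
  }
  tx_start <- parse_count(raw[[2]], path, "txStart")
  tx_end <- parse_count(raw[[3]], path, "txEnd")
  strand <- raw[[6]]
  if (any(!strand %in% c("+", "-"))) {
    abort(paste0("gene strand must be + or - in ", path))
  }
  n_blocks <- parse_count(raw[[10]], path, "blockCount")
  exons <- lapply(seq_len(nrow(raw)), function(i) {
    sizes <- parse_count(strsplit(sub(",$", "", raw[[11]][i]), ",")[[1]],
                         path, "blockSizes")
    starts <- parse_count(strsplit(sub(",$", "", raw[[12]][i]), ",")[[1]],
                          path, "blockStarts")
    if (length(sizes) != n_blocks[i] || length(starts) != n_blocks[i]) {
      abort(paste0("block count mismatch at data line ", i, " of ", path))
    }
    ex <- tibble(start = tx_start[i] + starts,
                 end = tx_start[i] + starts + sizes)
    ex <- arrange(ex, start)
    if (any(ex$end > tx_end[i]) || any(ex$start < tx_start[i])) {
      abort(paste0("exon block outside transcript bounds at data line ", i,
                   " of ", path))
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(paste0("overlapping exon blocks at data line ", i, " of ", path))
    }
    ex
  })
  genes <- tibble(
    gene_id = raw[[4]], chrom = raw[[1]], strand = strand,
    tx_start = tx_start, tx_end = tx_end, exons = exons
  )
  check_chroms(genes %>% transmute(chrom), genome)
  genes
}

#' Write gene models as BED12
#' @param genes gene model tibble from [read_gene_models()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    paste(genes$chrom[i], genes$tx_start[i], genes$tx_end[i],
          genes$gene_id[i], 0, genes$strand[i],
          genes$tx_start[i], genes$tx_end[i], "0",
          nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - genes$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Strand-aware transcription start sites
#' @param genes gene model tibble
#' @return integer vector of 0-based TSS positions
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
}

#' Exon intervals of a gene model set, one row per exon
#' @param genes gene model tibble
#' @return tibble (`gene_id`, `chrom`, `strand`, `start`, `end`)
#' @export
gene_exons <- function(genes) {
  genes %>%
    select(gene_id, chrom, strand, exons) %>%
    tidyr::unnest(exons)
}

#' Intron intervals (gaps between exons within the transcript span)
#' @param genes gene model tibble
#' @return tibble (`gene_id`, `chrom`, `strand`, `start`, `end`)
#' @export
gene_introns <- function(genes) {
  map_dfr(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    if (nrow(ex) < 2) return(NULL)
    tibble(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
           strand = genes$strand[i],
           start = ex$end[-nrow(ex)], end = ex$start[-1])
  })
}

#' Promoter intervals: a fixed window immediately upstream of the TSS
#'
#' On the plus strand the promoter is `[TSS - upstream_bp, TSS)`; on the
#' minus strand the strand-mirrored window downstream of `tx_end`.
#' Windows are clipped at position 0.
#' @param genes gene model tibble
#' @param upstream_bp window size in bp (default 1000)
#' @return tibble (`gene_id`, `chrom`, `strand`, `start`, `end`)
#' @export
gene_promoters <- function(genes, upstream_bp = 1000) {
  genes %>%
    transmute(
      gene_id, chrom, strand,
      start = ifelse(strand == "+", pmax(0L, tx_start - upstream_bp), tx_end),
      end = ifelse(strand == "+", tx_start, tx_end + upstream_bp)
    ) %>%
    filter(start < end)
}
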