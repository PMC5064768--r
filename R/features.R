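# Feature-level methylation summaries: promoter CGI classification, pooled
# (call-weighted) methylation per feature class, the imprinted-DMR panel
# and repeat-class methylation.

#' Classify promoters as CGI or non-CGI
#'
#' Promoters are the 1-kb windows immediately upstream of each TSS
#' (strand-aware). A promoter is a CGI promoter when it contains, overlaps
#' or lies within `cgi_margin_bp` of any CGI.
#'
#' @param genes gene model tibble
#' @param cgis CGI interval tibble
#' @param upstream_bp promoter window size (default 1000)
#' @param cgi_margin_bp maximum gap to a CGI (default 250)
#' @return promoter tibble with `feature_class` in
#'   `CGI_promoter` / `nonCGI_promoter`
#' @export
classify_promoters <- function(genes, cgis, upstream_bp = 1000,
                               cgi_margin_bp = 250) {
  prom <- gene_promoters(genes, upstream_bp)
  if (nrow(prom) == 0) return(prom %>% mutate(feature_class = character(0)))
  if (is.null(cgis) || nrow(cgis) == 0) {
    return(prom %>% mutate(feature_class = "nonCGI_promoter"))
  }
  d <- GenomicRanges::distanceToNearest(
    as_granges0(prom), as_granges0(cgis), ignore.strand = TRUE)
  dist <- rep(NA_real_, nrow(prom))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  prom %>%
    mutate(feature_class = ifelse(!is.na(dist) & dist <= cgi_margin_bp,
                                  "CGI_promoter", "nonCGI_promoter"))
}

#' Pooled methylation per feature class
#'
#' For each sample and feature class, sums methylated and unmethylated
#' calls over all CpGs inside the class intervals (intervals of a class
#' are merged first so no CpG is counted twice within a class) and reports
#' the weighted fraction. Classes with zero covered CpGs are reported as
#' missing, not zero.
#'
#' @param features interval tibble with a `feature_class` column
#' @param calls long CpG call tibble
#' @return tibble (`sample`, `feature_class`, `meth_fraction`,
#'   `total_calls`, `n_cpgs`)
#' @export
feature_methylation <- function(features, calls) {
  classes <- unique(features$feature_class)
  samples <- unique(calls$sample)
  grid <- crossing(sample = samples, feature_class = classes)
  sums <- map_dfr(classes, function(cl) {
    iv <- reduce_intervals(features %>% filter(feature_class == cl))
    if (nrow(iv) == 0) return(NULL)
    hits <- overlap_pairs(calls %>% transmute(chrom, start = pos, end = pos + 1L), iv)
    if (nrow(hits) == 0) return(NULL)
    calls[hits$q, ] %>%
      group_by(sample) %>%
      summarise(meth = sum(meth), unmeth = sum(unmeth), n_cpgs = n(),
                .groups = "drop") %>%
      mutate(feature_class = cl)
  })
  if (nrow(sums) == 0) {
    sums <- tibble(sample = character(), feature_class = character(),
                   meth = integer(), unmeth = integer(),
                   n_cpgs = integer())
  }
  grid %>%
    left_join(sums, by = c("sample", "feature_class")) %>%
    mutate(
      total_calls = as.integer(ifelse(is.na(meth), 0L, meth + unmeth)),
      n_cpgs = as.integer(ifelse(is.na(n_cpgs), 0L, n_cpgs)),
      meth_fraction = ifelse(total_calls > 0, meth / (meth + unmeth), NA_real_)
    ) %>%
    select(sample, feature_class, meth_fraction, total_calls, n_cpgs)
}

#' Intergenic intervals: the complement of gene bodies
#' @param genome genome index tibble
#' @param genes gene model tibble
#' @return interval tibble with `feature_class = "intergenic"`
#' @export
intergenic_intervals <- function(genome, genes) {
  bodies <- reduce_intervals(
    genes %>% transmute(chrom, start = tx_start, end = tx_end))
  out <- map_dfr(seq_len(nrow(genome)), function(i) {
    chr <- genome$chrom[i]
    b <- bodies %>% filter(chrom == chr) %>% arrange(start)
    edges_start <- c(0L, b$end)
    edges_end <- c(b$start, genome$length[i])
    tibble(chrom = chr, start = edges_start, end = edges_end) %>%
      filter(start < end)
  })
  out %>% mutate(strand = ".", name = paste0("intergenic", row_number()),
                 feature_class = "intergenic")
}

#' Assemble the standard genomic feature panel
#'
#' Builds the feature classes used for genome-wide summaries: exons,
#' introns, CGI and non-CGI promoters, promoter and non-promoter CGIs,
#' intergenic regions, and (optionally) maternal/paternal imprinted DMRs.
#'
#' @param genome genome index tibble
#' @param genes gene model tibble
#' @param cgis CGI interval tibble
#' @param dmrs optional DMR tibble with parent in `feature_class`
#' @param upstream_bp,cgi_margin_bp promoter definition parameters
#' @return interval tibble with a `feature_class` column
#' @export
feature_panel <- function(genome, genes, cgis, dmrs = NULL,
                          upstream_bp = 1000, cgi_margin_bp = 250) {
  prom <- classify_promoters(genes, cgis, upstream_bp, cgi_margin_bp)
  cgi_cls <- if (nrow(cgis) > 0) {
    near_prom <- overlaps_any(cgis, prom %>%
      mutate(start = pmax(0L, start - cgi_margin_bp),
             end = end + cgi_margin_bp))
    cgis %>% mutate(feature_class = ifelse(near_prom, "promoter_CGI",
                                           "nonpromoter_CGI"))
  } else NULL
  pieces <- list(
    gene_exons(genes) %>% mutate(feature_class = "exon"),
    gene_introns(genes) %>% mutate(feature_class = "intron"),
    prom,
    cgi_cls,
    intergenic_intervals(genome, genes)
  )
  if (!is.null(dmrs) && nrow(dmrs) > 0) {
    pieces <- c(pieces, list(
      dmrs %>% mutate(feature_class = paste0("DMR_", feature_class))))
  }
  bind_rows(pieces) %>%
    select(any_of(c("chrom", "start", "end", "strand", "name",
                    "feature_class")))
}

#' Imprinted-DMR panel methylation trajectory
#'
#' Reports the pooled methylation of the maternal panel, the paternal
#' panel, and both combined, per sample. Both parental panels sitting near
#' 50% combined methylation in early stages and falling together late is
#' the signature of imprint erasure.
#'
#' @param dmrs DMR tibble (parent in `feature_class`)
#' @param calls long CpG call tibble
#' @return tibble (`sample`, `panel`, `meth_fraction`, `total_calls`)
#' @export
dmr_methylation <- function(dmrs, calls) {
  per_parent <- feature_methylation(dmrs, calls) %>%
    rename(panel = feature_class)
  combined <- feature_methylation(
    dmrs %>% mutate(feature_class = "combined"), calls) %>%
    rename(panel = feature_class)
  bind_rows(per_parent, combined) %>%
    select(sample, panel, meth_fraction, total_calls) %>%
    arrange(sample, panel)
}

#' Pooled methylation per repeat class
#'
#' Sums methylation and non-methylation calls over all instances of each
#' repeat class and reports the fraction of methylated calls.
#'
#' @param repeats repeat instance tibble (`feature_class` = repeat class)
#' @param calls long CpG call tibble
#' @return tibble (`sample`, `feature_class`, `meth_fraction`,
#'   `total_calls`, `n_cpgs`)
#' @export
repeat_class_methylation <- function(repeats, calls) {
  feature_methylation(repeats, calls)
}
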