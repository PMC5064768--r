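# Metagene methylation profiles: overlapping fixed-width windows across the
# 5' and 3' flanks and a scaled gene body, pooled call-weighted across all
# genes with every gene oriented TSS -> TES.

#' Metagene methylation profile
#'
#' Averages CpG methylation in 1-kb windows stepped every 500 bp across
#' `flank_bp` upstream of the TSS and downstream of the TES, and in
#' `body_bins` equal-width bins across the (length-scaled) gene body.
#' Minus-strand genes are flipped so all genes read TSS to TES. Values are
#' call-weighted fractions pooled over genes. Genes shorter than
#' `body_bins` bp are skipped with a message.
#'
#' @param genes gene model tibble
#' @param calls long CpG call tibble (profiles are computed per sample and
#'   pooled over samples unless a single sample is supplied)
#' @param flank_bp flank size (default 5000)
#' @param win_bp flank window width (default 1000)
#' @param step_bp flank window step (default 500)
#' @param body_bins number of scaled gene-body bins (default 40)
#' @return tibble (`sample`, `region`, `bin_index`, `bin_label`,
#'   `mean_fraction`, `total_calls`, `n_genes`); `bin_index` runs from 1
#'   (outermost upstream window) through body to the outermost downstream
#'   window
#' @export
metagene_profile <- function(genes, calls, flank_bp = 5000, win_bp = 1000,
                             step_bp = 500, body_bins = 40) {
  n_flank <- (flank_bp - win_bp) %/% step_bp + 1L
  short <- (genes$tx_end - genes$tx_start) < body_bins
  if (any(short)) {
    inform(paste0("metagene_profile: skipping ", sum(short),
                  " gene(s) shorter than ", body_bins, " bp"))
    genes <- genes[!short, ]
  }
  if (nrow(genes) == 0) abort("no eligible genes for metagene profile")

  ext <- genes %>%
    transmute(gene = row_number(), gene_id, chrom, strand,
              tx_start, tx_end,
              start = pmax(0L, tx_start - flank_bp), end = tx_end + flank_bp)
  hits <- overlap_pairs(
    calls %>% transmute(chrom, start = pos, end = pos + 1L), ext)
  if (nrow(hits) == 0) abort("no CpG calls overlap any gene region")

  d <- tibble(
    sample = calls$sample[hits$q],
    meth = calls$meth[hits$q], unmeth = calls$unmeth[hits$q],
    pos = calls$pos[hits$q],
    strand = ext$strand[hits$s],
    tx_start = ext$tx_start[hits$s], tx_end = ext$tx_end[hits$s],
    gene = ext$gene[hits$s]
  ) %>%
    mutate(
      glen = tx_end - tx_start,
      # signed distance from the TSS (negative = upstream), gene-oriented
      rel5 = ifelse(strand == "+", pos - tx_start, tx_end - 1L - pos),
      # signed distance past the TES (positive = downstream)
      rel3 = ifelse(strand == "+", pos - tx_end + 1L, tx_start - pos),
      region = case_when(
        rel5 < 0 ~ "upstream",
        rel5 >= 0 & rel5 < glen ~ "body",
        TRUE ~ "downstream"
      )
    )

  # flank windows overlap (win_bp/step_bp per position), so expand each CpG
  # to every window containing it
  flank_rows <- function(offset_bp) {
    # offset_bp in [0, flank_bp): distance from the outer edge of the flank;
    # window j covers offsets [(j-1)*step, (j-1)*step + win)
    j_lo <- pmax(1L, as.integer(floor((offset_bp - win_bp) / step_bp)) + 2L)
    j_hi <- pmin(n_flank, as.integer(floor(offset_bp / step_bp)) + 1L)
    list(lo = j_lo, hi = j_hi)
  }

  up <- d %>% filter(region == "upstream", rel5 >= -flank_bp)
  up_idx <- flank_rows(up$rel5 + flank_bp)
  up_exp <- up[rep(seq_len(nrow(up)), pmax(0L, up_idx$hi - up_idx$lo + 1L)), ]
  up_exp$bin_index <- unlist(map2(up_idx$lo, up_idx$hi, function(a, b) {
    if (b < a) integer(0) else seq.int(a, b)
  }))

  body <- d %>% filter(region == "body") %>%
    mutate(bin_index = n_flank + pmin(body_bins,
                                      floor(rel5 / glen * body_bins) + 1L))

  down <- d %>% filter(region == "downstream", rel3 >= 1, rel3 <= flank_bp)
  down_idx <- flank_rows(down$rel3 - 1L)
  down_exp <- down[rep(seq_len(nrow(down)),
                       pmax(0L, down_idx$hi - down_idx$lo + 1L)), ]
  down_exp$bin_index <- n_flank + body_bins + unlist(
    map2(down_idx$lo, down_idx$hi, function(a, b) {
      if (b < a) integer(0) else seq.int(a, b)
    }))

  binned <- bind_rows(up_exp, body, down_exp)
  labels <- tibble(
    bin_index = seq_len(2L * n_flank + body_bins),
    region = c(rep("upstream", n_flank), rep("body", body_bins),
               rep("downstream", n_flank)),
    bin_label = c(
      paste0("up_", rev(seq_len(n_flank))),
      paste0("body_", seq_len(body_bins)),
      paste0("down_", seq_len(n_flank))
    )
  )
  crossing(sample = unique(calls$sample), labels) %>%
    left_join(
      binned %>%
        group_by(sample, bin_index) %>%
        summarise(meth = sum(meth), unmeth = sum(unmeth),
                  n_genes = n_distinct(gene), .groups = "drop"),
      by = c("sample", "bin_index")
    ) %>%
    mutate(
      total_calls = as.integer(ifelse(is.na(meth), 0L, meth + unmeth)),
      mean_fraction = ifelse(total_calls > 0, meth / (meth + unmeth), NA_real_),
      n_genes = as.integer(ifelse(is.na(n_genes), 0L, n_genes))
    ) %>%
    select(sample, region, bin_index, bin_label, mean_fraction, total_calls,
           n_genes) %>%
    arrange(sample, bin_index)
}

#' Plot a metagene profile
#' @param profile tibble from [metagene_profile()]
#' @return a ggplot object
#' @export
plot_metagene <- function(profile) {
  ggplot(profile, aes(x = bin_index, y = mean_fraction, colour = sample)) +
    geom_line() +
    geom_vline(xintercept = range(profile$bin_index[profile$region == "body"]) +
                 c(-0.5, 0.5), linetype = "dashed", colour = "grey50") +
    labs(x = "bin (TSS → TES, flanks at sides)",
         y = "weighted methylation", colour = NULL) +
    ylim(0, 1) +
    theme_minimal()
}
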