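# Feature classification and pooled feature methylation.

make_gene <- function(id, chrom, strand, s, e) {
  tibble(gene_id = id, chrom = chrom, strand = strand,
         tx_start = as.integer(s), tx_end = as.integer(e),
         exons = list(tibble(start = as.integer(s), end = as.integer(e))))
}

test_that("promoters are CGI promoters within 250 bp of a CGI", {
  gene <- make_gene("g1", "chr1", "+", 10000, 20000)
  # promoter = [9000, 10000); CGI ending 200 bp before it
  cgi_near <- tibble(chrom = "chr1", start = 8500L, end = 8800L,
                     feature_class = "CGI")
  cgi_far <- tibble(chrom = "chr1", start = 8500L, end = 8749L,
                    feature_class = "CGI")
  expect_equal(classify_promoters(gene, cgi_near)$feature_class,
               "CGI_promoter")
  expect_equal(classify_promoters(gene, cgi_far)$feature_class,
               "nonCGI_promoter")
})

test_that("promoter labels agree with a pairwise gap-distance oracle", {
  withr::with_seed(9, {
    genes <- purrr::map_dfr(1:30, function(i) {
      s <- sample.int(9e5, 1) + 20000
      make_gene(paste0("g", i), "chr1", sample(c("+", "-"), 1), s, s + 5000)
    })
    cs <- sample.int(95e4, 40)
  })
  cgis <- tibble(chrom = "chr1", start = cs, end = cs + 500L,
                 feature_class = "CGI")
  got <- classify_promoters(genes, cgis)
  prom <- gene_promoters(genes)
  want <- vapply(seq_len(nrow(prom)), function(i) {
    gaps <- vapply(seq_len(nrow(cgis)), function(j) {
      oracle_gap(prom$start[i], prom$end[i], cgis$start[j], cgis$end[j])
    }, numeric(1))
    if (min(gaps) <= 250) "CGI_promoter" else "nonCGI_promoter"
  }, character(1))
  expect_equal(got$feature_class, want)
})

test_that("feature methylation pools calls per class", {
  feats <- tibble(chrom = "chr1", start = 100L, end = 200L,
                  feature_class = "exon")
  calls <- tibble(sample = "s", chrom = "chr1", pos = c(120L, 150L),
                  meth = c(2L, 1L), unmeth = c(0L, 1L))
  fm <- feature_methylation(feats, calls)
  expect_equal(fm$meth_fraction, 0.75)
  # class with zero covered CpGs reports missing, not zero
  feats2 <- bind_rows(feats, tibble(chrom = "chr1", start = 5000L,
                                    end = 6000L, feature_class = "desert"))
  fm2 <- feature_methylation(feats2, calls)
  expect_true(is.na(fm2$meth_fraction[fm2$feature_class == "desert"]))
})

test_that("DMR panel combines maternal and paternal symmetrically", {
  dmrs <- tibble(chrom = "chr1", start = c(100L, 1000L),
                 end = c(200L, 1100L), name = c("mat1", "pat1"),
                 feature_class = c("maternal", "paternal"))
  calls <- tibble(sample = "s", chrom = "chr1", pos = c(150L, 1050L),
                  meth = c(10L, 0L), unmeth = c(0L, 10L))
  dm <- dmr_methylation(dmrs, calls)
  expect_equal(dm$meth_fraction[dm$panel == "maternal"], 1.0)
  expect_equal(dm$meth_fraction[dm$panel == "paternal"], 0.0)
  expect_equal(dm$meth_fraction[dm$panel == "combined"], 0.5)
})

test_that("per-class fractions match a brute-force pooling oracle", {
  g <- tiny_genome(1e5)
  withr::with_seed(21, {
    s <- sample.int(9e4, 20)
    cls <- sample(c("LINE/L1", "SINE", "LTR", "SVA", "DNA"), 20,
                  replace = TRUE)
  })
  feats <- tibble(chrom = "chr1", start = s, end = s + 1000L,
                  feature_class = cls)
  calls <- random_calls(500, g, seed = 22)
  got <- repeat_class_methylation(feats, calls)
  for (cl in unique(cls)) {
    iv <- feats[feats$feature_class == cl, ]
    inside <- vapply(calls$pos, function(p) {
      any(iv$start <= p & p < iv$end)
    }, logical(1))
    m <- sum(calls$meth[inside]); u <- sum(calls$unmeth[inside])
    want <- if (m + u > 0) m / (m + u) else NA_real_
    expect_equal(got$meth_fraction[got$feature_class == cl], want,
                 tolerance = 1e-12)
  }
})

test_that("metagene profile is flat on a uniform field and strand-symmetric", {
  gene_p <- make_gene("gp", "chr1", "+", 20000, 30000)
  pos <- as.integer(seq(14000, 36000, by = 100))
  calls <- tibble(sample = "s", chrom = "chr1", pos = pos,
                  meth = 5L, unmeth = 5L)
  prof_p <- metagene_profile(gene_p, calls)
  expect_true(all(abs(prof_p$mean_fraction - 0.5) < 1e-12))
  expect_equal(nrow(prof_p), 9 + 40 + 9)

  # mirrored minus-strand gene with mirrored calls gives the same profile
  gene_m <- make_gene("gm", "chr1", "-", 20000, 30000)
  calls_m <- calls %>% mutate(pos = as.integer(50000 - pos))
  prof_m <- metagene_profile(gene_m, calls_m)
  expect_equal(prof_p$mean_fraction, prof_m$mean_fraction)
})

test_that("a TSS-restricted unmethylated zone pulls down TSS-adjacent bins", {
  gene <- make_gene("g", "chr1", "+", 20000, 30000)
  pos <- as.integer(seq(14000, 36000, by = 50))
  near_tss <- abs(pos - 20000) <= 500
  calls <- tibble(sample = "s", chrom = "chr1", pos = pos,
                  meth = ifelse(near_tss, 0L, 8L),
                  unmeth = ifelse(near_tss, 8L, 0L))
  prof <- metagene_profile(gene, calls)
  lowest <- prof$bin_index[which.min(prof$mean_fraction)]
  # the minimum must sit in a bin touching the TSS (last upstream windows
  # or first body bins)
  expect_true(lowest %in% c(8, 9, 10, 11))
  # brute-force check of one flank window: up_1 = [TSS-1000, TSS)
  sel <- pos >= 19000 & pos < 20000
  want <- sum(calls$meth[sel]) / sum(calls$meth[sel] + calls$unmeth[sel])
  expect_equal(prof$mean_fraction[prof$bin_label == "up_1"], want)
})

test_that("short genes are skipped and empty input errors", {
  g_short <- make_gene("tiny", "chr1", "+", 100, 130)
  calls <- tibble(sample = "s", chrom = "chr1", pos = 110L,
                  meth = 1L, unmeth = 1L)
  expect_message(expect_error(metagene_profile(g_short, calls),
                              "no eligible genes"), "skipping")
})
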