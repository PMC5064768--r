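# Synthetic data generator: determinism, planted structure, generative
# consistency.

small_cfg <- function(seed = 5, ...) {
  simulation_config(seed = seed,
                    chrom_sizes = c(chr1 = 3e5, chr2 = 3e5), ...)
}

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(proportions = c(cgi = 0.5, old_te = 0.4)),
               "sum to 1")
  expect_error(
    simulation_config(stage_means = matrix(c(0.5, 1.2), 1, 2,
                                           dimnames = list("cgi", c("a", "b")))),
    "\\[0, 1\\]")
})

test_that("the generator is deterministic under the seed", {
  s1 <- simulate_genome_and_annotation(small_cfg())
  s2 <- simulate_genome_and_annotation(small_cfg())
  expect_identical(s1$regions, s2$regions)
  expect_identical(s1$cpgs, s2$cpgs)
  expect_identical(s1$sequence, s2$sequence)
  m1 <- simulate_methylomes(small_cfg(), s1)
  m2 <- simulate_methylomes(small_cfg(), s2)
  expect_identical(m1$calls, m2$calls)
  r1 <- simulate_smrna(small_cfg(), s1)
  r2 <- simulate_smrna(small_cfg(), s2)
  expect_identical(r1$reads, r2$reads)
})

test_that("zero CGI proportion emits no CGI intervals", {
  cfg <- small_cfg(proportions = c(cgi = 0, young_te = 0.05, old_te = 0.15,
                                   gene_body = 0.30, imprinted_dmr = 0.01,
                                   intergenic = 0.49))
  sim <- simulate_genome_and_annotation(cfg, emit_sequence = FALSE)
  expect_equal(nrow(sim$cgis), 0L)
})

test_that("CpG density inside CGIs is about tenfold enriched", {
  cfg <- simulation_config(seed = 2, chrom_sizes = c(chr1 = 2e6))
  sim <- simulate_genome_and_annotation(cfg, emit_sequence = FALSE)
  cgi_bp <- sum(sim$cgis$end - sim$cgis$start)
  other_bp <- sum(sim$genome$length) - cgi_bp
  in_cgi <- oracle_overlaps_any(
    sim$cpgs %>% mutate(start = pos, end = pos + 1L), sim$cgis)
  rate_in <- sum(in_cgi) / cgi_bp
  rate_out <- sum(!in_cgi) / other_bp
  ratio <- rate_in / rate_out
  # Poisson counting error on the CGI count dominates
  sd_ratio <- ratio / sqrt(sum(in_cgi))
  expect_lt(abs(ratio - 10), 3 * sd_ratio + 0.5)
})

test_that("a zero class mean produces fully unmethylated calls", {
  means <- rbind(cgi = 0, young_te = 0, old_te = 0, gene_body = 0,
                 imprinted_dmr = 0, intergenic = 0)
  colnames(means) <- "s1"
  cfg <- small_cfg(stage_means = means)
  sim <- simulate_genome_and_annotation(cfg, emit_sequence = FALSE)
  meth <- simulate_methylomes(cfg, sim)
  expect_equal(sum(meth$calls$meth), 0L)
})

test_that("high precision and coverage recover the stage-mean table", {
  cfg <- simulation_config(seed = 3, chrom_sizes = c(chr1 = 2e6),
                           beta_precision = 1e5, coverage_mean = 60,
                           coverage_size = 50)
  sim <- simulate_genome_and_annotation(cfg, emit_sequence = FALSE)
  meth <- simulate_methylomes(cfg, sim)
  # pooled over intergenic regions (largest class) per stage
  ig <- sim$regions %>% filter(class == "intergenic") %>%
    transmute(chrom, start, end, feature_class = "intergenic")
  fm <- feature_methylation(ig, meth$calls)
  for (st in cfg$stages) {
    expect_equal(fm$meth_fraction[fm$sample == st],
                 cfg$stage_means["intergenic", st], tolerance = 0.012)
  }
})

test_that("DMR panels echo the configured intermediate level", {
  cfg <- simulation_config(seed = 9, chrom_sizes = c(chr1 = 2e6))
  sim <- simulate_genome_and_annotation(cfg, emit_sequence = FALSE)
  meth <- simulate_methylomes(cfg, sim)
  dm <- dmr_methylation(sim$dmrs, meth$calls)
  early <- dm$meth_fraction[dm$panel == "combined" & dm$sample == "naive"]
  n_dmr <- nrow(sim$dmrs)
  sd_panel <- sqrt(0.25 / (cfg$beta_precision + 1) / n_dmr + 0.25 /
                     dm$total_calls[dm$panel == "combined" &
                                      dm$sample == "naive"])
  expect_lt(abs(early - 0.5), 3 * sd_panel)
})

test_that("emitted read sequences equal the genome substring, strand-aware", {
  cfg <- small_cfg()
  sim <- simulate_genome_and_annotation(cfg)
  smr <- simulate_smrna(cfg, sim)
  reads <- smr$reads
  idx <- seq_len(nrow(reads))
  want <- vapply(idx, function(i) {
    s <- substring(sim$sequence[[reads$chrom[i]]], reads$start[i] + 1,
                   reads$end[i])
    if (reads$strand[i] == "-") {
      chartr("ACGT", "TGCA",
             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    } else s
  }, character(1))
  expect_identical(reads$sequence, want)
})

test_that("slicer pairing plants 10-nt 5'-5' overlaps in the truth table", {
  cfg <- small_cfg()
  sim <- simulate_genome_and_annotation(cfg)
  smr <- simulate_smrna(cfg, sim)
  paired <- smr$truth %>% filter(!is.na(partner))
  expect_gt(nrow(paired), 0)
  j <- paired %>%
    left_join(smr$reads, by = "read_id") %>%
    left_join(smr$reads, by = c(partner = "read_id"),
              suffix = c("_sec", "_pri"))
  five <- function(start, end, strand) ifelse(strand == "+", start, end - 1L)
  p_sec <- five(j$start_sec, j$end_sec, j$strand_sec)
  p_pri <- five(j$start_pri, j$end_pri, j$strand_pri)
  d <- ifelse(j$strand_pri == "+", p_sec - p_pri + 1L, p_pri - p_sec + 1L)
  expect_true(all(d == 10L))
  # pairing fraction 0 leaves no partners
  cfg0 <- small_cfg(smrna = list(pingpong_fraction = 0))
  smr0 <- simulate_smrna(cfg0, simulate_genome_and_annotation(cfg0))
  expect_true(all(is.na(smr0$truth$partner)))
})

test_that("chip tracks separate resistant regions by the configured effect", {
  cfg <- simulation_config(seed = 4, chrom_sizes = c(chr1 = 2e6))
  sim <- simulate_genome_and_annotation(cfg, emit_sequence = FALSE)
  chip <- simulate_chip(cfg, sim)
  k9 <- chip %>% filter(feature_class == "H3K9me3") %>%
    left_join(sim$regions %>% select(name = region_id, resistant),
              by = "name")
  m_res <- mean(log(k9$score[k9$resistant]))
  m_oth <- mean(log(k9$score[!k9$resistant]))
  # two-sample comparison on the log scale against the configured effect
  se <- cfg$chip$noise_sd * sqrt(1 / sum(k9$resistant) +
                                   1 / sum(!k9$resistant))
  expect_lt(abs((m_res - m_oth) - log(cfg$chip$k9_effect)), 3 * se)
  # zero effect leaves the classes exchangeable
  cfg0 <- simulation_config(seed = 4, chrom_sizes = c(chr1 = 2e6),
                            chip = list(k9_effect = 1))
  chip0 <- simulate_chip(cfg0, sim)
  k90 <- chip0 %>% filter(feature_class == "H3K9me3") %>%
    left_join(sim$regions %>% select(name = region_id, resistant),
              by = "name")
  ks <- suppressWarnings(stats::ks.test(k90$score[k90$resistant],
                                        k90$score[!k90$resistant]))
  expect_gt(ks$p.value, 0.01)
})
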