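# IO layer: coordinate conventions, validation errors, round trips.

test_that("bismark coverage lines map to 0-based records", {
  tf <- withr::local_tempfile()
  writeLines("chr1 101 101 50.0 5 5", tf)
  calls <- read_cpg_calls(tf, "bismark_cov", "s1")
  expect_equal(calls$pos, 100L)
  expect_equal(calls$meth, 5L)
  expect_equal(calls$unmeth, 5L)
  expect_equal(calls$sample, "s1")
})

test_that("bismark and bedGraph encodings of the same CpG agree", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(c("chr1\t101\t101\t50\t5\t5", "chr1\t201\t201\t100\t7\t0"), f1)
  writeLines(c("chr1\t100\t101\t50\t5\t5", "chr1\t200\t201\t100\t7\t0"), f2)
  a <- read_cpg_calls(f1, "bismark_cov", "s")
  b <- read_cpg_calls(f2, "bedgraph_counts", "s")
  expect_equal(a, b)
})

test_that("empty call files give zero records", {
  tf <- withr::local_tempfile()
  writeLines(character(0), tf)
  expect_equal(nrow(read_cpg_calls(tf, "bismark_cov", "s")), 0L)
})

test_that("randomly ordered lines come back sorted (sort oracle)", {
  withr::with_seed(42, {
    pos <- sample.int(1e6, 1000)
    chrom <- sample(c("chr1", "chr2"), 1000, replace = TRUE)
  })
  lines <- paste(chrom, pos, pos, 0, 1, 1, sep = "\t")
  tf <- withr::local_tempfile()
  writeLines(lines, tf)
  calls <- read_cpg_calls(tf, "bismark_cov", "s")
  ord <- order(chrom, pos)   # independent sort
  expect_equal(calls$chrom, chrom[ord])
  expect_equal(calls$pos, as.integer(pos[ord] - 1L))
})

test_that("malformed call files error with diagnostics", {
  tf <- withr::local_tempfile()
  writeLines(c("chr1\t10\t10\t0\t1\t1", "chr1\tbroken"), tf)
  expect_error(read_cpg_calls(tf, "bismark_cov", "s"), "line 2")
  writeLines("chr1\t10\t10\t0\t-1\t1", tf)
  expect_error(read_cpg_calls(tf, "bismark_cov", "s"), "negative")
  writeLines(c("chr1\t10\t10\t0\t1\t1", "chr1\t10\t10\t0\t2\t2"), tf)
  expect_error(read_cpg_calls(tf, "bismark_cov", "s"), "duplicate")
  writeLines("chr9\t10\t10\t0\t1\t1", tf)
  expect_error(read_cpg_calls(tf, "bismark_cov", "s", genome = tiny_genome()),
               "chr9")
})

test_that("CpG call sets round-trip through both dialects", {
  g <- tiny_genome(1e5)
  calls <- random_calls(200, g, seed = 7)
  for (d in c("bismark_cov", "bedgraph_counts")) {
    tf <- withr::local_tempfile()
    write_cpg_calls(calls, tf, dialect = d)
    back <- read_cpg_calls(tf, d, "s1")
    expect_equal(back, calls, ignore_attr = TRUE)
  }
})

test_that("BED, repeat and DMR tables parse with validation", {
  tf <- withr::local_tempfile()
  writeLines("chr1\t0\t100\tcgi1", tf)
  iv <- read_intervals(tf, "bed", feature_class = "CGI")
  expect_equal(iv$start, 0L)
  expect_equal(iv$end, 100L)
  expect_equal(iv$name, "cgi1")

  writeLines("chr1\t500\t900\tICR1\tmaternal", tf)
  dmr <- read_intervals(tf, "dmr_tsv")
  expect_equal(dmr$feature_class, "maternal")
  writeLines("chr1\t500\t900\tICR1\tboth", tf)
  expect_error(read_intervals(tf, "dmr_tsv"), "maternal/paternal")

  withr::with_seed(1, {
    cls <- sample(c("LINE/L1", "SINE", "LTR/ERVK"), 10, replace = TRUE)
    cls[1:3] <- c("LINE/L1", "SINE", "LTR/ERVK")
    s <- sort(sample.int(1e4, 10)) * 10
  })
  writeLines(paste("chr1", s, s + 50, "+", cls, "fam", sep = "\t"), tf)
  reps <- read_intervals(tf, "repeat_tsv")
  expect_equal(nrow(reps), 10L)
  expect_equal(dplyr::n_distinct(reps$feature_class), 3L)

  writeLines("chr1\t100\t100\tx", tf)
  expect_error(read_intervals(tf, "bed"), "start >= end")
  writeLines("chrX\t0\t10\tx", tf)
  expect_error(read_intervals(tf, "bed", genome = tiny_genome()), "chrX")
})

test_that("BED12 gene models are strand-aware with exact introns", {
  tf <- withr::local_tempfile()
  writeLines(c(
    "chr1\t1000\t2000\tgplus\t0\t+\t1000\t2000\t0\t1\t1000,\t0,",
    "chr1\t1000\t2000\tgminus\t0\t-\t1000\t2000\t0\t1\t1000,\t0,",
    "chr1\t5000\t9000\tg2\t0\t+\t5000\t9000\t0\t2\t1000,2000,\t0,2000,"
  ), tf)
  genes <- read_gene_models(tf)
  expect_equal(gene_tss(genes)[1:2], c(1000L, 2000L))
  intr <- gene_introns(genes)
  # interval-algebra oracle: [5000,9000) minus exons [5000,6000),[7000,9000)
  expect_equal(intr$start, 6000L)
  expect_equal(intr$end, 7000L)
  writeLines("chr1\t1000\t2000\tbad\t0\t+\t1000\t2000\t0\t1\t1500,\t0,", tf)
  expect_error(read_gene_models(tf), "outside transcript bounds")
})

test_that("small RNA sets join by id, validate lengths, and round-trip", {
  fa <- withr::local_tempfile(); bed <- withr::local_tempfile()
  writeLines(c(">r1", strrep("A", 26)), fa)
  writeLines("chr1\t100\t126\tr1\t1\t+", bed)
  reads <- read_smrna(fa, bed)
  expect_equal(nrow(reads), 1L)
  expect_true(reads$unique_flag)

  writeLines("chr1\t100\t125\tr1\t1\t+", bed)
  expect_error(read_smrna(fa, bed), "length mismatch")
  writeLines("chr1\t100\t126\tr2\t1\t+", bed)
  expect_error(read_smrna(fa, bed), "without FASTA entry")

  withr::with_seed(3, {
    n <- 500
    len <- sample(20:30, n, replace = TRUE)
    seqs <- vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
    start <- sample.int(1e5, n)
  })
  set0 <- tibble(
    read_id = sprintf("r%03d", seq_len(500)), chrom = "chr1",
    start = start, end = start + len,
    strand = rep(c("+", "-"), length.out = 500),
    sequence = seqs, unique_flag = rep(c(TRUE, FALSE), length.out = 500),
    class_label = NA_character_
  )
  write_smrna(set0, fa, bed)
  back <- read_smrna(fa, bed)
  expect_equal(arrange(back, read_id), arrange(set0, read_id))
})
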