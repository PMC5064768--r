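# Small RNA signature statistics.

mk_reads <- function(chrom, start, len, strand, seqs = NULL,
                     unique_flag = TRUE) {
  n <- length(start)
  tibble(
    read_id = sprintf("r%04d", seq_len(n)), chrom = chrom,
    start = as.integer(start), end = as.integer(start + len),
    strand = strand,
    sequence = seqs %||% strrep("A", len),
    unique_flag = rep(unique_flag, length.out = n),
    class_label = NA_character_
  )
}

test_that("classification follows the fixed hierarchy and partitions reads", {
  reads <- mk_reads("chr1", c(100, 100, 900), 25, "+")
  ann <- list(
    miRNA = tibble(chrom = "chr1", start = 90L, end = 130L,
                   feature_class = "miRNA"),
    "repeat" = tibble(chrom = "chr1", start = 80L, end = 140L, strand = "+",
                      feature_class = "LINE/L1")
  )
  cls <- classify_reads(reads, ann)
  expect_equal(cls$class_label, c("miRNA", "miRNA", "unannotated"))
  expect_equal(sum(table(cls$class_label)), nrow(reads))
})

test_that("disjoint annotations recover planted origins almost perfectly", {
  # three disjoint blocks, one per class
  ann <- list(
    rRNA = tibble(chrom = "chr1", start = 0L, end = 10000L,
                  feature_class = "rRNA"),
    miRNA = tibble(chrom = "chr1", start = 20000L, end = 30000L,
                   feature_class = "miRNA"),
    "repeat" = tibble(chrom = "chr1", start = 40000L, end = 50000L,
                      strand = "+", feature_class = "SVA")
  )
  withr::with_seed(31, {
    origin <- sample(c("rRNA", "miRNA", "repeat"), 1000, replace = TRUE)
    off <- sample.int(9000, 1000)
  })
  base <- c(rRNA = 0L, miRNA = 20000L, `repeat` = 40000L)
  reads <- mk_reads("chr1", base[origin] + off, 25,
                    sample(c("+", "-"), 1000, replace = TRUE))
  cls <- classify_reads(reads, ann)
  expect_gte(mean(cls$class_label == origin), 0.99)
})

test_that("length distributions count and filter as configured", {
  reads <- bind_rows(
    mk_reads("chr1", seq(100, by = 100, length.out = 5), 26, "+"),
    mk_reads("chr1", seq(1000, by = 100, length.out = 3), 22, "+")
  ) %>% mutate(read_id = sprintf("r%04d", dplyr::row_number()))
  cls <- reads %>% mutate(class_label = "repeat", match_strand = "+")
  ld <- length_distribution(cls)
  expect_equal(ld$count[ld$length_nt == 26], 5L)
  expect_equal(ld$count[ld$length_nt == 22], 3L)
  expect_equal(sum(ld$count), 8L)
  # all-rRNA input leaves an empty histogram
  ld0 <- length_distribution(cls %>% mutate(class_label = "rRNA"))
  expect_equal(sum(ld0$count), 0L)
  # sense/antisense split relative to the matched repeat
  cls2 <- cls %>% mutate(strand = rep(c("+", "-"), length.out = 8))
  lds <- length_distribution(cls2, by_repeat_strand = TRUE)
  expect_equal(sum(lds$count[lds$orientation == "sense"]), 4L)
  expect_equal(sum(lds$count[lds$orientation == "antisense"]), 4L)
})

test_that("5' composition reads the genome strand-aware", {
  genome <- c(chr1 = paste(rep("ACGT", 30), collapse = ""))  # period 4
  # plus read starting at 0-based 8 -> first base = base 9 = "A"
  reads <- mk_reads("chr1", 8, 20, "+") %>%
    mutate(class_label = "repeat", match_strand = "+")
  comp <- five_prime_composition(reads, genome, window = 4)
  at1 <- comp %>% filter(position == 1)
  expect_equal(at1$freq[at1$base == "A"], 1)
  # minus-strand read: 5' end at its highest coordinate, complemented
  readm <- mk_reads("chr1", 8, 20, "-") %>%
    mutate(class_label = "repeat", match_strand = "+")
  compm <- five_prime_composition(readm, genome, window = 4)
  # genome base at 0-based 27 is "T" (27 %% 4 == 3), complement "A"
  at1m <- compm %>% filter(position == 1)
  expect_equal(at1m$freq[at1m$base == "A"], 1)
  expect_error(five_prime_composition(
    reads %>% mutate(chrom = "chr9"), genome), "chr9")
  # every fully-in-bounds position sums to 1
  sums <- comp %>% group_by(position) %>% summarise(s = sum(freq))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("ping-pong overlap arithmetic and degenerate cases", {
  # plus 5' at 100, minus 5' at 109 -> overlap 10
  reads <- bind_rows(
    mk_reads("chr1", 100, 26, "+"),
    mk_reads("chr1", 109 - 25, 26, "-")
  ) %>% mutate(read_id = c("a", "b"), class_label = "repeat")
  pp <- pingpong_profile(reads)
  expect_equal(pp$count[pp$overlap == 10], 1)
  expect_equal(sum(pp$count), 1)
  # one-strand input: zero profile, z10 undefined
  pp0 <- pingpong_profile(reads %>% mutate(strand = "+"))
  expect_equal(sum(pp0$count), 0)
  expect_true(is.na(pingpong_z(pp0)))
})

test_that("the overlap histogram is invariant under strand swapping", {
  withr::with_seed(33, {
    start <- sample.int(5e4, 300)
    strand <- sample(c("+", "-"), 300, replace = TRUE)
  })
  reads <- mk_reads("chr1", start, 26, strand) %>%
    mutate(class_label = "repeat")
  pp1 <- pingpong_profile(reads)
  # swapping strands maps a (p+, p-) pair to (p'-, p'+) with the same
  # 5'-5' spacing once coordinates are mirrored around the pair
  flip <- reads %>% mutate(strand = ifelse(strand == "+", "-", "+"),
                           start = 5e4 + 26 - end,
                           end = start + 26)
  pp2 <- pingpong_profile(flip)
  expect_equal(pp1$count, pp2$count)
})
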