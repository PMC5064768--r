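# piRNA signature statistics. Sequential exclusion of rRNA/miRNA reads is
# emulated by a single hierarchical labelling pass (identical partition
# given interval annotations): rRNA > miRNA > piRNA_gene > repeat > gene >
# unannotated. Downstream statistics: length spectra (optionally split by
# strand relative to the matched repeat), 5' nucleotide composition, and
# the ping-pong 5'-5' overlap profile with its z-score at 10 nt.

SMRNA_HIERARCHY <- c("rRNA", "miRNA", "piRNA_gene", "repeat", "gene")

#' Classify small RNA reads against annotation sets
#'
#' The first matching class in the fixed hierarchy
#' rRNA > miRNA > piRNA_gene > repeat > gene wins; a match is >= 1 bp
#' overlap of the read interval (strand-blind). Reads matching nothing are
#' `unannotated`. For repeat-class reads the strand of the matched repeat
#' instance is recorded in `match_strand` (largest-overlap instance on
#' ties).
#'
#' @param reads small RNA read tibble from [read_smrna()]
#' @param annotations named list of interval tibbles; recognised names:
#'   `rRNA`, `miRNA`, `piRNA_gene`, `repeat`, `gene`. Missing or empty
#'   entries leave that class unused.
#' @return `reads` with `class_label` filled and a `match_strand` column
#' @export
classify_reads <- function(reads, annotations = list()) {
  label <- rep(NA_character_, nrow(reads))
  match_strand <- rep(NA_character_, nrow(reads))
  for (cl in SMRNA_HIERARCHY) {
    ann <- annotations[[cl]]
    if (is.null(ann) || nrow(ann) == 0) next
    todo <- which(is.na(label))
    if (length(todo) == 0) break
    hits <- overlap_pairs(reads[todo, ], ann)
    if (nrow(hits) == 0) next
    if (cl == "repeat" && "strand" %in% names(ann)) {
      ov <- hits %>%
        mutate(
          w = pmin(reads$end[todo][q], ann$end[s]) -
            pmax(reads$start[todo][q], ann$start[s])
        ) %>%
        group_by(q) %>% slice_max(w, n = 1, with_ties = FALSE) %>% ungroup()
      match_strand[todo[ov$q]] <- ann$strand[ov$s]
    }
    label[todo[unique(hits$q)]] <- cl
  }
  label[is.na(label)] <- "unannotated"
  reads %>% mutate(class_label = label, match_strand = match_strand)
}

#' Small RNA length distribution
#'
#' Histogram of read lengths over 18-35 nt. With `by_repeat_strand`, only
#' repeat-class reads are used and counts are split by the read strand
#' relative to the matched repeat (same strand = sense).
#'
#' @param classified classified read tibble from [classify_reads()]
#' @param exclude classes to drop (default `"rRNA"`)
#' @param unique_only keep uniquely mapped reads only (default TRUE)
#' @param by_repeat_strand split repeat-class reads by sense/antisense
#' @param range lengths reported (default 18:35)
#' @return tibble (`length_nt`, `count`) or (`length_nt`, `orientation`,
#'   `count`)
#' @export
length_distribution <- function(classified, exclude = "rRNA",
                                unique_only = TRUE,
                                by_repeat_strand = FALSE, range = 18:35) {
  d <- classified %>% filter(!class_label %in% exclude)
  if (unique_only) d <- d %>% filter(unique_flag)
  d <- d %>% mutate(length_nt = end - start) %>%
    filter(length_nt >= min(range), length_nt <= max(range))
  if (by_repeat_strand) {
    d <- d %>%
      filter(class_label == "repeat", !is.na(match_strand),
             match_strand %in% c("+", "-")) %>%
      mutate(orientation = ifelse(strand == match_strand, "sense",
                                  "antisense"))
    d %>%
      count(length_nt, orientation, name = "count") %>%
      complete(length_nt = range, orientation = c("sense", "antisense"),
               fill = list(count = 0L)) %>%
      arrange(length_nt, orientation)
  } else {
    d %>%
      count(length_nt, name = "count") %>%
      complete(length_nt = range, fill = list(count = 0L)) %>%
      arrange(length_nt)
  }
}

#' Plot a length distribution
#' @param ld tibble from [length_distribution()]
#' @return a ggplot object
#' @export
plot_length_distribution <- function(ld) {
  p <- if ("orientation" %in% names(ld)) {
    ggplot(ld, aes(x = length_nt, y = count, fill = orientation)) +
      geom_col(position = "dodge") +
      scale_fill_manual(values = c(sense = "#2166ac", antisense = "#b2182b"))
  } else {
    ggplot(ld, aes(x = length_nt, y = count)) + geom_col(fill = "grey30")
  }
  p + labs(x = "read length (nt)", y = "reads") + theme_minimal()
}

#' Nucleotide composition around read 5' ends
#'
#' Base frequencies at positions -window..+window around the 5' end of
#' each read (position +1 is the read's first nucleotide; there is no
#' position 0). Minus-strand reads are reverse-complemented so positions
#' follow the read direction. Positions truncated at chromosome ends are
#' excluded from that position's normalisation.
#'
#' @param classified classified read tibble
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path
#' @param window flank size in nt (default 30)
#' @param class read class to profile (default `"repeat"`)
#' @param unique_only uniquely mapped reads only (default TRUE)
#' @return tibble (`position`, `base`, `freq`, `n`) where `n` is the
#'   number of in-bounds reads at that position; class `germ_fiveprime`
#' @export
five_prime_composition <- function(classified, genome, window = 30,
                                   class = "repeat", unique_only = TRUE) {
  seqs <- normalize_genome_seq(genome)
  d <- classified %>% filter(class_label %in% class)
  if (unique_only) d <- d %>% filter(unique_flag)
  if (nrow(d) == 0) abort("no reads in the requested class")
  missing_chr <- setdiff(unique(d$chrom), names(seqs))
  if (length(missing_chr) > 0) {
    abort(paste0("missing chromosome sequence(s): ",
                 paste(missing_chr, collapse = ", ")))
  }
  offsets <- setdiff(seq.int(-window, window), 0L)
  tally <- map_dfr(names(seqs), function(chr) {
    dd <- d %>% filter(chrom == chr)
    if (nrow(dd) == 0) return(NULL)
    s <- seqs[[chr]]
    slen <- nchar(s)
    plus <- dd$strand == "+"
    five0 <- ifelse(plus, dd$start, dd$end - 1L)  # 0-based 5' position
    map_dfr(offsets, function(k) {
      step <- if (k > 0) k - 1L else k
      g0 <- ifelse(plus, five0 + step, five0 - step)
      ok <- g0 >= 0 & g0 < slen
      if (!any(ok)) return(NULL)
      b <- substring(s, g0[ok] + 1L, g0[ok] + 1L)
      b <- ifelse(plus[ok], b, chartr("ACGT", "TGCA", b))
      tibble(position = k, base = b)
    })
  })
  grid <- crossing(position = offsets, base = c("A", "C", "G", "T"))
  out <- tally %>%
    filter(base %in% c("A", "C", "G", "T")) %>%
    count(position, base, name = "k") %>%
    group_by(position) %>% mutate(n = sum(k)) %>% ungroup() %>%
    mutate(freq = k / n) %>%
    right_join(grid, by = c("position", "base")) %>%
    group_by(position) %>%
    mutate(n = ifelse(is.na(n), max(n, 0L, na.rm = TRUE), n)) %>%
    ungroup() %>%
    mutate(freq = ifelse(is.na(freq) & n > 0, 0, freq),
           n = as.integer(n)) %>%
    select(position, base, freq, n) %>%
    arrange(position, base)
  class(out) <- c("germ_fiveprime", class(out))
  out
}

normalize_genome_seq <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
  } else if (is.character(genome) && !is.null(names(genome))) {
    genome
  } else {
    abort("genome must be a FASTA path, DNAStringSet or named character vector")
  }
}

#' @export
autoplot.germ_fiveprime <- function(object, ...) {
  ggplot(object, aes(x = position, y = freq, colour = base)) +
    geom_line() +
    geom_vline(xintercept = 0.5, linetype = "dashed", colour = "grey50") +
    labs(x = "position relative to 5' end (nt)", y = "frequency") +
    theme_minimal()
}

#' Ping-pong 5'-5' overlap profile
#'
#' Counts opposite-strand read pairs on the same chromosome whose 5' ends
#' overlap by d = 1..`d_max` nt (for a plus-strand 5' end at p+ and a
#' minus-strand 5' end at p-, d = p- - p+ + 1). Each read pair counts
#' once. The signature statistic is the z-score of the 10-nt bin against
#' the other bins: z10 = (c10 - mean(c, d != 10)) / sd(c, d != 10).
#'
#' @param classified classified read tibble
#' @param d_max maximum overlap distance (default 30)
#' @param class read class to use (default `"repeat"`); `NULL` uses all
#' @param unique_only uniquely mapped reads only (default TRUE)
#' @return tibble (`overlap`, `count`, `cpm`) of class `germ_pingpong`
#'   with attribute `z10` (NA when undefined); `cpm` is counts per million
#'   pairs
#' @export
pingpong_profile <- function(classified, d_max = 30, class = "repeat",
                             unique_only = TRUE) {
  d <- classified
  if (!is.null(class)) d <- d %>% filter(class_label %in% class)
  if (unique_only) d <- d %>% filter(unique_flag)
  counts <- rep(0, d_max)
  for (chr in unique(d$chrom)) {
    dd <- d %>% filter(chrom == chr)
    p5 <- dd$start[dd$strand == "+"]          # plus-strand 5' ends
    m5 <- dd$end[dd$strand == "-"] - 1L       # minus-strand 5' ends
    if (length(p5) == 0 || length(m5) == 0) next
    tp <- table(p5)
    tm <- table(m5)
    pp <- as.integer(names(tp)); np <- as.numeric(tp)
    pm <- as.integer(names(tm)); nm <- as.numeric(tm)
    for (dist in seq_len(d_max)) {
      idx <- match(pp + dist - 1L, pm)
      hit <- !is.na(idx)
      if (any(hit)) counts[dist] <- counts[dist] + sum(np[hit] * nm[idx[hit]])
    }
  }
  total <- sum(counts)
  out <- tibble(
    overlap = seq_len(d_max),
    count = counts,
    cpm = if (total > 0) counts / total * 1e6 else rep(NA_real_, d_max)
  )
  others <- counts[-10]
  z10 <- if (d_max >= 10 && sd(others) > 0) {
    (counts[10] - mean(others)) / sd(others)
  } else NA_real_
  attr(out, "z10") <- z10
  class(out) <- c("germ_pingpong", class(out))
  out
}

#' z-score of the 10-nt ping-pong bin
#' @param x a `germ_pingpong` tibble
#' @return numeric z10 (NA when undefined)
#' @export
pingpong_z <- function(x) attr(x, "z10")

#' @export
glance.germ_pingpong <- function(x, ...) {
  tibble(z10 = attr(x, "z10"), total_pairs = sum(x$count),
         modal_overlap = x$overlap[which.max(x$count)])
}

#' @export
autoplot.germ_pingpong <- function(object, ...) {
  ggplot(object, aes(x = overlap, y = count,
                     fill = overlap == 10)) +
    geom_col(show.legend = FALSE) +
    scale_fill_manual(values = c(`TRUE` = "#d7301f", `FALSE` = "grey40")) +
    labs(x = "5'-5' overlap (nt)", y = "read pairs") +
    theme_minimal()
}
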