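# Shared helpers: interval <-> GRanges conversion (0-based half-open to
# 1-based closed), TSV IO with a '#'-prefixed header line, input validation.

#' Convert an interval tibble to a GRanges object
#'
#' Internal coordinates are 0-based half-open; GRanges is 1-based closed,
#' so start is shifted by +1.
#' @param x tibble with columns `chrom`, `start`, `end` and optionally `strand`
#' @return a [GenomicRanges::GRanges] object
#' @keywords internal
#' @noRd
as_granges0 <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[is.na(s) | !s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# point GRanges for CpG positions (the C on the plus strand)
cpg_granges <- function(calls) {
  GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos + 1L, width = 1L)
  )
}

# query/subject hits as a two-column tibble, ignoring strand
overlap_pairs <- function(query, subject) {
  # suppress the harmless seqlevel-mismatch warning for disjoint chrom sets
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject),
                                ignore.strand = TRUE))
  tibble(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
}

# logical: does each row of `query` overlap any interval of `subject`?
overlaps_any <- function(query, subject) {
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges0(query), as_granges0(subject),
                                 ignore.strand = TRUE)) > 0
}

# merge overlapping/adjacent intervals within the tibble (strand-blind)
reduce_intervals <- function(x) {
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  gr <- GenomicRanges::reduce(as_granges0(x), ignore.strand = TRUE)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Read a genome index (chrom.sizes) file
#'
#' @param path two-column TSV: chromosome name, length in bp
#' @return tibble with columns `chrom`, `length`
#' @export
read_genome <- function(path) {
  raw <- read_token_table(path, n_min = 2)
  genome <- tibble(
    chrom = raw[[1]],
    length = parse_count(raw[[2]], path, "length")
  )
  validate_genome(genome)
  genome
}

validate_genome <- function(genome) {
  if (!all(c("chrom", "length") %in% names(genome))) {
    abort("genome index needs columns `chrom` and `length`")
  }
  if (anyDuplicated(genome$chrom)) abort("duplicate chromosome names in genome index")
  if (any(genome$length <= 0)) abort("chromosome lengths must be > 0")
  invisible(genome)
}

# error if intervals name chromosomes absent from the genome index
check_chroms <- function(x, genome) {
  if (is.null(genome)) return(invisible(x))
  bad <- setdiff(unique(x$chrom), genome$chrom)
  if (length(bad) > 0) {
    abort(paste0("unknown chromosome(s): ", paste(bad, collapse = ", ")))
  }
  invisible(x)
}

# -- whitespace-tolerant token table reader with line-number errors ---------

read_token_table <- function(path, n_min, comment = "#") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), comment) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(structure(list(), lineno = integer(0), class = "data.frame"))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf < n_min)) {
    i <- which(nf < n_min)[1]
    abort(paste0("malformed line ", lineno[i], " in ", path,
                 ": expected at least ", n_min, " fields, found ", nf[i]))
  }
  ncol <- min(nf)
  out <- lapply(seq_len(ncol), function(j) vapply(toks, `[[`, character(1), j))
  out <- as.data.frame(out, col.names = paste0("V", seq_len(ncol)),
                       stringsAsFactors = FALSE)
  attr(out, "lineno") <- lineno
  out
}

parse_count <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    abort(paste0("non-numeric ", what, " in ", path,
                 " (first offending value: '", x[which(is.na(v))[1]], "')"))
  }
  if (any(v < 0)) abort(paste0("negative ", what, " in ", path))
  as.integer(round(v))
}

# -- TSV IO with '#'-prefixed header -----------------------------------------

#' Write a tibble as TSV with a '#'-prefixed header line
#' @param x data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv_hash <- function(x, path) {
  con <- file(path, open = "wb")  # binary: stable \n endings
  on.exit(close(con))
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  if (nrow(x) > 0) {
    cols <- lapply(x, function(col) {
      if (is.double(col)) {
        ifelse(is.na(col), "NA", formatC(col, digits = 10, format = "g"))
      } else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a TSV written by [write_tsv_hash()]
#' @param path input path
#' @return tibble; column types guessed by [utils::type.convert]
#' @export
read_tsv_hash <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) abort(paste0("missing '#' header line in ", path))
  header <- strsplit(sub("^#", "", first), "\t")[[1]]
  body <- utils::read.table(path, sep = "\t", skip = 1, header = FALSE,
                            col.names = header, stringsAsFactors = FALSE,
                            na.strings = "NA", quote = "", comment.char = "")
  as_tibble(body)
}

# reverse complement of DNA strings without Biostrings round trips
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
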