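# Per-CpG methylation call IO. Internal representation: one row per covered
# CpG, keyed by the 0-based position of the C on the plus strand, with raw
# methylated/unmethylated call counts. The percent column of call files is
# never trusted; fractions are always recomputed from counts.

#' Read per-CpG methylation calls
#'
#' Supports the Bismark coverage dialect (1-based inclusive start) and a
#' bedGraph-with-counts dialect (0-based half-open start). Both carry six
#' columns: chrom, start, end, percent methylation, methylated calls,
#' unmethylated calls. Coordinates are normalised to 0-based positions of
#' the plus-strand C; records are sorted by chromosome and position.
#'
#' @param path call file (TSV or whitespace-separated)
#' @param dialect `"bismark_cov"` (1-based) or `"bedgraph_counts"` (0-based)
#' @param sample_id label stored in the `sample` column
#' @param genome optional genome index tibble; positions are validated
#'   against chromosome lengths when supplied
#' @return tibble with columns `sample`, `chrom`, `pos`, `meth`, `unmeth`
#' @examples
#' tf <- tempfile()
#' writeLines("chr1\t101\t101\t50.0\t5\t5", tf)
#' read_cpg_calls(tf, "bismark_cov", "s1")
#' @export
read_cpg_calls <- function(path, dialect = c("bismark_cov", "bedgraph_counts"),
                           sample_id, genome = NULL) {
  dialect <- match.arg(dialect)
  raw <- read_token_table(path, n_min = 6)
  if (length(raw) == 0 || nrow(raw) == 0) {
    return(tibble(sample = character(), chrom = character(), pos = integer(),
                  meth = integer(), unmeth = integer()))
  }
  start <- parse_count(raw[[2]], path, "start coordinate")
  pos <- if (dialect == "bismark_cov") start - 1L else start
  calls <- tibble(
    sample = sample_id,
    chrom = raw[[1]],
    pos = pos,
    meth = parse_count(raw[[5]], path, "methylated count"),
    unmeth = parse_count(raw[[6]], path, "unmethylated count")
  )
  validate_cpg_calls(calls, genome, path)
  arrange(calls, chrom, pos)
}

validate_cpg_calls <- function(calls, genome = NULL, path = "<calls>") {
  if (any(calls$pos < 0)) abort(paste0("negative CpG position in ", path))
  dup <- calls |> count(sample, chrom, pos) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate CpG position in ", path, ": ",
                 dup$chrom[1], ":", dup$pos[1]))
  }
  if (!is.null(genome)) {
    check_chroms(calls, genome)
    j <- left_join(calls, genome, by = "chrom")
    if (any(j$pos >= j$length)) {
      bad <- j[which(j$pos >= j$length)[1], ]
      abort(paste0("CpG position beyond chromosome end: ",
                   bad$chrom, ":", bad$pos))
    }
  }
  invisible(calls)
}

#' Write per-CpG methylation calls
#'
#' @param calls tibble as returned by [read_cpg_calls()] (single sample)
#' @param path output path
#' @inheritParams read_cpg_calls
#' @return `path`, invisibly
#' @export
write_cpg_calls <- function(calls, path,
                            dialect = c("bismark_cov", "bedgraph_counts")) {
  dialect <- match.arg(dialect)
  calls <- arrange(calls, chrom, pos)
  total <- calls$meth + calls$unmeth
  pct <- ifelse(total > 0, 100 * calls$meth / total, 0)
  start <- if (dialect == "bismark_cov") calls$pos + 1L else calls$pos
  end <- if (dialect == "bismark_cov") calls$pos + 1L else calls$pos + 1L
  lines <- paste(calls$chrom, start, end,
                 formatC(pct, digits = 8, format = "g"),
                 calls$meth, calls$unmeth, sep = "\t")
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
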