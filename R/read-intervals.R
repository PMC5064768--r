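# Interval annotation IO: BED (>=3 columns), repeatmasker-style repeat TSV
# (chrom, start, end, strand, class, family) and imprinted-DMR TSV
# (chrom, start, end, name, parent). All coordinates 0-based half-open.

#' Read genomic feature intervals
#'
#' @param path input file
#' @param kind `"bed"` (>= 3 columns; name/score/strand optional),
#'   `"repeat_tsv"` (chrom, start, end, strand, class, family) or
#'   `"dmr_tsv"` (chrom, start, end, name, parent with parent in
#'   maternal/paternal; the parent is stored in `feature_class`)
#' @param genome optional genome index; chromosomes validated when supplied
#' @param feature_class class label assigned to BED intervals
#'   (default `"feature"`); ignored for the other kinds
#' @return tibble with columns `chrom`, `start`, `end`, `strand`, `name`,
#'   `feature_class` (plus `family` for repeats)
#' @export
read_intervals <- function(path, kind = c("bed", "repeat_tsv", "dmr_tsv"),
                           genome = NULL, feature_class = "feature") {
  kind <- match.arg(kind)
  n_min <- switch(kind, bed = 3L, repeat_tsv = 6L, dmr_tsv = 5L)
  raw <- read_token_table(path, n_min = n_min)
  if (length(raw) == 0 || nrow(raw) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), name = character(),
                  feature_class = character())
    if (kind == "repeat_tsv") out$family <- character()
    return(out)
  }
  start <- parse_count(raw[[2]], path, "start")
  end <- parse_count(raw[[3]], path, "end")
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    abort(paste0("start >= end at data line ", i, " of ", path, " (",
                 raw[[1]][i], ":", start[i], "-", end[i], ")"))
  }
  out <- switch(kind,
    bed = tibble(
      chrom = raw[[1]], start = start, end = end,
      strand = if (ncol(raw) >= 6) raw[[6]] else ".",
      name = if (ncol(raw) >= 4) raw[[4]] else paste0("iv", seq_along(start)),
      feature_class = feature_class
    ),
    repeat_tsv = {
      cls <- raw[[5]]
      if (any(!nzchar(cls))) abort(paste0("empty repeat class in ", path))
      tibble(chrom = raw[[1]], start = start, end = end, strand = raw[[4]],
             name = paste0("rep", seq_along(start)), feature_class = cls,
             family = raw[[6]])
    },
    dmr_tsv = {
      parent <- raw[[5]]
      bad <- setdiff(unique(parent), c("maternal", "paternal"))
      if (length(bad) > 0) {
        abort(paste0("DMR parent must be maternal/paternal, found: ",
                     paste(bad, collapse = ", ")))
      }
      tibble(chrom = raw[[1]], start = start, end = end, strand = ".",
             name = raw[[4]], feature_class = parent)
    }
  )
  check_chroms(out, genome)
  if (!is.null(genome)) {
    j <- left_join(out, genome, by = "chrom")
    if (any(j$end > j$length)) {
      bad <- j[which(j$end > j$length)[1], ]
      abort(paste0("interval beyond chromosome end: ", bad$chrom, ":",
                   bad$start, "-", bad$end))
    }
  }
  out
}

#' Write intervals as BED
#'
#' Emits BED6 when `strand` is present, BED4 otherwise.
#' @param x interval tibble (`chrom`, `start`, `end`, optionally `name`,
#'   `strand`)
#' @param path output path
#' @param score value for the BED score column (recycled); defaults to 0
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path, score = 0) {
  name <- if ("name" %in% names(x)) x$name else paste0("iv", seq_len(nrow(x)))
  con <- file(path, open = "wb"); on.exit(close(con))
  if ("strand" %in% names(x)) {
    s <- ifelse(x$strand %in% c("+", "-"), x$strand, ".")
    sc <- if ("score" %in% names(x)) x$score else rep(score, length.out = nrow(x))
    writeLines(paste(x$chrom, x$start, x$end, name, sc, s, sep = "\t"), con)
  } else {
    writeLines(paste(x$chrom, x$start, x$end, name, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a repeat instance table
#' @param x repeat tibble (`chrom`, `start`, `end`, `strand`,
#'   `feature_class`, `family`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_repeats <- function(x, path) {
  fam <- if ("family" %in% names(x)) x$family else x$feature_class
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(paste(x$chrom, x$start, x$end, x$strand, x$feature_class, fam,
                   sep = "\t"), con)
  invisible(path)
}

#' Write an imprinted-DMR table
#' @param x DMR tibble (`chrom`, `start`, `end`, `name`, `feature_class`
#'   holding the parent of origin)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dmrs <- function(x, path) {
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(paste(x$chrom, x$start, x$end, x$name, x$feature_class,
                   sep = "\t"), con)
  invisible(path)
}
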