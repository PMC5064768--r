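# Small RNA read sets: mapped reads as BED6 joined with their sequences
# from FASTA. The BED score column carries the unique-mapper flag
# (1 = unique, 0 = multi-mapper).

#' Read a mapped small RNA read set
#'
#' Joins a BED6 alignment file with a FASTA file of read sequences by read
#' id. Every BED name must have a FASTA entry and the alignment interval
#' length must equal the sequence length.
#'
#' @param fasta_path FASTA of read sequences (DNA alphabet)
#' @param bed6_path BED6 of alignments; score column = unique flag
#' @param genome optional genome index for chromosome validation
#' @return tibble with columns `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `sequence`, `unique_flag`, `class_label` (initially `NA`)
#' @export
read_smrna <- function(fasta_path, bed6_path, genome = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  raw <- read_token_table(bed6_path, n_min = 6)
  if (length(raw) == 0 || nrow(raw) == 0) {
    return(tibble(read_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  sequence = character(), unique_flag = logical(),
                  class_label = NA_character_))
  }
  reads <- tibble(
    read_id = raw[[4]],
    chrom = raw[[1]],
    start = parse_count(raw[[2]], bed6_path, "start"),
    end = parse_count(raw[[3]], bed6_path, "end"),
    unique_flag = parse_count(raw[[5]], bed6_path, "unique flag") == 1L,
    strand = raw[[6]]
  )
  if (any(!reads$strand %in% c("+", "-"))) {
    abort(paste0("read strand must be + or - in ", bed6_path))
  }
  missing_ids <- setdiff(reads$read_id, names(seqs))
  if (length(missing_ids) > 0) {
    abort(paste0("read id(s) in BED without FASTA entry: ",
                 paste(head(missing_ids, 3), collapse = ", ")))
  }
  reads$sequence <- unname(toupper(as.character(seqs[reads$read_id])))
  len <- nchar(reads$sequence)
  if (any(reads$end - reads$start != len)) {
    i <- which(reads$end - reads$start != len)[1]
    abort(paste0("alignment/sequence length mismatch for read ",
                 reads$read_id[i], " (interval ",
                 reads$end[i] - reads$start[i], " bp, sequence ",
                 len[i], " nt)"))
  }
  if (any(len < 15 | len > 50)) {
    abort("read lengths must be within 15-50 nt")
  }
  check_chroms(reads, genome)
  reads$class_label <- NA_character_
  reads %>% select(read_id, chrom, start, end, strand, sequence,
                   unique_flag, class_label)
}

#' Write a small RNA read set as FASTA + BED6
#' @param reads small RNA read tibble (see [read_smrna()])
#' @param fasta_path,bed6_path output paths
#' @return invisibly, a list of the two paths
#' @export
write_smrna <- function(reads, fasta_path, bed6_path) {
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_bed(reads %>% mutate(name = read_id, score = as.integer(unique_flag)),
            bed6_path)
  invisible(list(fasta = fasta_path, bed = bed6_path))
}
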