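#' Write a genome assembly to FASTA (60-column wrapped)
#' @param genome a `genome_assembly`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seq, filepath = path, width = 60L)
  invisible(path)
}

#' Read a genome assembly from FASTA
#' @param path FASTA file.
#' @param copy_number per-chromosome copy numbers (recycled; default 1).
#' @return A `genome_assembly`.
#' @export
read_genome_fasta <- function(path, copy_number = 1L) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_assembly(seqs, copy_number = copy_number)
}

#' Write intervals as BED6
#'
#' Coordinates are emitted as stored (0-based half-open, BED native).
#'
#' @param intervals data frame with `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand` columns are used when present.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0L,
    strand = if ("strand" %in% names(intervals)) intervals$strand else "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (3-6 columns)
#' @param path BED file.
#' @return Data frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(ncol(df))]
  df
}

#' Write a read set as a minimal alignment TSV
#'
#' Columns: `chrom`, `pos` (0-based 5' position), `strand`.
#'
#' @param reads a [read_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads$reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a minimal alignment TSV into a read set
#' @param path TSV with columns `chrom`, `pos`, `strand`.
#' @param ... metadata passed to [read_set()].
#' @return A [read_set()].
#' @export
read_reads_tsv <- function(path, ...) {
  read_set(utils::read.delim(path, stringsAsFactors = FALSE), ...)
}

#' Write a read set as minimal single-end SAM
#'
#' Header carries `@SQ` lines from the genome; records use FLAG 0/16,
#' MAPQ 255, CIGAR `<read_length>M`, and `*` for SEQ/QUAL. SAM POS is
#' 1-based and always the leftmost aligned base, so minus-strand reads are
#' written at `pos5prime - read_length + 2` (1-based).
#'
#' @param reads a [read_set()].
#' @param genome a `genome_assembly` (for the header).
#' @param path output file.
#' @param read_length alignment length in nt (default 50).
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, genome, path, read_length = 50L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ch in names(genome$seq)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, genome$lengths[[ch]]), con)
  }
  rd <- reads$reads
  plus <- rd$strand == "+"
  pos1 <- ifelse(plus, rd$pos + 1L, rd$pos - read_length + 2L)
  pos1 <- pmax(pos1, 1L)
  rec <- sprintf("%s.%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                 reads$sample_id, seq_len(nrow(rd)),
                 ifelse(plus, 0L, 16L), rd$chrom, pos1, read_length)
  writeLines(rec, con)
  invisible(path)
}

#' Read a minimal SAM file into a read set
#'
#' Only FLAG 0/16 single-end records are consumed; the 5' position is
#' recovered from POS and the CIGAR-implied alignment length.
#'
#' @param path SAM file.
#' @param ... metadata passed to [read_set()].
#' @return A [read_set()].
#' @export
read_reads_sam <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  chrom <- vapply(f, `[`, character(1), 3L)
  pos1 <- vapply(f, function(x) as.integer(x[4]), integer(1))
  cig <- vapply(f, `[`, character(1), 6L)
  alen <- as.integer(sub("M$", "", cig))
  minus <- bitwAnd(flag, 16L) != 0L
  pos0 <- ifelse(minus, pos1 - 1L + alen - 1L, pos1 - 1L)
  read_set(data.frame(chrom = chrom, pos = pos0,
                      strand = ifelse(minus, "-", "+"),
                      stringsAsFactors = FALSE), ...)
}

#' Export simulation ground truth as JSON
#' @param truth a [binding_truth()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a window set or enrichment track as TSV
#' @param x data frame (windows, enrichment track, repeat table, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export an enrichment track as bedGraph
#' @param track an `enrichment_track` (or window data frame with a value
#'   column).
#' @param path output file.
#' @param value column to export (default `"e"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "e") {
  df <- as.data.frame(track)
  keep <- !is.na(df[[value]])
  out <- data.frame(df$chrom[keep], df$start[keep], df$end[keep],
                    df[[value]][keep])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
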