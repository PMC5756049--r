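# shared fixture builders and independent brute-force oracles

tiny_genome <- function(...) {
  seqs <- Biostrings::DNAStringSet(c(...))
  genome_assembly(seqs)
}

random_seq <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# string-census mappability oracle: counts every k-mer occurrence on both
# strands and calls a start mappable iff its k-mer occurs exactly once
oracle_mappability <- function(genome, k) {
  allk <- character(0)
  per_chrom <- list()
  for (ch in names(genome$seq)) {
    s <- as.character(genome$seq[[ch]])
    L <- nchar(s)
    n <- L - k + 1L
    fw <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    rv <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fw)))
    per_chrom[[ch]] <- fw
    allk <- c(allk, fw, rv)
  }
  tab <- table(allk)
  lapply(per_chrom, function(fw) {
    unname(as.integer(tab[fw]) == 1L & !grepl("N", fw, fixed = TRUE))
  })
}

# per-read assignment loop oracle for shifted window counting
oracle_count_reads <- function(reads, windows, shift) {
  counts <- integer(nrow(windows))
  rd <- reads$reads
  for (i in seq_len(nrow(rd))) {
    dest <- if (rd$strand[i] == "+") rd$pos[i] + shift else rd$pos[i] - shift
    hit <- which(windows$chrom == rd$chrom[i] & windows$start <= dest &
                   dest < windows$end)
    if (length(hit) == 1L) counts[hit] <- counts[hit] + 1L
  }
  counts
}

# dictionary-loop k-mer counting oracle (plus strand, N-skipping)
oracle_kmer_counts <- function(seq_chr, k) {
  kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[
    , k:1, drop = FALSE], 1, paste, collapse = ""))
  out <- stats::setNames(integer(length(kmers)), kmers)
  n <- nchar(seq_chr) - k + 1L
  for (i in seq_len(n)) {
    km <- substr(seq_chr, i, i + k - 1L)
    if (!grepl("N", km, fixed = TRUE)) out[km] <- out[km] + 1L
  }
  out
}

# character-loop W-run oracle
oracle_stretch_counts <- function(seq_chr, L) {
  ch <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  r <- rle(ch %in% c("A", "T"))
  runs <- r$lengths[r$values]
  tabulate(runs[runs <= L], nbins = L)
}

# three-pass repeat filter oracle
oracle_filter_repeats <- function(repeats, mapfrac, min_length = 300,
                                  min_mappable = 0.8, min_instances = 10) {
  keep <- (repeats$end - repeats$start) >= min_length & mapfrac >= min_mappable
  out <- repeats[keep, , drop = FALSE]
  tab <- table(out$name)
  out[out$name %in% names(tab)[tab >= min_instances], , drop = FALSE]
}

# genome + panel simulation used by several analysis tests
panel_fixture <- function() {
  spec <- genome_spec(n_chromosomes = 2L, chrom_length = 3e5,
                      isochore_block_length = 1e4, n_cpg_islands = 20L,
                      cpg_island_length = 1000L, n_TA_repeats = 6L,
                      TA_repeat_length = 400L, n_promoters = 60L, seed = 3L)
  generate_genome(spec)
}

# TRUE for each window overlapping any feature interval
overlaps_windows <- function(windows, features) {
  if (is.null(features) || !nrow(features)) return(rep(FALSE, nrow(windows)))
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  fgr <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start + 1L,
                                                 features$end))
  GenomicRanges::countOverlaps(wgr, fgr) > 0L
}
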