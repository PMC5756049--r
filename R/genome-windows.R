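#' Tile a genome into fixed-size windows
#'
#' Emits `floor(length / w)` windows per chromosome starting at 0; a
#' trailing partial window is dropped so that every window has identical
#' width and window counts stay comparable. Coordinates are 0-based
#' half-open.
#'
#' @param genome a `genome_assembly`.
#' @param w window size in nucleotides.
#' @return A data frame (`chrom`, `start`, `end`) in chromosome-then-
#'   coordinate order.
#' @export
tile_genome <- function(genome, w) {
  stopifnot(w >= 1)
  w <- as.integer(w)
  out <- lapply(names(genome$seq), function(ch) {
    L <- genome$lengths[[ch]]
    n <- L %/% w
    if (n == 0L) {
      warning("chromosome ", ch, " shorter than window size ", w,
              "; no windows emitted")
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    }
    data.frame(chrom = ch, start = (seq_len(n) - 1L) * w,
               end = seq_len(n) * w, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genome-wide k-mer mappability
#'
#' A k-mer start position is mappable when its k-mer contains no N, is not
#' its own reverse complement, and occurs exactly once in the genome
#' considering both strands. This is an aligner-free stand-in for unique
#' alignability: exact two-strand uniqueness of the k-mer.
#'
#' @param genome a `genome_assembly`.
#' @param k k-mer length (default 50).
#' @return Named list of per-chromosome logical vectors, one element per
#'   valid 0-based start position `0 .. length - k`.
#' @export
genome_mappability <- function(genome, k = 50L) {
  k <- as.integer(k)
  if (k > 52L) stop("k-mer length above 52 is not supported")
  k1 <- (k + 1L) %/% 2L
  k2 <- k - k1
  chroms <- names(genome$seq)
  # every k-mer is encoded exactly as a pair of base-4 integers (two halves
  # of <= 26 bases each, so both fit a double without rounding); duplicate
  # detection is a radix sort over the canonical (strand-min) code pairs
  f1 <- f2 <- r1 <- r2 <- vector("list", length(chroms))
  nstarts <- integer(length(chroms))
  for (ci in seq_along(chroms)) {
    s <- as.character(genome$seq[[ci]])
    L <- nchar(s)
    if (L < k) {
      f1[[ci]] <- f2[[ci]] <- r1[[ci]] <- r2[[ci]] <- numeric(0)
      next
    }
    n <- L - k + 1L
    nstarts[ci] <- n
    b <- kmer_base_codes(s)
    rb <- 3 - b[L:1]                          # reverse complement codes
    i <- seq_len(n)
    f1[[ci]] <- rolling_code(b, k1)[i]
    f2[[ci]] <- if (k2 > 0L) rolling_code(b, k2)[i + k1] else numeric(n)
    # revcomp of the k-mer starting at i begins at position L-i-k+2 of rb
    j <- L - i - k + 2L
    r1[[ci]] <- rolling_code(rb, k1)[j]
    r2[[ci]] <- if (k2 > 0L) rolling_code(rb, k2)[j + k1] else numeric(n)
  }
  f1 <- unlist(f1); f2 <- unlist(f2); r1 <- unlist(r1); r2 <- unlist(r2)
  has_n <- is.na(f1) | is.na(f2)
  f1[is.na(f1)] <- -1; f2[is.na(f2)] <- -1
  r1[is.na(r1)] <- -1; r2[is.na(r2)] <- -1
  pal <- f1 == r1 & f2 == r2
  use_f <- f1 < r1 | (f1 == r1 & f2 <= r2)
  c1 <- r1; c1[use_f] <- f1[use_f]
  c2 <- r2; c2[use_f] <- f2[use_f]
  o <- order(c1, c2, method = "radix")
  s1 <- c1[o]; s2 <- c2[o]
  m <- length(s1)
  eq_next <- c(s1[-m] == s1[-1] & s2[-m] == s2[-1], FALSE)
  dup_sorted <- eq_next | c(FALSE, eq_next[-m])
  dup <- logical(m)
  dup[o] <- dup_sorted
  ok <- !dup & !pal & !has_n
  split_at <- rep.int(seq_along(chroms), nstarts)
  out <- split(ok, factor(split_at, levels = seq_along(chroms)))
  names(out) <- chroms
  out
}

# map a DNA string to per-base integer codes A=0, C=1, G=2, T=3; other
# letters (N etc.) become NA and poison every k-mer containing them
kmer_base_codes <- function(s) {
  lut <- rep(NA_real_, 127L)
  lut[utf8ToInt("A")] <- 0
  lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2
  lut[utf8ToInt("T")] <- 3
  lut[utf8ToInt(s)]
}

# base-4 code of every w-mer of the code vector b (exact for w <= 26)
rolling_code <- function(b, w) {
  n <- length(b) - w + 1L
  acc <- numeric(n)
  for (j in seq_len(w)) {
    acc <- acc + b[seq.int(j, j + n - 1L)] * 4^(w - j)
  }
  acc
}

#' Per-window mappable fraction
#'
#' For each window, the fraction of k-mer start positions `p` in
#' `[start, end - k]` whose k-mer is uniquely mappable (see
#' [genome_mappability()]).
#'
#' @param genome a `genome_assembly`.
#' @param windows window data frame from [tile_genome()] (or any interval
#'   table with `chrom`, `start`, `end`).
#' @param k k-mer length; must not exceed the window width.
#' @param mappability optional precomputed [genome_mappability()] result.
#' @return `windows` with a `mappable_fraction` column added.
#' @export
mappable_fraction <- function(genome, windows, k = 50L,
                              mappability = NULL) {
  k <- as.integer(k)
  if (nrow(windows) && any(windows$end - windows$start < k)) {
    stop("k must not exceed the window width")
  }
  if (is.null(mappability)) mappability <- genome_mappability(genome, k)
  frac <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    rows <- which(windows$chrom == ch)
    m <- mappability[[ch]]
    cs <- cumsum(c(0, m))
    lo <- windows$start[rows] + 1L            # first valid start, 1-based
    hi <- windows$end[rows] - k + 1L          # last valid start, 1-based
    frac[rows] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  windows$mappable_fraction <- frac
  windows
}

#' AT content of DNA sequences
#'
#' `(#A + #T) / (#A + #C + #G + #T)`; N bases are excluded from both
#' numerator and denominator. All-N (or empty-denominator) input yields NA.
#'
#' @param x a character vector, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet].
#' @return numeric vector of AT fractions.
#' @export
at_content <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (methods::is(x, "DNAString")) x <- Biostrings::DNAStringSet(list(x))
  if (any(Biostrings::width(x) == 0)) stop("sequences must be non-empty")
  cnt <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(cnt)
  out <- (cnt[, "A"] + cnt[, "T"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

#' Per-window AT content
#'
#' @param genome a `genome_assembly`.
#' @param windows interval data frame.
#' @return `windows` with an `at_content` column added.
#' @export
window_at_content <- function(genome, windows) {
  windows$at_content <- at_content(window_sequences(genome, windows))
  windows
}

#' Per-window GC content (N-excluded complement of AT content)
#' @inheritParams window_at_content
#' @return `windows` with a `gc_content` column added.
#' @export
window_gc_content <- function(genome, windows) {
  windows$gc_content <- 1 - at_content(window_sequences(genome, windows))
  windows
}

#' Extract window sequences as a DNAStringSet
#' @inheritParams window_at_content
#' @return A [Biostrings::DNAStringSet], one element per window.
#' @export
window_sequences <- function(genome, windows) {
  out <- vector("list", nrow(windows))
  for (ch in unique(windows$chrom)) {
    rows <- which(windows$chrom == ch)
    v <- Biostrings::Views(genome$seq[[ch]],
                           start = windows$start[rows] + 1L,
                           end = windows$end[rows])
    out[rows] <- as.list(Biostrings::DNAStringSet(v))
  }
  ss <- Biostrings::DNAStringSet(out)
  names(ss) <- window_ids(windows)
  ss
}

#' Annotate tiling windows with mappability and AT content
#'
#' Convenience wrapper producing the standard window substrate used by the
#' enrichment and modelling stages.
#'
#' @inheritParams mappable_fraction
#' @return `windows` with `mappable_fraction` and `at_content` columns.
#' @export
annotate_windows <- function(genome, windows, k = 50L, mappability = NULL) {
  windows <- mappable_fraction(genome, windows, k = k,
                               mappability = mappability)
  window_at_content(genome, windows)
}

#' Select one promoter per gene by PolII enrichment
#'
#' Candidate promoters are TSS +/- 1000 nt. Candidates below the
#' mappability threshold are dropped; per gene the candidate with the
#' highest PolII ChIP enrichment over input (reads shifted by a fixed 60 nt,
#' assuming 120 nt fragments) is kept, ties broken by transcript id; any
#' retained promoter overlapping another retained promoter is then removed
#' (both of an overlapping pair are removed).
#'
#' @param tss_table data frame with `gene_id`, `transcript_id`, `chrom`,
#'   `tss` (0-based), `strand`.
#' @param polii_ip,polii_input PolII IP and input [read_set()]s.
#' @param genome a `genome_assembly`.
#' @param mappability optional precomputed [genome_mappability()].
#' @param shift read shift in nt (default 60).
#' @param min_mappable mappable-fraction threshold (default 0.8).
#' @param flank promoter half-width in nt (default 1000).
#' @return Data frame of retained promoters (`gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `tss`, `strand`, `mappable_fraction`,
#'   `polii_enrichment`), of class `promoter_set`.
#' @export
define_promoters <- function(tss_table, polii_ip, polii_input, genome,
                             mappability = NULL, shift = 60L,
                             min_mappable = 0.8, flank = 1000L) {
  stopifnot_cols(tss_table, c("gene_id", "transcript_id", "chrom", "tss",
                              "strand"), "tss_table")
  if (any(is.na(tss_table$strand)) ||
      !all(tss_table$strand %in% c("+", "-"))) {
    stop("tss_table strand must be '+' or '-' with no missing values")
  }
  cand <- data.frame(
    gene_id = tss_table$gene_id,
    transcript_id = tss_table$transcript_id,
    chrom = tss_table$chrom,
    start = pmax(tss_table$tss - flank, 0L),
    end = tss_table$tss + flank + 1L,
    tss = tss_table$tss,
    strand = tss_table$strand,
    stringsAsFactors = FALSE
  )
  cand$end <- pmin(cand$end, unname(genome$lengths[cand$chrom]))
  cand <- mappable_fraction(genome, cand, mappability = mappability)
  cand <- cand[cand$mappable_fraction >= min_mappable, , drop = FALSE]
  if (!nrow(cand)) {
    return(structure(cand, class = c("promoter_set", "data.frame")))
  }
  n_ip <- count_reads(polii_ip, cand, shift = shift)
  n_in <- count_reads(polii_input, cand, shift = shift)
  cand$polii_enrichment <- log2_enrichment(n_ip, n_in, n_reads(polii_ip),
                                           n_reads(polii_input))
  # per-gene maximum, ties by transcript id
  ord <- order(cand$gene_id, -cand$polii_enrichment, cand$transcript_id)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand$gene_id), , drop = FALSE]
  # remove both members of any overlapping pair among retained candidates
  gr <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start + 1L, cand$end))
  ov <- GenomicRanges::countOverlaps(gr, gr)
  cand <- cand[ov == 1L, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  structure(cand, class = c("promoter_set", "data.frame"))
}
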