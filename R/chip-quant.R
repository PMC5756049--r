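#' Estimate the sonication fragment length from strand-split profiles
#'
#' Builds two promoter-anchored 5'-coverage profiles at 1-nt resolution, one
#' from reads on the same strand as the promoter and one from reads on the
#' opposite strand, and returns the shift of the same-strand profile against
#' the opposite-strand profile that minimizes their root-mean-square
#' deviation. Because plus-strand reads start at fragment 5' ends and
#' minus-strand reads at fragment 3' ends, that displacement estimates the
#' fragment length F; the read shift used for window counting is
#' `floor(F / 2)`.
#'
#' @param reads a [read_set()].
#' @param promoters a data frame with `chrom`, `tss` (0-based) and `strand`
#'   (e.g. from [define_promoters()]).
#' @param search_max largest shift searched, in nt (default 500; step 1).
#' @param halfwidth profile half-width around the TSS in nt.
#' @param smooth odd running-mean width applied to both profiles before the
#'   RMSD scan (1 = none).
#' @return An object of class `fragment_length_estimate` with elements
#'   `fragment_length`, `shift` (= `floor(fragment_length / 2)`) and
#'   `rmsd_curve` (data frame `shift`, `rmsd`).
#' @export
estimate_fragment_length <- function(reads, promoters, search_max = 500L,
                                     halfwidth = 1000L, smooth = 51L) {
  stopifnot_cols(promoters, c("chrom", "tss", "strand"), "promoters")
  stopifnot(smooth %% 2L == 1L)
  hw <- as.integer(halfwidth)
  nbin <- 2L * hw + 1L
  same <- numeric(nbin)
  opp <- numeric(nbin)
  n_prom_with_reads <- 0L
  rd <- reads$reads
  for (i in seq_len(nrow(promoters))) {
    sel <- rd$chrom == promoters$chrom[i]
    if (!any(sel)) next
    pos <- rd$pos[sel]
    str <- rd$strand[sel]
    off <- if (promoters$strand[i] == "+") pos - promoters$tss[i] else
      promoters$tss[i] - pos
    keep <- off >= -hw & off <= hw
    if (!any(keep)) next
    n_prom_with_reads <- n_prom_with_reads + 1L
    is_same <- str[keep] == promoters$strand[i]
    idx <- off[keep] + hw + 1L
    if (any(is_same)) {
      t1 <- tabulate(idx[is_same], nbins = nbin)
      same <- same + t1
    }
    if (any(!is_same)) {
      t2 <- tabulate(idx[!is_same], nbins = nbin)
      opp <- opp + t2
    }
  }
  if (sum(same) == 0 || sum(opp) == 0) {
    stop("no reads over promoters on one or both strands")
  }
  if (n_prom_with_reads < 50L) {
    warning("only ", n_prom_with_reads,
            " promoters carry reads; fragment-length estimate may be noisy")
  }
  same <- running_mean(same, smooth)
  opp <- running_mean(opp, smooth)
  shifts <- 0:as.integer(search_max)
  # profiles are standardized over the overlap so that the scan aligns
  # profile shape; raw intensities differ between the strands and between
  # the compared segments as the overlap shrinks
  rmsd <- vapply(shifts, function(s) {
    a <- same[seq_len(nbin - s)]
    b <- opp[(1L + s):nbin]
    if (stats::sd(a) > 0) a <- (a - mean(a)) / stats::sd(a)
    if (stats::sd(b) > 0) b <- (b - mean(b)) / stats::sd(b)
    sqrt(mean((a - b)^2))
  }, numeric(1))
  if (diff(range(rmsd)) < 1e-12) {
    stop("degenerate input: strand profiles are flat, no shift is preferred")
  }
  best <- shifts[which.min(rmsd)]
  if (best == 0L) {
    warning("strand profiles already aligned at shift 0; degenerate input")
  }
  structure(list(
    fragment_length = best,
    shift = best %/% 2L,
    rmsd_curve = data.frame(shift = shifts, rmsd = rmsd),
    n_promoters = n_prom_with_reads
  ), class = "fragment_length_estimate")
}

#' @export
print.fragment_length_estimate <- function(x, ...) {
  cat(sprintf(paste0("fragment_length_estimate: F = %d nt ",
                     "(read shift %d nt, %d informative promoters)\n"),
              x$fragment_length, x$shift, x$n_promoters))
  invisible(x)
}

#' Count shifted reads in windows
#'
#' Each read is assigned to the window containing its shifted position:
#' `pos + s` for plus-strand reads, `pos - s` for minus-strand reads. Reads
#' whose shifted position falls outside all windows (including off the
#' chromosome ends) are dropped. Windows must be non-overlapping and sorted
#' within each chromosome.
#'
#' @param reads a [read_set()].
#' @param windows interval data frame (`chrom`, `start`, `end`).
#' @param shift read shift s in nt (half the estimated fragment length).
#' @return Integer vector of counts, one per window row.
#' @export
count_reads <- function(reads, windows, shift = 0L) {
  stopifnot(shift >= 0)
  shift <- as.integer(shift)
  rd <- reads$reads
  dest <- ifelse(rd$strand == "+", rd$pos + shift, rd$pos - shift)
  counts <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    rows <- which(windows$chrom == ch)
    rows <- rows[order(windows$start[rows])]
    d <- dest[rd$chrom == ch]
    if (!length(d)) next
    idx <- findInterval(d, windows$start[rows])
    ok <- idx >= 1L & d < windows$end[rows][pmax(idx, 1L)]
    tab <- tabulate(idx[ok], nbins = length(rows))
    counts[rows] <- counts[rows] + tab
  }
  counts
}

#' Log2 enrichment over input with library-size normalization
#'
#' Counts are normalized to the smaller library:
#' `ns_IP = min(N_IP, N_input) * (n_IP / N_IP)` and
#' `ns_input = min(N_IP, N_input) * (n_input / N_input)`; the enrichment is
#' `log2(ns_IP + c) - log2(ns_input + c)`. The pseudo-count `c` damps noise
#' at low read counts.
#'
#' @param n_ip,n_input raw per-region counts (vectors).
#' @param N_ip,N_input total aligned reads of the IP and input libraries.
#' @param pseudocount pseudo-count c (default 8).
#' @return Numeric vector of log2 enrichments.
#' @export
log2_enrichment <- function(n_ip, n_input, N_ip, N_input, pseudocount = 8) {
  if (any(n_ip < 0, na.rm = TRUE) || any(n_input < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  stopifnot(N_ip > 0, N_input > 0)
  m <- min(N_ip, N_input)
  ns_ip <- m * (n_ip / N_ip)
  ns_input <- m * (n_input / N_input)
  log2(ns_ip + pseudocount) - log2(ns_input + pseudocount)
}

#' Window-level enrichment track for one IP/input pair
#'
#' Computes shifted counts and [log2_enrichment()] on an annotated window
#' set. Windows below the mappability threshold get NA: enrichment is only
#' defined where at least 80% of overlapping 50-mers are unique.
#'
#' @param ip,input [read_set()]s for the IP and its paired input.
#' @param windows annotated window data frame (needs `mappable_fraction`).
#' @param shift read shift in nt.
#' @param pseudocount pseudo-count (default 8).
#' @param min_mappable mappability threshold (default 0.8).
#' @return An object of class `enrichment_track`: the window data frame plus
#'   columns `n_ip`, `n_input`, `e`, with pairing metadata in attributes.
#' @export
enrichment_track <- function(ip, input, windows, shift = 0L,
                             pseudocount = 8, min_mappable = 0.8) {
  stopifnot_cols(windows, c("chrom", "start", "end", "mappable_fraction"),
                 "windows")
  out <- windows
  out$n_ip <- count_reads(ip, windows, shift)
  out$n_input <- count_reads(input, windows, shift)
  out$e <- log2_enrichment(out$n_ip, out$n_input, n_reads(ip),
                           n_reads(input), pseudocount)
  out$e[out$mappable_fraction < min_mappable] <- NA_real_
  structure(out,
            class = c("enrichment_track", "data.frame"),
            sample_id = ip$sample_id, input_id = input$sample_id,
            genotype = ip$genotype, replicate = ip$replicate,
            shift = shift, pseudocount = pseudocount)
}

#' Normalize a wild-type track against its paired DBD-mutant track
#'
#' `delta_e = e_WT - e_mutant` windowwise. Wild-type and mutant samples are
#' paired by replicate letter ("a" with "a", "b" with "b"); add-back samples
#' reuse the mutant tracks of the parental background, which reduces to the
#' same windowwise subtraction.
#'
#' @param e_wt,e_mutant `enrichment_track`s on the same window set.
#' @param check_replicate require matching replicate letters (default TRUE).
#' @return An `enrichment_track` whose `e` column holds `delta_e`.
#' @export
mutant_normalize <- function(e_wt, e_mutant, check_replicate = TRUE) {
  if (!identical(e_wt[, c("chrom", "start", "end")],
                 e_mutant[, c("chrom", "start", "end")])) {
    stop("wild-type and mutant tracks are on different window sets")
  }
  if (check_replicate &&
      !identical(attr(e_wt, "replicate"), attr(e_mutant, "replicate"))) {
    stop("no mutant track with matching replicate letter '",
         attr(e_wt, "replicate"), "'")
  }
  out <- e_wt
  out$e <- e_wt$e - e_mutant$e
  out$n_ip <- out$n_input <- NULL
  attr(out, "mutant_id") <- attr(e_mutant, "sample_id")
  out
}

#' Average enrichment profile around genomic anchors
#'
#' For every offset relative to the anchor positions, reads (after shifting)
#' falling in a `smooth`-wide window centered at that offset are summed over
#' all anchors, separately for IP and control; replicate read sets are
#' scaled to the mean total aligned reads across all supplied samples before
#' pooling; the per-offset enrichment is then
#' `log2(ip + c) - log2(control + c)` on the pooled, scaled counts.
#'
#' @param ip_reads,control_reads a [read_set()] or list of read sets to pool.
#' @param anchors data frame with `chrom` and `pos` (0-based anchor points,
#'   e.g. midpoints of regions).
#' @param halfwidth profile half-width in nt.
#' @param smooth odd smoothing window in nt (51 by default; 201 is used for
#'   sparse anchor classes such as `(TA)n` repeats).
#' @param shift read shift in nt.
#' @param pseudocount pseudo-count (default 8).
#' @return Object of class `average_profile`: data frame (`offset`,
#'   `enrichment`) with the anchor count and smoothing width as attributes.
#' @export
average_profile <- function(ip_reads, control_reads, anchors,
                            halfwidth = 2000L, smooth = 51L, shift = 0L,
                            pseudocount = 8) {
  if (inherits(ip_reads, "read_set")) ip_reads <- list(ip_reads)
  if (inherits(control_reads, "read_set")) control_reads <- list(control_reads)
  stopifnot(length(anchors$chrom) > 0, smooth %% 2L == 1L)
  all_sets <- c(ip_reads, control_reads)
  mean_n <- mean(vapply(all_sets, n_reads, numeric(1)))

  known <- unique(unlist(lapply(all_sets, function(r) unique(r$reads$chrom))))
  bad <- !(anchors$chrom %in% known)
  if (any(bad)) {
    warning(sum(bad), " anchor(s) on chromosomes absent from the reads; skipped")
    anchors <- anchors[!bad, , drop = FALSE]
  }
  if (!nrow(anchors)) stop("no usable anchors")

  h <- (as.integer(smooth) - 1L) %/% 2L
  ext <- as.integer(halfwidth) + h
  nbin <- 2L * ext + 1L
  raw_counts <- function(sets) {
    acc <- numeric(nbin)
    for (rs in sets) {
      rd <- rs$reads
      dest <- ifelse(rd$strand == "+", rd$pos + shift, rd$pos - shift)
      f <- mean_n / n_reads(rs)
      for (i in seq_len(nrow(anchors))) {
        d <- dest[rd$chrom == anchors$chrom[i]] - anchors$pos[i]
        d <- d[d >= -ext & d <= ext]
        if (length(d)) acc <- acc + f * tabulate(d + ext + 1L, nbins = nbin)
      }
    }
    acc
  }
  ip_prof <- running_sum(raw_counts(ip_reads), smooth)
  ct_prof <- running_sum(raw_counts(control_reads), smooth)
  central <- (h + 1L):(nbin - h)
  enr <- log2(ip_prof[central] + pseudocount) -
    log2(ct_prof[central] + pseudocount)
  structure(data.frame(offset = -halfwidth:halfwidth, enrichment = enr),
            class = c("average_profile", "data.frame"),
            n_anchors = nrow(anchors), smooth = smooth, shift = shift)
}
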