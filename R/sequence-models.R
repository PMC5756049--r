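#' k-mer frequency features per window
#'
#' Sliding-window k-mer counts on the plus strand only (so that strand
#' symmetry of the fitted coefficients is an internal-consistency check, not
#' an assumption); positions whose k-mer contains N are skipped. Frequencies
#' are counts divided by the number of valid positions in the window.
#'
#' @param genome a `genome_assembly`.
#' @param windows window data frame.
#' @param k k-mer length, 1 to 4.
#' @param frequencies return frequencies (default) or raw counts.
#' @return Numeric matrix (windows x 4^k), rownames are window ids; the
#'   number of valid positions per window is in attribute `valid`.
#' @export
kmer_features <- function(genome, windows, k, frequencies = TRUE) {
  stopifnot(k %in% 1:4)
  seqs <- window_sequences(genome, windows)
  cnt <- Biostrings::oligonucleotideFrequency(seqs, width = k, step = 1L)
  valid <- rowSums(cnt)
  out <- if (frequencies) cnt / valid else cnt
  rownames(out) <- window_ids(windows)
  attr(out, "valid") <- valid
  attr(out, "kind") <- sprintf("%d-mer %s", k,
                               if (frequencies) "frequencies" else "counts")
  out
}

#' AT-stretch (W-run) features per window
#'
#' Counts maximal runs of consecutive W bases (W = A or T) by exact length
#' 1..L, where L is the largest run length observed across the window set
#' (unless fixed by the caller).
#'
#' @param genome a `genome_assembly`.
#' @param windows window data frame.
#' @param L maximum stretch length; `NULL` (default) uses the maximum
#'   observed run length.
#' @return Integer matrix (windows x L) with columns `W1..WL`.
#' @export
stretch_features <- function(genome, windows, L = NULL) {
  stopifnot(nrow(windows) > 0)
  seqs <- as.character(window_sequences(genome, windows))
  runs <- lapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
    r <- rle(ch %in% c("A", "T"))
    r$lengths[r$values]
  })
  maxlen <- max(c(0L, unlist(runs, use.names = FALSE)))
  if (is.null(L)) L <- maxlen
  if (L < 1L) stop("no W stretches found and L not supplied")
  out <- t(vapply(runs, function(x) tabulate(pmin(x, L), nbins = L),
                  integer(L)))
  colnames(out) <- paste0("W", seq_len(L))
  rownames(out) <- window_ids(windows)
  attr(out, "kind") <- "W-stretch counts"
  out
}

#' Synthetic pentamer DNA-shape table
#'
#' A deterministic stand-in lookup of the four local shape features (minor
#' groove width, propeller twist, helix twist, roll) for all 1024 ungapped
#' ACGT pentamers, built from pentamer base composition: W-rich pentamers
#' get narrower minor grooves and more negative propeller twist, loosely
#' emulating the qualitative behaviour of simulation-derived shape tables.
#' It is synthetic: values are for testing the feature machinery, not for
#' biophysical interpretation. Real tables can be supplied as a data frame
#' with columns `pentamer`, `MGW`, `ProT`, `HelT1`, `HelT2`, `Roll1`,
#' `Roll2` (the two inter-step HelT/Roll values are averaged on load).
#'
#' @return Data frame with columns `pentamer`, `MGW`, `ProT`, `HelT`,
#'   `Roll`.
#' @export
synthetic_shape_table <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = b, p4 = b, p3 = b, p2 = b, p1 = b,
                   stringsAsFactors = FALSE)
  penta <- paste0(g$p1, g$p2, g$p3, g$p4, g$p5)
  m <- matrix(unlist(g[, 5:1]), ncol = 5)
  w <- matrix(m %in% c("A", "T"), ncol = 5)
  # position weights emphasize the pentamer center
  pw <- c(0.5, 1, 2, 1, 0.5)
  wscore <- as.numeric(w %*% pw) / sum(pw)
  step <- function(x, y) as.numeric(paste0(x, y) %in% c("AA", "TT", "AT", "TA"))
  stack_w <- (step(m[, 2], m[, 3]) + step(m[, 3], m[, 4])) / 2
  data.frame(
    pentamer = penta,
    MGW = 5.8 - 1.5 * wscore,                # Angstrom; narrower when AT-rich
    ProT = -2 - 10 * wscore,                 # degrees
    HelT = 34 + 2 * stack_w,                 # degrees
    Roll = 2 - 4 * stack_w,                  # degrees
    stringsAsFactors = FALSE
  )
}

#' Read a pentamer shape table from TSV
#'
#' @param path TSV with columns `pentamer`, `MGW`, `ProT`, `HelT1`, `HelT2`,
#'   `Roll1`, `Roll2` (or already-averaged `HelT`, `Roll`).
#' @return Data frame with `pentamer`, `MGW`, `ProT`, `HelT`, `Roll`.
#' @export
read_shape_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("HelT1", "HelT2") %in% names(tab))) {
    tab$HelT <- (tab$HelT1 + tab$HelT2) / 2
  }
  if (all(c("Roll1", "Roll2") %in% names(tab))) {
    tab$Roll <- (tab$Roll1 + tab$Roll2) / 2
  }
  stopifnot_cols(tab, c("pentamer", "MGW", "ProT", "HelT", "Roll"),
                 "shape table")
  tab[, c("pentamer", "MGW", "ProT", "HelT", "Roll")]
}

#' Binned DNA-shape features per window
#'
#' Every nucleotide position with a full, N-free pentamer context receives
#' the four shape values of its pentamer (HelT and Roll already averaged
#' over the two inter-step values). For each central-base identity and each
#' feature, the values are binned into 5 bins whose edges are fixed from the
#' pooled distribution over all windows (equal-width over the observed range
#' by default; equal-occupancy optional), and per-window counts per
#' (base, feature, bin) give 4 x 4 x 5 = 80 predictors.
#'
#' @param genome a `genome_assembly`.
#' @param windows window data frame.
#' @param table shape lookup (default [synthetic_shape_table()]); must cover
#'   every pentamer encountered.
#' @param bins number of bins per (base, feature) (default 5).
#' @param binning `"width"` for equal-width bins over the observed range,
#'   `"quantile"` for equal-occupancy bins.
#' @return Integer matrix (windows x 80) with columns like `A_MGW_b1`.
#' @export
shape_features <- function(genome, windows, table = synthetic_shape_table(),
                           bins = 5L, binning = c("width", "quantile")) {
  binning <- match.arg(binning)
  feats <- c("MGW", "ProT", "HelT", "Roll")
  stopifnot_cols(table, c("pentamer", feats), "shape table")
  seqs <- as.character(window_sequences(genome, windows))
  nw <- length(seqs)

  win_idx <- integer(0)
  base <- character(0)
  vals <- matrix(numeric(0), ncol = 4)
  per_window <- vector("list", nw)
  for (i in seq_len(nw)) {
    s <- seqs[i]
    wlen <- nchar(s)
    if (wlen < 5L) next
    np <- wlen - 4L
    pent <- substring(s, seq_len(np), seq_len(np) + 4L)
    ctr <- substring(s, 3:(wlen - 2L), 3:(wlen - 2L))
    idx <- match(pent, table$pentamer)
    hasN <- grepl("N", pent, fixed = TRUE)
    if (any(is.na(idx) & !hasN)) {
      stop("shape table does not cover pentamer '",
           pent[which(is.na(idx) & !hasN)[1]], "'")
    }
    keep <- !is.na(idx)
    per_window[[i]] <- list(win = rep.int(i, sum(keep)), base = ctr[keep],
                            v = as.matrix(table[idx[keep], feats]))
  }
  win_idx <- unlist(lapply(per_window, `[[`, "win"), use.names = FALSE)
  base <- unlist(lapply(per_window, `[[`, "base"), use.names = FALSE)
  vals <- do.call(rbind, lapply(per_window, `[[`, "v"))

  out <- matrix(0L, nrow = nw, ncol = 4L * length(feats) * bins)
  cn <- character(ncol(out))
  col <- 0L
  for (b in c("A", "C", "G", "T")) {
    sel <- base == b
    for (fi in seq_along(feats)) {
      if (!any(sel)) {
        # no position with this central base anywhere: zero columns
        cn[col + seq_len(bins)] <- paste0(b, "_", feats[fi], "_b",
                                          seq_len(bins))
        col <- col + bins
        next
      }
      v <- vals[sel, fi]
      edges <- if (binning == "width") {
        seq(min(v), max(v), length.out = bins + 1L)
      } else {
        unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L)))
      }
      if (length(edges) < 2L || edges[1] == edges[length(edges)]) {
        # degenerate (constant) feature: all mass in bin 1
        bin <- rep.int(1L, length(v))
        nb <- 1L
      } else {
        bin <- findInterval(v, edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
        nb <- length(edges) - 1L
      }
      counts <- matrix(0L, nrow = nw, ncol = bins)
      tt <- tabulate((win_idx[sel] - 1L) * bins + bin, nbins = nw * bins)
      counts <- matrix(tt, nrow = nw, ncol = bins, byrow = TRUE)
      out[, col + seq_len(bins)] <- counts
      cn[col + seq_len(bins)] <- paste0(b, "_", feats[fi], "_b",
                                        seq_len(bins))
      col <- col + bins
    }
  }
  colnames(out) <- cn
  rownames(out) <- window_ids(windows)
  attr(out, "kind") <- "shape bin counts"
  out
}

#' Balanced sampling of windows over the enrichment range
#'
#' Enrichment values pile up near zero, which would dominate a naive fit.
#' The values are divided into 12 bins: `[min, q2.5]`, ten equal-width bins
#' on `[q2.5, q97.5]`, and `[q97.5, max]`. The same number n of windows (the
#' size of the smallest bin) is sampled from each bin without replacement,
#' and the sampled set is split at random into equal train and test halves.
#'
#' @param y numeric enrichment values.
#' @param exclude optional logical vector or index vector of windows to
#'   exclude beforehand (repeat- or CpG-island-overlapping windows).
#' @param seed integer seed.
#' @return Object of class `balanced_split` with `edges`, `n` (per-bin
#'   sample size), `train` and `test` (index vectors into `y`), `bin` (bin
#'   assignment of every retained window), and `seed`.
#' @export
balanced_split <- function(y, exclude = NULL, seed = 1L) {
  idx <- seq_along(y)
  if (!is.null(exclude)) {
    if (is.logical(exclude)) idx <- idx[!exclude] else idx <- setdiff(idx, exclude)
  }
  idx <- idx[!is.na(y[idx])]
  yy <- y[idx]
  if (length(unique(yy)) < 12L) {
    stop("need at least 12 distinct enrichment values after exclusions")
  }
  q <- stats::quantile(yy, c(0.025, 0.975), names = FALSE)
  inner <- seq(q[1], q[2], length.out = 11L)
  edges <- c(min(yy), inner, max(yy))
  if (any(diff(edges) <= 0)) {
    stop("degenerate enrichment distribution: bin edges are not increasing")
  }
  bin <- findInterval(yy, edges, rightmost.closed = TRUE, all.inside = TRUE)
  sizes <- tabulate(bin, nbins = 12L)
  if (any(sizes == 0L)) {
    stop("bin ", which(sizes == 0L)[1], " of 12 is empty")
  }
  n <- min(sizes)
  with_seed(seed, {
    sampled <- unlist(lapply(1:12, function(b) {
      pool <- idx[bin == b]
      pool[sample.int(length(pool), n)]
    }), use.names = FALSE)
    perm <- sample(sampled)
    half <- length(perm) %/% 2L
    structure(list(
      edges = edges, n = n,
      train = sort(perm[seq_len(half)]),
      test = sort(perm[(half + 1L):length(perm)]),
      bin = stats::setNames(bin, idx),
      seed = seed
    ), class = "balanced_split")
  })
}

#' @export
print.balanced_split <- function(x, ...) {
  cat(sprintf("balanced_split: n = %d per bin, %d train / %d test windows\n",
              x$n, length(x$train), length(x$test)))
  invisible(x)
}
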