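#' Principal component analysis of enrichment tracks
#'
#' Samples are observations and windows are variables: each window's
#' enrichment values are centered across samples (no variance scaling) and
#' decomposed by SVD, giving per-sample scores and per-window loadings. PC
#' signs are arbitrary, so if the first component's loading correlates
#' negatively with window AT content, all loadings and scores are negated;
#' binding then reads as positive along PC1.
#'
#' @param track_matrix numeric matrix, samples in rows, windows in columns
#'   (restrict columns to well-mappable windows beforehand).
#' @param at numeric vector of window AT contents (one per column), used for
#'   the sign convention; omit to skip sign fixing.
#' @return Object of class `binding_pca` with `scores` (samples x PCs),
#'   `loadings` (windows x PCs), `variance_fraction`, `center`, and
#'   `sign_flipped`.
#' @export
run_pca <- function(track_matrix, at = NULL) {
  stopifnot(is.matrix(track_matrix))
  if (nrow(track_matrix) < 3L) stop("need at least 3 samples")
  if (any(is.na(track_matrix))) {
    keep <- colSums(is.na(track_matrix)) == 0L
    track_matrix <- track_matrix[, keep, drop = FALSE]
    if (!is.null(at)) at <- at[keep]
  }
  if (all(apply(track_matrix, 2, stats::var) < .Machine$double.eps)) {
    stop("constant track matrix: no variance to decompose")
  }
  p <- stats::prcomp(track_matrix, center = TRUE, scale. = FALSE)
  varfrac <- p$sdev^2 / sum(p$sdev^2)
  flipped <- FALSE
  if (!is.null(at)) {
    stopifnot(length(at) == ncol(track_matrix))
    if (stats::cor(p$rotation[, 1], at) < 0) {
      p$rotation <- -p$rotation
      p$x <- -p$x
      flipped <- TRUE
    }
  }
  structure(list(
    scores = p$x,
    loadings = p$rotation,
    variance_fraction = varfrac,
    center = p$center,
    sign_flipped = flipped
  ), class = "binding_pca")
}

#' @export
print.binding_pca <- function(x, ...) {
  cat("binding_pca:", nrow(x$scores), "samples,", nrow(x$loadings),
      "windows\n  variance fractions:",
      paste(sprintf("%.3f", utils::head(x$variance_fraction, 5)),
            collapse = " "), "\n")
  invisible(x)
}

#' Pairwise Pearson correlation of window-level tracks
#'
#' @param tracks numeric matrix (windows x tracks) or a named list of
#'   equal-length numeric vectors. Windows with missing values are dropped
#'   pairwise.
#' @return Symmetric Pearson correlation matrix with unit diagonal.
#' @export
correlate_tracks <- function(tracks) {
  if (is.list(tracks) && !is.data.frame(tracks)) {
    tracks <- do.call(cbind, tracks)
  }
  tracks <- as.matrix(tracks)
  r <- stats::cor(tracks, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Chromosome-scale display track
#'
#' Masks windows below the mappability threshold (gaps mark low-mappability
#' regions) and produces a display copy in which the top and bottom 1% of
#' the data range are clipped; the underlying data series is untouched.
#'
#' @param windows annotated window data frame (needs `mappable_fraction`).
#' @param values numeric vector, one value per window.
#' @param trim fraction of the data range clipped at each end for display
#'   (default 0.01).
#' @param min_mappable mappability threshold (default 0.8).
#' @return List with `data` (masked values) and `display` (masked and
#'   range-clipped values), plus the window table.
#' @export
chromosome_track <- function(windows, values, trim = 0.01,
                             min_mappable = 0.8) {
  stopifnot(length(values) == nrow(windows))
  data <- values
  data[windows$mappable_fraction < min_mappable] <- NA_real_
  rng <- range(data, na.rm = TRUE)
  lo <- rng[1] + trim * diff(rng)
  hi <- rng[2] - trim * diff(rng)
  display <- pmin(pmax(data, lo), hi)
  list(windows = windows[, c("chrom", "start", "end")],
       data = data, display = display)
}

#' Filter repeat instances for enrichment analysis
#'
#' Three passes: instances shorter than `min_length` are removed (short
#' repeats cannot be resolved at sonication-fragment scale), instances whose
#' mappable fraction is below `min_mappable` are removed, and repeat names
#' with fewer than `min_instances` surviving instances are removed entirely.
#'
#' @param repeats data frame with `chrom`, `start`, `end`, `name`, `family`.
#' @param genome a `genome_assembly`.
#' @param mappability optional precomputed [genome_mappability()].
#' @param min_length minimum instance length in nt (default 300).
#' @param min_mappable minimum mappable fraction (default 0.8).
#' @param min_instances minimum surviving instances per name (default 10).
#' @param k k-mer length for mappability (default 50).
#' @return Filtered repeat data frame with a `mappable_fraction` column.
#' @export
filter_repeats <- function(repeats, genome, mappability = NULL,
                           min_length = 300L, min_mappable = 0.8,
                           min_instances = 10L, k = 50L) {
  stopifnot_cols(repeats, c("chrom", "start", "end", "name", "family"),
                 "repeats")
  out <- repeats[repeats$end - repeats$start >= min_length, , drop = FALSE]
  if (nrow(out)) {
    out <- mappable_fraction(genome, out, k = k, mappability = mappability)
    out <- out[out$mappable_fraction >= min_mappable, , drop = FALSE]
  }
  if (nrow(out)) {
    tab <- table(out$name)
    keep <- names(tab)[tab >= min_instances]
    out <- out[out$name %in% keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Aggregate repeat-class enrichment over the DBD-mutant
#'
#' Counts are aggregated over all instances of each repeat name, enrichment
#' over input is computed on the aggregates, and the paired mutant
#' enrichment is subtracted. The mean AT content over the instances of each
#' name is reported alongside.
#'
#' @param wt_ip,wt_input wild-type IP and input [read_set()]s.
#' @param mut_ip,mut_input paired DBD-mutant IP and input read sets.
#' @param repeats filtered repeat set from [filter_repeats()].
#' @param genome a `genome_assembly`.
#' @param shift read shift in nt.
#' @param pseudocount pseudo-count (default 8).
#' @return Data frame (`name`, `family`, `n_instances`, `e_wt`, `e_mutant`,
#'   `delta_e`, `mean_at`, `low_coverage`).
#' @export
repeat_enrichment <- function(wt_ip, wt_input, mut_ip, mut_input, repeats,
                              genome, shift = 0L, pseudocount = 8) {
  if (!nrow(repeats)) stop("empty filtered repeat set")
  cnt <- data.frame(
    name = repeats$name,
    wt_ip = count_reads(wt_ip, repeats, shift),
    wt_in = count_reads(wt_input, repeats, shift),
    mut_ip = count_reads(mut_ip, repeats, shift),
    mut_in = count_reads(mut_input, repeats, shift),
    at = at_content(window_sequences(genome, repeats)),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(cnt[, c("wt_ip", "wt_in", "mut_ip", "mut_in")],
                          by = list(name = cnt$name), FUN = sum)
  at_mean <- stats::aggregate(list(mean_at = cnt$at),
                              by = list(name = cnt$name), FUN = mean)
  n_inst <- stats::aggregate(list(n_instances = cnt$name),
                             by = list(name = cnt$name), FUN = length)
  fam <- repeats$family[match(agg$name, repeats$name)]
  e_wt <- log2_enrichment(agg$wt_ip, agg$wt_in, n_reads(wt_ip),
                          n_reads(wt_input), pseudocount)
  e_mut <- log2_enrichment(agg$mut_ip, agg$mut_in, n_reads(mut_ip),
                           n_reads(mut_input), pseudocount)
  data.frame(
    name = agg$name,
    family = fam,
    n_instances = n_inst$n_instances,
    e_wt = e_wt,
    e_mutant = e_mut,
    delta_e = e_wt - e_mut,
    mean_at = at_mean$mean_at,
    low_coverage = agg$wt_in == 0 | agg$mut_in == 0,
    stringsAsFactors = FALSE
  )
}
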