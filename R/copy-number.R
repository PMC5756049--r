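#' GC-corrected read-depth karyotype comparison
#'
#' For each input sample, reads are counted in well-mappable tiling windows
#' (1 Mb by default), log2 counts are centered to their mean across windows
#' (windows with zero counts get a +1 count floor first), and a loess
#' regression of the centered log2 counts on window GC content removes the
#' shared GC sampling bias. Residuals are averaged per chromosome, the two
#' sample groups are averaged, and their difference gives the per-chromosome
#' log2 copy-number ratio (group A over group B).
#'
#' @param group_a,group_b lists of input [read_set()]s (at least one each).
#' @param genome a `genome_assembly`.
#' @param window_size tiling window size in nt (default 1e6).
#' @param span loess span (default 0.75; local quadratic fit).
#' @param min_mappable mappability threshold (default 0.8).
#' @param mappability optional precomputed [genome_mappability()].
#' @param shift read shift in nt (0 for input libraries).
#' @return Object of class `cnv_result`: data frame (`chrom`, `mean_a`,
#'   `mean_b`, `log2_ratio`) with the loess span as an attribute.
#' @export
cnv_ratios <- function(group_a, group_b, genome, window_size = 1e6,
                       span = 0.75, min_mappable = 0.8,
                       mappability = NULL, shift = 0L) {
  if (inherits(group_a, "read_set")) group_a <- list(group_a)
  if (inherits(group_b, "read_set")) group_b <- list(group_b)
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  ws <- tile_genome(genome, window_size)
  ws <- mappable_fraction(genome, ws, mappability = mappability)
  ws <- window_gc_content(genome, ws)
  keep <- ws$mappable_fraction >= min_mappable & !is.na(ws$gc_content)
  ws <- ws[keep, , drop = FALSE]
  dropped <- setdiff(names(genome$seq), unique(ws$chrom))
  if (length(dropped)) {
    warning("chromosome(s) without mappable windows omitted: ",
            paste(dropped, collapse = ", "))
  }
  if (!nrow(ws)) stop("no mappable windows at this window size")

  chrom_resid <- function(rs) {
    n <- count_reads(rs, ws, shift)
    x <- log2(pmax(n, 1L))
    x <- x - mean(x)
    fit <- stats::loess(x ~ gc, data = data.frame(x = x, gc = ws$gc_content),
                        span = span, degree = 2,
                        family = "gaussian", surface = "direct")
    res <- stats::residuals(fit)
    tapply(res, ws$chrom, mean)
  }
  ra <- sapply(group_a, chrom_resid)
  rb <- sapply(group_b, chrom_resid)
  if (is.null(dim(ra))) ra <- matrix(ra, ncol = 1)
  if (is.null(dim(rb))) rb <- matrix(rb, ncol = 1)
  chroms <- rownames(ra)
  mean_a <- rowMeans(ra)
  mean_b <- rowMeans(rb)
  out <- data.frame(chrom = chroms, mean_a = mean_a, mean_b = mean_b,
                    log2_ratio = mean_a - mean_b, stringsAsFactors = FALSE)
  # report in genome chromosome order
  out <- out[order(match(out$chrom, names(genome$seq))), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cnv_result", "data.frame"), span = span,
            window_size = window_size)
}

#' @export
print.cnv_result <- function(x, ...) {
  cat("cnv_result: per-chromosome log2 read-depth ratios (A / B), loess span",
      attr(x, "span"), "\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
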