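#' Evaluate an expression with a temporary RNG state
#'
#' Sets the Mersenne-Twister seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so that every exported operation taking a
#' `seed` argument is deterministic without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Reverse complement of character k-mers
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# window id strings used as row identifiers throughout
window_ids <- function(windows) {
  paste0(windows$chrom, ":", windows$start, "-", windows$end)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
  }
}

# running mean with an odd box width; ends use partial windows
running_mean <- function(x, width) {
  if (width <= 1L) return(x)
  stopifnot(width %% 2L == 1L)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# running sum over a centered odd-width box, truncated at the ends
running_sum <- function(x, width) {
  if (width <= 1L) return(x)
  stopifnot(width %% 2L == 1L)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  cs[hi + 1L] - cs[lo]
}
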