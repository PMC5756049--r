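#' Specification of a synthetic genome
#'
#' Describes an artificial genome with megabase-scale base-composition
#' structure (isochores), GC/CpG-rich islands, AT-rich `(TA)n` tandem
#' repeats, and annotated promoters. The emitted genome is the substrate for
#' the read simulator: wild-type binding is driven by local AT fraction,
#' while control samples are biased toward the GC-rich "open" features.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of every chromosome in nucleotides.
#' @param isochore_block_length length of each constant-composition block.
#' @param at_levels numeric vector of AT fractions in `[0, 1]`. If its length
#'   equals the total number of blocks it is used in order; otherwise one
#'   level is drawn per block (uniformly from the vector) with the spec seed.
#' @param n_cpg_islands,cpg_island_length count and length of CpG islands.
#' @param n_TA_repeats,TA_repeat_length count and length of `(TA)n` arrays.
#' @param n_promoters number of annotated promoters (TSS +/- 1000 nt).
#' @param seed integer seed controlling every random choice of the generator.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 2L,
                        chrom_length = 1e6L,
                        isochore_block_length = 1e4L,
                        at_levels = NULL,
                        n_cpg_islands = 40L,
                        cpg_island_length = 1000L,
                        n_TA_repeats = 12L,
                        TA_repeat_length = 400L,
                        n_promoters = 60L,
                        seed = 1L) {
  if (is.null(at_levels)) {
    # drawn once here so the spec fully determines the genome
    n_blocks <- n_chromosomes * ceiling(chrom_length / isochore_block_length)
    at_levels <- with_seed(seed, stats::runif(n_blocks, 0.35, 0.75))
  }
  spec <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    isochore_block_length = as.integer(isochore_block_length),
    at_levels = as.numeric(at_levels),
    n_cpg_islands = as.integer(n_cpg_islands),
    cpg_island_length = as.integer(cpg_island_length),
    n_TA_repeats = as.integer(n_TA_repeats),
    TA_repeat_length = as.integer(TA_repeat_length),
    n_promoters = as.integer(n_promoters),
    seed = as.integer(seed)
  )
  validate_genome_spec(spec)
  structure(spec, class = "genome_spec")
}

validate_genome_spec <- function(spec) {
  if (any(spec$at_levels < 0 | spec$at_levels > 1)) {
    stop("at_levels must all lie within [0, 1]")
  }
  if (spec$isochore_block_length > spec$chrom_length) {
    stop("isochore_block_length must not exceed chrom_length")
  }
  feat_len <- c(spec$cpg_island_length, spec$TA_repeat_length, 2001L)
  used <- c(spec$n_cpg_islands, spec$n_TA_repeats, spec$n_promoters)
  if (any(feat_len[used > 0] >= spec$chrom_length)) {
    stop("feature lengths must be smaller than chrom_length")
  }
  total <- sum(as.numeric(feat_len) * used)
  if (total > spec$n_chromosomes * as.numeric(spec$chrom_length)) {
    stop("infeasible placement: features exceed total chromosome capacity")
  }
  invisible(spec)
}

#' Ground-truth binding model for the read simulator
#'
#' Parameterizes how sequencing fragments are sampled. Wild-type IP
#' fragments carry weight `exp(beta_at * AT_fraction)` computed over the
#' full fragment; DNA-binding-domain-mutant and GFP IPs carry weight
#' `1 + gamma_open * openness` where openness is a smoothed indicator over
#' CpG islands and promoters; input fragments carry a smooth GC-dependent
#' weight `exp(g1 * GC + g2 * GC^2)`. Setting all coefficients to zero
#' yields a uniform sampler.
#'
#' @param beta_at slope of the log sampling weight versus fragment AT
#'   fraction for wild-type IPs. The default gives a 3-fold weight ratio
#'   across an AT difference of 0.4.
#' @param gamma_open openness bias of mutant/GFP IPs (dimensionless).
#' @param fragment_length,fragment_sd mean and standard deviation of the
#'   sonication fragment length in nucleotides.
#' @param gc_bias_coeffs numeric length-2 vector `(g1, g2)` of the input GC
#'   bias polynomial.
#' @param copy_number per-chromosome positive integer copy numbers
#'   (recycled across chromosomes).
#' @return An object of class `binding_truth`.
#' @export
binding_truth <- function(beta_at = log(3) / 0.4,
                          gamma_open = 3,
                          fragment_length = 150L,
                          fragment_sd = 15,
                          gc_bias_coeffs = c(0.5, 0),
                          copy_number = 1L) {
  stopifnot(fragment_length > 0, all(copy_number >= 1))
  structure(list(
    beta_at = beta_at,
    gamma_open = gamma_open,
    fragment_length = as.integer(fragment_length),
    fragment_sd = fragment_sd,
    gc_bias_coeffs = rep_len(as.numeric(gc_bias_coeffs), 2L),
    copy_number = as.integer(copy_number)
  ), class = "binding_truth")
}

#' Generate a synthetic genome with annotations
#'
#' Emits chromosome sequences whose AT content follows the blockwise
#' isochore targets of the spec, overlays non-overlapping CpG islands
#' (GC >= 0.6 with elevated CpG dinucleotide density), exact `(TA)n` tandem
#' arrays, and promoter annotations (the promoter sequence itself is
#' background). Identical `(spec, truth)` inputs give byte-identical output.
#'
#' @param spec a [genome_spec()].
#' @param truth a [binding_truth()]; its `copy_number` is recycled over the
#'   chromosomes and attached to the assembly.
#' @return A list with elements `genome` (class `genome_assembly`: a
#'   [Biostrings::DNAStringSet] plus per-chromosome copy numbers),
#'   `annotations` (data frames: `blocks` with per-block AT targets,
#'   `cpg_island`, `ta_repeat`, `promoter`, `tss`), and `truth`. All
#'   coordinates are 0-based half-open.
#' @export
generate_genome <- function(spec, truth = binding_truth()) {
  stopifnot(inherits(spec, "genome_spec"))
  validate_genome_spec(spec)
  with_seed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$n_chromosomes))
    L <- spec$chrom_length
    bl <- spec$isochore_block_length
    n_blk_per <- ceiling(L / bl)
    n_blk <- spec$n_chromosomes * n_blk_per

    at_target <- if (length(spec$at_levels) == n_blk) {
      spec$at_levels
    } else {
      spec$at_levels[sample.int(length(spec$at_levels), n_blk, replace = TRUE)]
    }

    blocks <- data.frame(
      chrom = rep(chroms, each = n_blk_per),
      start = rep.int((seq_len(n_blk_per) - 1L) * bl, spec$n_chromosomes),
      stringsAsFactors = FALSE
    )
    blocks$end <- pmin(blocks$start + bl, L)
    blocks$at_target <- at_target

    bases <- c("A", "C", "G", "T")
    letters_by_chrom <- lapply(chroms, function(ch) {
      rows <- which(blocks$chrom == ch)
      unlist(lapply(rows, function(i) {
        m <- blocks$end[i] - blocks$start[i]
        a <- blocks$at_target[i]
        p <- c(a / 2, (1 - a) / 2, (1 - a) / 2, a / 2)
        bases[sample.int(4L, m, replace = TRUE, prob = p)]
      }), use.names = FALSE)
    })
    names(letters_by_chrom) <- chroms

    # one non-overlap pool per chromosome for islands, repeats and promoters
    feat <- data.frame(
      type = c(rep("cpg_island", spec$n_cpg_islands),
               rep("ta_repeat", spec$n_TA_repeats),
               rep("promoter", spec$n_promoters)),
      len = c(rep(spec$cpg_island_length, spec$n_cpg_islands),
              rep(spec$TA_repeat_length, spec$n_TA_repeats),
              rep(2001L, spec$n_promoters)),
      stringsAsFactors = FALSE
    )
    placed <- list()
    occupied <- lapply(chroms, function(ch) {
      data.frame(start = integer(0), end = integer(0))
    })
    names(occupied) <- chroms
    if (nrow(feat)) {
      feat$chrom <- chroms[sample.int(spec$n_chromosomes, nrow(feat), replace = TRUE)]
      # CpG islands and promoters preferentially occupy GC-rich blocks,
      # giving the openness track its anti-correlation with AT content
      block_w <- lapply(chroms, function(ch) {
        a <- blocks$at_target[blocks$chrom == ch]
        (1 - a)^2
      })
      names(block_w) <- chroms
      for (i in seq_len(nrow(feat))) {
        ch <- feat$chrom[i]
        len <- feat$len[i]
        occ <- occupied[[ch]]
        gc_biased <- feat$type[i] %in% c("cpg_island", "promoter")
        ok <- FALSE
        for (try in seq_len(500L)) {
          if (gc_biased) {
            b <- sample.int(length(block_w[[ch]]), 1L, prob = block_w[[ch]])
            lo <- (b - 1L) * bl
            hi <- min(b * bl, L) - len
            if (hi < lo) next
            s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          } else {
            s <- sample.int(L - len + 1L, 1L) - 1L
          }
          e <- s + len
          if (!any(s < occ$end & e > occ$start)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("infeasible placement: could not place feature '",
                      feat$type[i], "' on ", ch)
        occupied[[ch]] <- rbind(occ, data.frame(start = s, end = e))
        placed[[length(placed) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e, type = feat$type[i],
          stringsAsFactors = FALSE)
      }
    }
    placed <- if (length(placed)) do.call(rbind, placed) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), type = character(0))

    cpg <- placed[placed$type == "cpg_island", c("chrom", "start", "end")]
    ta <- placed[placed$type == "ta_repeat", c("chrom", "start", "end")]
    prom <- placed[placed$type == "promoter", c("chrom", "start", "end")]
    rownames(cpg) <- rownames(ta) <- rownames(prom) <- NULL

    # overwrite feature sequence into the background
    if (nrow(cpg)) {
      for (i in seq_len(nrow(cpg))) {
        m <- cpg$end[i] - cpg$start[i]
        seqv <- cpg_island_letters(m)
        letters_by_chrom[[cpg$chrom[i]]][(cpg$start[i] + 1L):cpg$end[i]] <- seqv
      }
    }
    if (nrow(ta)) {
      for (i in seq_len(nrow(ta))) {
        m <- ta$end[i] - ta$start[i]
        seqv <- rep_len(c("T", "A"), m)
        letters_by_chrom[[ta$chrom[i]]][(ta$start[i] + 1L):ta$end[i]] <- seqv
      }
    }

    if (nrow(prom)) {
      prom$strand <- sample(c("+", "-"), nrow(prom), replace = TRUE)
      prom$tss <- prom$start + 1000L
      prom$gene_id <- sprintf("gene%03d", seq_len(nrow(prom)))
      prom$transcript_id <- sprintf("tx%03d", seq_len(nrow(prom)))
    } else {
      prom$strand <- character(0)
      prom$tss <- integer(0)
      prom$gene_id <- character(0)
      prom$transcript_id <- character(0)
    }
    tss <- prom[, c("gene_id", "transcript_id", "chrom", "tss", "strand")]

    seqs <- Biostrings::DNAStringSet(vapply(
      letters_by_chrom, paste, character(1), collapse = ""))
    names(seqs) <- chroms
    genome <- genome_assembly(seqs,
                              copy_number = rep_len(truth$copy_number,
                                                    spec$n_chromosomes))

    list(
      genome = genome,
      annotations = list(blocks = blocks, cpg_island = cpg, ta_repeat = ta,
                         promoter = prom, tss = tss),
      truth = truth
    )
  })
}

# CpG-island generator: pairs are "CG" with prob 0.25, otherwise two
# independent GC-rich bases; gives GC ~ 0.78 and strongly elevated CpG.
cpg_island_letters <- function(m) {
  bases <- c("A", "C", "G", "T")
  npair <- ceiling(m / 2)
  is_cpg <- stats::runif(npair) < 0.25
  out <- character(2L * npair)
  idx <- which(is_cpg)
  out[2L * idx - 1L] <- "C"
  out[2L * idx] <- "G"
  oth <- which(!is_cpg)
  if (length(oth)) {
    draw <- bases[sample.int(4L, 2L * length(oth), replace = TRUE,
                             prob = c(0.15, 0.35, 0.35, 0.15))]
    out[2L * oth - 1L] <- draw[seq_along(oth)]
    out[2L * oth] <- draw[length(oth) + seq_along(oth)]
  }
  out[seq_len(m)]
}

#' Genome assembly container
#'
#' @param seqs a named [Biostrings::DNAStringSet].
#' @param copy_number per-chromosome positive integers (recycled).
#' @return An object of class `genome_assembly` with elements `seq`,
#'   `copy_number`, and `lengths`.
#' @export
genome_assembly <- function(seqs, copy_number = 1L) {
  stopifnot(methods::is(seqs, "DNAStringSet"), !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  structure(list(
    seq = seqs,
    copy_number = stats::setNames(rep_len(as.integer(copy_number),
                                          length(seqs)), names(seqs)),
    lengths = stats::setNames(Biostrings::width(seqs), names(seqs))
  ), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x$seq), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  for (ch in names(x$seq)) {
    cat(sprintf("  %s  %s bp  copy number %d\n", ch,
                format(x$lengths[[ch]], big.mark = ","),
                x$copy_number[[ch]]))
  }
  invisible(x)
}

#' Aligned single-end read set
#'
#' @param reads data frame with columns `chrom`, `pos` (0-based 5' position)
#'   and `strand` (`+`/`-`).
#' @param sample_id,role,genotype,replicate sample metadata. `role` must be
#'   `"IP"` or `"input"`; `genotype` one of `"WT-Hmga1"`, `"WT-Hmga2"`,
#'   `"DBD-mutant-1"`, `"DBD-mutant-2"`, `"GFP"`.
#' @return An object of class `read_set`; `n_reads()` returns the total
#'   aligned read count N.
#' @export
read_set <- function(reads, sample_id = "sample", role = "IP",
                     genotype = "WT-Hmga1", replicate = "a") {
  stopifnot_cols(reads, c("chrom", "pos", "strand"), "reads")
  role <- match.arg(role, c("IP", "input"))
  genotype <- match.arg(genotype, c("WT-Hmga1", "WT-Hmga2", "DBD-mutant-1",
                                    "DBD-mutant-2", "GFP"))
  if (!all(reads$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  structure(list(
    reads = data.frame(chrom = as.character(reads$chrom),
                       pos = as.integer(reads$pos),
                       strand = as.character(reads$strand),
                       stringsAsFactors = FALSE),
    sample_id = sample_id, role = role, genotype = genotype,
    replicate = replicate
  ), class = "read_set")
}

#' Total aligned reads of a read set
#' @param x a `read_set`.
#' @return integer count N.
#' @export
n_reads <- function(x) nrow(x$reads)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s' (%s, %s, replicate %s): %d reads\n",
              x$sample_id, x$role, x$genotype, x$replicate, n_reads(x)))
  invisible(x)
}

#' Openness track: smoothed indicator over CpG islands and promoter cores
#'
#' Emulates the accessibility bias of chromatin immunoprecipitation at open,
#' GC-rich regions: 1 inside CpG islands and a TSS-centered promoter core
#' (accessibility peaks at the nucleosome-depleted region around the TSS,
#' not across the whole promoter), 0 elsewhere, smoothed with a centered
#' box filter.
#'
#' @param genome a `genome_assembly`.
#' @param annotations annotation list from [generate_genome()].
#' @param bandwidth odd box width in nucleotides.
#' @param core_halfwidth half-width of the open promoter core around the
#'   TSS, in nucleotides.
#' @return named list of per-chromosome numeric vectors in `[0, 1]`.
#' @export
openness_track <- function(genome, annotations, bandwidth = 501L,
                           core_halfwidth = 250L) {
  prom <- annotations$promoter
  core <- if (!is.null(prom) && nrow(prom)) {
    data.frame(chrom = prom$chrom,
               start = pmax(prom$tss - core_halfwidth, 0L),
               end = prom$tss + core_halfwidth + 1L,
               stringsAsFactors = FALSE)
  } else NULL
  out <- lapply(names(genome$seq), function(ch) {
    L <- genome$lengths[[ch]]
    ind <- numeric(L)
    for (tab in list(annotations$cpg_island, core)) {
      if (is.null(tab) || !nrow(tab)) next
      rows <- which(tab$chrom == ch)
      for (i in rows) ind[(tab$start[i] + 1L):min(tab$end[i], L)] <- 1
    }
    running_mean(ind, bandwidth)
  })
  names(out) <- names(genome$seq)
  out
}

#' Simulate one aligned ChIP-seq or input sample
#'
#' Samples `n_reads` sonication fragments with role- and genotype-dependent
#' weights (see [binding_truth()]), chromosome mass proportional to
#' length x copy number, fragment length Normal(F, sd) truncated at 50 nt,
#' and emits one single-end read per fragment at its 5' end on a uniformly
#' random strand.
#'
#' @param genome a `genome_assembly`.
#' @param truth a [binding_truth()].
#' @param sample_spec list with `id`, `role` ("IP"/"input"), `genotype`, and
#'   `replicate`.
#' @param n_reads number of reads to emit.
#' @param seed integer seed.
#' @param annotations annotation list (needed for the openness weight of
#'   mutant/GFP IPs; may be omitted for other samples).
#' @param openness optional precomputed [openness_track()].
#' @return A [read_set()].
#' @export
simulate_sample <- function(genome, truth, sample_spec, n_reads, seed,
                            annotations = NULL, openness = NULL) {
  stopifnot(inherits(genome, "genome_assembly"),
            inherits(truth, "binding_truth"), n_reads > 0)
  role <- sample_spec$role
  genotype <- sample_spec$genotype
  if (!role %in% c("IP", "input")) stop("unknown role: ", role)
  gt_ok <- c("WT-Hmga1", "WT-Hmga2", "DBD-mutant-1", "DBD-mutant-2", "GFP")
  if (!genotype %in% gt_ok) stop("unknown genotype: ", genotype)
  is_wt_ip <- role == "IP" && genotype %in% c("WT-Hmga1", "WT-Hmga2")
  is_open_ip <- role == "IP" && !is_wt_ip
  if (is_open_ip && truth$gamma_open != 0 && is.null(openness)) {
    if (is.null(annotations)) {
      stop("mutant/GFP IP simulation needs 'annotations' or 'openness'")
    }
    openness <- openness_track(genome, annotations)
  }

  FL <- truth$fragment_length
  chroms <- names(genome$seq)
  cn <- rep_len(genome$copy_number, length(chroms))

  wts <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    L <- genome$lengths[[ch]]
    if (L < FL) {
      wts[[ci]] <- numeric(0)
      next
    }
    nstart <- L - FL + 1L           # starts 0 .. L-FL
    if (is_wt_ip && truth$beta_at != 0) {
      frac <- fragment_base_fraction(genome$seq[[ch]], FL, c("A", "T"))
      w <- exp(truth$beta_at * frac)
    } else if (is_open_ip && truth$gamma_open != 0) {
      mid <- pmin(seq_len(nstart) + FL %/% 2L, L)  # fragment midpoints, 1-based
      w <- 1 + truth$gamma_open * openness[[ch]][mid]
    } else if (role == "input" && any(truth$gc_bias_coeffs != 0)) {
      frac <- fragment_base_fraction(genome$seq[[ch]], FL, c("C", "G"))
      g <- truth$gc_bias_coeffs
      w <- exp(g[1] * frac + g[2] * frac^2)
    } else {
      w <- rep.int(1, nstart)
    }
    wts[[ci]] <- w * cn[ci]
  }
  nstarts <- lengths(wts)
  allw <- unlist(wts, use.names = FALSE)

  with_seed(seed, {
    pick <- sample.int(length(allw), n_reads, replace = TRUE, prob = allw)
    chrom_idx <- findInterval(pick, cumsum(c(1, nstarts)))
    start0 <- pick - c(0L, cumsum(nstarts))[chrom_idx] - 1L  # 0-based start
    len <- as.integer(round(stats::rnorm(n_reads, FL, truth$fragment_sd)))
    len <- pmax(len, 50L)
    chrom_len <- unname(genome$lengths[chrom_idx])
    len <- pmin(len, chrom_len - start0)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    pos <- ifelse(strand == "+", start0, start0 + len - 1L)
    read_set(data.frame(chrom = chroms[chrom_idx], pos = pos,
                        strand = strand, stringsAsFactors = FALSE),
             sample_id = sample_spec$id %||% "sample",
             role = role, genotype = genotype,
             replicate = sample_spec$replicate %||% "a")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fraction of the given letters over [p, p+F) for every valid 0-based start p
fragment_base_fraction <- function(seq, FL, letters) {
  L <- length(seq)
  v <- as.integer(Biostrings::letterFrequencyInSlidingView(
    seq, view.width = FL, letters = paste(letters, collapse = "")))
  nN <- as.integer(Biostrings::letterFrequencyInSlidingView(
    seq, view.width = FL, letters = "N"))
  denom <- FL - nN
  out <- ifelse(denom > 0, v / denom, 0)
  out
}
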