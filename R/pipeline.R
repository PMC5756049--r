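#' Default (all-synthetic demonstration) pipeline configuration
#'
#' A fully specified configuration that simulates a two-chromosome genome
#' and a replicated sample panel (wild-type Hmga1/Hmga2 IPs a/b, paired
#' DBD-mutant IPs a/b, one GFP IP, inputs a/b), then runs every analysis
#' stage. All values can be overridden by the user configuration passed to
#' [validate_config()].
#'
#' @return Nested list of class `atchip_config`.
#' @export
default_config <- function() {
  manifest <- data.frame(
    sample = c("hmga1_a", "hmga1_b", "hmga2_a", "hmga2_b",
               "mut1_a", "mut1_b", "mut2_a", "mut2_b",
               "gfp_a", "input_a", "input_b"),
    role = c(rep("IP", 9L), "input", "input"),
    genotype = c("WT-Hmga1", "WT-Hmga1", "WT-Hmga2", "WT-Hmga2",
                 "DBD-mutant-1", "DBD-mutant-1", "DBD-mutant-2",
                 "DBD-mutant-2", "GFP", "WT-Hmga1", "WT-Hmga1"),
    replicate = c("a", "b", "a", "b", "a", "b", "a", "b", "a", "a", "b"),
    stringsAsFactors = FALSE
  )
  structure(list(
    seed = 1L,
    genome = list(simulate = TRUE,
                  n_chromosomes = 2L, chrom_length = 1000000L,
                  isochore_block_length = 10000L,
                  n_cpg_islands = 40L, cpg_island_length = 1000L,
                  n_TA_repeats = 12L, TA_repeat_length = 400L,
                  n_promoters = 60L),
    truth = list(beta_at = log(3) / 0.4, gamma_open = 3,
                 fragment_length = 150L, fragment_sd = 15,
                 gc_bias_coeffs = c(0.5, 0), copy_number = 1L),
    samples = manifest,
    n_reads = 200000L,
    params = list(window_size = 1000L, pseudocount = 8,
                  min_mappable = 0.8, kmer_k = 1:4, n_flank = 3L,
                  folds = 10L, cnv_window_size = 100000L,
                  loess_span = 0.75),
    stages = list(simulate = TRUE, windows = TRUE, quantify = TRUE,
                  pca = TRUE, models = TRUE, repeats = TRUE, cnv = TRUE)
  ), class = "atchip_config")
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every missing field from [default_config()], normalizes the sample
#' manifest to a data frame, resolves cross-references, and reports all
#' problems at once rather than stopping at the first. Validation is
#' idempotent: normalizing a normalized configuration is a no-op.
#'
#' @param config nested list (possibly partial; an empty list yields the
#'   fully-defaulted synthetic demo configuration), or a path to a YAML
#'   file.
#' @param strict stop with the collected error messages (default); if
#'   FALSE, return the normalized config with the errors in attribute
#'   `"errors"`.
#' @return Normalized configuration of class `atchip_config`.
#' @export
validate_config <- function(config = list(), strict = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  def <- default_config()
  user_samples <- config$samples
  config$samples <- NULL
  cfg <- utils::modifyList(unclass(def), config)
  cfg$samples <- if (is.null(user_samples)) def$samples else
    as.data.frame(user_samples, stringsAsFactors = FALSE)

  errors <- character(0)
  err <- function(...) errors <<- c(errors, sprintf(...))

  man <- cfg$samples
  need <- c("sample", "role", "genotype", "replicate")
  if (!all(need %in% names(man))) {
    err("sample manifest must have columns: %s", paste(need, collapse = ", "))
  } else {
    man[] <- lapply(man, as.character)
    cfg$samples <- man
    bad_role <- !man$role %in% c("IP", "input")
    if (any(bad_role)) {
      err("unknown role for sample(s): %s",
          paste(man$sample[bad_role], collapse = ", "))
    }
    gt_ok <- c("WT-Hmga1", "WT-Hmga2", "DBD-mutant-1", "DBD-mutant-2", "GFP")
    bad_gt <- !man$genotype %in% gt_ok
    if (any(bad_gt)) {
      err("unknown genotype for sample(s): %s",
          paste(man$sample[bad_gt], collapse = ", "))
    }
    if (anyDuplicated(man$sample)) err("duplicate sample ids in manifest")
    inputs <- man[man$role == "input", , drop = FALSE]
    ips <- man[man$role == "IP", , drop = FALSE]
    if (!nrow(inputs)) err("manifest contains no input sample")
    for (i in seq_len(nrow(ips))) {
      if (!any(inputs$replicate == ips$replicate[i])) {
        err("IP sample '%s' has no input with replicate letter '%s'",
            ips$sample[i], ips$replicate[i])
      }
      gt <- ips$genotype[i]
      if (gt %in% c("WT-Hmga1", "WT-Hmga2")) {
        mut_gt <- if (gt == "WT-Hmga1") "DBD-mutant-1" else "DBD-mutant-2"
        ok <- ips$genotype == mut_gt & ips$replicate == ips$replicate[i]
        if (!any(ok)) {
          err("wild-type IP '%s' has no %s IP with replicate letter '%s'",
              ips$sample[i], mut_gt, ips$replicate[i])
        }
      }
    }
  }
  if (!isTRUE(cfg$genome$simulate)) {
    if (is.null(cfg$genome$fasta) || !file.exists(cfg$genome$fasta)) {
      err("genome$simulate is FALSE but genome$fasta does not exist")
    }
  }
  if (cfg$params$window_size < 1) err("params$window_size must be >= 1")
  if (cfg$params$pseudocount < 0) err("params$pseudocount must be >= 0")
  if (cfg$n_reads < 1) err("n_reads must be positive")

  cfg <- structure(cfg, class = "atchip_config")
  if (length(errors)) {
    if (strict) stop("invalid configuration:\n  ",
                     paste(errors, collapse = "\n  "))
    attr(cfg, "errors") <- errors
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stage graph (simulate, windows, quantify, pca, models,
#' repeats, cnv) in dependency order, writing every result as TSV under
#' `outdir` together with a provenance manifest (parameters, seeds, files,
#' timing). Stages whose output files already exist are skipped unless an
#' upstream stage was re-run, so deleting an intermediate regenerates only
#' it and its dependents. Reruns with the same configuration reproduce all
#' TSV outputs byte-identically.
#'
#' @param config configuration (validated with [validate_config()]).
#' @param outdir run directory (created if missing).
#' @param quiet suppress progress messages.
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir, quiet = FALSE) {
  cfg <- if (inherits(config, "atchip_config")) config else
    validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config = prune_config(cfg), stages = list())
  pth <- function(...) file.path(outdir, ...)
  man <- cfg$samples
  reran <- FALSE

  run_stage <- function(name, outputs, fun) {
    t0 <- proc.time()[["elapsed"]]
    if (!isTRUE(cfg$stages[[name]])) {
      say("stage %-9s disabled", name)
      return(invisible(NULL))
    }
    if (!reran && all(file.exists(pth(outputs)))) {
      say("stage %-9s up to date", name)
    } else {
      say("stage %-9s running", name)
      fun()
      reran <<- TRUE
    }
    manifest$stages[[name]] <<- list(
      outputs = outputs, seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }

  # -- simulate ------------------------------------------------------------
  sim_outputs <- c("genome.fa", "annotations_cpg.bed", "annotations_ta.bed",
                   "annotations_promoter.bed", "tss.tsv", "truth.json",
                   paste0("reads_", man$sample, ".tsv"))
  run_stage("simulate", sim_outputs, function() {
    g <- cfg$genome
    spec <- genome_spec(n_chromosomes = g$n_chromosomes,
                        chrom_length = g$chrom_length,
                        isochore_block_length = g$isochore_block_length,
                        n_cpg_islands = g$n_cpg_islands,
                        cpg_island_length = g$cpg_island_length,
                        n_TA_repeats = g$n_TA_repeats,
                        TA_repeat_length = g$TA_repeat_length,
                        n_promoters = g$n_promoters,
                        seed = cfg$seed)
    tr <- cfg$truth
    truth <- binding_truth(beta_at = tr$beta_at, gamma_open = tr$gamma_open,
                           fragment_length = tr$fragment_length,
                           fragment_sd = tr$fragment_sd,
                           gc_bias_coeffs = tr$gc_bias_coeffs,
                           copy_number = tr$copy_number)
    sim <- generate_genome(spec, truth)
    write_genome_fasta(sim$genome, pth("genome.fa"))
    write_bed(cbind(sim$annotations$cpg_island, name = "cpg_island"),
              pth("annotations_cpg.bed"))
    write_bed(cbind(sim$annotations$ta_repeat, name = "(TA)n"),
              pth("annotations_ta.bed"))
    write_bed(cbind(sim$annotations$promoter[, c("chrom", "start", "end",
                                                 "strand")],
                    name = "promoter"),
              pth("annotations_promoter.bed"))
    write_track_tsv(sim$annotations$tss, pth("tss.tsv"))
    write_truth_json(truth, pth("truth.json"))
    open_tr <- openness_track(sim$genome, sim$annotations)
    for (i in seq_len(nrow(man))) {
      rs <- simulate_sample(sim$genome, truth,
                            list(id = man$sample[i], role = man$role[i],
                                 genotype = man$genotype[i],
                                 replicate = man$replicate[i]),
                            n_reads = cfg$n_reads, seed = cfg$seed + i,
                            annotations = sim$annotations,
                            openness = open_tr)
      write_reads_tsv(rs, pth(paste0("reads_", man$sample[i], ".tsv")))
    }
  })

  load_genome <- function() {
    cn <- rep_len(cfg$truth$copy_number, cfg$genome$n_chromosomes)
    read_genome_fasta(if (isTRUE(cfg$genome$simulate)) pth("genome.fa") else
      cfg$genome$fasta, copy_number = cn)
  }
  load_reads <- function(i) {
    read_reads_tsv(pth(paste0("reads_", man$sample[i], ".tsv")),
                   sample_id = man$sample[i], role = man$role[i],
                   genotype = man$genotype[i], replicate = man$replicate[i])
  }

  # -- windows -------------------------------------------------------------
  run_stage("windows", "windows.tsv", function() {
    genome <- load_genome()
    ws <- tile_genome(genome, cfg$params$window_size)
    ws <- annotate_windows(genome, ws)
    write_track_tsv(ws, pth("windows.tsv"))
  })

  # -- quantify ------------------------------------------------------------
  ip_rows <- which(man$role == "IP")
  run_stage("quantify", c("enrichment.tsv", "delta_enrichment.tsv",
                          "fragment_lengths.tsv"), function() {
    genome <- load_genome()
    ws <- utils::read.delim(pth("windows.tsv"), stringsAsFactors = FALSE)
    tss <- utils::read.delim(pth("tss.tsv"), stringsAsFactors = FALSE)
    tracks <- list()
    flens <- data.frame(sample = character(0), fragment_length = integer(0),
                        shift = integer(0))
    for (i in ip_rows) {
      ip <- load_reads(i)
      j <- which(man$role == "input" & man$replicate == man$replicate[i])[1]
      input <- load_reads(j)
      fl <- estimate_fragment_length(ip, tss, smooth = 51L)
      flens <- rbind(flens, data.frame(sample = man$sample[i],
                                       fragment_length = fl$fragment_length,
                                       shift = fl$shift))
      tracks[[man$sample[i]]] <-
        enrichment_track(ip, input, ws, shift = fl$shift,
                         pseudocount = cfg$params$pseudocount,
                         min_mappable = cfg$params$min_mappable)
    }
    emat <- ws
    for (nm in names(tracks)) emat[[nm]] <- tracks[[nm]]$e
    write_track_tsv(emat, pth("enrichment.tsv"))
    write_track_tsv(flens, pth("fragment_lengths.tsv"))

    dmat <- ws
    for (i in ip_rows) {
      gt <- man$genotype[i]
      if (!gt %in% c("WT-Hmga1", "WT-Hmga2")) next
      mut_gt <- if (gt == "WT-Hmga1") "DBD-mutant-1" else "DBD-mutant-2"
      k <- which(man$genotype == mut_gt & man$role == "IP" &
                   man$replicate == man$replicate[i])
      if (!length(k)) next
      d <- mutant_normalize(tracks[[man$sample[i]]],
                            tracks[[man$sample[k[1]]]])
      dmat[[man$sample[i]]] <- d$e
    }
    write_track_tsv(dmat, pth("delta_enrichment.tsv"))
  })

  # -- pca -----------------------------------------------------------------
  run_stage("pca", c("pca_scores.tsv", "pca_variance.tsv"), function() {
    emat <- utils::read.delim(pth("enrichment.tsv"), stringsAsFactors = FALSE)
    samples <- man$sample[ip_rows]
    keep <- emat$mappable_fraction >= cfg$params$min_mappable
    m <- t(as.matrix(emat[keep, samples, drop = FALSE]))
    pca <- run_pca(m, at = emat$at_content[keep])
    scores <- data.frame(sample = rownames(pca$scores),
                         genotype = man$genotype[ip_rows],
                         round(pca$scores, 6))
    write_track_tsv(scores, pth("pca_scores.tsv"))
    write_track_tsv(data.frame(component = seq_along(pca$variance_fraction),
                               variance_fraction =
                                 round(pca$variance_fraction, 6)),
                    pth("pca_variance.tsv"))
  })

  # -- models --------------------------------------------------------------
  run_stage("models", c("model_ladder.tsv", "proximity.tsv"), function() {
    genome <- load_genome()
    dmat <- utils::read.delim(pth("delta_enrichment.tsv"),
                              stringsAsFactors = FALSE,
                              check.names = FALSE)
    wt <- intersect(man$sample[ip_rows], colnames(dmat))[1]
    ws <- dmat[, c("chrom", "start", "end", "mappable_fraction",
                   "at_content")]
    y <- dmat[[wt]]
    excl <- overlaps_any(ws, read_bed(pth("annotations_ta.bed"))) |
      overlaps_any(ws, read_bed(pth("annotations_cpg.bed"))) |
      ws$mappable_fraction < cfg$params$min_mappable
    split <- balanced_split(y, exclude = excl, seed = cfg$seed)
    ladder <- data.frame()
    for (k in cfg$params$kmer_k) {
      Xk <- kmer_features(genome, ws, k)
      fit <- fit_ridge(Xk[split$train, ], y[split$train],
                       folds = cfg$params$folds, seed = cfg$seed)
      ev <- evaluate(fit, Xk[split$test, ], y[split$test])
      ladder <- rbind(ladder, data.frame(
        model = paste0(k, "-mer"), k = k, r = round(ev$r, 4),
        rmsd = round(ev$rmsd, 4),
        revcomp_r = if (k >= 2) round(revcomp_consistency(fit), 4) else NA))
    }
    write_track_tsv(ladder, pth("model_ladder.tsv"))
    cpg_ov <- overlaps_any(ws, read_bed(pth("annotations_cpg.bed")))
    prox <- proximity_fit(ws, y, n_flank = cfg$params$n_flank,
                          cpg_overlap = cpg_ov,
                          min_mappable = cfg$params$min_mappable,
                          seed = cfg$seed)
    write_track_tsv(data.frame(position = -cfg$params$n_flank:
                                 cfg$params$n_flank,
                               coefficient = round(prox$coefficients, 4)),
                    pth("proximity.tsv"))
  })

  # -- repeats -------------------------------------------------------------
  run_stage("repeats", "repeat_enrichment.tsv", function() {
    genome <- load_genome()
    ta <- read_bed(pth("annotations_ta.bed"))
    ta$family <- "Simple_repeat"
    wt_i <- which(man$genotype == "WT-Hmga1" & man$role == "IP")[1]
    mut_i <- which(man$genotype == "DBD-mutant-1" & man$role == "IP" &
                     man$replicate == man$replicate[wt_i])[1]
    in_i <- which(man$role == "input" &
                    man$replicate == man$replicate[wt_i])[1]
    flens <- utils::read.delim(pth("fragment_lengths.tsv"))
    sh <- flens$shift[flens$sample == man$sample[wt_i]]
    filt <- filter_repeats(ta, genome)
    if (!nrow(filt)) {
      # exact tandem arrays are inherently multi-mapping: every instance can
      # fail the mappable-fraction filter, leaving an empty table
      message("no repeat instance passes the filters; writing empty table")
      tab <- data.frame(name = character(0), family = character(0),
                        n_instances = integer(0), e_wt = numeric(0),
                        e_mutant = numeric(0), delta_e = numeric(0),
                        mean_at = numeric(0), low_coverage = logical(0))
    } else {
      tab <- repeat_enrichment(load_reads(wt_i), load_reads(in_i),
                               load_reads(mut_i), load_reads(in_i),
                               filt, genome, shift = sh,
                               pseudocount = cfg$params$pseudocount)
      tab$e_wt <- round(tab$e_wt, 4)
      tab$e_mutant <- round(tab$e_mutant, 4)
      tab$delta_e <- round(tab$delta_e, 4)
      tab$mean_at <- round(tab$mean_at, 4)
    }
    write_track_tsv(tab, pth("repeat_enrichment.tsv"))
  })

  # -- cnv -----------------------------------------------------------------
  run_stage("cnv", "cnv_ratios.tsv", function() {
    genome <- load_genome()
    ins <- which(man$role == "input")
    ga <- lapply(ins[1], load_reads)
    gb <- lapply(ins[length(ins)], load_reads)
    res <- cnv_ratios(ga, gb, genome,
                      window_size = cfg$params$cnv_window_size,
                      span = cfg$params$loess_span)
    res$mean_a <- round(res$mean_a, 4)
    res$mean_b <- round(res$mean_b, 4)
    res$log2_ratio <- round(res$log2_ratio, 4)
    write_track_tsv(res, pth("cnv_ratios.tsv"))
  })

  manifest$seed <- cfg$seed
  manifest$finished <- TRUE
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

# configuration as plain lists for JSON provenance
prune_config <- function(cfg) {
  out <- unclass(cfg)
  out$samples <- as.list(out$samples)
  out
}

# TRUE for every window overlapping any interval in `features`
overlaps_any <- function(windows, features) {
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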