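test_that("generated genomes are deterministic and hit blockwise AT targets", {
  spec <- genome_spec(n_chromosomes = 2L, chrom_length = 1e5,
                      isochore_block_length = 1e4,
                      n_cpg_islands = 0L, n_TA_repeats = 0L, n_promoters = 0L,
                      seed = 1L)
  sim1 <- generate_genome(spec)
  sim2 <- generate_genome(spec)
  expect_identical(as.character(sim1$genome$seq), as.character(sim2$genome$seq))
  expect_identical(sim1$annotations, sim2$annotations)

  blk <- sim1$annotations$blocks
  measured <- at_content(window_sequences(sim1$genome, blk))
  expect_true(all(abs(measured - blk$at_target) <= 0.03))
  expect_true(all(blk$at_target >= 0.35 & blk$at_target <= 0.75))
})

test_that("an all-AT block contains only A and T", {
  spec <- genome_spec(n_chromosomes = 1L, chrom_length = 5000L,
                      isochore_block_length = 5000L, at_levels = 1.0,
                      n_cpg_islands = 0L, n_TA_repeats = 0L, n_promoters = 0L,
                      seed = 2L)
  sim <- generate_genome(spec)
  s <- as.character(sim$genome$seq[[1]])
  expect_identical(at_content(s), 1.0)
  expect_false(grepl("[CG]", s))
})

test_that("CpG islands are GC- and CpG-rich; (TA)n repeats are exact arrays", {
  sim <- panel_fixture()
  isl <- window_sequences(sim$genome, sim$annotations$cpg_island)
  expect_true(all(1 - at_content(isl) >= 0.6))
  cpg_freq <- function(ss) {
    d <- Biostrings::dinucleotideFrequency(ss)
    sum(d[, "CG"]) / sum(d)
  }
  bg <- window_sequences(sim$genome,
                         data.frame(chrom = "chr1", start = 0, end = 1e5))
  expect_gt(cpg_freq(isl), 2 * cpg_freq(bg))

  ta <- window_sequences(sim$genome, sim$annotations$ta_repeat)
  for (s in as.character(ta)) {
    expect_identical(s, paste(rep_len(c("T", "A"), nchar(s)), collapse = ""))
  }
})

test_that("infeasible feature placement raises an error", {
  expect_error(
    genome_spec(n_chromosomes = 1L, chrom_length = 1e4,
                n_cpg_islands = 20L, cpg_island_length = 1000L,
                n_TA_repeats = 0L, n_promoters = 0L, seed = 1L),
    "infeasible|capacity|smaller"
  )
})

test_that("read simulation conserves counts, strand balance and determinism", {
  sim <- panel_fixture()
  ss <- list(id = "s1", role = "IP", genotype = "WT-Hmga1", replicate = "a")
  rs1 <- simulate_sample(sim$genome, sim$truth, ss, 5e4, seed = 9,
                         annotations = sim$annotations)
  rs2 <- simulate_sample(sim$genome, sim$truth, ss, 5e4, seed = 9,
                         annotations = sim$annotations)
  expect_identical(rs1$reads, rs2$reads)
  expect_identical(n_reads(rs1), 5e4L + 0L)
  n_plus <- sum(rs1$reads$strand == "+")
  expect_lt(abs(n_plus - 2.5e4), 3 * sqrt(5e4 * 0.25))
  lens <- sim$genome$lengths[rs1$reads$chrom]
  expect_true(all(rs1$reads$pos >= 0 & rs1$reads$pos < lens))
})

test_that("unbiased sampling is uniform (chi-square goodness of fit)", {
  spec <- genome_spec(n_chromosomes = 1L, chrom_length = 2e5,
                      isochore_block_length = 1e4,
                      n_cpg_islands = 0L, n_TA_repeats = 0L, n_promoters = 0L,
                      seed = 4L)
  truth <- binding_truth(beta_at = 0, gamma_open = 0,
                         gc_bias_coeffs = c(0, 0))
  sim <- generate_genome(spec, truth)
  rs <- simulate_sample(sim$genome, truth,
                        list(id = "u", role = "IP", genotype = "WT-Hmga1",
                             replicate = "a"),
                        1e6, seed = 5)
  # interior 1 kb bins only: chromosome ends are depleted by the
  # fragment-interior constraint on start positions
  bins <- findInterval(rs$reads$pos, seq(0, 2e5, by = 1000))
  counts <- tabulate(bins, nbins = 200)[2:199]
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("AT weighting gives the closed-form read-density ratio", {
  # two 50 kb blocks at AT 0.8 and 0.4; weight ratio exp(beta * dAT) = 3
  spec <- genome_spec(n_chromosomes = 1L, chrom_length = 1e5,
                      isochore_block_length = 5e4, at_levels = c(0.8, 0.4),
                      n_cpg_islands = 0L, n_TA_repeats = 0L, n_promoters = 0L,
                      seed = 6L)
  truth <- binding_truth(beta_at = log(3) / 0.4, gamma_open = 0,
                         gc_bias_coeffs = c(0, 0))
  sim <- generate_genome(spec, truth)
  rs <- simulate_sample(sim$genome, truth,
                        list(id = "w", role = "IP", genotype = "WT-Hmga1",
                             replicate = "a"),
                        2e5, seed = 7)
  # fragment-interior positions only, away from the block boundary
  pos <- rs$reads$pos
  n1 <- sum(pos >= 1000 & pos < 49000)
  n2 <- sum(pos >= 51000 & pos < 99000)
  blk_at <- at_content(window_sequences(sim$genome, sim$annotations$blocks))
  expected <- exp(truth$beta_at * (blk_at[1] - blk_at[2]))
  ratio <- n1 / n2
  se <- ratio * sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(ratio - expected), 3 * se + 0.02 * expected)
})

test_that("chromosome sampling mass follows length x copy number", {
  spec <- genome_spec(n_chromosomes = 3L, chrom_length = 1e5,
                      isochore_block_length = 1e4,
                      n_cpg_islands = 0L, n_TA_repeats = 0L, n_promoters = 0L,
                      seed = 8L)
  truth <- binding_truth(beta_at = 0, gamma_open = 0,
                         gc_bias_coeffs = c(0, 0),
                         copy_number = c(1L, 2L, 1L))
  sim <- generate_genome(spec, truth)
  rs <- simulate_sample(sim$genome, truth,
                        list(id = "c", role = "input", genotype = "WT-Hmga1",
                             replicate = "a"),
                        2e5, seed = 9)
  share <- mean(rs$reads$chrom == "chr2")
  se <- sqrt(0.5 * 0.5 / 2e5)
  expect_lt(abs(share - 0.5), 3 * se)
})

test_that("WT read density is monotone in window AT content", {
  sim <- panel_fixture()
  rs <- simulate_sample(sim$genome, sim$truth,
                        list(id = "w", role = "IP", genotype = "WT-Hmga1",
                             replicate = "a"),
                        1e6, seed = 10, annotations = sim$annotations)
  ws <- window_at_content(sim$genome, tile_genome(sim$genome, 1000))
  counts <- count_reads(rs, ws, shift = 75)
  dec <- cut(ws$at_content, stats::quantile(ws$at_content, 0:10 / 10),
             include.lowest = TRUE)
  means <- tapply(counts, dec, mean)
  expect_true(all(diff(means) > 0))
})

test_that("unknown sample labels are rejected", {
  sim <- panel_fixture()
  expect_error(simulate_sample(sim$genome, sim$truth,
                               list(id = "x", role = "IP",
                                    genotype = "supermutant", replicate = "a"),
                               10, seed = 1), "genotype")
  expect_error(simulate_sample(sim$genome, sim$truth,
                               list(id = "x", role = "control",
                                    genotype = "GFP", replicate = "a"),
                               10, seed = 1), "role")
})

test_that("FASTA, BED, TSV and SAM round-trips preserve the data", {
  sim <- panel_fixture()
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fa")
  write_genome_fasta(sim$genome, fa)
  g2 <- read_genome_fasta(fa)
  expect_identical(as.character(g2$seq), as.character(sim$genome$seq))
  # rewriting gives byte-identical output
  fa2 <- file.path(td, "g2.fa")
  write_genome_fasta(g2, fa2)
  expect_identical(readLines(fa), readLines(fa2))

  bed <- file.path(td, "cpg.bed")
  write_bed(sim$annotations$cpg_island, bed)
  b <- read_bed(bed)
  expect_identical(b[, c("chrom", "start", "end")],
                   sim$annotations$cpg_island[, c("chrom", "start", "end")])

  rs <- simulate_sample(sim$genome, sim$truth,
                        list(id = "s", role = "IP", genotype = "WT-Hmga1",
                             replicate = "a"),
                        500, seed = 2, annotations = sim$annotations)
  tsv <- file.path(td, "r.tsv")
  write_reads_tsv(rs, tsv)
  rs_t <- read_reads_tsv(tsv, sample_id = "s")
  expect_identical(rs_t$reads, rs$reads)

  sam <- file.path(td, "r.sam")
  write_reads_sam(rs, sim$genome, sam)
  rs_s <- read_reads_sam(sam, sample_id = "s")
  reset <- function(df) `rownames<-`(df, NULL)
  ord <- order(rs$reads$chrom, rs$reads$pos, rs$reads$strand)
  ord2 <- order(rs_s$reads$chrom, rs_s$reads$pos, rs_s$reads$strand)
  expect_identical(reset(rs_s$reads[ord2, ]), reset(rs$reads[ord, ]))
})
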