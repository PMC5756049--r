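# atchip

Genome-wide quantification and sequence modelling of dispersed,
AT-content-driven protein–DNA binding from ChIP-seq with paired input and
DNA-binding-domain-mutant controls.

Proteins such as the high-mobility-group Hmga1/Hmga2 bind AT-rich DNA
through minor-groove AT-hooks and occupy the genome broadly, without focal
peaks. `atchip` implements the full analysis such data needs, for
computational biologists working on chromatin:

* **Enrichment.** Reads are counted in tiling windows after shifting by
  half the estimated fragment length (`estimate_fragment_length()` scans
  the shift minimizing the RMSD between promoter-anchored same- and
  opposite-strand coverage profiles). Per-window enrichment is

  ```
  e = log2(ns_IP + 8) − log2(ns_input + 8),   ns = min(N_IP, N_input) · n / N
  ```

  and the mutant-normalized track Δe = e_WT − e_mutant cancels
  accessibility and sequencing bias. Analyses are restricted to windows
  with ≥ 80% uniquely mappable 50-mers.
* **Structure.** `run_pca()` decomposes window-level enrichments over
  samples (mean-centered, sign-fixed so PC1 tracks AT content);
  `correlate_tracks()`, `chromosome_track()` and `average_profile()` cover
  correlation matrices, chromosome-scale display tracks and anchored
  metaprofiles.
* **Sequence models.** A ladder of ridge regressions of Δe on window
  sequence features — k-mer frequencies (k = 1..4), AT-stretch (W-run)
  counts, binned pentamer DNA-shape features — with balanced sampling over
  the enrichment range, 10-fold cross-validation under the one-standard-
  error rule, held-out Pearson r / RMSD, and a reverse-complement
  consistency check; plus an OLS proximity model asking whether
  neighbouring windows' AT content adds predictive power.
* **Repeats and karyotype.** Aggregate enrichment per repeat name after
  length/mappability/instance filtering; per-chromosome GC-loess-corrected
  read-depth ratios between two input groups (`cnv_ratios()`).
* **Synthetic data.** `generate_genome()` / `simulate_sample()` produce
  isochore-structured genomes (CpG islands, (TA)n arrays, promoters) and
  aligned reads under a known binding truth — wild-type weight
  `exp(β_AT · AT_fraction)`, openness-biased controls, GC-biased inputs —
  so every stage is testable without external data.

## Worked example

```r
library(atchip)

sim <- generate_genome(genome_spec(n_chromosomes = 2, chrom_length = 3e5, seed = 3))
ws  <- annotate_windows(sim$genome, tile_genome(sim$genome, 1000))

mk <- function(id, role, gt) {
  simulate_sample(sim$genome, sim$truth,
                  list(id = id, role = role, genotype = gt, replicate = "a"),
                  n_reads = 2e5, seed = match(id, c("wt", "in", "mut")),
                  annotations = sim$annotations)
}
wt  <- mk("wt",  "IP",    "WT-Hmga1")
inp <- mk("in",  "input", "WT-Hmga1")
mut <- mk("mut", "IP",    "DBD-mutant-1")

d <- mutant_normalize(enrichment_track(wt,  inp, ws, shift = 75),
                      enrichment_track(mut, inp, ws, shift = 75))
cor(d$e, ws$at_content, use = "complete.obs", method = "spearman")
#> [1] 0.8563138
```

A Spearman correlation near 0.86 between the mutant-normalized enrichment
and window AT content says the simulated wild-type occupancy is, as
constructed, almost entirely a read-out of local base composition — the
same signature the analysis is designed to detect in real data. The
end-to-end demonstration (simulation → windows → enrichment → PCA →
models → repeats → copy number, with a provenance manifest) is

```r
run_pipeline(validate_config(list()), "demo_run")
```

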