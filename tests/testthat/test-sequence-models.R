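test_that("k-mer features match enumeration and the dictionary oracle", {
  g <- tiny_genome(chr1 = "ACGTACGT")
  w1 <- data.frame(chrom = "chr1", start = 0L, end = 4L)
  f1 <- kmer_features(g, w1, 1, frequencies = FALSE)
  expect_identical(as.integer(f1[1, c("A", "C", "G", "T")]), rep(1L, 4))

  g2 <- tiny_genome(chr1 = "AATT")
  f2 <- kmer_features(g2, tile_genome(g2, 4), 2, frequencies = FALSE)
  expect_identical(as.integer(f2[1, c("AA", "AT", "TT")]), rep(1L, 3))
  expect_identical(sum(f2), 3L)  # all other dimers zero

  set.seed(31)
  g3 <- tiny_genome(chr1 = random_seq(20000))
  ws <- tile_genome(g3, 200)
  for (k in c(1L, 3L)) {
    got <- kmer_features(g3, ws, k, frequencies = FALSE)
    seqs <- as.character(window_sequences(g3, ws))
    for (i in c(1, 50, 100)) {
      want <- oracle_kmer_counts(seqs[i], k)
      expect_identical(as.integer(got[i, names(want)]),
                       as.integer(want))
    }
    # counts sum to valid positions; frequencies to 1
    expect_true(all(rowSums(got) == 200 - k + 1))
    fr <- kmer_features(g3, ws, k)
    expect_equal(unname(rowSums(fr)), rep(1, nrow(ws)), tolerance = 1e-12)
  }
})

test_that("W-stretch features tally maximal runs by exact length", {
  g <- tiny_genome(chr1 = "TTAAGGCGCAGTGA")
  ws <- data.frame(chrom = "chr1", start = c(0L, 5L, 9L),
                   end = c(5L, 9L, 14L))
  s <- stretch_features(g, ws)
  # "TTAAG": one run of 4; "GCGC": none; "AGTGA": three runs of 1
  expect_identical(as.integer(s[1, ]), c(0L, 0L, 0L, 1L))
  expect_identical(sum(s[2, ]), 0L)
  expect_identical(as.integer(s[3, c("W1")]), 3L)
  expect_identical(sum(s[3, -1]), 0L)

  set.seed(32)
  g2 <- tiny_genome(chr1 = random_seq(10000))
  ws2 <- tile_genome(g2, 100)
  s2 <- stretch_features(g2, ws2)
  seqs <- as.character(window_sequences(g2, ws2))
  for (i in c(1, 42, 100)) {
    expect_identical(as.integer(s2[i, ]),
                     oracle_stretch_counts(seqs[i], ncol(s2)))
  }
  # conservation: sum(length * count) equals the number of W bases
  wcount <- rowSums(Biostrings::letterFrequency(
    window_sequences(g2, ws2), letters = c("A", "T")))
  expect_equal(unname(as.numeric(s2 %*% seq_len(ncol(s2)))), unname(wcount))
})

test_that("shape features partition positions into bins", {
  set.seed(33)
  g <- tiny_genome(chr1 = random_seq(5000))
  ws <- tile_genome(g, 500)
  sf <- shape_features(g, ws)
  expect_identical(ncol(sf), 80L)
  # conservation per (base, feature): bin counts sum to the number of
  # positions with that central base and a full pentamer context
  seqs <- as.character(window_sequences(g, ws))
  for (b in c("A", "C", "G", "T")) {
    centers <- vapply(seqs, function(s) {
      sum(strsplit(substr(s, 3, nchar(s) - 2), "")[[1]] == b)
    }, numeric(1))
    for (f in c("MGW", "ProT", "HelT", "Roll")) {
      cols <- grep(paste0("^", b, "_", f, "_"), colnames(sf))
      expect_equal(unname(rowSums(sf[, cols])), unname(centers))
    }
  }

  # degenerate constant table: all mass in a single bin
  tab <- synthetic_shape_table()
  tab[, c("MGW", "ProT", "HelT", "Roll")] <-
    list(5, -7, 34, 2)
  sf2 <- shape_features(g, ws, table = tab)
  nz <- colSums(sf2) > 0
  per_bf <- table(sub("_b[0-9]$", "", colnames(sf2)[nz]))
  expect_true(all(per_bf == 1))

  expect_error(shape_features(g, ws, table = tab[-1, ]), "does not cover")
})

test_that("hand-computed shape bins on a toy window agree", {
  # window "ACGTACG": pentamers ACGTA (center G), CGTAC (T), GTACG (A)
  g <- tiny_genome(chr1 = "ACGTACG")
  ws <- data.frame(chrom = "chr1", start = 0L, end = 7L)
  tab <- synthetic_shape_table()
  sf <- shape_features(g, ws, table = tab)
  expect_identical(sum(sf), 12L)  # 3 positions x 4 features
  expect_identical(sum(sf[, grep("^G_", colnames(sf))]), 4L)
  expect_identical(sum(sf[, grep("^T_", colnames(sf))]), 4L)
  expect_identical(sum(sf[, grep("^A_", colnames(sf))]), 4L)
  expect_identical(sum(sf[, grep("^C_", colnames(sf))]), 0L)
})

test_that("balanced sampling flattens the 12-bin histogram", {
  # 12 separated clusters, one per bin: the tail clusters hold exactly the
  # 2.5% tails (5 of 181 values each) so that the quantile edges fall in
  # the gaps; the smallest bin has 5 members
  set.seed(34)
  y <- c(runif(5, 0, 0.5),
         unlist(lapply(1:10, function(b) {
           b * 10 + runif(if (b == 10) 18 else 17, -0.5, 0.5)
         })),
         runif(5, 110, 110.5))
  sp <- balanced_split(y, seed = 1)
  expect_identical(sp$n, 5L)
  expect_identical(length(sp$train), 30L)
  expect_identical(length(sp$test), 30L)
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  sampled_bins <- sp$bin[as.character(c(sp$train, sp$test))]
  expect_true(all(table(sampled_bins) == 5L))

  sp2 <- balanced_split(y, seed = 1)
  expect_identical(sp$train, sp2$train)
  expect_identical(sp$test, sp2$test)

  expect_error(balanced_split(rep(1, 100)), "12 distinct")
  # a hole in the middle of the range leaves an inner bin empty
  y_gap <- c(runif(50, 0, 1), runif(50, 9, 10), 4)
  expect_error(balanced_split(y_gap), "empty")
})

test_that("ridge fits obey closed forms and penalty limits", {
  set.seed(35)
  # orthonormal design: beta(lambda) = X'y / (1 + lambda)
  X <- qr.Q(qr(matrix(rnorm(400), 100, 4)))
  colnames(X) <- paste0("f", 1:4)
  y <- drop(X %*% c(2, -1, 0.5, 0) + rnorm(100, 0, 0.01))
  fit <- fit_ridge(X, y, folds = 5, standardize = FALSE,
                   lambda = c(0.3, 0.2))
  manual <- unname(drop(crossprod(X, y))) / (1 + fit$lambda)
  expect_equal(unname(fit$coefficients), manual, tolerance = 1e-8)

  # generic design against the normal-equation oracle
  X2 <- matrix(rnorm(500), 100, 5)
  colnames(X2) <- paste0("g", 1:5)
  y2 <- rnorm(100)
  l0 <- 3.7
  fit2 <- fit_ridge(X2, y2, folds = 5, standardize = FALSE,
                    lambda = c(l0, l0 / 2))
  want <- unname(drop(solve(crossprod(X2) + fit2$lambda * diag(5),
                            crossprod(X2, y2))))
  expect_equal(unname(fit2$coefficients), want, tolerance = 1e-8)

  # infinite-penalty limit: coefficients vanish, intercept -> mean(y)
  fit3 <- fit_ridge(X2, y2, folds = 5, intercept = TRUE,
                    lambda = c(1e10, 5e9))
  expect_lt(max(abs(fit3$coefficients)), 1e-6)
  expect_equal(fit3$intercept, mean(y2), tolerance = 1e-12)

  # coefficient norm shrinks monotonically along the penalty path
  norms <- vapply(10^seq(-2, 4, length.out = 7), function(l) {
    f <- fit_ridge(X2, y2, folds = 5, standardize = FALSE,
                   lambda = c(l, l / 2))
    sqrt(sum(f$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))

  expect_error(fit_ridge(X2, y2, folds = 200), "folds")
})

test_that("ridge recovers known coefficients from noisy data", {
  set.seed(36)
  X <- matrix(rnorm(5000 * 4), 5000, 4)
  colnames(X) <- paste0("b", 1:4)
  beta <- c(1.5, -0.7, 0.2, 0)
  y <- drop(X %*% beta + rnorm(5000, 0, 0.1))
  fit <- fit_ridge(X, y, seed = 2)
  expect_true(all(abs(fit$coefficients_raw - beta) < 0.1))
  # CV agreement: glmnet as an independent cross-check at the same penalty
  gl <- glmnet::glmnet(X, y, alpha = 0, intercept = FALSE,
                       standardize = FALSE,
                       lambda = fit$lambda / 5000, thresh = 1e-12)
  ours <- fit_ridge(X, y, standardize = FALSE, folds = 5,
                    lambda = c(fit$lambda, fit$lambda / 2))
  expect_equal(unname(ours$coefficients),
               unname(drop(as.matrix(gl$beta))), tolerance = 0.02)
})

test_that("model evaluation reports Pearson r and RMSD", {
  fake_fit <- structure(list(coefficients = c(x = 1), center = c(x = 0),
                             scale = c(x = 1), intercept = 0,
                             has_intercept = FALSE),
                        class = "ridge_fit")
  X <- matrix(c(0, 1, 1), ncol = 1, dimnames = list(NULL, "x"))
  ev <- evaluate(fake_fit, X, c(0, 1, 2))
  expect_equal(ev$rmsd, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(ev$r, sqrt(3) / 2, tolerance = 1e-12)

  X2 <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(NULL, "x"))
  ev_perfect <- evaluate(fake_fit, X2, c(0, 1, 2))
  expect_equal(ev_perfect$r, 1)
  expect_equal(ev_perfect$rmsd, 0)
  ev_neg <- evaluate(fake_fit, X2, c(2, 1, 0))
  expect_equal(ev_neg$r, -1)
  ev_flat <- evaluate(fake_fit, matrix(rep(1, 3), ncol = 1,
                                       dimnames = list(NULL, "x")),
                      c(0, 1, 2))
  expect_true(is.na(ev_flat$r))
})

test_that("reverse-complement pairing of coefficients behaves", {
  dimers <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  rc <- stats::setNames(vapply(strsplit(chartr("ACGT", "TGCA", dimers), ""),
                               function(x) paste(rev(x), collapse = ""), ""),
                        dimers)
  b <- rnorm(16)
  names(b) <- dimers
  sym <- stats::setNames((b + unname(b[rc])) / 2, dimers)  # symmetrized
  fit_sym <- structure(list(coefficients = sym), class = "ridge_fit")
  expect_equal(revcomp_consistency(fit_sym), 1, tolerance = 1e-12)
  # palindromes sit on the identity line by self-pairing
  pal <- dimers[dimers == rc]
  expect_true(all(sym[pal] == sym[rc[pal]]))
})

test_that("proximity model recovers a purely local simulated truth", {
  set.seed(37)
  lv <- runif(1000, 0, 1)
  spec <- genome_spec(n_chromosomes = 2L, chrom_length = 5e5,
                      isochore_block_length = 1000L, at_levels = lv,
                      n_cpg_islands = 0L, n_TA_repeats = 0L,
                      n_promoters = 0L, seed = 5L)
  sim <- generate_genome(spec)
  ws <- window_at_content(sim$genome, tile_genome(sim$genome, 1000))
  ws$mappable_fraction <- 1
  y <- 2 * ws$at_content + rnorm(nrow(ws), 0, 0.2)
  pf <- proximity_fit(ws, y, n_flank = 3, balance = FALSE, seed = 7)
  expect_gt(pf$coefficients[["AT_0"]], 1.8)
  expect_lt(pf$coefficients[["AT_0"]], 2.2)
  expect_true(all(abs(pf$coefficients[names(pf$coefficients) != "AT_0"]) < 0.1))
  expect_lt(pf$test_r[["flank3"]] - pf$test_r[["flank0"]], 0.02)

  # independent response: everything near zero
  y0 <- rnorm(nrow(ws), 0, 0.5)
  pf0 <- proximity_fit(ws, y0, n_flank = 3, balance = FALSE, seed = 7)
  expect_true(all(abs(pf0$coefficients) < 0.25))
  expect_lt(abs(pf0$test_r[["flank0"]]), 0.15)

  ws_const <- ws
  ws_const$at_content <- 0.5
  expect_error(proximity_fit(ws_const, y, balance = FALSE), "collinear")
})
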