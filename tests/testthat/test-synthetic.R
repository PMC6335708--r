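test_that("the generator is a deterministic function of the configuration", {
  cfg <- synthetic_config(n_coding = 25, n_noncoding = 15,
                          n_planted_pairs = 4, n_planted_de = 4, seed = 77)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$counts, b$counts)
  expect_identical(a$de, b$de)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(a, d1); write_study(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6), label = f)
  }
})

test_that("configuration invariants are enforced", {
  expect_equal(sum(default_replicate_layout()$n_reps), 16)
  cfg <- synthetic_config(n_coding = 5, n_noncoding = 0,
                          n_planted_pairs = 0, n_planted_de = 2, seed = 1)
  st <- simulate_sequences(cfg)
  expect_length(st$truth$true_lncrna_ids, 0)
  expect_error(
    synthetic_config(transcript_length_range = c(150, 400)),
    "infeasible")
  expect_error(synthetic_config(n_coding = 5, n_noncoding = 5,
                                n_planted_pairs = 9), "planted_pairs")
})

test_that("sequence designs are separable by construction", {
  cfg <- synthetic_config(n_coding = 40, n_noncoding = 40,
                          n_planted_pairs = 5, n_planted_de = 5, seed = 31)
  st <- simulate_sequences(cfg)
  tx <- st$transcripts
  nc <- tx[tx$transcript_id %in% st$truth$true_lncrna_ids, ]
  cod <- tx[tx$transcript_id %in% st$truth$true_coding_ids, ]
  # noncoding: >= 200 nt and longest ORF < 100 aa by the exhaustive oracle
  expect_true(all(nchar(nc$sequence) >= 200))
  expect_true(all(vapply(nc$sequence, orf_oracle, integer(1)) < 100))
  # coding: embedded ORF >= 100 aa and a strong homology hit
  expect_true(all(vapply(cod$sequence, orf_oracle, integer(1)) >= 100))
  strong <- st$homology_hits$query_id[st$homology_hits$evalue <= 1e-6]
  expect_true(all(cod$transcript_id %in% strong))
  # noncoding never hit at or below any sensible exclusion cutoff
  nc_hits <- st$homology_hits[st$homology_hits$query_id %in% nc$transcript_id, ]
  expect_true(all(nc_hits$evalue > 1e-2))
  # sequence length always equals summed exon length
  expect_equal(nchar(tx$sequence), tx$length_nt)
})

test_that("replicate layout produces the 16-library design", {
  st <- small_study()
  libs <- st$libraries
  expect_equal(nrow(libs), 16)
  expect_equal(sum(libs$condition == "control" & libs$time_h == 4), 3)
  expect_equal(sum(libs$condition == "infected" & libs$time_h == 12), 2)
  expect_false(anyDuplicated(libs[c("condition", "time_h", "replicate")]) > 0)
  expect_identical(setdiff(names(st$counts), "transcript_id"),
                   libs$library_id)
})

test_that("planted pairs reach correlation 1 in the near-noiseless limit", {
  cfg <- synthetic_config(n_coding = 30, n_noncoding = 20,
                          n_planted_pairs = 8, n_planted_de = 0,
                          planted_latent_correlation = 1.0,
                          nb_dispersion = 1e-4, seed = 5)
  st <- simulate_study(cfg)
  m <- log1p(as.matrix(st$counts[-1]))
  rownames(m) <- st$counts$transcript_id
  pp <- st$truth$planted_pairs
  r <- mapply(function(l, q) cor(m[l, ], m[q, ]), pp$lncrna_id, pp$mrna_id)
  expect_true(all(r > 1 - 0.02))
})

test_that("null pair correlations follow the t tail", {
  cfg <- synthetic_config(n_coding = 100, n_noncoding = 20,
                          n_planted_pairs = 0, n_planted_de = 0, seed = 13)
  st <- simulate_study(cfg)
  m <- log1p(as.matrix(st$counts[-1]))
  rownames(m) <- st$counts$transcript_id
  lnc <- m[st$truth$true_lncrna_ids, ]
  mrna <- m[st$truth$true_coding_ids, ]
  r <- abs(cor(t(lnc), t(mrna)))
  n <- ncol(m)
  thr <- 0.5
  p0 <- 2 * pt(-thr * sqrt((n - 2) / (1 - thr^2)), n - 2)
  phat <- mean(r >= thr)
  se <- sqrt(p0 * (1 - p0) / length(r))
  expect_lt(abs(phat - p0), 3 * se)
})

test_that("planted DE transcripts appear with their planted direction", {
  cfg <- synthetic_config(n_coding = 200, n_noncoding = 100,
                          n_planted_pairs = 20, n_planted_de = 20,
                          planted_lfc = -2, seed = 8)
  st <- simulate_study(cfg)
  sub <- st$de[match(st$truth$planted_de$transcript_id,
                     st$de$transcript_id), ]
  expect_true(all(sub$direction == "down"))
  expect_true(all(sub$log2fc < 0))
  # DERecord invariant holds on the whole table
  expect_identical(st$de$direction,
                   ifelse(st$de$fdr <= 0.05 & st$de$log2fc > 0, "up",
                          ifelse(st$de$fdr <= 0.05 & st$de$log2fc < 0,
                                 "down", "ns")))
})

test_that("AS injection creates loci differing by exactly one event", {
  n_by_mode <- setNames(c(2L, 1L, 1L, 1L, 1L),
                        c("intron_retention", "exon_skipping",
                          "alt_3_acceptor", "alt_5_donor",
                          "mutually_exclusive_exon"))
  cfg <- synthetic_config(n_coding = 10, n_noncoding = 5,
                          n_planted_pairs = 2, n_planted_de = 2,
                          as_events_per_mode = n_by_mode, seed = 3)
  st <- simulate_sequences(cfg)
  inj <- st$transcripts[st$transcripts$chrom == "chrAS", ]
  expect_equal(nrow(inj), 2L * sum(n_by_mode))
  ev <- find_as_events(inj)
  expect_equal(nrow(ev), sum(n_by_mode))
  expect_equal(sort(table(ev$mode))[["intron_retention"]], 2L)
  # injected isoforms carry valid sequences and are part of the truth
  expect_true(all(nchar(inj$sequence) == inj$length_nt))
  expect_true(all(inj$transcript_id %in% st$truth$true_lncrna_ids))
})
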