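test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(10, 20, 30, 40), ncol = 1)
  two <- cbind(m, m)
  colnames(two) <- c("A", "B")
  norm <- normalize_counts(expr_tbl(two, libs = c("A", "B")))
  expect_equal(norm$size_factors$size_factor, c(1, 1))

  # library B = 2x library A -> factors (1/sqrt(2), sqrt(2))
  twox <- cbind(m, 2 * m)
  colnames(twox) <- c("A", "B")
  norm <- normalize_counts(expr_tbl(twox, libs = c("A", "B")))
  expect_equal(norm$size_factors$size_factor, c(1 / sqrt(2), sqrt(2)))

  # post-normalization the median ratio of each library to the reference is 1
  set.seed(6)
  raw <- matrix(rnbinom(200 * 6, mu = 100, size = 5), ncol = 6) + 1
  sf <- c(0.5, 1, 2, 1.5, 0.8, 1.2)
  counts <- expr_tbl(sweep(raw, 2, sf, "*"))
  norm <- normalize_counts(counts)
  nm <- as.matrix(norm$normalized[-1])
  raw_m <- as.matrix(counts[-1])
  ref <- exp(rowMeans(log(raw_m)))      # reference of the raw matrix
  med_ratio <- apply(nm / ref, 2, median)
  expect_equal(unname(med_ratio), rep(1, 6), tolerance = 1e-12)

  zero <- expr_tbl(matrix(c(0, 5, 5, 0), 2))
  expect_error(normalize_counts(zero), "positive counts")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  # odd row count: the median of ratios and the exponentiated median of
  # log ratios then coincide exactly
  m <- matrix(rnbinom(501 * 8, mu = 80, size = 3), ncol = 8) + 1
  colnames(m) <- sprintf("lib%d", 1:8)
  ours <- normalize_counts(expr_tbl(m))$size_factors$size_factor
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("pearson matches hand values and the definitional oracle", {
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1.0)
  expect_equal(pearson(c(1, 2, 3, 4), -c(1, 2, 3, 4)), -1.0)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(16); y <- rnorm(16)
    expect_equal(pearson(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  }
  # invariances: positive affine transform; antisymmetry under negation
  x <- rnorm(16); y <- rnorm(16)
  expect_equal(pearson(2 * x + 7, y), pearson(x, y), tolerance = 1e-12)
  expect_equal(pearson(-x, y), -pearson(x, y), tolerance = 1e-12)
  expect_warning(r <- pearson(rep(1, 5), rnorm(5)),
                 class = "lncnet_undefined_correlation")
  expect_true(is.na(r))
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("pcc_pvalue follows the t approximation with its closed forms", {
  expect_equal(pcc_pvalue(0, 10), 1)
  expect_equal(pcc_pvalue(1, 10), 0)
  # df = 2 closed form: p = 1 - t/sqrt(2 + t^2); r = 0.8, n = 4 -> 0.2
  expect_equal(pcc_pvalue(0.8, 4), 0.2, tolerance = 1e-12)
  # symmetric in the sign of r
  expect_equal(pcc_pvalue(-0.8, 4), pcc_pvalue(0.8, 4))
  # regression against the standard test statistic
  set.seed(3)
  x <- rnorm(16); y <- rnorm(16)
  ct <- cor.test(x, y)
  expect_equal(pcc_pvalue(unname(ct$estimate), 16), ct$p.value,
               tolerance = 1e-12)
  expect_error(pcc_pvalue(0.5, 2), "n")
  expect_error(pcc_pvalue(1.2, 10), "\\[-1, 1\\]")
})

test_that("bh_adjust is the exact step-up procedure", {
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_edges applies both thresholds on raw p-values", {
  n <- 16
  set.seed(42)
  base <- rnorm(n)
  mk <- function(target_r) {
    # construct y with exact sample correlation target_r to base
    z1 <- scale(base)[, 1]
    raw <- rnorm(n)
    z2 <- scale(resid(lm(raw ~ z1)))[, 1]
    target_r * z1 + sqrt(1 - target_r^2) * z2
  }
  lnc <- expr_tbl(rbind(base), ids = "lnc1")
  mr <- expr_tbl(rbind(mk(0.96), mk(0.94), mk(0.30)),
                 ids = c("hi", "mid", "lo"))
  cfg <- coexpression_config(log_transform = FALSE)
  edges <- call_edges(lnc, mr, cfg)
  expect_equal(edges$mrna_id, "hi")     # 0.94 fails |r| despite tiny p
  expect_equal(edges$pcc, 0.96, tolerance = 1e-10)
  expect_lt(edges$pvalue, 0.05)

  # |r| above threshold but p too large: n = 3, r = 0.96 -> p ~ 0.18
  x3 <- c(0, 1, 2)
  z1 <- scale(x3)[, 1]
  z2 <- scale(resid(lm(c(1, 0, 1) ~ x3)))[, 1]
  y3 <- 0.96 * z1 + sqrt(1 - 0.96^2) * z2   # exact sample correlation 0.96
  expect_equal(cor(x3, y3), 0.96, tolerance = 1e-12)
  expect_gt(pcc_pvalue(0.96, 3), 0.05)
  edges3 <- call_edges(expr_tbl(rbind(x3), ids = "l", libs = letters[1:3]),
                       expr_tbl(rbind(y3), ids = "m", libs = letters[1:3]),
                       cfg)
  expect_equal(nrow(edges3), 0)

  # constant vectors are excluded and counted, not propagated
  lnc_c <- expr_tbl(rbind(base, rep(1, n)), ids = c("ok", "flat"))
  e2 <- call_edges(lnc_c, mr, cfg)
  expect_equal(attr(e2, "n_undefined"), 3)
  expect_false("flat" %in% e2$lncrna_id)

  expect_error(call_edges(lnc, expr_tbl(rbind(base), libs = sprintf("zz%02d", 1:n))),
               "same libraries")
})

test_that("the edge set shrinks as thresholds tighten", {
  set.seed(19)
  lnc <- expr_tbl(matrix(rnorm(30 * 16), 30), ids = sprintf("l%02d", 1:30))
  mr <- expr_tbl(matrix(rnorm(40 * 16), 40), ids = sprintf("m%02d", 1:40))
  loose <- call_edges(lnc, mr, coexpression_config(0.4, 0.2, log_transform = FALSE))
  tight_r <- call_edges(lnc, mr, coexpression_config(0.6, 0.2, log_transform = FALSE))
  tight_p <- call_edges(lnc, mr, coexpression_config(0.4, 0.01, log_transform = FALSE))
  key <- function(e) paste(e$lncrna_id, e$mrna_id)
  expect_true(all(key(tight_r) %in% key(loose)))
  expect_true(all(key(tight_p) %in% key(loose)))
})

test_that("permutation_validate is seeded, monotone and threshold-complete", {
  set.seed(33)
  lnc <- expr_tbl(matrix(rnorm(30 * 16), 30), ids = sprintf("l%02d", 1:30))
  mr <- expr_tbl(matrix(rnorm(10 * 16), 10), ids = sprintf("m%02d", 1:10))
  pv <- permutation_validate(lnc, mr, n_lncrnas = 10, n_repetitions = 20,
                             threshold = c(0, 0.3, 0.6, 0.95), seed = 5,
                             log_transform = FALSE)
  s <- pv$summary
  expect_equal(s$proportion[s$threshold == 0], 1)         # every |r| >= 0
  expect_true(all(diff(s$proportion) <= 0))               # non-increasing
  expect_equal(s$pooled, rep(20 * 10 * 10, 4))
  # bit-for-bit reproducible under a fixed seed
  pv2 <- permutation_validate(lnc, mr, n_lncrnas = 10, n_repetitions = 20,
                              threshold = c(0, 0.3, 0.6, 0.95), seed = 5,
                              log_transform = FALSE)
  expect_identical(pv$summary, pv2$summary)
  expect_identical(pv$abs_pcc_hist, pv2$abs_pcc_hist)
  # parameters echoed in the summary object
  expect_equal(pv$params$n_lncrnas, 10)
  expect_equal(pv$params$n_repetitions, 20)
  expect_error(permutation_validate(lnc, mr, n_lncrnas = 500,
                                    n_repetitions = 5, seed = 1,
                                    log_transform = FALSE),
               "available")
})

test_that("shared-permutation mode preserves within-repetition structure", {
  set.seed(44)
  lnc <- expr_tbl(matrix(rnorm(12 * 16), 12), ids = sprintf("l%02d", 1:12))
  mr <- expr_tbl(matrix(rnorm(5 * 16), 5), ids = sprintf("m%02d", 1:5))
  pv <- permutation_validate(lnc, mr, n_lncrnas = 6, n_repetitions = 10,
                             threshold = 0.5, seed = 2,
                             shared_permutation = TRUE, log_transform = FALSE)
  expect_equal(pv$summary$pooled, 10 * 6 * 5)
  expect_true(pv$summary$proportion >= 0 && pv$summary$proportion <= 1)
})
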