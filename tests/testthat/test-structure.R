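# Exon chains below are written in 1-based inclusive coordinates (as a GTF
# would give them) and converted by make_tx().

ir_pair <- function(strand = "+", shift = 0) {
  make_tx(c("A", "B"),
          list(list(c(1, 100) + shift, c(201, 300) + shift),
               list(c(1, 300) + shift)),
          strand = strand)
}

test_that("the five canonical modes classify exactly as defined", {
  # intron retention: B's single exon spans A's intron
  ev <- classify_events(ir_pair())
  expect_equal(ev$mode, "intron_retention")
  expect_equal(ev$detail, "retained_by=B")

  # exon skipping
  es <- make_tx(c("A", "B"),
                list(list(c(1, 100), c(201, 300), c(401, 500)),
                     list(c(1, 100), c(401, 500))))
  ev <- classify_events(es)
  expect_equal(ev$mode, "exon_skipping")
  expect_equal(c(ev$start, ev$end), c(200L, 300L))

  # alternative 5' donor on the plus strand
  a5 <- make_tx(c("A", "B"),
                list(list(c(1, 100), c(201, 300)),
                     list(c(1, 130), c(201, 300))))
  expect_equal(classify_events(a5)$mode, "alt_5_donor")

  # alternative 3' acceptor on the plus strand
  a3 <- make_tx(c("A", "B"),
                list(list(c(1, 100), c(201, 300)),
                     list(c(1, 100), c(171, 300))))
  expect_equal(classify_events(a3)$mode, "alt_3_acceptor")

  # mutually exclusive exons
  mxe <- make_tx(c("A", "B"),
                 list(list(c(1, 100), c(201, 250), c(401, 500)),
                      list(c(1, 100), c(301, 350), c(401, 500))))
  expect_equal(classify_events(mxe)$mode, "mutually_exclusive_exon")
})

test_that("each template pair emits exactly one event", {
  modes <- c("intron_retention", "exon_skipping", "alt_3_acceptor",
             "alt_5_donor", "mutually_exclusive_exon")
  pairs <- simulate_as_pairs(setNames(rep(1L, 5), modes))
  ev <- find_as_events(pairs)
  expect_equal(nrow(ev), 5)
  expect_setequal(ev$mode, modes)
})

test_that("relabeling the strand swaps donor and acceptor consistently", {
  a5_plus <- make_tx(c("A", "B"),
                     list(list(c(1, 100), c(201, 300)),
                          list(c(1, 130), c(201, 300))))
  a5_minus <- a5_plus
  a5_minus$strand <- "-"
  expect_equal(classify_events(a5_plus)$mode, "alt_5_donor")
  expect_equal(classify_events(a5_minus)$mode, "alt_3_acceptor")
  # IR is strand-symmetric
  m <- ir_pair("-")
  expect_equal(classify_events(m)$mode, "intron_retention")
})

test_that("classification is invariant under coordinate translation and pair order", {
  base <- classify_events(ir_pair())
  shifted <- classify_events(ir_pair(shift = 5000))
  expect_equal(shifted$mode, base$mode)
  expect_equal(shifted$start - 5000L, base$start)
  flipped <- classify_events(ir_pair()[2:1, ])
  expect_equal(flipped$mode, base$mode)
  expect_equal(flipped$detail, base$detail)  # B still the retainer
  expect_error(classify_events(make_tx(c("A", "B"),
                                       list(list(c(1, 100)), list(c(1, 90))),
                                       strand = c("+", "-"))),
               "mixed strands")
})

test_that("event distribution reproduces injected mode counts", {
  modes <- c("intron_retention", "exon_skipping", "alt_3_acceptor",
             "alt_5_donor", "mutually_exclusive_exon")
  pairs <- simulate_as_pairs(setNames(c(10L, 5L, 5L, 5L, 0L), modes))
  dist <- event_mode_distribution(find_as_events(pairs))
  got <- setNames(dist$proportion, dist$mode)
  expect_equal(unname(got[modes]), c(0.4, 0.2, 0.2, 0.2, 0))
  expect_equal(sum(dist$n), 25)
  # zero events: empty table, not NaN
  none <- event_mode_distribution(find_as_events(ir_pair()[1, ]))
  expect_equal(nrow(none), 0)
})

test_that("identical events from different pairs deduplicate per locus", {
  # three isoforms: two identical B-like retainers -> one deduped IR event
  tx <- make_tx(c("A", "B1", "B2"),
                list(list(c(1, 100), c(201, 300)),
                     list(c(1, 300)),
                     list(c(1, 300))))
  ev <- find_as_events(tx)
  expect_equal(sum(ev$mode == "intron_retention"), 2)  # one per pair
  dist <- event_mode_distribution(ev, dedupe = TRUE)
  expect_equal(dist$n[dist$mode == "intron_retention"], 1L)
  nodedup <- event_mode_distribution(ev, dedupe = FALSE)
  expect_equal(nodedup$n[nodedup$mode == "intron_retention"], 2L)
})

test_that("status overlap matches a brute-force membership tabulation", {
  sets <- tibble::tibble(status = c("S1", "S1", "S2", "S2"),
                         key = c("a", "b", "b", "c"))
  ov <- status_overlap(sets)
  expect_equal(ov$specific$n_specific[ov$specific$status == "S1"], 1L)
  expect_equal(ov$specific$n_specific[ov$specific$status == "S2"], 1L)
  expect_equal(ov$cells$n[ov$cells$statuses == "S1&S2"], 1L)
  expect_equal(ov$n_union, 3)

  # six disjoint sets: every key specific
  six <- tibble::tibble(status = sprintf("st%d", rep(1:6, each = 3)),
                        key = sprintf("k%02d", 1:18))
  ov6 <- status_overlap(six)
  expect_true(all(ov6$specific$n_specific == 3))
  expect_equal(sum(ov6$cells$n), ov6$n_union)

  # random sets vs brute-force tabulation
  set.seed(21)
  rs <- tibble::tibble(
    status = sample(sprintf("s%d", 1:4), 200, replace = TRUE),
    key = sample(sprintf("k%02d", 1:40), 200, replace = TRUE))
  ov_r <- status_overlap(rs)
  brute <- table(vapply(unique(rs$key), function(k) {
    paste(sort(unique(rs$status[rs$key == k])), collapse = "&")
  }, character(1)))
  got <- setNames(ov_r$cells$n, ov_r$cells$statuses)
  expect_equal(got[names(brute)], setNames(as.integer(brute), names(brute)))
  expect_equal(sum(ov_r$cells$n), length(unique(rs$key)))
})

test_that("structure keys identify transcripts by intron chain", {
  # same intron chain, different terminal exon ends -> same key
  tx <- make_tx(c("x", "y"),
                list(list(c(1, 100), c(201, 300)),
                     list(c(11, 100), c(201, 290))))
  keys <- structure_key(tx)
  expect_equal(keys[1], keys[2])
  # mono-exon transcripts compare by exact coordinates
  mono <- make_tx(c("p", "q"), list(list(c(1, 100)), list(c(1, 101))))
  expect_false(structure_key(mono)[1] == structure_key(mono)[2])
})

test_that("novelty classification applies the reference E-value cutoff", {
  hits <- tibble::tibble(
    query_id = c("t1", "t2"), subject_id = "ref1", percent_identity = 95,
    align_length = 100, mismatches = 0, gap_opens = 0, q_start = 1,
    q_end = 100, s_start = 1, s_end = 100,
    evalue = c(1e-6, 1e-4), bitscore = 100)
  out <- classify_novelty(c("t1", "t2", "t3"), hits)
  expect_equal(setNames(out$novelty, out$transcript_id),
               c(t1 = "known", t2 = "novel", t3 = "novel"))

  set.seed(3)
  ids <- sprintf("q%03d", 1:100)
  rh <- tibble::tibble(
    query_id = sample(ids, 150, replace = TRUE), subject_id = "r",
    percent_identity = 90, align_length = 50, mismatches = 0, gap_opens = 0,
    q_start = 1, q_end = 50, s_start = 1, s_end = 50,
    evalue = 10^runif(150, -12, 0), bitscore = 80)
  out <- classify_novelty(ids, rh)
  oracle <- vapply(ids, function(q) {
    if (any(rh$query_id == q & rh$evalue <= 1e-5)) "known" else "novel"
  }, character(1))
  expect_equal(setNames(out$novelty, out$transcript_id), oracle)
})

test_that("loci are connected components of same-strand exonic overlap", {
  tx <- make_tx(c("a", "b", "c", "d"),
                list(list(c(1, 100)), list(c(50, 150)),
                     list(c(140, 220)), list(c(1000, 1100))))
  loci <- transcript_loci(tx)
  expect_equal(loci$locus_id[1], loci$locus_id[2])  # direct overlap
  expect_equal(loci$locus_id[2], loci$locus_id[3])  # chained overlap
  expect_false(loci$locus_id[1] == loci$locus_id[4])
  # same span, opposite strand: different loci
  opp <- make_tx(c("p", "q"), list(list(c(1, 100)), list(c(1, 100))),
                 strand = c("+", "-"))
  lo <- transcript_loci(opp)
  expect_false(lo$locus_id[1] == lo$locus_id[2])
})
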