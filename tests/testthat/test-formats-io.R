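test_that("read_gtf builds one model per transcript and converts coordinates", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tasm\texon\t1\t100\t.\t+\t.\t",
           'transcript_id "T1"; gene_id "G1";'),
    paste0("chr1\tasm\texon\t201\t300\t.\t+\t.\t",
           'transcript_id "T1"; gene_id "G1";')
  ), gtf)
  tx <- read_gtf(gtf)
  expect_equal(nrow(tx), 1)
  expect_equal(tx$n_exons, 2L)
  # 1-based inclusive 1-100 becomes 0-based half-open [0, 100)
  expect_equal(as.data.frame(tx$exons[[1]]),
               data.frame(start = c(0L, 200L), end = c(100L, 300L)))
  expect_equal(tx$length_nt, 200L)
})

test_that("read_gtf handles empty files and reports malformed lines", {
  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_equal(nrow(read_gtf(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("# comment",
               "chr1\tasm\texon\t1\t100"), bad)
  expect_error(read_gtf(bad), "line 2")
})

test_that("GTF write/read round-trips synthetic models exactly", {
  st <- small_study()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(st$transcripts, gtf)
  back <- read_gtf(gtf)
  back <- back[match(st$transcripts$transcript_id, back$transcript_id), ]
  expect_equal(back$transcript_id, st$transcripts$transcript_id)
  expect_equal(back$chrom, st$transcripts$chrom)
  expect_equal(back$strand, st$transcripts$strand)
  expect_equal(lapply(back$exons, as.data.frame),
               lapply(st$transcripts$exons, as.data.frame))
})

test_that("read_fasta upper-cases, converts U to T, and round-trips", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgu"), fa)
  expect_equal(read_fasta(fa), c(a = "ACGT"))

  writeLines(c(">w desc", "ACGT", "ACGT", ">x", "GGGG"), fa)
  got <- read_fasta(fa)
  expect_equal(got, c(w = "ACGTACGT", x = "GGGG"))

  writeLines(c(">d", "AC", ">d", "GG"), fa)
  expect_error(read_fasta(fa), "duplicate")

  st <- small_study()
  seqs <- setNames(st$transcripts$sequence, st$transcripts$transcript_id)
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, out)
  expect_identical(read_fasta(out), seqs)
})

test_that("attach_sequences enforces the exon-length invariant", {
  tx <- make_tx("t1", list(list(c(1, 10))))
  expect_error(attach_sequences(tx, c(t1 = "ACGT")), "length")
  ok <- attach_sequences(tx, c(t1 = "ACGTACGTAC"))
  expect_equal(ok$sequence, "ACGTACGTAC")
})

test_that("read_hits parses the 12-column dialect and preserves order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("# comment line",
            "q1\ts1\t98.0\t100\t2\t0\t1\t100\t5\t104\t1e-10\t190\textra",
            "q2\ts2\t80.0\t50\t9\t1\t1\t50\t1\t50\t0.001\t60\textra",
            "q3\ts1\t70.0\t30\t9\t1\t1\t30\t1\t30\t2.5\t20\textra")
  writeLines(rows, f)
  hits <- read_hits(f)
  expect_equal(hits$query_id, c("q1", "q2", "q3"))
  expect_equal(hits$evalue, c(1e-10, 1e-3, 2.5))
  expect_false("extra" %in% unlist(hits))

  writeLines(character(0), f)
  expect_equal(nrow(read_hits(f)), 0)

  writeLines("q1\ts1\tNOTANUMBER\t100\t2\t0\t1\t100\t5\t104\t1e-10\t190", f)
  expect_error(read_hits(f), "non-numeric")
})

test_that("count/library/DE/energy readers validate their invariants", {
  st <- small_study()
  d <- withr::local_tempdir()
  write_study(st, d)
  counts <- read_counts(file.path(d, "counts.tsv"))
  expect_identical(counts, st$counts)
  libs <- read_library_info(file.path(d, "libraries.tsv"))
  expect_identical(libs, st$libraries)
  expect_equal(nrow(libs), 16)
  de <- read_de_table(file.path(d, "de.tsv"))
  expect_identical(de$direction, st$de$direction)
  en <- read_energy_sites(file.path(d, "energy_sites.tsv"))
  expect_equal(en, st$energy_sites)

  badlib <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("library_id\tcondition\ttime_h\treplicate",
               "a\tcontrol\t4\t1", "b\tcontrol\t4\t1"), badlib)
  expect_error(read_library_info(badlib), "unique")
})

test_that("network export round-trips graphml and tsv; sif keeps topology", {
  set.seed(9)
  edges <- tibble::tibble(
    lncrna_id = rep(sprintf("l%d", 1:5), each = 2),
    mrna_id = sprintf("m%d", 1:10),
    pcc = round(runif(10, 0.95, 1), 4),
    pvalue = signif(runif(10, 1e-8, 1e-3), 4))
  sites <- tibble::tibble(lncrna_id = "l1", mrna_id = "m1",
                          energy = c(-3.2, -1.8))
  de <- tibble::tibble(transcript_id = c("l1", "m1", "m2"),
                       direction = c("down", "down", "up"))
  net <- build_network(edges, sites, de)

  for (fmt in c("graphml", "tsv")) {
    f <- withr::local_tempfile()
    write_network(net, f, fmt)
    back <- read_network(f, fmt)
    ord <- match(paste(net$edges$lncrna_id, net$edges$mrna_id),
                 paste(back$edges$lncrna_id, back$edges$mrna_id))
    expect_equal(as.data.frame(back$edges[ord, names(net$edges)]),
                 as.data.frame(net$edges), tolerance = 1e-9)
    nord <- match(net$nodes$id, back$nodes$id)
    expect_equal(as.data.frame(back$nodes[nord, names(net$nodes)]),
                 as.data.frame(net$nodes))
  }

  f <- withr::local_tempfile()
  write_network(net, f, "sif")
  lines <- readLines(f)
  expect_length(lines, 10)
  expect_equal(lines[1], sprintf("%s\tinteracts\t%s", edges$lncrna_id[1],
                                 edges$mrna_id[1]))

  empty <- build_network(edges[0, ])
  f2 <- withr::local_tempfile()
  write_network(empty, f2, "graphml")
  expect_equal(nrow(read_network(f2, "graphml")$edges), 0)
})
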