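# Independent oracles used across the suite.  These deliberately take
# different computational routes than the package implementation.

# Six-frame stop-to-stop ORF length via Biostrings translation + string
# splitting on the stop symbol (ambiguous codons translate to X, non-stop,
# matching the N-is-not-a-stop convention).
orf_oracle <- function(s) {
  s <- chartr("U", "T", toupper(s))
  best <- 0L
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (seqs in c(s, rc)) {
    L <- nchar(seqs)
    for (f in 1:3) {
      if (L - f + 1 < 3) next
      sub <- substr(seqs, f, f + ((L - f + 1) %/% 3) * 3 - 1)
      aa <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X")))
      runs <- nchar(strsplit(aa, "*", fixed = TRUE)[[1]])
      if (length(runs) > 0) best <- max(best, runs)
    }
  }
  as.integer(best)
}

random_seq <- function(len, with_n = TRUE) {
  alphabet <- c("A", "C", "G", "T", if (with_n) "N")
  prob <- if (with_n) c(0.24, 0.24, 0.24, 0.24, 0.04) else rep(0.25, 4)
  paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by direct summation of choose() terms.
hyper_tail_oracle <- function(k_min, K, N, n) {
  if (k_min <= max(0, n - (N - K))) return(1)
  ks <- seq(k_min, min(K, n))
  if (length(ks) == 0) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Definitional Pearson correlation (no stats::cor).
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Build a transcript model tibble from a list of exon matrices given in
# 1-based inclusive coordinates (converted to internal 0-based half-open).
make_tx <- function(ids, exons_1based, chrom = "chr1", strand = "+",
                    sequence = NA_character_) {
  tibble::tibble(
    transcript_id = ids,
    gene_id = paste0("g_", ids),
    chrom = chrom,
    strand = strand,
    exons = lapply(exons_1based, function(e) {
      m <- matrix(unlist(e), ncol = 2, byrow = TRUE)
      tibble::tibble(start = as.integer(m[, 1] - 1L), end = as.integer(m[, 2]))
    }),
    n_exons = vapply(exons_1based, length, integer(1)),
    length_nt = vapply(exons_1based, function(e) {
      m <- matrix(unlist(e), ncol = 2, byrow = TRUE)
      as.integer(sum(m[, 2] - m[, 1] + 1))
    }, integer(1)),
    sequence = sequence
  )
}

# Wide expression tibble from a numeric matrix.
expr_tbl <- function(m, ids = sprintf("t%03d", seq_len(nrow(m))),
                     libs = sprintf("lib%02d", seq_len(ncol(m)))) {
  out <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(out) <- libs
  dplyr::bind_cols(tibble::tibble(transcript_id = ids), out)
}

# A transcript whose longest stop-to-stop ORF is exactly 100 aa (verified
# against orf_oracle when frozen) and a 99-aa counterpart.
ORF100_SEQ <- "TAATATTCGAAAGGCGGAGCGTACATTTATCATCGCTCAGCGGGCTCGAATCCCTGCACTCATGAATGGGGCATCGCGTCGAAGTTGCCACCCACGCTCGGGGAAATTGAGATGCGCTTCCTGAACTCCATTAGAGCGACATCCTACTTGCTCCCAACAACGGGTACTCCGCGCAGCTATTCTTGCACTGCAGCACAAGCTGAAAGTGCCCAACGTAGGATTGGAGGGCCAGAGTATCGGGCGTTGATGCGAGTCCTACCCCGACTGCCGGTCCACTCGCTCGGTAATCCACTCAGTCAATACTAA"
ORF99_SEQ <- "TAACGCTATTACCCAAATGGGCGTGGGGCCGCGTGTGCGCGGATGTACATCGTATCTAGTACCCAGCACAGTGTTGTCGACGTGCGATGTGCCCTGTGTATTGATAGAGTCCGTAGGAAAGTATTACCACGACGTCACTGCCTGATGATGGGTGAGCTTTGTGTCGGCCCTCAGGACAATTTACATGCAGGTCATCTGTCGCACTATAGTTATACTAAGACGTTCCAGGCATCCAGGAAGGCACCCGTTAACACGATGAGCGTTCTATGCTGGAAACAAGGTCGCACGGGCCTCCTGTTTTAA"

# Minimal synthetic study shared by several files (small for speed).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_coding = 60, n_noncoding = 30,
                              n_planted_pairs = 8, n_planted_de = 8,
                              seed = 2024)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

study_inputs <- function(dir) {
  list(fasta = file.path(dir, "transcripts.fasta"),
       gtf = file.path(dir, "transcripts.gtf"),
       hits = file.path(dir, "homology_hits.tsv"),
       domains = file.path(dir, "domain_hits.tsv"),
       cpc_labels = file.path(dir, "cpc_labels.tsv"),
       counts = file.path(dir, "counts.tsv"),
       libraries = file.path(dir, "libraries.tsv"),
       de = file.path(dir, "de.tsv"),
       energies = file.path(dir, "energy_sites.tsv"),
       annotation = file.path(dir, "annotation.tsv"))
}
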