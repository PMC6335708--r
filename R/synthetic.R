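# Seeded synthetic-study generator.
#
# Emulates the design of a two-condition (control vs Symbiodinium-infected)
# x three-timepoint (4/12/48 h) coral larva RNA-seq experiment with 16
# libraries (replicate layout 3/3/2/2/3/3), so that every downstream stage
# -- filtering, structure analysis, co-expression, network assembly,
# enrichment -- can be exercised offline against known ground truth.
#
# Design of the sequence classes:
#  * coding-designed transcripts embed a stop-free ORF of >= 100 aa flanked
#    by stop codons, and carry strong protein-homology hits;
#  * noncoding-designed transcripts are assembled from short random filler
#    blocks (<= 150 nt) interleaved with the 12-nt cassette TTAATTAATTAA,
#    which is its own reverse complement and contains a stop codon in every
#    one of the six frames.  Every stop-free codon run is therefore shorter
#    than (150 + 24)/3 = 58 aa by construction, comfortably under the
#    100-aa cap, and these transcripts receive no homology hits.

AS_MODES <- c("intron_retention", "exon_skipping", "alt_3_acceptor",
              "alt_5_donor", "mutually_exclusive_exon")

STOP_CASSETTE <- "TTAATTAATTAA"

#' Configuration for the synthetic study generator
#'
#' Defaults encode the emulated study design: 16 libraries in a
#' control/infected x 4/12/48 h layout with 3/3/2/2/3/3 replicates,
#' negative-binomial counts with log10-uniform means, latent log-normal
#' biological modulation shared within planted lncRNA-mRNA pairs, and
#' differential expression planted in the infected 4-h libraries only.
#'
#' @param n_coding Number of coding-designed transcripts.
#' @param n_noncoding Number of noncoding-designed transcripts (the planted
#'   lncRNAs).
#' @param transcript_length_range Length range in nt; the noncoding minimum
#'   must be at least 200 nt.
#' @param replicate_layout Tibble with `condition`, `time_h`, `n_reps`;
#'   must sum to 16 libraries by default.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param mean_expression_log_range Range of log10 mean expression.
#' @param latent_sd Standard deviation (natural-log scale) of the latent
#'   per-library biological modulation of a background transcript's mean.
#'   Kept modest by default so planted expression shifts are detectable
#'   against within-group variability.
#' @param planted_pair_latent_sd Latent modulation SD of planted-pair
#'   members. Planted pairs emulate strongly co-modulated transcripts, so
#'   their shared latent swing must dominate counting noise for the pair
#'   correlation to survive the count layer.
#' @param n_planted_pairs Number of lncRNA-mRNA pairs sharing a latent
#'   factor.
#' @param planted_latent_correlation Target expected Pearson correlation of
#'   the pairs' log-expression, in (0, 1]. The latent loading is inflated
#'   analytically to compensate the attenuation caused by counting noise
#'   (and clamped at 1 when the target is unreachable).
#' @param n_planted_de Number of transcripts whose mean is shifted in
#'   infected 4-h libraries. Planted among well-expressed transcripts
#'   (base mean in the upper half of the range) outside the planted pairs,
#'   emulating the detectable portion of a DE signal.
#' @param planted_lfc log2 fold change(s) for planted DE transcripts,
#'   recycled over them; the sign gives the planted direction.
#' @param orf_aa_range Length range (aa) of the ORF embedded in
#'   coding-designed transcripts.
#' @param as_events_per_mode Named integer vector over the five splicing
#'   modes; for each count an isoform pair differing by exactly that event
#'   is added to the transcript set (with noncoding-designed sequences).
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the configuration.
#' @return A validated `lnc_synthetic_config` list.
#' @export
synthetic_config <- function(n_coding = 400,
                             n_noncoding = 200,
                             transcript_length_range = c(300, 1500),
                             replicate_layout = default_replicate_layout(),
                             nb_dispersion = 0.05,
                             mean_expression_log_range = c(1.5, 3.5),
                             latent_sd = 0.1,
                             planted_pair_latent_sd = 3,
                             n_planted_pairs = 50,
                             planted_latent_correlation = 0.99,
                             n_planted_de = 40,
                             planted_lfc = c(-2, 2),
                             orf_aa_range = c(110, 250),
                             as_events_per_mode = setNames(rep(0L, 5), AS_MODES),
                             seed = 1L) {
  config <- list(
    n_coding = n_coding, n_noncoding = n_noncoding,
    transcript_length_range = transcript_length_range,
    replicate_layout = replicate_layout,
    nb_dispersion = nb_dispersion,
    mean_expression_log_range = mean_expression_log_range,
    latent_sd = latent_sd,
    planted_pair_latent_sd = planted_pair_latent_sd,
    n_planted_pairs = n_planted_pairs,
    planted_latent_correlation = planted_latent_correlation,
    n_planted_de = n_planted_de, planted_lfc = planted_lfc,
    orf_aa_range = orf_aa_range,
    as_events_per_mode = as_events_per_mode,
    seed = seed
  )
  class(config) <- "lnc_synthetic_config"
  validate_synthetic_config(config)
}

#' @rdname synthetic_config
#' @export
default_replicate_layout <- function() {
  tibble(
    condition = rep(c("control", "infected"), 3),
    time_h = rep(c(4L, 12L, 48L), each = 2),
    n_reps = c(3L, 3L, 2L, 2L, 3L, 3L)
  )
}

validate_synthetic_config <- function(config) {
  assert_scalar_number(config$n_coding, "n_coding", min = 0)
  assert_scalar_number(config$n_noncoding, "n_noncoding", min = 0)
  assert_scalar_number(config$nb_dispersion, "nb_dispersion", min = 0)
  assert_scalar_number(config$latent_sd, "latent_sd", min = 0)
  assert_scalar_number(config$planted_pair_latent_sd,
                       "planted_pair_latent_sd", min = 0)
  assert_scalar_number(config$planted_latent_correlation,
                       "planted_latent_correlation", min = 1e-6, max = 1)
  assert_scalar_number(config$seed, "seed")
  lr <- config$transcript_length_range
  if (length(lr) != 2 || lr[1] > lr[2]) {
    abort("`transcript_length_range` must be an increasing pair")
  }
  if (config$n_noncoding > 0 && lr[1] < 200) {
    abort(paste0("infeasible config: noncoding transcripts must be >= 200 nt, ",
                 "but transcript_length_range starts at ", lr[1]))
  }
  assert_columns(config$replicate_layout, c("condition", "time_h", "n_reps"),
                 "replicate_layout")
  if (config$n_planted_pairs > min(config$n_coding, config$n_noncoding)) {
    abort("n_planted_pairs exceeds the available coding or noncoding transcripts")
  }
  if (config$n_planted_de > config$n_coding + config$n_noncoding) {
    abort("n_planted_de exceeds the number of transcripts")
  }
  if (!setequal(names(config$as_events_per_mode), AS_MODES)) {
    abort(sprintf("as_events_per_mode must be named over: %s",
                  paste(AS_MODES, collapse = ", ")))
  }
  config
}

library_table <- function(replicate_layout) {
  bind_rows(pmap(replicate_layout[c("condition", "time_h", "n_reps")],
                 function(condition, time_h, n_reps) {
                   tibble(condition = condition, time_h = time_h,
                          replicate = seq_len(n_reps))
                 })) |>
    mutate(library_id = sprintf("%s_%02dh_rep%d", .data$condition,
                                .data$time_h, .data$replicate)) |>
    select("library_id", "condition", "time_h", "replicate")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Noncoding-designed sequence: filler blocks interleaved with the all-frame
# stop cassette; longest stop-to-stop ORF < 100 aa by construction.
noncoding_sequence <- function(len) {
  out <- character(0)
  total <- 0L
  repeat {
    filler <- random_dna(sample(50:150, 1))
    out <- c(out, filler, STOP_CASSETTE)
    total <- total + nchar(filler) + nchar(STOP_CASSETTE)
    if (total >= len) break
  }
  substr(paste(out, collapse = ""), 1, len)
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# Coding-designed sequence: random flanks around TAA + a stop-free codon
# run of orf_aa codons + TAA.
coding_sequence <- function(len, orf_aa) {
  core <- paste0("TAA", paste(sample(NONSTOP_CODONS, orf_aa, replace = TRUE),
                              collapse = ""), "TAA")
  rest <- len - nchar(core)
  left <- sample.int(max(rest - 1, 1), 1)
  paste0(random_dna(left), core, random_dna(max(rest - left, 0)))
}

# Split a transcript of `len` nt into an exon chain at genomic offset
# `offset` (0-based), with random intron lengths.
make_exon_chain <- function(len, offset) {
  max_ex <- max(1L, min(5L, len %/% 60L))
  n_ex <- sample.int(max_ex, 1)
  if (n_ex == 1) {
    widths <- len
  } else {
    cuts <- sort(sample(seq(30L, len - 30L), n_ex - 1))
    widths <- diff(c(0L, cuts, len))
  }
  introns <- if (n_ex > 1) sample(60:500, n_ex - 1, replace = TRUE) else integer(0)
  starts <- offset + cumsum(c(0L, widths[-n_ex] + introns))
  tibble(start = as.integer(starts), end = as.integer(starts + widths))
}

#' Generate the synthetic transcript set with ground truth
#'
#' Builds transcript models (sequences plus exon chains on a toy genome,
#' one chromosome per ~50 transcripts), the matching homology and domain
#' hit tables, coding-potential labels, and the `truth` record naming the
#' planted lncRNAs, planted co-expressed pairs and planted DE transcripts.
#'
#' @param config A [synthetic_config()].
#' @return List with `transcripts`, `truth`, `homology_hits`,
#'   `domain_hits`, `coding_labels`.
#' @export
simulate_sequences <- function(config) {
  config <- validate_synthetic_config(config)
  with_seed(derive_seed(config$seed, "sequences"), {
    lr <- config$transcript_length_range
    cod_ids <- sprintf("cd_%05d", seq_len(config$n_coding))
    nc_ids <- sprintf("nc_%05d", seq_len(config$n_noncoding))

    min_cod_len <- 3L * (config$orf_aa_range[1] + 4L) + 40L
    cod_len <- pmax(sample(lr[1]:lr[2], config$n_coding, replace = TRUE),
                    min_cod_len)
    nc_len <- sample(max(lr[1], 200L):max(lr[2], 200L), config$n_noncoding,
                     replace = TRUE)
    cod_orf <- pmin(sample(config$orf_aa_range[1]:config$orf_aa_range[2],
                           config$n_coding, replace = TRUE),
                    (cod_len - 40L) %/% 3L - 4L)
    cod_seq <- map2_chr(cod_len, cod_orf, coding_sequence)
    nc_seq <- map_chr(nc_len, noncoding_sequence)

    ids <- c(cod_ids, nc_ids)
    seqs <- c(cod_seq, nc_seq)
    lens <- nchar(seqs)

    # genome placement: shuffled over chromosomes of ~50 transcripts
    ord <- sample(seq_along(ids))
    chrom_of <- integer(length(ids))
    offset_of <- integer(length(ids))
    exons <- vector("list", length(ids))
    cursor <- integer(0)
    for (pos in seq_along(ord)) {
      i <- ord[pos]
      chr <- (pos - 1L) %/% 50L + 1L
      if (length(cursor) < chr) cursor[chr] <- 0L
      off <- cursor[chr] + sample(200:1000, 1)
      ex <- make_exon_chain(lens[i], off)
      exons[[i]] <- ex
      chrom_of[i] <- chr
      cursor[chr] <- max(ex$end)
    }

    transcripts <- tibble(
      transcript_id = ids,
      gene_id = paste0("g_", ids),
      chrom = sprintf("chr%02d", chrom_of),
      strand = sample(c("+", "-"), length(ids), replace = TRUE),
      exons = exons,
      n_exons = map_int(exons, nrow),
      length_nt = as.integer(lens),
      sequence = seqs
    )

    # AS-event injection: isoform pairs differing by exactly one event,
    # appended with noncoding-designed sequences
    n_by_mode <- config$as_events_per_mode[AS_MODES]
    if (sum(n_by_mode) > 0) {
      as_models <- simulate_as_pairs(n_by_mode)
      as_models$sequence <- map_chr(as_models$length_nt, noncoding_sequence)
      transcripts <- bind_rows(transcripts, as_models)
      nc_ids <- c(nc_ids, as_models$transcript_id)
    }

    all_ids <- c(cod_ids, nc_ids)
    base_means <- setNames(
      10^runif(length(all_ids), config$mean_expression_log_range[1],
               config$mean_expression_log_range[2]),
      all_ids)
    planted_pairs <- tibble(
      lncrna_id = sample(nc_ids, config$n_planted_pairs),
      mrna_id = sample(cod_ids, config$n_planted_pairs)
    )
    pair_members <- c(planted_pairs$lncrna_id, planted_pairs$mrna_id)
    # planted-pair members emulate well-expressed, strongly co-modulated
    # transcripts: base means in the top of the range, so the latent swing
    # is observable above the zero-count floor
    hi <- config$mean_expression_log_range[2]
    base_means[pair_members] <-
      10^runif(length(pair_members), hi - 0.3, hi)
    # plant DE among well-expressed transcripts outside the planted pairs,
    # below the abundance band of the pair members so the two planted
    # populations do not share a dispersion-trend neighborhood
    mid <- 10^mean(config$mean_expression_log_range)
    below_pairs <- 10^(hi - 0.5)
    eligible <- setdiff(
      all_ids[base_means >= mid & base_means <= below_pairs], pair_members)
    if (length(eligible) < config$n_planted_de) {
      eligible <- setdiff(all_ids, pair_members)
    }
    if (length(eligible) < config$n_planted_de) {
      abort("not enough transcripts outside planted pairs to plant DE")
    }
    de_ids <- sample(eligible, config$n_planted_de)
    lfc <- rep_len(config$planted_lfc, config$n_planted_de)
    truth <- list(
      true_coding_ids = cod_ids,
      true_lncrna_ids = nc_ids,
      planted_pairs = planted_pairs,
      planted_de = tibble(transcript_id = de_ids, lfc = lfc,
                          direction = ifelse(lfc > 0, "up", "down")),
      base_means = base_means
    )

    homology_hits <- make_homology_hits(cod_ids, nc_ids)
    dom_n <- ceiling(0.3 * length(cod_ids))
    dom_ids <- if (dom_n > 0) sample(cod_ids, dom_n) else character(0)
    domain_hits <- tibble(
      query_id = dom_ids,
      domain_accession = sprintf("PF%05d", sample.int(20000, length(dom_ids),
                                                      replace = TRUE)),
      domain_evalue = 10^-runif(length(dom_ids), 4, 30)
    )
    coding_labels <- tibble(
      transcript_id = c(cod_ids, nc_ids),
      label = c(rep("coding", length(cod_ids)),
                rep("noncoding", length(nc_ids)))
    )
    list(transcripts = transcripts, truth = truth,
         homology_hits = homology_hits, domain_hits = domain_hits,
         coding_labels = coding_labels)
  })
}

# Strong hits (E <= 1e-6) for every coding transcript; weak decoy hits
# (E > 1e-2, above any sensible exclusion cutoff) for 10% of noncoding.
make_homology_hits <- function(cod_ids, nc_ids) {
  hit_row <- function(qid, evalue) {
    alen <- sample(80:600, length(qid), replace = TRUE)
    tibble(
      query_id = qid,
      subject_id = sprintf("sp|P%05d", sample.int(99999, length(qid),
                                                  replace = TRUE)),
      percent_identity = round(runif(length(qid), 40, 98), 1),
      align_length = alen,
      mismatches = sample(0:40, length(qid), replace = TRUE),
      gap_opens = sample(0:5, length(qid), replace = TRUE),
      q_start = sample(1:50, length(qid), replace = TRUE),
      q_end = sample(1:50, length(qid), replace = TRUE) + alen,
      s_start = sample(1:50, length(qid), replace = TRUE),
      s_end = sample(1:50, length(qid), replace = TRUE) + alen,
      evalue = evalue,
      bitscore = round(runif(length(qid), 50, 800), 1)
    )
  }
  strong <- hit_row(cod_ids, 10^-runif(length(cod_ids), 6, 50))
  extra_idx <- which(runif(length(cod_ids)) < 0.5)
  strong2 <- hit_row(cod_ids[extra_idx], 10^-runif(length(extra_idx), 6, 40))
  n_decoy <- floor(0.1 * length(nc_ids))
  decoys <- if (n_decoy > 0) {
    hit_row(sample(nc_ids, n_decoy), 10^runif(n_decoy, -2, -0.3))
  } else {
    hit_row(character(0), numeric(0))
  }
  bind_rows(strong, strong2, decoys) |> arrange(.data$query_id)
}

#' Build isoform pairs differing by exactly one splicing event
#'
#' For each requested count, a two-transcript locus is created whose
#' isoforms differ by exactly one canonical event of the given mode
#' (intron retention, exon skipping, alternative 3'-acceptor, alternative
#' 5'-donor, mutually exclusive exons).  All loci are on the plus strand of
#' one synthetic chromosome, spaced apart so they form separate loci.
#'
#' @param n_by_mode Named integer vector over the five modes.
#' @param chrom Chromosome name for the injected loci.
#' @param spacing Gap between consecutive loci in nt.
#' @return Transcript model tibble (no sequences attached).
#' @export
simulate_as_pairs <- function(n_by_mode, chrom = "chrAS", spacing = 5000L) {
  n_by_mode <- n_by_mode[AS_MODES]
  n_by_mode[is.na(n_by_mode)] <- 0L
  names(n_by_mode) <- AS_MODES
  templates <- list(
    intron_retention = list(
      a = tibble(start = c(0L, 200L), end = c(100L, 300L)),
      b = tibble(start = 0L, end = 300L)),
    exon_skipping = list(
      a = tibble(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)),
      b = tibble(start = c(0L, 400L), end = c(100L, 500L))),
    alt_3_acceptor = list(
      a = tibble(start = c(0L, 200L), end = c(100L, 300L)),
      b = tibble(start = c(0L, 170L), end = c(100L, 300L))),
    alt_5_donor = list(
      a = tibble(start = c(0L, 200L), end = c(100L, 300L)),
      b = tibble(start = c(0L, 200L), end = c(130L, 300L))),
    mutually_exclusive_exon = list(
      a = tibble(start = c(0L, 200L, 400L), end = c(100L, 250L, 500L)),
      b = tibble(start = c(0L, 300L, 400L), end = c(100L, 350L, 500L)))
  )
  out <- list()
  offset <- 0L
  counter <- 0L
  for (mode in AS_MODES) {
    for (i in seq_len(n_by_mode[[mode]])) {
      counter <- counter + 1L
      tpl <- templates[[mode]]
      for (iso in c("a", "b")) {
        ex <- tpl[[iso]] |> mutate(start = .data$start + offset,
                                   end = .data$end + offset)
        out[[length(out) + 1L]] <- tibble(
          transcript_id = sprintf("as_%s_%03d_%s", abbreviate_mode(mode),
                                  counter, iso),
          gene_id = sprintf("as_locus_%03d", counter),
          chrom = chrom, strand = "+",
          exons = list(ex),
          n_exons = nrow(ex),
          length_nt = as.integer(exon_span(ex)),
          sequence = NA_character_
        )
      }
      offset <- offset + spacing
    }
  }
  if (length(out) == 0) return(empty_transcript_tbl())
  bind_rows(out)
}

abbreviate_mode <- function(mode) {
  c(intron_retention = "ir", exon_skipping = "es", alt_3_acceptor = "a3",
    alt_5_donor = "a5", mutually_exclusive_exon = "mxe")[[mode]]
}

#' Generate counts and a differential-expression table
#'
#' Counts are negative binomial with log10-uniform base means modulated by
#' a latent per-library log-normal factor; each planted pair shares a
#' latent factor with loading chosen so the expected log-expression
#' correlation equals `planted_latent_correlation`; planted DE transcripts
#' have their mean multiplied by `2^lfc` in infected 4-h libraries only.
#' The DE table comes from an exact negative-binomial two-sample test
#' (infected vs control at 4 h) with Benjamini-Hochberg adjustment, so its
#' p-values behave like real ones rather than being set to zero.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth record from [simulate_sequences()].
#' @return List with `counts` (wide tibble), `libraries` (metadata tibble)
#'   and `de` (transcript_id, log2fc, pvalue, fdr, direction).
#' @export
simulate_counts <- function(config, truth) {
  config <- validate_synthetic_config(config)
  with_seed(derive_seed(config$seed, "counts"), {
    libraries <- library_table(config$replicate_layout)
    n_lib <- nrow(libraries)
    ids <- c(truth$true_coding_ids, truth$true_lncrna_ids)
    n_tx <- length(ids)
    if (n_tx == 0) abort("truth contains no transcripts")

    mu <- truth$base_means
    if (is.null(mu)) {
      mu <- setNames(10^runif(n_tx, config$mean_expression_log_range[1],
                              config$mean_expression_log_range[2]), ids)
    }
    mu <- mu[ids]
    pair_members <- c(truth$planted_pairs$lncrna_id,
                      truth$planted_pairs$mrna_id)
    lat_sd <- ifelse(ids %in% pair_members, config$planted_pair_latent_sd,
                     config$latent_sd)
    names(lat_sd) <- ids
    latent <- matrix(rnorm(n_tx * n_lib), nrow = n_tx,
                     dimnames = list(ids, libraries$library_id))

    # planted co-expression: shared latent factor; the loading is inflated
    # so the expected log-expression correlation (after counting noise)
    # equals rho, clamped at 1 when the target is out of reach
    rho <- config$planted_latent_correlation
    pp <- truth$planted_pairs
    sP <- config$planted_pair_latent_sd
    for (i in seq_len(nrow(pp))) {
      l <- pp$lncrna_id[i]; m <- pp$mrna_id[i]
      f <- rnorm(n_lib)
      noise_var <- function(id) config$nb_dispersion + 1 / mu[[id]]
      a2 <- if (sP > 0) {
        rho * sqrt((sP^2 + noise_var(l)) * (sP^2 + noise_var(m))) / sP^2
      } else {
        1
      }
      a <- sqrt(min(1, a2))
      latent[l, ] <- a * f + sqrt(1 - a^2) * rnorm(n_lib)
      latent[m, ] <- a * f + sqrt(1 - a^2) * rnorm(n_lib)
    }

    # background transcripts: mean-preserving modulation; pair members:
    # median-preserving, so their typical counts stay near the (high) base
    # mean instead of collapsing toward zero
    center <- ifelse(ids %in% pair_members, 0, lat_sd^2 / 2)
    mean_mat <- mu * exp(lat_sd * latent - center)

    # planted DE: shift infected 4-h libraries only
    infected4 <- libraries$condition == "infected" & libraries$time_h == 4
    pd <- truth$planted_de
    for (i in seq_len(nrow(pd))) {
      mean_mat[pd$transcript_id[i], infected4] <-
        mean_mat[pd$transcript_id[i], infected4] * 2^pd$lfc[i]
    }

    counts <- matrix(
      if (config$nb_dispersion < 1e-8) {
        rpois(n_tx * n_lib, lambda = mean_mat)
      } else {
        rnbinom(n_tx * n_lib, mu = mean_mat, size = 1 / config$nb_dispersion)
      },
      nrow = n_tx, dimnames = dimnames(mean_mat)
    )

    de <- de_exact_test(counts, libraries)
    list(counts = matrix_to_expr(counts), libraries = libraries, de = de)
  })
}

# Exact NB two-sample test, infected vs control at 4 h, BH-adjusted.
de_exact_test <- function(counts, libraries, fdr_max = 0.05) {
  sel <- libraries$time_h == 4
  if (sum(sel) < 4 || length(unique(libraries$condition[sel])) < 2) {
    abort("DE test needs control and infected libraries at 4 h")
  }
  grp <- factor(libraries$condition[sel], levels = c("control", "infected"))
  d <- edgeR::DGEList(counts = counts[, sel, drop = FALSE], group = grp)
  # TMM + robust dispersion: a few strongly modulated transcripts dominate
  # raw library sizes and would otherwise distort everyone's fold changes
  # and inflate the common dispersion
  d <- edgeR::calcNormFactors(d)
  d <- suppressMessages(edgeR::estimateDisp(d, robust = TRUE))
  et <- edgeR::exactTest(d, pair = c("control", "infected"))
  tab <- et$table
  tibble(
    transcript_id = rownames(tab),
    log2fc = tab$logFC,
    pvalue = tab$PValue,
    fdr = p.adjust(tab$PValue, method = "BH")
  ) |>
    mutate(direction = de_direction(.data$log2fc, .data$fdr, fdr_max))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [simulate_sequences()] and
#' [simulate_counts()] and attaching per-site hybridization-energy records
#' for the planted pairs (and an equal number of decoy pairs) from the
#' non-physical [naive_duplex_energy()] scorer.
#'
#' @param config A [synthetic_config()].
#' @return List with `transcripts`, `truth`, `homology_hits`,
#'   `domain_hits`, `coding_labels`, `counts`, `libraries`, `de`,
#'   `energy_sites`, `annotation`, `config`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  seqs <- simulate_sequences(config)
  cnt <- simulate_counts(config, seqs$truth)
  energy_sites <- with_seed(derive_seed(config$seed, "energies"), {
    pp <- seqs$truth$planted_pairs
    n_decoy <- nrow(pp)
    decoys <- if (n_decoy > 0 && length(seqs$truth$true_lncrna_ids) > 0) {
      tibble(
        lncrna_id = sample(seqs$truth$true_lncrna_ids, n_decoy, replace = TRUE),
        mrna_id = sample(seqs$truth$true_coding_ids, n_decoy, replace = TRUE)
      )
    } else {
      tibble(lncrna_id = character(), mrna_id = character())
    }
    pairs <- bind_rows(pp, decoys) |> distinct()
    bind_rows(pmap(pairs, function(lncrna_id, mrna_id) {
      n_sites <- sample(1:4, 1)
      tibble(lncrna_id = lncrna_id, mrna_id = mrna_id,
             energy = -round(10^runif(n_sites, -0.2, 1.6), 2))
    }))
  })
  annotation <- with_seed(derive_seed(config$seed, "annotation"), {
    bg <- seqs$truth$true_coding_ids
    if (length(bg) >= 10) {
      bind_rows(lapply(seq_len(10), function(t) {
        tibble(term_id = sprintf("TERM:%04d", t),
               member_id = sample(bg, sample(5:min(30, length(bg)), 1)))
      }))
    } else {
      tibble(term_id = character(), member_id = character())
    }
  })
  c(seqs, cnt,
    list(energy_sites = energy_sites, annotation = annotation,
         config = config))
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Produces `transcripts.gtf`, `transcripts.fasta`, `homology_hits.tsv`
#' (12-column, headerless), `domain_hits.tsv`, `cpc_labels.tsv`,
#' `counts.tsv`, `libraries.tsv`, `de.tsv`, `energy_sites.tsv`,
#' `annotation.tsv` and `truth.json`.  Output is a deterministic function
#' of the study object.
#'
#' @param study A study list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gtf(study$transcripts, p("transcripts.gtf"))
  write_fasta(setNames(study$transcripts$sequence[!is.na(study$transcripts$sequence)],
                       study$transcripts$transcript_id[!is.na(study$transcripts$sequence)]),
              p("transcripts.fasta"))
  readr::write_tsv(study$homology_hits, p("homology_hits.tsv"),
                   col_names = FALSE)
  readr::write_tsv(study$domain_hits, p("domain_hits.tsv"))
  readr::write_tsv(study$coding_labels, p("cpc_labels.tsv"))
  readr::write_tsv(study$counts, p("counts.tsv"))
  readr::write_tsv(study$libraries, p("libraries.tsv"))
  readr::write_tsv(study$de, p("de.tsv"))
  readr::write_tsv(study$energy_sites, p("energy_sites.tsv"))
  readr::write_tsv(study$annotation, p("annotation.tsv"))
  truth <- study$truth
  jsonlite::write_json(
    list(true_coding_ids = truth$true_coding_ids,
         true_lncrna_ids = truth$true_lncrna_ids,
         planted_pairs = truth$planted_pairs,
         planted_de = truth$planted_de),
    p("truth.json"), auto_unbox = FALSE, digits = NA)
  files <- c("transcripts.gtf", "transcripts.fasta", "homology_hits.tsv",
             "domain_hits.tsv", "cpc_labels.tsv", "counts.tsv",
             "libraries.tsv", "de.tsv", "energy_sites.tsv", "annotation.tsv",
             "truth.json")
  invisible(setNames(file.path(dir, files), files))
}
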