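# Stepwise lncRNA identification cascade.
#
# Stage order is fixed: protein-homology exclusion -> minimum length ->
# longest-ORF rule -> coding-potential labels -> protein-domain table.
# A transcript is removed at the FIRST failing stage; the per-stage counts
# therefore always partition the input set.

FILTER_STAGES <- c("removed:homology", "removed:length", "removed:orf",
                   "removed:coding_potential", "removed:domain", "lncRNA")

#' Configuration of the lncRNA filter cascade
#'
#' Defaults follow the conventional thresholds: homology exclusion at
#' E-value 1e-3 (the only stated protein-search cutoff, reused for the
#' exclusion step), minimum length 200 nt, and a longest-ORF cap of 100 aa
#' ("less than 100 aa" is kept, i.e. a transcript whose longest stop-to-stop
#' ORF reaches 100 aa is removed).
#'
#' @param homology_evalue_max Remove transcripts with at least one homology
#'   hit at E-value at or below this cutoff.
#' @param min_length_nt Minimum transcript length retained.
#' @param max_orf_aa Transcripts whose longest ORF reaches this many amino
#'   acids are removed.
#' @param require_coding_potential_labels Error when no coding-potential
#'   label table is supplied (otherwise the stage passes everything
#'   through).
#' @param require_domain_table Same for the protein-domain stage.
#' @return An `lnc_filter_config` list.
#' @export
filter_config <- function(homology_evalue_max = 1e-3,
                          min_length_nt = 200,
                          max_orf_aa = 100,
                          require_coding_potential_labels = FALSE,
                          require_domain_table = FALSE) {
  assert_scalar_number(homology_evalue_max, "homology_evalue_max", min = 0)
  assert_scalar_number(min_length_nt, "min_length_nt", min = 1)
  assert_scalar_number(max_orf_aa, "max_orf_aa", min = 1)
  structure(list(homology_evalue_max = homology_evalue_max,
                 min_length_nt = min_length_nt,
                 max_orf_aa = max_orf_aa,
                 require_coding_potential_labels = require_coding_potential_labels,
                 require_domain_table = require_domain_table),
            class = "lnc_filter_config")
}

#' Run the stepwise lncRNA identification cascade
#'
#' @param transcripts Transcript model tibble with sequences attached (the
#'   `sequence` column is used for the length and ORF stages; if absent,
#'   `length_nt` is used for length and the ORF stage errors).
#' @param homology_hits Homology hit table ([read_hits()] layout), or
#'   `NULL` for none.
#' @param domain_hits Domain hit table ([read_domain_hits()] layout), or
#'   `NULL` to pass the stage through.
#' @param coding_labels Tibble with `transcript_id`, `label` (ids labeled
#'   `"coding"` are removed), or `NULL` to pass the stage through.
#' @param config A [filter_config()].
#' @return An `lnc_filter_report`: a list with `report` (one row per input
#'   transcript: id, terminal `status`, `length_nt`, `longest_orf_aa` where
#'   evaluated, `n_hits`), `stage_counts`, `lncrna_ids`, `config`.
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
run_filter_cascade <- function(transcripts, homology_hits = NULL,
                               domain_hits = NULL, coding_labels = NULL,
                               config = filter_config()) {
  stopifnot(inherits(config, "lnc_filter_config"))
  assert_columns(transcripts, c("transcript_id", "sequence"),
                 "transcript table")
  if (anyDuplicated(transcripts$transcript_id)) {
    abort("duplicate transcript ids in input")
  }
  if (config$require_coding_potential_labels && is.null(coding_labels)) {
    abort("config requires coding-potential labels but none were supplied")
  }
  if (config$require_domain_table && is.null(domain_hits)) {
    abort("config requires a domain hit table but none was supplied")
  }
  check_ids <- function(tbl, col, what) {
    if (is.null(tbl) || nrow(tbl) == 0) return(invisible(NULL))
    unknown <- setdiff(unique(tbl[[col]]), transcripts$transcript_id)
    if (length(unknown) > 0) {
      abort(sprintf("%s references unknown transcript id(s): %s", what,
                    paste(head(unknown, 5), collapse = ", ")))
    }
  }
  check_ids(homology_hits, "query_id", "homology hit table")
  check_ids(domain_hits, "query_id", "domain hit table")
  check_ids(coding_labels, "transcript_id", "coding-potential label table")

  report <- tibble(
    transcript_id = transcripts$transcript_id,
    status = NA_character_,
    length_nt = if ("sequence" %in% names(transcripts) &&
                    !all(is.na(transcripts$sequence))) {
      ifelse(is.na(transcripts$sequence), transcripts$length_nt,
             nchar(transcripts$sequence))
    } else {
      transcripts$length_nt
    },
    longest_orf_aa = NA_integer_,
    n_hits = 0L
  )

  # stage 1: homology exclusion
  if (!is.null(homology_hits) && nrow(homology_hits) > 0) {
    sig <- homology_hits |>
      filter(.data$evalue <= config$homology_evalue_max) |>
      count(.data$query_id)
    idx <- match(sig$query_id, report$transcript_id)
    report$n_hits[idx] <- sig$n
    report$status[idx] <- "removed:homology"
  }

  # stage 2: minimum length
  alive <- is.na(report$status)
  report$status[alive & report$length_nt < config$min_length_nt] <-
    "removed:length"

  # stage 3: longest stop-to-stop ORF over six frames
  alive <- which(is.na(report$status))
  if (length(alive) > 0) {
    seqs <- transcripts$sequence[alive]
    if (any(is.na(seqs))) {
      abort("transcripts reaching the ORF stage must have sequences attached")
    }
    orfs <- map_int(seqs, \(s) longest_orf(s)$longest_orf_aa)
    report$longest_orf_aa[alive] <- orfs
    report$status[alive[orfs >= config$max_orf_aa]] <- "removed:orf"
  }

  # stage 4: coding-potential labels (plug-in classifier output)
  if (!is.null(coding_labels) && nrow(coding_labels) > 0) {
    coding_ids <- coding_labels$transcript_id[coding_labels$label == "coding"]
    report$status[is.na(report$status) &
                    report$transcript_id %in% coding_ids] <-
      "removed:coding_potential"
  }

  # stage 5: protein domains (any listed id is removed)
  if (!is.null(domain_hits) && nrow(domain_hits) > 0) {
    report$status[is.na(report$status) &
                    report$transcript_id %in% domain_hits$query_id] <-
      "removed:domain"
  }

  report$status[is.na(report$status)] <- "lncRNA"
  stage_counts <- tibble(stage = FILTER_STAGES) |>
    left_join(count(report, .data$status), by = c(stage = "status")) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))

  structure(
    list(report = report,
         stage_counts = stage_counts,
         lncrna_ids = report$transcript_id[report$status == "lncRNA"],
         config = config),
    class = "lnc_filter_report")
}

#' @export
print.lnc_filter_report <- function(x, ...) {
  cat("lncRNA filter cascade report\n")
  cat(sprintf("  input transcripts: %d\n", nrow(x$report)))
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-26s %6d\n", x$stage_counts$stage[i],
                x$stage_counts$n[i]))
  }
  invisible(x)
}

#' @export
tidy.lnc_filter_report <- function(x, ...) x$report

#' @export
glance.lnc_filter_report <- function(x, ...) {
  cnt <- setNames(x$stage_counts$n, x$stage_counts$stage)
  tibble(
    n_input = nrow(x$report),
    n_removed_homology = cnt[["removed:homology"]],
    n_removed_length = cnt[["removed:length"]],
    n_removed_orf = cnt[["removed:orf"]],
    n_candidates = nrow(x$report) - cnt[["removed:homology"]] -
      cnt[["removed:length"]] - cnt[["removed:orf"]],
    n_removed_coding_potential = cnt[["removed:coding_potential"]],
    n_removed_domain = cnt[["removed:domain"]],
    n_lncrna = cnt[["lncRNA"]]
  )
}

#' @export
autoplot.lnc_filter_report <- function(object, ...) {
  df <- object$stage_counts |>
    mutate(stage = factor(.data$stage, levels = rev(FILTER_STAGES)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "transcripts", y = NULL,
                  title = "lncRNA filter cascade: terminal status") +
    ggplot2::theme_minimal()
}

#' Feature characterization of lncRNAs versus mRNAs
#'
#' Per-transcript features (length, longest ORF, exon count, mean
#' normalized expression when counts are given) split into lncRNA and mRNA
#' classes, with per-class summary quartiles -- the usual length/ORF/exon
#' count comparison between the two classes.
#'
#' @param transcripts Transcript model tibble with sequences.
#' @param lncrna_ids Character vector of ids classified as lncRNA; all
#'   other transcripts are treated as mRNA.
#' @param counts Optional wide count tibble; when given, expression is
#'   median-of-ratios normalized and the per-transcript mean of
#'   `log10(normalized + 1)` is added.
#' @return An `lnc_features` list with `features` (per transcript) and
#'   `summary` (per class and feature: median and quartiles).  Methods:
#'   [tidy()], [autoplot()].
#' @export
characterize_transcripts <- function(transcripts, lncrna_ids, counts = NULL) {
  unknown <- setdiff(lncrna_ids, transcripts$transcript_id)
  if (length(unknown) > 0) {
    abort(sprintf("unknown lncRNA id(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  feats <- transcripts |>
    mutate(class = ifelse(.data$transcript_id %in% lncrna_ids,
                          "lncRNA", "mRNA")) |>
    select("transcript_id", "class", "length_nt", "n_exons", "sequence")
  feats$longest_orf_aa <- ifelse(
    is.na(feats$sequence), NA_integer_,
    map_int(feats$sequence, \(s) longest_orf(s)$longest_orf_aa))
  feats$sequence <- NULL
  if (!is.null(counts)) {
    norm <- normalize_counts(counts)
    m <- expr_to_matrix(norm$normalized)
    feats$mean_log10_expr <-
      rowMeans(log10(m + 1))[match(feats$transcript_id, rownames(m))]
  }
  value_cols <- intersect(c("length_nt", "n_exons", "longest_orf_aa",
                            "mean_log10_expr"), names(feats))
  summary <- feats |>
    tidyr::pivot_longer(all_of(value_cols), names_to = "feature") |>
    group_by(.data$class, .data$feature) |>
    summarise(
      n = sum(!is.na(.data$value)),
      q25 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      median = median(.data$value, na.rm = TRUE),
      q75 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
  structure(list(features = feats, summary = summary),
            class = "lnc_features")
}

#' @export
tidy.lnc_features <- function(x, ...) x$features

#' @export
print.lnc_features <- function(x, ...) {
  cat("Transcript feature characterization\n")
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.lnc_features <- function(object, feature = "length_nt", ...) {
  df <- object$features
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data[[feature]]),
                                   fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = sprintf("log10(%s)", feature),
                  title = "lncRNA vs mRNA feature distribution") +
    ggplot2::theme_minimal()
}
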