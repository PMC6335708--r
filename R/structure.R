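# Transcript structure analyses: grouping transcripts into loci,
# classification of the five canonical alternative-splicing modes from
# exon chains, condition-specific transcript overlap, and novel-vs-known
# calling against a reference-transcriptome hit table.
#
# All coordinates here are package-internal 0-based half-open intervals.
# An intron of a transcript is the gap between two consecutive exons; on
# the plus strand the intron start is its donor (5') boundary and the
# intron end its acceptor (3') boundary, and vice versa on the minus
# strand.

introns_of <- function(exons) {
  n <- nrow(exons)
  if (n < 2) return(tibble(start = integer(0), end = integer(0)))
  tibble(start = exons$end[-n], end = exons$start[-1])
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Group transcripts into loci by exonic overlap
#'
#' Loci are connected components of the exonic-overlap relation between
#' transcripts on the same chromosome and strand.
#'
#' @param transcripts Transcript model tibble.
#' @return `transcripts` with a `locus_id` column added.
#' @export
transcript_loci <- function(transcripts) {
  if (nrow(transcripts) == 0) {
    return(mutate(transcripts, locus_id = character(0)))
  }
  spans <- transcripts |>
    mutate(span_start = map_int(.data$exons, \(e) min(e$start)),
           span_end = map_int(.data$exons, \(e) max(e$end)))
  edges <- spans |>
    group_by(.data$chrom, .data$strand) |>
    group_map(function(g, key) {
      n <- nrow(g)
      if (n < 2) return(NULL)
      pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
      keep <- map_lgl(seq_len(nrow(pairs)), function(p) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        if (!overlaps(g$span_start[i], g$span_end[i],
                      g$span_start[j], g$span_end[j])) return(FALSE)
        ei <- g$exons[[i]]; ej <- g$exons[[j]]
        any(outer(seq_len(nrow(ei)), seq_len(nrow(ej)), function(a, b) {
          overlaps(ei$start[a], ei$end[a], ej$start[b], ej$end[b])
        }))
      })
      if (!any(keep)) return(NULL)
      tibble(from = g$transcript_id[pairs[keep, 1]],
             to = g$transcript_id[pairs[keep, 2]])
    }) |> bind_rows()
  g <- igraph::graph_from_data_frame(
    if (nrow(edges) > 0) edges else tibble(from = character(), to = character()),
    directed = FALSE,
    vertices = tibble(name = transcripts$transcript_id))
  comp <- igraph::components(g)$membership
  transcripts |>
    mutate(locus_id = sprintf("locus_%04d",
                              comp[.data$transcript_id]))
}

#' Classify alternative-splicing events between transcripts of one locus
#'
#' For every unordered transcript pair of the locus, reports all matching
#' canonical events:
#' * `intron_retention` -- one transcript has an exon fully spanning an
#'   intron of the other, including both flanking exon edges;
#' * `exon_skipping` -- an internal exon of one transcript is absent from
#'   the other while both flanking exon boundaries are shared;
#' * `alt_5_donor` / `alt_3_acceptor` -- a shared intron differs only at
#'   its donor (5') or acceptor (3') boundary (labels strand-aware), with
#'   the flanking exons at the differing boundary overlapping;
#' * `mutually_exclusive_exon` -- two non-overlapping internal exons, one
#'   per transcript, each absent from the other, between shared flanking
#'   boundaries.
#'
#' @param transcripts Transcript model tibble; all rows must share `chrom`
#'   and `strand` (mixed strands are an error).
#' @return Tibble of events: `transcript_a`, `transcript_b`, `mode`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open defining
#'   interval), `detail` (which transcript retains/contains the feature).
#' @export
classify_events <- function(transcripts) {
  if (nrow(transcripts) < 2) return(empty_event_tbl())
  if (length(unique(transcripts$chrom)) > 1) {
    abort("transcripts of one locus must share a chromosome")
  }
  if (length(unique(transcripts$strand)) > 1) {
    abort("mixed strands in one locus")
  }
  strand <- transcripts$strand[1]
  chrom <- transcripts$chrom[1]
  out <- list()
  n <- nrow(transcripts)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ev <- pair_events(transcripts$transcript_id[i], transcripts$exons[[i]],
                        transcripts$transcript_id[j], transcripts$exons[[j]],
                        strand)
      if (nrow(ev) > 0) out[[length(out) + 1]] <- ev
    }
  }
  if (length(out) == 0) return(empty_event_tbl())
  bind_rows(out) |> mutate(chrom = chrom, strand = strand) |>
    relocate("transcript_a", "transcript_b", "mode", "chrom", "strand",
             "start", "end", "detail")
}

empty_event_tbl <- function() {
  tibble(transcript_a = character(), transcript_b = character(),
         mode = character(), chrom = character(), strand = character(),
         start = integer(), end = integer(), detail = character())
}

pair_events <- function(id_a, ex_a, id_b, ex_b, strand) {
  out <- list()
  add <- function(mode, start, end, detail) {
    out[[length(out) + 1]] <<- tibble(
      transcript_a = id_a, transcript_b = id_b, mode = mode,
      start = as.integer(start), end = as.integer(end), detail = detail)
  }
  in_a <- introns_of(ex_a)
  in_b <- introns_of(ex_b)

  # intron retention: an exon of one spans an intron of the other plus at
  # least one nt of each flanking exon
  ir_scan <- function(ex_ret, intr, retainer) {
    for (k in seq_len(nrow(intr))) {
      hit <- ex_ret$start < intr$start[k] & ex_ret$end > intr$end[k]
      if (any(hit)) {
        add("intron_retention", intr$start[k], intr$end[k],
            sprintf("retained_by=%s", retainer))
      }
    }
  }
  ir_scan(ex_a, in_b, id_a)
  ir_scan(ex_b, in_a, id_b)

  # exon skipping: internal exon of one, absent from the other, flanking
  # boundaries shared with a consecutive exon pair of the other
  es_scan <- function(ex_inc, ex_skp, includer, skipper) {
    n_inc <- nrow(ex_inc)
    if (n_inc < 3 || nrow(ex_skp) < 2) return(invisible(NULL))
    for (k in seq(2, n_inc - 1)) {
      prev_end <- ex_inc$end[k - 1]
      next_start <- ex_inc$start[k + 1]
      js <- which(ex_skp$end[-nrow(ex_skp)] == prev_end &
                    ex_skp$start[-1] == next_start)
      if (length(js) == 0) next
      x_s <- ex_inc$start[k]; x_e <- ex_inc$end[k]
      if (any(overlaps(x_s, x_e, ex_skp$start, ex_skp$end))) next
      add("exon_skipping", x_s, x_e,
          sprintf("contained_by=%s;skipped_in=%s", includer, skipper))
    }
  }
  es_scan(ex_a, ex_b, id_a, id_b)
  es_scan(ex_b, ex_a, id_b, id_a)

  # alternative donor/acceptor: introns sharing exactly one boundary, with
  # the flanking exons at the differing boundary overlapping
  if (nrow(in_a) > 0 && nrow(in_b) > 0) {
    for (ka in seq_len(nrow(in_a))) {
      for (kb in seq_len(nrow(in_b))) {
        sa <- in_a$start[ka]; ea <- in_a$end[ka]
        sb <- in_b$start[kb]; eb <- in_b$end[kb]
        if (sa == sb && ea != eb) {
          # differ at the intron end (genomic right boundary)
          down_a <- ex_a[ex_a$start == ea, , drop = FALSE]
          down_b <- ex_b[ex_b$start == eb, , drop = FALSE]
          if (nrow(down_a) == 1 && nrow(down_b) == 1 &&
              overlaps(down_a$start, down_a$end, down_b$start, down_b$end)) {
            mode <- if (strand == "-") "alt_5_donor" else "alt_3_acceptor"
            add(mode, min(ea, eb), max(ea, eb),
                sprintf("boundary=%s", if (strand == "-") "donor" else "acceptor"))
          }
        } else if (ea == eb && sa != sb) {
          # differ at the intron start (genomic left boundary)
          up_a <- ex_a[ex_a$end == sa, , drop = FALSE]
          up_b <- ex_b[ex_b$end == sb, , drop = FALSE]
          if (nrow(up_a) == 1 && nrow(up_b) == 1 &&
              overlaps(up_a$start, up_a$end, up_b$start, up_b$end)) {
            mode <- if (strand == "-") "alt_3_acceptor" else "alt_5_donor"
            add(mode, min(sa, sb), max(sa, sb),
                sprintf("boundary=%s", if (strand == "-") "acceptor" else "donor"))
          }
        }
      }
    }
  }

  # mutually exclusive exons: one internal exon per transcript, mutually
  # non-overlapping and absent from the other, between shared boundaries
  na <- nrow(ex_a); nb <- nrow(ex_b)
  if (na >= 3 && nb >= 3) {
    for (ka in seq(2, na - 1)) {
      for (kb in seq(2, nb - 1)) {
        xa_s <- ex_a$start[ka]; xa_e <- ex_a$end[ka]
        xb_s <- ex_b$start[kb]; xb_e <- ex_b$end[kb]
        if (overlaps(xa_s, xa_e, xb_s, xb_e)) next
        if (ex_a$end[ka - 1] != ex_b$end[kb - 1]) next
        if (ex_a$start[ka + 1] != ex_b$start[kb + 1]) next
        if (any(overlaps(xa_s, xa_e, ex_b$start, ex_b$end))) next
        if (any(overlaps(xb_s, xb_e, ex_a$start, ex_a$end))) next
        add("mutually_exclusive_exon", min(xa_s, xb_s), max(xa_e, xb_e),
            sprintf("exon_a=%d-%d;exon_b=%d-%d", xa_s, xa_e, xb_s, xb_e))
      }
    }
  }

  if (length(out) == 0) return(
    tibble(transcript_a = character(), transcript_b = character(),
           mode = character(), start = integer(), end = integer(),
           detail = character()))
  bind_rows(out)
}

#' Find alternative-splicing events across a whole transcript set
#'
#' Groups transcripts into loci with [transcript_loci()] and runs
#' [classify_events()] within each locus.
#'
#' @param transcripts Transcript model tibble.
#' @return Event tibble with a `locus_id` column.
#' @export
find_as_events <- function(transcripts) {
  with_loci <- transcript_loci(transcripts)
  with_loci |>
    group_by(.data$locus_id) |>
    group_map(function(g, key) {
      ev <- classify_events(g)
      if (nrow(ev) == 0) return(NULL)
      ev$locus_id <- key$locus_id
      ev
    }) |>
    bind_rows() |>
    (\(d) if (nrow(d) == 0) mutate(empty_event_tbl(), locus_id = character(0))
          else relocate(d, "locus_id"))()
}

#' Splicing-mode distribution
#'
#' Proportion of events per mode (optionally per status), after
#' deduplicating events with identical mode and coordinates within a locus
#' (the default: a distribution of event types, not of transcript pairs).
#'
#' @param events Event tibble from [find_as_events()] or
#'   [classify_events()]; an optional `status` column groups the
#'   distribution.
#' @param dedupe Deduplicate identical (locus, mode, coordinates) events
#'   (default `TRUE`).
#' @return Tibble with (`status`,) `mode`, `n`, `proportion`; proportions
#'   sum to 1 within each status when events exist. Zero events give an
#'   empty (zero-row) table.
#' @export
event_mode_distribution <- function(events, dedupe = TRUE) {
  if (nrow(events) == 0) {
    return(tibble(mode = character(), n = integer(), proportion = numeric()))
  }
  grouping <- intersect("status", names(events))
  if (dedupe) {
    keys <- intersect(c("status", "locus_id", "mode", "chrom", "strand",
                        "start", "end"), names(events))
    events <- distinct(events, across(all_of(keys)))
  }
  events |>
    group_by(across(all_of(grouping))) |>
    count(mode = factor(.data$mode, levels = AS_MODES), .drop = FALSE) |>
    mutate(proportion = .data$n / sum(.data$n),
           mode = as.character(.data$mode)) |>
    ungroup()
}

#' Canonical structure key of each transcript
#'
#' The identity used to compare transcripts across independently assembled
#' condition sets: chromosome, strand and intron chain for multi-exon
#' transcripts; chromosome, strand and exact exon coordinates for
#' mono-exon transcripts.
#'
#' @param transcripts Transcript model tibble.
#' @return Character vector of keys, parallel to the rows.
#' @export
structure_key <- function(transcripts) {
  map_chr(seq_len(nrow(transcripts)), function(i) {
    ex <- transcripts$exons[[i]]
    if (nrow(ex) > 1) {
      intr <- introns_of(ex)
      sprintf("%s:%s:I:%s", transcripts$chrom[i], transcripts$strand[i],
              paste(intr$start, intr$end, sep = "-", collapse = ","))
    } else {
      sprintf("%s:%s:E:%d-%d", transcripts$chrom[i], transcripts$strand[i],
              ex$start, ex$end)
    }
  })
}

#' Overlap of transcript sets across statuses
#'
#' @param status_sets Long tibble with columns `status` and `key`
#'   (canonical structure keys, e.g. from [structure_key()]); at least two
#'   distinct statuses.
#' @return List with `cells` (one row per observed membership pattern:
#'   `statuses` label, `n`), `specific` (per status: keys present in that
#'   status only), and `n_union`.
#' @export
status_overlap <- function(status_sets) {
  assert_columns(status_sets, c("status", "key"), "status set table")
  statuses <- unique(status_sets$status)
  if (length(statuses) < 2) abort("need at least two statuses")
  membership <- status_sets |>
    distinct(.data$status, .data$key) |>
    group_by(.data$key) |>
    summarise(statuses = paste(sort(unique(.data$status)), collapse = "&"),
              n_statuses = n_distinct(.data$status), .groups = "drop")
  cells <- membership |> count(.data$statuses, name = "n") |>
    arrange(desc(.data$n), .data$statuses)
  specific <- membership |>
    filter(.data$n_statuses == 1) |>
    count(status = .data$statuses, name = "n_specific")
  specific <- tibble(status = sort(statuses)) |>
    left_join(specific, by = "status") |>
    mutate(n_specific = ifelse(is.na(.data$n_specific), 0L, .data$n_specific))
  list(cells = cells, specific = specific, n_union = nrow(membership))
}

#' Classify transcripts as known or novel against a reference hit table
#'
#' A query is `known` when it has at least one reference hit at or below
#' the E-value cutoff, `novel` otherwise.
#'
#' @param query_ids Character vector of transcript ids.
#' @param reference_hits Hit table ([read_hits()] layout) of the queries
#'   against the reference transcriptome.
#' @param evalue_max E-value cutoff (default 1e-5).
#' @return Tibble with `transcript_id` and `novelty` in `known`/`novel`.
#' @export
classify_novelty <- function(query_ids, reference_hits, evalue_max = 1e-5) {
  known <- reference_hits |>
    filter(.data$evalue <= evalue_max) |>
    pull("query_id") |> unique()
  tibble(transcript_id = query_ids,
         novelty = ifelse(query_ids %in% known, "known", "novel"))
}
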