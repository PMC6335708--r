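# Readers and writers for the external formats the pipeline consumes:
# transcript models (GTF), sequences (FASTA), homology / domain hit tables,
# count matrices with library metadata, differential-expression tables,
# per-site hybridization-energy tables and network exports.
#
# Internal coordinate convention: 0-based half-open intervals.  GTF I/O
# converts from/to the 1-based inclusive convention of the format, so
# interval arithmetic inside the package is uniform.

#' Read transcript models from a GTF file
#'
#' Parses the `exon` features of a GTF file into one transcript model per
#' `transcript_id`: chromosome, strand, and a sorted, merged exon chain.
#' GTF 1-based inclusive coordinates are converted to the package-internal
#' 0-based half-open convention; [write_gtf()] inverts the conversion
#' exactly.
#'
#' @param path Path to a GTF file with `exon` features carrying
#'   `transcript_id` (and optionally `gene_id`) attributes.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`"+"`, `"-"` or `"."` for unstranded assembler output),
#'   `exons` (list-column of tibbles with 0-based half-open `start`/`end`),
#'   `n_exons`, `length_nt` and `sequence` (`NA` until attached with
#'   [attach_sequences()]).
#' @export
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0("chr1\tasm\texon\t1\t100\t.\t+\t.\t",
#'                   'transcript_id "t1"; gene_id "g1";'), gtf)
#' read_gtf(gtf)
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0) return(empty_transcript_tbl())
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfields < 9]
  if (length(bad) > 0) {
    abort(sprintf("GTF parse error: line %d has %d tab-separated fields (9 required)",
                  bad[1], nfields[which(body == bad[1])]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == "exon"]
  if (length(gr) == 0) return(empty_transcript_tbl())
  tid <- as.character(gr$transcript_id)
  if (any(is.na(tid) | !nzchar(tid))) {
    abort("GTF record error: exon feature without a transcript_id attribute")
  }
  gid <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$gene_id)
  } else {
    rep(NA_character_, length(gr))
  }
  gid <- ifelse(is.na(gid) | !nzchar(gid), tid, gid)
  ex <- tibble(
    transcript_id = tid,
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = chartr("*", ".", as.character(BiocGenerics::strand(gr))),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr)
  )
  models <- ex |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      exons = list(merge_exons(pick("start", "end"))),
      .groups = "drop"
    ) |>
    mutate(
      n_exons = map_int(.data$exons, nrow),
      length_nt = map_int(.data$exons, \(e) as.integer(exon_span(e))),
      sequence = NA_character_
    )
  multi <- ex |> distinct(.data$transcript_id, .data$chrom, .data$strand) |>
    count(.data$transcript_id) |> filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(sprintf("transcript(s) with exons on multiple chromosomes/strands: %s",
                  paste(multi$transcript_id, collapse = ", ")))
  }
  for (i in seq_len(nrow(models))) {
    validate_exons(models$exons[[i]], models$transcript_id[i])
  }
  models
}

empty_transcript_tbl <- function() {
  tibble(transcript_id = character(), gene_id = character(),
         chrom = character(), strand = character(), exons = list(),
         n_exons = integer(), length_nt = integer(), sequence = character())
}

# Sort and merge book-ended/overlapping exon intervals of one transcript.
merge_exons <- function(ex) {
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  if (nrow(ex) > 1) {
    keep_start <- ex$start[1]
    out_s <- integer(0); out_e <- integer(0)
    cur_s <- ex$start[1]; cur_e <- ex$end[1]
    for (i in seq_len(nrow(ex))[-1]) {
      if (ex$start[i] <= cur_e) {
        cur_e <- max(cur_e, ex$end[i])
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        cur_s <- ex$start[i]; cur_e <- ex$end[i]
      }
    }
    ex <- tibble(start = c(out_s, cur_s), end = c(out_e, cur_e))
  }
  tibble(start = as.integer(ex$start), end = as.integer(ex$end))
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exon coordinates are
#' written back as 1-based inclusive GTF `exon` features, so a read/write
#' cycle reproduces the input coordinates exactly.
#'
#' @param transcripts Transcript model tibble as produced by [read_gtf()]
#'   or [simulate_sequences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  if (nrow(transcripts) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rows <- pmap(
    list(transcripts$transcript_id, transcripts$gene_id, transcripts$chrom,
         transcripts$strand, transcripts$exons),
    function(tid, gid, chrom, strand, exons) {
      tibble(chrom = chrom, start = exons$start + 1L, end = exons$end,
             strand = if (strand == ".") "*" else strand,
             transcript_id = tid, gene_id = gid)
    }
  ) |> bind_rows()
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand
  )
  gr$source <- "lncnet"
  gr$type <- "exon"
  gr$gene_id <- rows$gene_id
  gr$transcript_id <- rows$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping record id (first whitespace token
#'   of the header) to its sequence. Sequences are upper-cased and `U` is
#'   converted to `T`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- chartr("u", "t", toupper(as.character(ss)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warn(sprintf("FASTA record(s) with empty sequence retained: %s",
                 paste(ids[empty], collapse = ", ")))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Attach sequences to transcript models
#'
#' @param transcripts Transcript model tibble.
#' @param sequences Named character vector (e.g. from [read_fasta()]).
#' @param check_length Error when a sequence length does not equal the
#'   summed exon length of its model (default `TRUE`).
#' @return `transcripts` with the `sequence` column filled in.
#' @export
attach_sequences <- function(transcripts, sequences, check_length = TRUE) {
  idx <- match(transcripts$transcript_id, names(sequences))
  transcripts$sequence <- unname(sequences[idx])
  if (check_length) {
    have <- !is.na(transcripts$sequence)
    bad <- have & nchar(transcripts$sequence) != transcripts$length_nt
    if (any(bad)) {
      abort(sprintf("sequence length != summed exon length for: %s",
                    paste(transcripts$transcript_id[bad], collapse = ", ")))
    }
  }
  transcripts
}

#' Read a tabular homology hit table
#'
#' Parses the common 12-column tab-separated hit dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`).  Columns beyond `min_columns` are ignored; comment
#' lines starting with `#` are skipped.  No filtering is applied here.
#'
#' @param path Path to the tab-separated hit table.
#' @param min_columns Minimum number of columns a row must have
#'   (default 12).
#' @return Tibble with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`, in input
#'   row order.
#' @export
read_hits <- function(path, min_columns = 12) {
  if (!file.exists(path)) abort(sprintf("hit table not found: %s", path))
  cols <- c("query_id", "subject_id", "percent_identity", "align_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) {
    return(as_tibble(setNames(
      c(rep(list(character()), 2), rep(list(numeric()), 10)), cols)))
  }
  if (ncol(raw) < min_columns) {
    abort(sprintf("hit table has %d column(s); at least %d required",
                  ncol(raw), min_columns))
  }
  raw <- raw[, seq_len(12)]
  names(raw) <- cols
  out <- suppressWarnings(
    raw |> mutate(across(!c("query_id", "subject_id"), as.numeric)))
  numbad <- out |> summarise(across(!c("query_id", "subject_id"),
                                    \(x) sum(is.na(x))))
  if (any(unlist(numbad) > 0)) {
    bad <- names(numbad)[unlist(numbad) > 0]
    abort(sprintf("hit table parse error: non-numeric value(s) in column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (any(out$evalue < 0)) abort("hit table has negative E-value(s)")
  if (any(!nzchar(out$query_id))) abort("hit table has empty query id(s)")
  out
}

#' Read a protein-domain hit table
#'
#' Tab-separated table with columns `query_id`, `domain_accession`,
#' `domain_evalue` (header optional; detected from the first row).
#'
#' @param path Path to the table.
#' @return Tibble with the three columns above.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) abort(sprintf("domain table not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(query_id = character(), domain_accession = character(),
                  domain_evalue = numeric()))
  }
  if (ncol(raw) < 3) abort("domain table needs 3 columns")
  raw <- raw[, 1:3]
  names(raw) <- c("query_id", "domain_accession", "domain_evalue")
  if (identical(tolower(raw$query_id[1]), "query_id")) raw <- raw[-1, ]
  out <- raw |> mutate(domain_evalue = as.numeric(.data$domain_evalue))
  if (any(is.na(out$domain_evalue))) {
    abort("domain table parse error: non-numeric domain_evalue")
  }
  if (any(out$domain_evalue < 0)) abort("domain table has negative E-value(s)")
  out
}

#' Read a count matrix
#'
#' Tab-separated file whose header gives the library ids and whose first
#' column holds transcript ids.
#'
#' @param path Path to the counts TSV.
#' @return Wide tibble: `transcript_id` plus one numeric column per library.
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE,
                         name_repair = "minimal")
  names(out)[1] <- "transcript_id"
  out <- out |> mutate(across(!"transcript_id", as.numeric))
  if (anyDuplicated(out$transcript_id)) abort("duplicate transcript ids in counts")
  if (any(vapply(out[-1], \(x) any(is.na(x) | x < 0), logical(1)))) {
    abort("counts must be non-negative numbers")
  }
  out
}

#' Read library metadata
#'
#' @param path TSV with columns `library_id`, `condition` (`control` or
#'   `infected`), `time_h` and `replicate`.
#' @return Validated tibble.
#' @export
read_library_info <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccii", progress = FALSE,
                         show_col_types = FALSE)
  validate_library_info(out)
}

validate_library_info <- function(libraries) {
  assert_columns(libraries, c("library_id", "condition", "time_h", "replicate"),
                 "library metadata")
  bad <- setdiff(unique(libraries$condition), c("control", "infected"))
  if (length(bad) > 0) {
    abort(sprintf("unknown condition value(s): %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(libraries[c("condition", "time_h", "replicate")])) {
    abort("(condition, time_h, replicate) must be unique across libraries")
  }
  if (anyDuplicated(libraries$library_id)) abort("duplicate library ids")
  libraries
}

#' Read a differential-expression results table
#'
#' @param path TSV with columns `transcript_id`, `log2fc`, `pvalue`, `fdr`
#'   (a `direction` column, if present, is recomputed and checked).
#' @param fdr_max FDR threshold used to assign direction (default 0.05).
#' @return Tibble with `transcript_id`, `log2fc`, `pvalue`, `fdr`,
#'   `direction` in `up`/`down`/`ns`.
#' @export
read_de_table <- function(path, fdr_max = 0.05) {
  out <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  assert_columns(out, c("transcript_id", "log2fc", "pvalue", "fdr"), "DE table")
  if (any(out$pvalue < 0 | out$pvalue > 1, na.rm = TRUE) ||
      any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE)) {
    abort("DE table p-values/FDR must lie in [0, 1]")
  }
  dir <- de_direction(out$log2fc, out$fdr, fdr_max)
  if ("direction" %in% names(out) && !identical(as.character(out$direction), dir)) {
    abort("DE table `direction` column is inconsistent with log2fc/fdr")
  }
  out$direction <- dir
  out |> select("transcript_id", "log2fc", "pvalue", "fdr", "direction")
}

de_direction <- function(log2fc, fdr, fdr_max = 0.05) {
  dplyr::case_when(
    !is.na(fdr) & fdr <= fdr_max & log2fc > 0 ~ "up",
    !is.na(fdr) & fdr <= fdr_max & log2fc < 0 ~ "down",
    .default = "ns"
  )
}

#' Read a per-site RNA-RNA hybridization-energy table
#'
#' @param path TSV with columns `lncrna_id`, `mrna_id`, `energy` (one row
#'   per predicted interaction site; negative energies are favorable).
#' @return Tibble with those columns.
#' @export
read_energy_sites <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccd", progress = FALSE,
                         show_col_types = FALSE)
  assert_columns(out, c("lncrna_id", "mrna_id", "energy"), "energy table")
  if (any(is.na(out$energy))) abort("energy table parse error: non-numeric energy")
  out
}

# ---- network export / import ------------------------------------------------

#' Write an interaction network to disk
#'
#' Exports to formats Cytoscape and igraph ingest. `graphml` and `tsv`
#' round-trip nodes, edges and attributes through [read_network()];
#' `sif` preserves topology only.
#'
#' @param network An `lnc_network` object from [build_network()].
#' @param path Output path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "lnc_network"))
  nodes <- network$nodes
  edges <- network$edges
  if (format == "sif") {
    lines <- sprintf("%s\tinteracts\t%s", edges$lncrna_id, edges$mrna_id)
    writeLines(lines, path)
    return(invisible(path))
  }
  if (format == "tsv") {
    nd <- nodes |> mutate(record_type = "node")
    ed <- edges |> mutate(record_type = "edge")
    out <- bind_rows(nd, ed) |> relocate("record_type")
    readr::write_tsv(out, path, na = "")
    return(invisible(path))
  }
  # graphml via igraph; character NAs are not representable, map to ""
  nd <- nodes |> mutate(across(where(is.character), \(x) ifelse(is.na(x), "", x)))
  ed <- edges |> mutate(across(where(is.character), \(x) ifelse(is.na(x), "", x)))
  g <- igraph::graph_from_data_frame(
    d = ed |> relocate("lncrna_id", "mrna_id"),
    directed = FALSE,
    vertices = nd |> relocate("id")
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an interaction network written by [write_network()]
#'
#' @param path Path to a `graphml` or `tsv` network file.
#' @param format `"graphml"` or `"tsv"`.
#' @return An `lnc_network` object.
#' @export
read_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    raw <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE,
                           na = c("", "NA"))
    nodes <- raw |> filter(.data$record_type == "node") |>
      select(!"record_type") |>
      select(where(\(x) !all(is.na(x))))
    edges <- raw |> filter(.data$record_type == "edge") |>
      select(!"record_type") |>
      select(where(\(x) !all(is.na(x))))
    return(new_lnc_network(as_tibble(nodes), as_tibble(edges)))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices"))
  # igraph's graphml writer adds its own node ids; the vertex name holds ours
  if (all(c("name", "id") %in% names(nodes))) nodes$id <- NULL
  nodes <- nodes |>
    rename(id = "name") |>
    select(!any_of("id.1"))
  edges <- as_tibble(igraph::as_data_frame(g, what = "edges")) |>
    rename(lncrna_id = "from", mrna_id = "to") |>
    select(!any_of(c("lncrna_id.1", "mrna_id.1")))
  clean <- function(df) {
    df |> mutate(
      across(where(is.character), \(x) ifelse(!nzchar(x), NA_character_, x)),
      across(where(is.numeric), \(x) ifelse(is.nan(x), NA_real_, x))
    )
  }
  new_lnc_network(clean(nodes), clean(edges))
}
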