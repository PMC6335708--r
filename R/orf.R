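# Stop-to-stop open reading frame search over all six frames.
#
# An ORF here is a maximal run of codons containing no stop codon
# (TAA/TAG/TGA), bounded by stop codons or by the sequence ends; no start
# codon is required.  This is deliberately conservative toward calling
# coding potential: boundary-truncated segments count, and codons containing
# N are treated as non-stop so ambiguity cannot fragment a genuine ORF into
# pieces that would slip under the length cap.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest stop-to-stop ORF of a nucleotide sequence
#'
#' Scans all six reading frames (three on the given sequence, three on its
#' reverse complement) for the longest maximal stop-free codon run.  Ties
#' are broken in favor of the plus strand, then the lower frame number,
#' then the leftmost segment.
#'
#' @param sequence A single nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (lower case accepted; `U` is converted to `T`).
#' @return One-row tibble with `longest_orf_aa` (0 for sequences shorter
#'   than one codon), `frame` (`+1 +2 +3 -1 -2 -3`, `NA` when no codon
#'   exists), and `start`/`end`: the 1-based inclusive span of the segment
#'   on the input sequence.
#' @export
#' @examples
#' longest_orf("ATGAAATAG")  # 3 aa, attained on the reverse strand
longest_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, !is.na(sequence))
  s <- chartr("u", "t", toupper(sequence))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGTN]", s)) {
    abort(sprintf("illegal character(s) in sequence: %s",
                  paste(unique(strsplit(gsub("[ACGTN]", "", s), "")[[1]]),
                        collapse = ", ")))
  }
  L <- nchar(s)
  best <- list(aa = 0L, frame = NA_character_, start = NA_integer_,
               end = NA_integer_)
  if (L < 3) {
    return(tibble(longest_orf_aa = 0L, frame = NA_character_,
                  start = NA_integer_, end = NA_integer_))
  }
  rc <- revcomp(s)
  for (strand in c("+", "-")) {
    seq_used <- if (strand == "+") s else rc
    for (f in 1:3) {
      seg <- best_segment(seq_used, f)
      if (is.null(seg)) next
      if (seg$aa > best$aa) {
        if (strand == "+") {
          best <- list(aa = seg$aa, frame = paste0("+", f),
                       start = seg$start, end = seg$end)
        } else {
          # map coordinates on the reverse complement back to the input
          best <- list(aa = seg$aa, frame = paste0("-", f),
                       start = L - seg$end + 1L, end = L - seg$start + 1L)
        }
      }
    }
  }
  tibble(longest_orf_aa = best$aa, frame = best$frame,
         start = best$start, end = best$end)
}

# Longest stop-free codon run in one frame (1-based offset f).
# Returns list(aa, start, end) in coordinates of `s`, or NULL if no codon.
best_segment <- function(s, f) {
  L <- nchar(s)
  if (L - f + 1 < 3) return(NULL)
  starts <- seq.int(f, L - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  is_stop <- codons %in% STOP_CODONS
  r <- rle(is_stop)
  runs_false <- which(!r$values)
  if (length(runs_false) == 0) return(NULL)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  lens <- r$lengths[runs_false]
  k <- runs_false[which.max(lens)]          # leftmost maximal run
  first_codon <- starts_idx[k]
  n_codons <- r$lengths[k]
  list(aa = as.integer(n_codons),
       start = as.integer(starts[first_codon]),
       end = as.integer(starts[first_codon] + 3L * n_codons - 1L))
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement string.
#' @export
revcomp <- function(sequence) {
  chartr("ACGTN", "TGCAN",
         vapply(sequence, \(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Longest ORF for every transcript in a model table
#'
#' @param transcripts Transcript tibble with a `sequence` column.
#' @return Tibble with `transcript_id` and the [longest_orf()] columns.
#' @export
orf_table <- function(transcripts) {
  assert_columns(transcripts, c("transcript_id", "sequence"), "transcript table")
  if (any(is.na(transcripts$sequence))) {
    abort("orf_table() needs sequences attached for every transcript")
  }
  bind_cols(
    tibble(transcript_id = transcripts$transcript_id),
    bind_rows(map(transcripts$sequence, longest_orf))
  )
}
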