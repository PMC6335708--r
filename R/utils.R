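# Internal helpers shared across modules.

# Deterministic child seed derived from a user seed and a stage label.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

# Run code under a temporary RNG state when a seed is supplied.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Wide expression table -> numeric matrix with transcript_id rownames.
expr_to_matrix <- function(expr, what = "expression table") {
  assert_columns(expr, "transcript_id", what)
  ids <- as.character(expr$transcript_id)
  if (anyDuplicated(ids)) {
    abort(sprintf("%s contains duplicated transcript ids", what))
  }
  m <- as.matrix(expr[setdiff(names(expr), "transcript_id")])
  if (!is.numeric(m)) abort(sprintf("%s has non-numeric value columns", what))
  rownames(m) <- ids
  m
}

matrix_to_expr <- function(m) {
  as_tibble(m, rownames = "transcript_id")
}

# Total exonic length of one exon tibble (0-based half-open).
exon_span <- function(exons) sum(exons$end - exons$start)

validate_exons <- function(exons, transcript_id = "?") {
  if (!is.data.frame(exons) || nrow(exons) == 0) {
    abort(sprintf("transcript %s has an empty exon chain", transcript_id))
  }
  assert_columns(exons, c("start", "end"), "exon table")
  if (any(exons$end <= exons$start)) {
    abort(sprintf("transcript %s has an exon with end <= start", transcript_id))
  }
  if (is.unsorted(exons$start, strictly = TRUE) && nrow(exons) > 1) {
    abort(sprintf("transcript %s exons are not sorted by start", transcript_id))
  }
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    abort(sprintf("transcript %s has overlapping exons", transcript_id))
  }
  invisible(exons)
}
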