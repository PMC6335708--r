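# Co-expression analysis: median-of-ratios normalization, Pearson
# correlation with t-approximation p-values, BH adjustment, edge calling at
# |r| >= 0.95 & p < 0.05, and the individualized permutation validation of
# the correlation cutoff.

#' Configuration of co-expression edge calling
#'
#' @param pcc_threshold Minimum absolute Pearson correlation for an edge
#'   (inclusive; default 0.95).
#' @param pvalue_max Maximum (exclusive) raw two-sided p-value (default
#'   0.05). Raw p-values are used for edge calling, matching the original
#'   convention; BH adjustment is available separately via [bh_adjust()].
#' @param min_libraries Minimum number of libraries required (default 3).
#' @param log_transform Correlate `log1p` of the normalized expression
#'   (default `TRUE`); set `FALSE` to correlate the values as given.
#' @return An `lnc_coexpression_config` list.
#' @export
coexpression_config <- function(pcc_threshold = 0.95, pvalue_max = 0.05,
                                min_libraries = 3, log_transform = TRUE) {
  assert_scalar_number(pcc_threshold, "pcc_threshold", min = 1e-12, max = 1)
  assert_scalar_number(pvalue_max, "pvalue_max", min = 1e-12, max = 1)
  assert_scalar_number(min_libraries, "min_libraries", min = 3)
  structure(list(pcc_threshold = pcc_threshold, pvalue_max = pvalue_max,
                 min_libraries = min_libraries, log_transform = log_transform),
            class = "lnc_coexpression_config")
}

#' Median-of-ratios library normalization
#'
#' Size factor of a library = median, over transcripts with positive
#' counts in every library, of the ratio of its count to the per-transcript
#' geometric mean across libraries; normalized counts are the raw counts
#' divided by the library's factor.
#'
#' @param counts Wide tibble: `transcript_id` plus one numeric column per
#'   library (at least two libraries).
#' @return An `lnc_normalization` list with `normalized` (same shape as
#'   `counts`) and `size_factors` (tibble `library_id`, `size_factor`).
#' @export
normalize_counts <- function(counts) {
  m <- expr_to_matrix(counts, "count table")
  if (ncol(m) < 2) abort("normalization needs at least two libraries")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    abort(paste0("no transcript has positive counts in every library; ",
                 "filter the count table before normalizing"))
  }
  ref <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
  ratios <- m[all_pos, , drop = FALSE] / ref
  size_factors <- apply(ratios, 2, median)
  normalized <- sweep(m, 2, size_factors, "/")
  structure(
    list(normalized = matrix_to_expr(normalized),
         size_factors = tibble(library_id = colnames(m),
                               size_factor = unname(size_factors))),
    class = "lnc_normalization")
}

#' @export
print.lnc_normalization <- function(x, ...) {
  cat("Median-of-ratios normalization\n")
  print(x$size_factors)
  invisible(x)
}

#' @export
tidy.lnc_normalization <- function(x, ...) x$size_factors

#' Pearson product-moment correlation of two vectors
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return The correlation coefficient; `NA` with a warning of class
#'   `lncnet_undefined_correlation` when either vector is constant (the
#'   caller is expected to exclude such pairs).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("correlation needs at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("correlation undefined for a constant vector",
         class = "lncnet_undefined_correlation")
    return(NA_real_)
  }
  cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t approximation `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with
#' `n - 2` degrees of freedom; `|r| = 1` gives `p = 0`.
#'
#' @param pcc Correlation value(s) in `[-1, 1]`.
#' @param n Number of paired observations (at least 3).
#' @return Two-sided p-value(s), vectorized over `pcc`.
#' @export
pcc_pvalue <- function(pcc, n) {
  assert_scalar_number(n, "n", min = 3)
  if (any(abs(pcc) > 1, na.rm = TRUE)) abort("pcc must lie in [-1, 1]")
  out <- rep(NA_real_, length(pcc))
  exact1 <- !is.na(pcc) & abs(pcc) == 1
  out[exact1] <- 0
  ok <- !is.na(pcc) & abs(pcc) < 1
  t <- abs(pcc[ok]) * sqrt((n - 2) / (1 - pcc[ok]^2))
  out[ok] <- 2 * pt(t, df = n - 2, lower.tail = FALSE)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Row-standardize a wide expression table for fast correlation; drops
# constant rows and returns them for QC accounting.
standardize_rows <- function(expr, log_transform, what) {
  m <- expr_to_matrix(expr, what)
  if (log_transform) m <- log1p(m)
  mu <- rowMeans(m)
  cs <- m - mu
  ss <- sqrt(rowSums(cs^2))
  constant <- ss == 0
  list(z = cs[!constant, , drop = FALSE] / ss[!constant],
       constant_ids = rownames(m)[constant])
}

#' Call co-expressed lncRNA-mRNA pairs
#'
#' Computes the Pearson correlation of every lncRNA against every mRNA
#' across libraries and retains pairs with `|r| >=` the threshold AND raw
#' two-sided p-value below `pvalue_max`.  Pairs with an undefined
#' correlation (constant expression) are excluded and counted.
#'
#' @param lncrna_expr,mrna_expr Wide expression tibbles (`transcript_id`
#'   plus per-library columns) sharing the same library columns in the same
#'   order; normalized counts are expected.
#' @param config A [coexpression_config()].
#' @return Tibble of edges (`lncrna_id`, `mrna_id`, `pcc`, `pvalue`) with
#'   attributes `n_pairs_tested`, `n_undefined` (pairs skipped for constant
#'   vectors), `n_libraries` and `config`.
#' @export
call_edges <- function(lncrna_expr, mrna_expr,
                       config = coexpression_config()) {
  stopifnot(inherits(config, "lnc_coexpression_config"))
  lib_l <- setdiff(names(lncrna_expr), "transcript_id")
  lib_m <- setdiff(names(mrna_expr), "transcript_id")
  if (!identical(lib_l, lib_m)) {
    abort("lncRNA and mRNA tables must share the same libraries in the same order")
  }
  n <- length(lib_l)
  if (n < max(3, config$min_libraries)) {
    abort(sprintf("need at least %d libraries", max(3, config$min_libraries)))
  }
  zl <- standardize_rows(lncrna_expr, config$log_transform, "lncRNA expression")
  zm <- standardize_rows(mrna_expr, config$log_transform, "mRNA expression")
  n_undefined <- length(zl$constant_ids) * nrow(mrna_expr) +
    length(zm$constant_ids) * nrow(lncrna_expr) -
    length(zl$constant_ids) * length(zm$constant_ids)
  if (nrow(zl$z) == 0 || nrow(zm$z) == 0) {
    edges <- tibble(lncrna_id = character(), mrna_id = character(),
                    pcc = numeric(), pvalue = numeric())
  } else {
    r <- tcrossprod(zl$z, zm$z)
    r[r > 1] <- 1; r[r < -1] <- -1
    hit <- which(abs(r) >= config$pcc_threshold, arr.ind = TRUE)
    pcc <- r[hit]
    pv <- pcc_pvalue(pcc, n)
    keep <- pv < config$pvalue_max
    edges <- tibble(
      lncrna_id = rownames(zl$z)[hit[keep, 1]],
      mrna_id = rownames(zm$z)[hit[keep, 2]],
      pcc = pcc[keep],
      pvalue = pv[keep]
    ) |> arrange(.data$lncrna_id, .data$mrna_id)
  }
  attr(edges, "n_pairs_tested") <- nrow(zl$z) * nrow(zm$z)
  attr(edges, "n_undefined") <- n_undefined
  attr(edges, "n_libraries") <- n
  attr(edges, "config") <- config
  edges
}

#' Permutation validation of the correlation cutoff
#'
#' The individualized permutation test: per repetition, sample
#' `n_lncrnas` lncRNAs without replacement, permute each sampled lncRNA's
#' library vector independently (the mRNAs stay unchanged), correlate every
#' sampled lncRNA against every mRNA, pool all `|r|` values across
#' repetitions, and report the proportion at or above the threshold(s).
#'
#' @param lncrna_expr,mrna_expr Wide expression tibbles sharing library
#'   columns.
#' @param n_lncrnas Number of lncRNAs sampled per repetition (default 100).
#' @param n_repetitions Number of repetitions (default 1000).
#' @param threshold Correlation cutoff(s) to evaluate (default 0.95; may be
#'   a vector, evaluated on one shared pool).
#' @param seed Integer seed; the summary is bit-reproducible under a fixed
#'   seed.
#' @param shared_permutation Permute all sampled lncRNAs with one shared
#'   library permutation per repetition instead of independent ones
#'   (default `FALSE`).
#' @param log_transform Correlate `log1p` of the values (default `TRUE`).
#' @return An `lnc_permutation` list: `summary` (tibble with `threshold`,
#'   `pooled`, `exceed`, `proportion`), `n_undefined`, `params`, and a
#'   500-bin histogram of the pooled `|r|` values for plotting.  Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
permutation_validate <- function(lncrna_expr, mrna_expr,
                                 n_lncrnas = 100, n_repetitions = 1000,
                                 threshold = 0.95, seed = NULL,
                                 shared_permutation = FALSE,
                                 log_transform = TRUE) {
  assert_scalar_number(n_lncrnas, "n_lncrnas", min = 1)
  assert_scalar_number(n_repetitions, "n_repetitions", min = 1)
  if (any(threshold < 0 | threshold > 1)) abort("threshold must lie in [0, 1]")
  lib_l <- setdiff(names(lncrna_expr), "transcript_id")
  lib_m <- setdiff(names(mrna_expr), "transcript_id")
  if (!identical(lib_l, lib_m)) {
    abort("lncRNA and mRNA tables must share the same libraries in the same order")
  }
  n <- length(lib_l)
  if (n < 3) abort("need at least 3 libraries")

  ml <- expr_to_matrix(lncrna_expr, "lncRNA expression")
  if (log_transform) ml <- log1p(ml)
  keep_l <- apply(ml, 1, sd) > 0
  n_undefined_l <- sum(!keep_l)
  ml <- ml[keep_l, , drop = FALSE]
  if (nrow(ml) < n_lncrnas) {
    abort(sprintf("only %d usable lncRNAs available but n_lncrnas = %d",
                  nrow(ml), n_lncrnas))
  }
  zm <- standardize_rows(mrna_expr, log_transform, "mRNA expression")
  n_mrna <- nrow(zm$z)
  if (n_mrna == 0) abort("no usable (non-constant) mRNA vectors")

  breaks <- seq(0, 1, length.out = 501)
  hist_counts <- numeric(500)
  exceed <- numeric(length(threshold))
  pooled <- 0

  with_seed(seed, {
    for (rep_i in seq_len(n_repetitions)) {
      rows <- sample.int(nrow(ml), n_lncrnas)
      x <- ml[rows, , drop = FALSE]
      if (shared_permutation) {
        perm <- sample.int(n)
        x <- x[, perm, drop = FALSE]
      } else {
        x <- t(apply(x, 1, sample))
      }
      cs <- x - rowMeans(x)
      ss <- sqrt(rowSums(cs^2))
      zx <- cs / ss
      r <- abs(tcrossprod(zx, zm$z))
      r[r > 1] <- 1
      pooled <- pooled + length(r)
      for (k in seq_along(threshold)) {
        exceed[k] <- exceed[k] + sum(r >= threshold[k])
      }
      h <- .bincode(r, breaks, include.lowest = TRUE)
      th <- tabulate(h, nbins = 500)
      hist_counts <- hist_counts + th
    }
  })

  structure(
    list(
      summary = tibble(threshold = threshold, pooled = pooled,
                       exceed = exceed, proportion = exceed / pooled),
      n_undefined = n_undefined_l + length(zm$constant_ids),
      params = list(n_lncrnas = n_lncrnas, n_repetitions = n_repetitions,
                    threshold = threshold, seed = seed,
                    shared_permutation = shared_permutation,
                    n_libraries = n, n_mrnas = n_mrna),
      abs_pcc_hist = tibble(bin_low = breaks[-501], bin_high = breaks[-1],
                            count = hist_counts)
    ),
    class = "lnc_permutation")
}

#' @export
print.lnc_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation validation: %d lncRNAs x %d repetitions x %d mRNAs (n = %d libraries)\n",
    x$params$n_lncrnas, x$params$n_repetitions, x$params$n_mrnas,
    x$params$n_libraries))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.lnc_permutation <- function(x, ...) x$summary

#' @export
glance.lnc_permutation <- function(x, ...) {
  tibble(n_lncrnas = x$params$n_lncrnas,
         n_repetitions = x$params$n_repetitions,
         n_mrnas = x$params$n_mrnas,
         n_libraries = x$params$n_libraries,
         pooled = x$summary$pooled[1],
         min_proportion = min(x$summary$proportion),
         n_undefined = x$n_undefined)
}

#' @export
autoplot.lnc_permutation <- function(object, ...) {
  df <- object$abs_pcc_hist |>
    mutate(mid = (.data$bin_low + .data$bin_high) / 2,
           density = .data$count / sum(.data$count) /
             (.data$bin_high - .data$bin_low))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = df$bin_high[1] - df$bin_low[1],
                      fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$params$threshold,
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "|Pearson correlation| under permutation",
                  y = "density",
                  title = "Null distribution of the correlation cutoff") +
    ggplot2::theme_minimal()
}
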