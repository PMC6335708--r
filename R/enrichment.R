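# Term enrichment: hypergeometric (Fisher one-sided) upper-tail p-value
# and its conservative EASE variant (the same tail evaluated after removal
# of one overlapping member), computed against an explicit background.

#' Fisher/EASE enrichment score of one term
#'
#' `fisher_p` is the hypergeometric upper tail `P(X >= k)` for the overlap
#' `k` between query and term given the background; `ease_p` is the same
#' tail evaluated at `k - 1` successes (one overlapping member removed,
#' the EASE convention), with `ease_p = 1` whenever `k <= 1`.
#'
#' @param query Character vector of query ids (must be a subset of the
#'   background).
#' @param term_members Character vector of the term's member ids.
#' @param background Character vector of background ids.
#' @return One-row tibble: `n_background`, `n_term`, `n_query`, `overlap`,
#'   `fold_enrichment`, `fisher_p`, `ease_p`.
#' @export
ease_score <- function(query, term_members, background) {
  background <- unique(background)
  query <- unique(query)
  term_members <- unique(term_members)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    abort(sprintf("query id(s) not in background: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  outside_t <- setdiff(term_members, background)
  if (length(outside_t) > 0) {
    abort(sprintf("term member(s) not in background: %s",
                  paste(head(outside_t, 5), collapse = ", ")))
  }
  N <- length(background)
  K <- length(term_members)
  n <- length(query)
  k <- length(intersect(query, term_members))
  fisher_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  ease_p <- if (k <= 1) 1 else phyper(k - 2, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  tibble(n_background = N, n_term = K, n_query = n, overlap = k,
         fold_enrichment = fold, fisher_p = fisher_p, ease_p = ease_p)
}

#' Term enrichment of a query set against an annotation table
#'
#' One EASE/Fisher test per term; terms are ranked by ascending `ease_p`
#' (ties broken by term id).  Significance uses the raw EASE score at
#' `alpha` by default (the conventional EASE <= 0.05 rule); BH adjustment
#' is available via `adjust = "bh"` and is then used for the significance
#' call.
#'
#' @param query Character vector of query ids.
#' @param annotation Tibble with `term_id`, `member_id`.
#' @param background Character vector of background ids; every member and
#'   query id must belong to it.
#' @param alpha Significance level on the (possibly adjusted) EASE score
#'   (default 0.05, inclusive).
#' @param adjust `"none"` (default) or `"bh"`.
#' @return An `lnc_enrichment`: tibble with one row per term
#'   (`term_id`, counts, `fold_enrichment`, `fisher_p`, `ease_p`,
#'   optional `ease_p_adjusted`, `significant`), sorted ascending by
#'   `ease_p`.  Methods: [tidy()], [autoplot()].
#' @export
enrich <- function(query, annotation, background, alpha = 0.05,
                   adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  assert_columns(annotation, c("term_id", "member_id"), "annotation table")
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  query <- unique(query)
  if (length(query) == 0) {
    warn("empty query set; returning an empty enrichment table")
    out <- tibble(term_id = character(), n_background = integer(),
                  n_term = integer(), n_query = integer(),
                  overlap = integer(), fold_enrichment = numeric(),
                  fisher_p = numeric(), ease_p = numeric(),
                  significant = logical())
    return(structure(list(table = out, alpha = alpha, adjust = adjust),
                     class = "lnc_enrichment"))
  }
  terms <- split(annotation$member_id, annotation$term_id)
  rows <- imap(terms, function(members, term) {
    ease_score(query, members, background) |> mutate(term_id = term)
  }) |> bind_rows() |> relocate("term_id")
  if (adjust == "bh") {
    rows$ease_p_adjusted <- bh_adjust(rows$ease_p)
    rows$significant <- rows$ease_p_adjusted <= alpha
  } else {
    rows$significant <- rows$ease_p <= alpha
  }
  rows <- rows |> arrange(.data$ease_p, .data$term_id)
  structure(list(table = rows, alpha = alpha, adjust = adjust),
            class = "lnc_enrichment")
}

#' @export
print.lnc_enrichment <- function(x, ...) {
  cat(sprintf("Term enrichment: %d terms, %d significant (EASE %s <= %g)\n",
              nrow(x$table), sum(x$table$significant),
              if (x$adjust == "bh") "BH-adjusted" else "raw", x$alpha))
  print(head(x$table, 10))
  invisible(x)
}

#' @export
tidy.lnc_enrichment <- function(x, ...) x$table

#' @export
glance.lnc_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x$table),
         n_significant = sum(x$table$significant),
         alpha = x$alpha, adjust = x$adjust)
}

#' @export
autoplot.lnc_enrichment <- function(object, top = 15, ...) {
  df <- head(object$table, top) |>
    mutate(term_id = factor(.data$term_id, levels = rev(.data$term_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$ease_p),
                                   y = .data$term_id,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10(EASE score)", y = NULL,
                  title = "Term enrichment") +
    ggplot2::theme_minimal()
}
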