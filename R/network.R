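# Bipartite lncRNA-mRNA interaction network: hybridization-energy edge
# weighting (three log10 bins), DE annotation, sub-network extraction and
# hub-lncRNA degree tables.

#' Aggregate per-site hybridization energies to one record per pair
#'
#' @param energy_sites Tibble with `lncrna_id`, `mrna_id`, `energy` (one
#'   row per predicted interaction site; negative = favorable).
#' @param interpretation How to aggregate a pair's site energies:
#'   `"sum_abs"` (sum of magnitudes, the default), `"abs_sum"` (magnitude
#'   of the signed sum) or `"min_site"` (magnitude of the most favorable,
#'   i.e. lowest-energy, site).
#' @return Tibble with `lncrna_id`, `mrna_id`, `sum_energy` (> 0); pairs
#'   whose aggregate is zero are dropped with a warning.
#' @export
aggregate_energy <- function(energy_sites,
                             interpretation = c("sum_abs", "abs_sum",
                                                "min_site")) {
  interpretation <- match.arg(interpretation)
  assert_columns(energy_sites, c("lncrna_id", "mrna_id", "energy"),
                 "energy site table")
  if (any(is.na(energy_sites$energy))) {
    abort("energy site table contains non-numeric/missing energies")
  }
  agg <- switch(interpretation,
    sum_abs = \(e) sum(abs(e)),
    abs_sum = \(e) abs(sum(e)),
    min_site = \(e) abs(min(e))
  )
  out <- energy_sites |>
    group_by(.data$lncrna_id, .data$mrna_id) |>
    summarise(sum_energy = agg(.data$energy), .groups = "drop")
  zero <- out$sum_energy <= 0
  if (any(zero)) {
    warn(sprintf("%d pair(s) with non-positive aggregate energy dropped",
                 sum(zero)))
    out <- out[!zero, , drop = FALSE]
  }
  out
}

#' Edge weight class from aggregate hybridization energy
#'
#' Bins `log10(sum_energy)`: below 1 is `thin`, in `[1, 2)` is `dotted`,
#' at or above 2 is `thick` (lower boundary inclusive, upper exclusive).
#'
#' @param sum_energy Positive aggregate energy value(s); non-positive
#'   values map to `thin` with a warning.
#' @return Character vector in `thin`/`dotted`/`thick`.
#' @export
#' @examples
#' weight_class(c(5, 10, 250))  # thin, dotted, thick
weight_class <- function(sum_energy) {
  out <- rep(NA_character_, length(sum_energy))
  bad <- !is.na(sum_energy) & sum_energy <= 0
  if (any(bad)) {
    warn(sprintf("%d non-positive sum_energy value(s) classed as 'thin'",
                 sum(bad)))
    out[bad] <- "thin"
  }
  ok <- !is.na(sum_energy) & sum_energy > 0
  lg <- log10(sum_energy[ok])
  out[ok] <- dplyr::case_when(lg < 1 ~ "thin",
                              lg < 2 ~ "dotted",
                              .default = "thick")
  out
}

new_lnc_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "lnc_network")
}

#' Assemble the bipartite lncRNA-mRNA interaction network
#'
#' Nodes are typed by the side of the edge list they appear on; an id
#' appearing on both sides violates bipartiteness and is an error.  DE
#' directions are joined by id (missing ids become `ns`).  Energies are
#' left-joined: edges without an energy record carry no weight class.
#'
#' @param edges Edge tibble from [call_edges()] (`lncrna_id`, `mrna_id`,
#'   optionally `pcc`, `pvalue`).
#' @param energies Optional aggregated energy tibble from
#'   [aggregate_energy()], or a per-site table (detected by its `energy`
#'   column and aggregated with `interpretation`).
#' @param de Optional DE tibble with `transcript_id` and `direction`.
#' @param interpretation Energy aggregation passed to [aggregate_energy()]
#'   when `energies` holds per-site records.
#' @return An `lnc_network` with `nodes` (`id`, `node_class`,
#'   `de_direction`) and `edges` (input columns plus `sum_energy`,
#'   `weight_class`).  Methods: [tidy()], [glance()], [autoplot()].
#' @export
build_network <- function(edges, energies = NULL, de = NULL,
                          interpretation = "sum_abs") {
  assert_columns(edges, c("lncrna_id", "mrna_id"), "edge table")
  edges <- as_tibble(edges)
  lnc <- unique(edges$lncrna_id)
  mrna <- unique(edges$mrna_id)
  both <- intersect(lnc, mrna)
  if (length(both) > 0) {
    abort(sprintf("bipartite violation: id(s) appear as both lncRNA and mRNA: %s",
                  paste(head(both, 5), collapse = ", ")))
  }
  if (!is.null(energies)) {
    if ("energy" %in% names(energies)) {
      energies <- aggregate_energy(energies, interpretation)
    }
    assert_columns(energies, c("lncrna_id", "mrna_id", "sum_energy"),
                   "energy table")
    edges <- edges |>
      left_join(energies, by = c("lncrna_id", "mrna_id")) |>
      mutate(weight_class = weight_class(.data$sum_energy))
  } else {
    edges$sum_energy <- NA_real_
    edges$weight_class <- NA_character_
  }
  nodes <- tibble(
    id = c(lnc, mrna),
    node_class = c(rep("lncRNA", length(lnc)), rep("mRNA", length(mrna)))
  )
  if (!is.null(de)) {
    assert_columns(de, c("transcript_id", "direction"), "DE table")
    nodes <- nodes |>
      left_join(de |> select(id = "transcript_id",
                             de_direction = "direction"),
                by = "id")
    nodes$de_direction[is.na(nodes$de_direction)] <- "ns"
  } else {
    nodes$de_direction <- "ns"
  }
  new_lnc_network(nodes, edges)
}

#' @export
print.lnc_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Bipartite lncRNA-mRNA network: %d lncRNAs, %d mRNAs, %d edges\n",
              g$n_lncrna, g$n_mrna, g$n_edges))
  invisible(x)
}

#' @export
tidy.lnc_network <- function(x, ...) x$edges

#' @export
glance.lnc_network <- function(x, ...) {
  tibble(
    n_lncrna = sum(x$nodes$node_class == "lncRNA"),
    n_mrna = sum(x$nodes$node_class == "mRNA"),
    n_edges = nrow(x$edges),
    n_weighted = sum(!is.na(x$edges$weight_class)),
    n_de_nodes = sum(x$nodes$de_direction != "ns")
  )
}

#' @export
autoplot.lnc_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty network"))
  }
  g <- igraph::graph_from_data_frame(
    object$edges[c("lncrna_id", "mrna_id")], directed = FALSE,
    vertices = object$nodes["id"])
  set.seed(1)
  lay <- igraph::layout_with_fr(g)
  pos <- tibble(id = igraph::V(g)$name, x = lay[, 1], y = lay[, 2]) |>
    left_join(object$nodes, by = "id")
  seg <- object$edges |>
    left_join(pos |> select("id", x1 = "x", y1 = "y"),
              by = c(lncrna_id = "id")) |>
    left_join(pos |> select("id", x2 = "x", y2 = "y"),
              by = c(mrna_id = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$node_class,
                                     shape = .data$de_direction),
                        size = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "lncRNA-mRNA interaction network")
}

#' Extract the sub-network matching a DE-direction criterion
#'
#' Keeps the edges whose endpoints match the requested DE direction --
#' by default both endpoints down-regulated, the "decreased lncRNAs with
#' their co-expressed down-regulated mRNAs" sub-network -- and drops
#' nodes left isolated.
#'
#' @param network An `lnc_network` with DE-annotated nodes.
#' @param direction DE direction to filter on (default `"down"`).
#' @param endpoints `"both"` (default) requires both endpoints to match;
#'   `"either"` requires at least one.
#' @return An `lnc_network`; idempotent under repeated extraction with the
#'   same criterion.
#' @export
extract_subnetwork <- function(network, direction = "down",
                               endpoints = c("both", "either")) {
  stopifnot(inherits(network, "lnc_network"))
  endpoints <- match.arg(endpoints)
  dir_of <- setNames(network$nodes$de_direction, network$nodes$id)
  l_match <- dir_of[network$edges$lncrna_id] == direction
  m_match <- dir_of[network$edges$mrna_id] == direction
  keep <- if (endpoints == "both") l_match & m_match else l_match | m_match
  edges <- network$edges[keep, , drop = FALSE]
  used <- unique(c(edges$lncrna_id, edges$mrna_id))
  nodes <- network$nodes |> filter(.data$id %in% used)
  new_lnc_network(nodes, edges)
}

#' Per-lncRNA target counts (hub table)
#'
#' @param network An `lnc_network`.
#' @return Tibble (`lncrna_id`, `degree`) sorted by decreasing degree,
#'   ties by id.
#' @export
lncrna_degree_table <- function(network) {
  stopifnot(inherits(network, "lnc_network"))
  network$edges |>
    count(.data$lncrna_id, name = "degree") |>
    arrange(desc(.data$degree), .data$lncrna_id)
}

#' Naive duplex energy scorer (test plumbing; non-physical)
#'
#' A deliberately simple stand-in used to exercise the energy-weighting
#' path without an external RNA-RNA interaction predictor: it slides the
#' reverse complement of the lncRNA along the mRNA, takes the longest
#' perfect match of at least `min_match` nt as the single predicted site,
#' and scores it as `match length x energy_per_nt`.  It is NOT a physical
#' hybridization-energy model and must not be used for inference.
#'
#' @param lncrna_seq,mrna_seq Nucleotide strings.
#' @param min_match Minimum perfect-match length to call a site
#'   (default 8).
#' @param energy_per_nt Energy contribution per matched nt (default -1.5,
#'   negative = favorable).
#' @return Tibble with `energy` (one row per predicted site; zero rows
#'   when no match reaches `min_match`).
#' @export
naive_duplex_energy <- function(lncrna_seq, mrna_seq, min_match = 8,
                                energy_per_nt = -1.5) {
  rc <- revcomp(toupper(lncrna_seq))
  m <- toupper(mrna_seq)
  best <- 0L
  # longest common substring by k-mer extension
  k <- as.integer(min_match)
  if (nchar(rc) >= k && nchar(m) >= k) {
    starts <- seq_len(nchar(m) - k + 1L)
    kmers <- substring(m, starts, starts + k - 1L)
    for (i in seq_len(nchar(rc) - k + 1L)) {
      probe <- substr(rc, i, i + k - 1L)
      for (j in which(kmers == probe)) {
        len <- k
        while (i + len <= nchar(rc) && j + len <= nchar(m) &&
               substr(rc, i + len, i + len) == substr(m, j + len, j + len)) {
          len <- len + 1L
        }
        if (len > best) best <- len
      }
    }
  }
  if (best >= min_match) {
    tibble(energy = best * energy_per_nt)
  } else {
    tibble(energy = numeric(0))
  }
}
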