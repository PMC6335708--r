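# End-to-end orchestration: one configuration drives
# filter -> structure -> coexpress -> network -> enrich, writing each
# stage's artifacts before the next starts and finishing with a JSON
# manifest of output checksums.  Identical configuration + seed give
# byte-identical outputs; `resume` skips stages whose outputs already
# match the previous manifest.

PIPELINE_STAGES <- c("filter", "structure", "coexpress", "network", "enrich")

#' Build a pipeline configuration
#'
#' @param inputs Named list of input paths: required `fasta`, `gtf`,
#'   `counts`, `libraries`; optional `hits`, `domains`, `cpc_labels`, `de`,
#'   `energies`, `annotation`, `reference_hits`.
#' @param out_dir Output directory.
#' @param filter A [filter_config()].
#' @param coexpression A [coexpression_config()].
#' @param permutation List with `n_lncrnas`, `n_repetitions`, `threshold`
#'   (defaults 100 / 1000 / 0.95, the conventional parameterization).
#' @param energy_interpretation Passed to [aggregate_energy()].
#' @param de_fdr_max FDR threshold defining DE direction (default 0.05).
#' @param seed Global seed; per-stage seeds are derived from it so stages
#'   are individually reproducible.
#' @return An `lnc_pipeline_config` list.
#' @export
pipeline_config <- function(inputs, out_dir,
                            filter = filter_config(),
                            coexpression = coexpression_config(),
                            permutation = list(n_lncrnas = 100,
                                               n_repetitions = 1000,
                                               threshold = 0.95),
                            energy_interpretation = "sum_abs",
                            de_fdr_max = 0.05,
                            seed = 1L) {
  structure(list(inputs = inputs, out_dir = out_dir, filter = filter,
                 coexpression = coexpression, permutation = permutation,
                 energy_interpretation = energy_interpretation,
                 de_fdr_max = de_fdr_max, seed = seed),
            class = "lnc_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Paths in the file are interpreted relative to the file's directory.
#'
#' @param path Path to a YAML document with keys `inputs`, `out_dir` and
#'   optionally `filter`, `coexpression`, `permutation`,
#'   `energy_interpretation`, `de_fdr_max`, `seed`.
#' @return An `lnc_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) NULL
    else if (grepl("^(/|[A-Za-z]:)", p)) p
    else file.path(base, p)
  }
  inputs <- lapply(raw$inputs, rel)
  fc <- do.call(filter_config, raw$filter %||% list())
  cc <- do.call(coexpression_config, raw$coexpression %||% list())
  pm <- modifyList(list(n_lncrnas = 100, n_repetitions = 1000,
                        threshold = 0.95), raw$permutation %||% list())
  pipeline_config(
    inputs = inputs,
    out_dir = rel(raw$out_dir) %||% file.path(base, "lncnet_out"),
    filter = fc, coexpression = cc, permutation = pm,
    energy_interpretation = raw$energy_interpretation %||% "sum_abs",
    de_fdr_max = raw$de_fdr_max %||% 0.05,
    seed = raw$seed %||% 1L)
}

#' Validate a pipeline configuration
#'
#' Checks paths, ranges and cross-field constraints, distinguishing
#' warnings from errors; the pipeline refuses to run on errors.
#'
#' @param config An `lnc_pipeline_config` or the path to a YAML file.
#' @return Tibble with `level` (`error`/`warning`), `field`, `message`;
#'   zero rows mean the configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  problems <- list()
  note <- function(level, field, message) {
    problems[[length(problems) + 1]] <<- tibble(level = level, field = field,
                                                message = message)
  }
  required <- c("fasta", "gtf", "counts", "libraries")
  for (f in required) {
    p <- config$inputs[[f]]
    if (is.null(p)) note("error", paste0("inputs$", f), "required input missing")
    else if (!file.exists(p)) note("error", paste0("inputs$", f),
                                   sprintf("file not found: %s", p))
  }
  optional <- c("hits", "domains", "cpc_labels", "de", "energies",
                "annotation", "reference_hits")
  for (f in optional) {
    p <- config$inputs[[f]]
    if (!is.null(p) && !file.exists(p)) {
      note("error", paste0("inputs$", f), sprintf("file not found: %s", p))
    }
  }
  cc <- config$coexpression
  if (cc$pcc_threshold > 1 || cc$pcc_threshold <= 0) {
    note("error", "coexpression$pcc_threshold", "must lie in (0, 1]")
  }
  if (cc$pvalue_max > 1 || cc$pvalue_max <= 0) {
    note("error", "coexpression$pvalue_max", "must lie in (0, 1]")
  }
  fc <- config$filter
  if (fc$min_length_nt < 1) note("error", "filter$min_length_nt", "must be >= 1")
  if (fc$max_orf_aa < 1) note("error", "filter$max_orf_aa", "must be >= 1")
  if (!is.null(config$inputs$libraries) && file.exists(config$inputs$libraries %||% "")) {
    libs <- tryCatch(read_library_info(config$inputs$libraries),
                     error = function(e) NULL)
    if (is.null(libs)) {
      note("error", "inputs$libraries", "library metadata failed validation")
    } else if (nrow(libs) != 16) {
      note("warning", "inputs$libraries",
           sprintf("%d libraries found where the reference design has 16",
                   nrow(libs)))
    }
  }
  if (config$permutation$n_lncrnas < 1 || config$permutation$n_repetitions < 1) {
    note("error", "permutation", "n_lncrnas and n_repetitions must be >= 1")
  }
  if (length(problems) == 0) {
    return(tibble(level = character(), field = character(),
                  message = character()))
  }
  bind_rows(problems)
}

#' Run the full pipeline
#'
#' Stages run in order filter, structure, coexpress, network, enrich; each
#' stage's outputs are written before the next starts.  The manifest lists
#' every produced file with an MD5 checksum; an identical configuration and
#' seed give identical checksums.  With `resume = TRUE`, stages whose
#' outputs already exist with checksums matching the previous manifest are
#' skipped.
#'
#' @param config An `lnc_pipeline_config` (or YAML path).
#' @param resume Skip stages with up-to-date outputs (default `FALSE`).
#' @return The manifest, invisibly: list with `seed`, `stages` (status per
#'   stage) and `files` (path + md5).  Also written as `manifest.json` in
#'   the output directory.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  problems <- validate_config(config)
  errs <- problems |> filter(.data$level == "error")
  if (nrow(errs) > 0) {
    abort(paste0("pipeline configuration invalid:\n",
                 paste(sprintf("  %s: %s", errs$field, errs$message),
                       collapse = "\n")))
  }
  for (w in which(problems$level == "warning")) {
    warn(sprintf("%s: %s", problems$field[w], problems$message[w]))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  }

  stage_files <- list(
    filter = c("filter_report.tsv", "stage_counts.tsv", "lncrna_ids.txt",
               "features.tsv"),
    structure = c("as_events.tsv", "as_distribution.tsv",
                  "status_overlap.tsv", "status_specific.tsv", "novelty.tsv"),
    coexpress = c("size_factors.tsv", "edges.tsv", "permutation.json"),
    network = c("network.graphml", "network.sif", "network_nodes.tsv",
                "network_edges.tsv", "subnetwork_down.tsv",
                "lncrna_degrees.tsv"),
    enrich = c("enrichment.tsv")
  )
  p <- function(f) file.path(out_dir, f)
  stage_done <- function(stage) {
    if (is.null(old_manifest)) return(FALSE)
    files <- stage_files[[stage]]
    old <- old_manifest$files
    all(map_lgl(files, function(f) {
      fp <- p(f)
      file.exists(fp) && f %in% old$name &&
        identical(unname(tools::md5sum(fp)), old$md5[old$name == f])
    }))
  }

  status <- setNames(rep("pending", length(PIPELINE_STAGES)), PIPELINE_STAGES)
  state <- new.env(parent = emptyenv())
  state$dirty <- FALSE  # once a stage recomputes, downstream stages must too

  run_stage <- function(stage, fun) {
    if (resume && !state$dirty && stage_done(stage)) {
      status[[stage]] <<- "skipped (up to date)"
      load_stage_state(stage, state, out_dir, config)
      return(invisible(NULL))
    }
    state$dirty <- TRUE
    tryCatch(fun(), error = function(e) {
      status[[stage]] <<- paste0("failed: ", conditionMessage(e))
      write_manifest(manifest_path, config, status, stage_files, out_dir,
                     partial = TRUE)
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
    status[[stage]] <<- "ok"
  }

  # shared inputs
  transcripts <- read_gtf(config$inputs$gtf)
  sequences <- read_fasta(config$inputs$fasta)
  transcripts <- attach_sequences(transcripts, sequences)
  counts <- read_counts(config$inputs$counts)
  libraries <- read_library_info(config$inputs$libraries)
  hits <- if (!is.null(config$inputs$hits)) read_hits(config$inputs$hits)
  domains <- if (!is.null(config$inputs$domains)) {
    read_domain_hits(config$inputs$domains)
  }
  cpc <- if (!is.null(config$inputs$cpc_labels)) {
    readr::read_tsv(config$inputs$cpc_labels, col_types = "cc",
                    progress = FALSE, show_col_types = FALSE)
  }
  de <- if (!is.null(config$inputs$de)) {
    read_de_table(config$inputs$de, config$de_fdr_max)
  }

  run_stage("filter", function() {
    fr <- run_filter_cascade(transcripts, hits, domains, cpc, config$filter)
    readr::write_tsv(fr$report, p("filter_report.tsv"))
    readr::write_tsv(fr$stage_counts, p("stage_counts.tsv"))
    writeLines(fr$lncrna_ids, p("lncrna_ids.txt"))
    feats <- characterize_transcripts(transcripts, fr$lncrna_ids, counts)
    readr::write_tsv(feats$features, p("features.tsv"))
    state$lncrna_ids <- fr$lncrna_ids
  })

  run_stage("structure", function() {
    ev <- find_as_events(transcripts)
    readr::write_tsv(ev, p("as_events.tsv"))
    readr::write_tsv(event_mode_distribution(ev), p("as_distribution.tsv"))
    # status presence: a transcript belongs to a status when it has a
    # positive count in at least one library of that status
    m <- expr_to_matrix(counts)
    keys <- structure_key(transcripts)
    names(keys) <- transcripts$transcript_id
    sets <- libraries |>
      mutate(status = paste0(.data$condition, "_", .data$time_h, "h")) |>
      group_by(.data$status) |>
      group_map(function(g, key) {
        present <- rownames(m)[rowSums(m[, g$library_id, drop = FALSE] > 0) > 0]
        tibble(status = key$status, key = unname(keys[present]))
      }) |> bind_rows() |> filter(!is.na(.data$key))
    ov <- status_overlap(sets)
    readr::write_tsv(ov$cells, p("status_overlap.tsv"))
    readr::write_tsv(ov$specific, p("status_specific.tsv"))
    nov <- if (!is.null(config$inputs$reference_hits)) {
      classify_novelty(transcripts$transcript_id,
                       read_hits(config$inputs$reference_hits))
    } else {
      tibble(transcript_id = character(), novelty = character())
    }
    readr::write_tsv(nov, p("novelty.tsv"))
  })

  run_stage("coexpress", function() {
    norm <- normalize_counts(counts)
    readr::write_tsv(norm$size_factors, p("size_factors.tsv"))
    lnc_ids <- state$lncrna_ids
    expr <- norm$normalized
    lnc_expr <- expr |> filter(.data$transcript_id %in% lnc_ids)
    mrna_expr <- expr |> filter(!.data$transcript_id %in% lnc_ids)
    edges <- call_edges(lnc_expr, mrna_expr, config$coexpression)
    readr::write_tsv(edges, p("edges.tsv"))
    # reload from disk so resumed runs (which start from this file) see
    # bit-identical values
    state$edges <- readr::read_tsv(p("edges.tsv"), col_types = "ccdd",
                                   progress = FALSE, show_col_types = FALSE)
    pm <- config$permutation
    n_use <- min(pm$n_lncrnas, nrow(lnc_expr))
    perm <- permutation_validate(
      lnc_expr, mrna_expr, n_lncrnas = n_use,
      n_repetitions = pm$n_repetitions, threshold = pm$threshold,
      seed = derive_seed(config$seed, "coexpress"))
    jsonlite::write_json(
      list(summary = perm$summary,
           params = perm$params[c("n_lncrnas", "n_repetitions", "threshold",
                                  "n_libraries", "n_mrnas")],
           n_undefined = perm$n_undefined),
      p("permutation.json"), auto_unbox = TRUE, digits = NA)
  })

  run_stage("network", function() {
    energies <- if (!is.null(config$inputs$energies)) {
      aggregate_energy(read_energy_sites(config$inputs$energies),
                       config$energy_interpretation)
    }
    net <- build_network(state$edges, energies, de)
    write_network(net, p("network.graphml"), "graphml")
    write_network(net, p("network.sif"), "sif")
    readr::write_tsv(net$nodes, p("network_nodes.tsv"))
    readr::write_tsv(net$edges, p("network_edges.tsv"))
    sub <- extract_subnetwork(net, "down")
    readr::write_tsv(sub$edges, p("subnetwork_down.tsv"))
    readr::write_tsv(lncrna_degree_table(net), p("lncrna_degrees.tsv"))
    state$network <- net
  })

  run_stage("enrich", function() {
    if (is.null(config$inputs$annotation)) {
      readr::write_tsv(tibble(term_id = character(), note = character()),
                       p("enrichment.tsv"))
      return(invisible(NULL))
    }
    annotation <- readr::read_tsv(config$inputs$annotation, col_types = "cc",
                                  progress = FALSE, show_col_types = FALSE)
    background <- unique(annotation$member_id)
    targets <- unique(state$network$edges$mrna_id)
    query <- intersect(targets, background)
    if (length(query) == 0) {
      readr::write_tsv(tibble(term_id = character(), note = character()),
                       p("enrichment.tsv"))
      return(invisible(NULL))
    }
    res <- enrich(query, annotation, background)
    readr::write_tsv(res$table, p("enrichment.tsv"))
  })

  manifest <- write_manifest(manifest_path, config, status, stage_files,
                             out_dir, partial = FALSE)
  invisible(manifest)
}

# Reload the state later stages need when an earlier stage was skipped.
load_stage_state <- function(stage, state, out_dir, config) {
  if (stage == "filter") {
    state$lncrna_ids <- readLines(file.path(out_dir, "lncrna_ids.txt"))
  }
  if (stage == "coexpress") {
    state$edges <- readr::read_tsv(file.path(out_dir, "edges.tsv"),
                                   col_types = "ccdd", progress = FALSE,
                                   show_col_types = FALSE)
  }
  if (stage == "network") {
    state$network <- read_network(file.path(out_dir, "network.graphml"),
                                  "graphml")
  }
  invisible(NULL)
}

write_manifest <- function(path, config, status, stage_files, out_dir,
                           partial) {
  all_files <- unlist(stage_files, use.names = FALSE)
  present <- all_files[file.exists(file.path(out_dir, all_files))]
  files <- tibble(
    name = present,
    md5 = unname(tools::md5sum(file.path(out_dir, present)))
  )
  manifest <- list(
    seed = config$seed,
    partial = partial,
    thresholds = list(
      homology_evalue_max = config$filter$homology_evalue_max,
      min_length_nt = config$filter$min_length_nt,
      max_orf_aa = config$filter$max_orf_aa,
      pcc_threshold = config$coexpression$pcc_threshold,
      pvalue_max = config$coexpression$pvalue_max,
      permutation = config$permutation,
      energy_interpretation = config$energy_interpretation,
      de_fdr_max = config$de_fdr_max
    ),
    stages = as.list(status),
    files = files
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest
}
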