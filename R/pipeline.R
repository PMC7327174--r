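#' Run the full MHC repertoire pipeline
#'
#' Orchestrates the stages in order: CXXCH scanning and MHC calling,
#' all-vs-all homology search over the called MHCs, orthologous-family
#' clustering, abundance matrix and conservation summary, gene-neighborhood
#' signature matching (when coordinates are given), marker presence/absence
#' (when labels and marker definitions are given) and the cross-taxon
#' homology network (when a reference panel is given). All stages are
#' deterministic, so a rerun on identical inputs reproduces the summary
#' exactly; the effective configuration and its hash are embedded in the
#' result.
#'
#' @param proteins Protein table (`protein_id`, `genome_id`, `sequence`,
#'   optionally coordinates and `functional_label`).
#' @param genes Optional gene coordinate table for neighborhood analysis;
#'   defaults to `proteins` when it carries coordinates.
#' @param labels Optional label table (`protein_id`, `genome_id`, `label`).
#' @param reference Optional reference MHC panel with `taxonomy`.
#' @param patterns Cluster signatures to match (default the five built-in
#'   oxidoreductase signatures).
#' @param marker_defs Optional marker definitions for [marker_matrix()].
#' @param min_motifs MHC calling threshold (default 3).
#' @param params An [alignment_params()].
#' @param family_max_evalue,family_min_identity,family_min_coverage Family
#'   graph thresholds (per directed hit; coverage of the shorter sequence).
#' @param family_method `"components"` or `"mcl"`.
#' @param network_max_evalue,network_min_identity Network edge thresholds.
#' @param prune Prune single-role network components (default `TRUE`).
#' @return Object of class `mhc_run` holding every stage result plus a
#'   `summary` list.
#' @export
run_pipeline <- function(proteins,
                         genes = NULL,
                         labels = NULL,
                         reference = NULL,
                         patterns = oxidoreductase_patterns(),
                         marker_defs = NULL,
                         min_motifs = 3L,
                         params = alignment_params(),
                         family_max_evalue = 1e-3,
                         family_min_identity = 50,
                         family_min_coverage = 50,
                         family_method = "components",
                         network_max_evalue = 1e-20,
                         network_min_identity = 50,
                         prune = TRUE) {
  check_protein_table(proteins, require_genome = TRUE)

  config <- list(
    min_motifs = as.integer(min_motifs), params = unclass(params),
    family_max_evalue = family_max_evalue,
    family_min_identity = family_min_identity,
    family_min_coverage = family_min_coverage,
    family_method = family_method,
    network_max_evalue = network_max_evalue,
    network_min_identity = network_min_identity,
    prune = prune
  )
  config_hash <- rlang::hash(config)

  scan <- scan_proteome(proteins, min_motifs = min_motifs)
  mhc <- proteins |>
    inner_join(scan$annotations |>
                 filter(.data$is_mhc) |>
                 select("protein_id", "heme_count"),
               by = "protein_id")

  hits <- search_all(mhc, mhc, params, symmetric = TRUE)
  graph <- build_homology_graph(hits, max_evalue = family_max_evalue,
                                min_identity = family_min_identity,
                                min_coverage = family_min_coverage,
                                seq_lengths = setNames(nchar(mhc$sequence),
                                                       mhc$protein_id),
                                nodes = mhc$protein_id)
  families <- cluster_families(graph, method = family_method,
                               genomes = setNames(mhc$genome_id, mhc$protein_id))
  matrix_tbl <- abundance_matrix(families, genomes = scan$stats$genome_id)
  conservation <- conservation_profile(matrix_tbl)

  if (is.null(genes) && all(c("scaffold_id", "start", "end") %in% names(proteins)) &&
      !all(is.na(proteins$start))) {
    genes <- proteins |>
      select(any_of(c("protein_id", "genome_id", "scaffold_id", "start",
                      "end", "strand", "functional_label")))
  }
  matches <- NULL
  if (!is.null(genes)) {
    matches <- match_patterns(order_genes(genes), scan$annotations,
                              patterns = patterns, labels = labels)
  }

  markers <- NULL
  if (!is.null(labels) && !is.null(marker_defs)) {
    markers <- marker_matrix(labels, marker_defs,
                             genomes = scan$stats$genome_id)
  }

  network <- NULL
  if (!is.null(reference)) {
    network <- build_network(mhc, reference, params,
                             max_evalue = network_max_evalue,
                             min_identity = network_min_identity)
    if (prune) network <- prune_components(network)
  }

  summary <- list(
    config_hash = config_hash,
    n_genomes = nrow(scan$stats),
    n_proteins = nrow(proteins),
    n_mhc = sum(scan$annotations$is_mhc),
    max_hemes = if (any(scan$annotations$is_mhc)) {
      max(scan$annotations$heme_count[scan$annotations$is_mhc])
    } else 0L,
    mean_mhc_per_genome = mean(scan$stats$n_mhc),
    n_families = families$n_families,
    n_core_families = conservation$n_core_families[nrow(conservation)],
    matches_per_pattern = if (!is.null(matches)) {
      as.list(table(matches$pattern))
    } else NULL,
    network = if (!is.null(network)) {
      list(n_nodes = nrow(network$nodes), n_edges = nrow(network$edges),
           n_components = length(unique(network$nodes$component)))
    } else NULL,
    config = config
  )

  structure(list(scan = scan, hits = hits, families = families,
                 abundance = matrix_tbl, conservation = conservation,
                 matches = matches, markers = markers, network = network,
                 summary = summary, config = config),
            class = "mhc_run")
}

#' @export
print.mhc_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<mhc_run> %d genomes, %d proteins -> %d MHCs (max %d hemes) in %d families; hash %s\n",
              s$n_genomes, s$n_proteins, s$n_mhc, s$max_hemes, s$n_families,
              substr(s$config_hash, 1, 8)))
  invisible(x)
}

#' Write the stage outputs of a pipeline run
#'
#' Writes annotation/stats/families/abundance/conservation tables as TSV,
#' the summary as JSON (embedding the full effective configuration and its
#' hash) and, when present, cluster matches, marker matrix and the network
#' as GraphML + edge list.
#'
#' @param run An `mhc_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "mhc_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotations_tsv(run$scan$annotations, file.path(dir, "mhc_annotations.tsv"))
  readr::write_tsv(run$scan$stats, file.path(dir, "genome_stats.tsv"))
  readr::write_tsv(run$families$families, file.path(dir, "families.tsv"))
  readr::write_tsv(run$abundance, file.path(dir, "abundance_matrix.tsv"))
  readr::write_tsv(run$conservation, file.path(dir, "conservation.tsv"))
  if (!is.null(run$matches)) readr::write_tsv(run$matches, file.path(dir, "cluster_matches.tsv"))
  if (!is.null(run$markers)) readr::write_tsv(run$markers, file.path(dir, "marker_matrix.tsv"))
  if (!is.null(run$network)) {
    export_graph(run$network, file.path(dir, "network.graphml"), "graphml")
    export_graph(run$network, file.path(dir, "network_edges.tsv"), "edgelist")
  }
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
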