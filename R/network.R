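#' Build a cross-taxon MHC homology network
#'
#' All-vs-all local alignment over the union of query MHCs and a reference
#' MHC panel; an edge joins two proteins when their best reciprocal hits
#' pass the E-value and identity thresholds (defaults 1e-20 and 50%,
#' applied to per-hit percent identity). Nodes are all proteins on at least
#' one passing edge plus isolated query nodes; node attributes carry the
#' role (query/reference), taxonomy and heme count, edge attributes the
#' percent identity (weight) and E-value.
#'
#' With `by_family` the query side is collapsed to one representative per
#' orthologous family (the longest member).
#'
#' @param query Query MHC table (`protein_id`, `genome_id`, `sequence`;
#'   optional `heme_count`, recomputed when absent). Must be non-empty.
#' @param reference Reference panel (`protein_id`, `taxonomy`, `sequence`;
#'   optional `heme_count`).
#' @param params An [alignment_params()].
#' @param max_evalue,min_identity Edge thresholds (defaults 1e-20, 50).
#' @param by_family Optional `mhc_families` object for representative mode.
#' @return Object of class `mhc_network`: `graph` (igraph), `nodes`,
#'   `edges` tibbles, and `params`.
#' @export
build_network <- function(query, reference, params = alignment_params(),
                          max_evalue = 1e-20, min_identity = 50,
                          by_family = NULL) {
  check_protein_table(query)
  if (nrow(query) == 0L) abort("configuration error: empty query set.")
  check_protein_table(reference)
  stopifnot("taxonomy" %in% names(reference))

  if (!is.null(by_family)) {
    stopifnot(inherits(by_family, "mhc_families"))
    reps <- by_family$families |>
      left_join(query |> select("protein_id", "sequence"), by = "protein_id") |>
      filter(!is.na(.data$sequence)) |>
      group_by(.data$family_id) |>
      arrange(desc(nchar(.data$sequence)), .data$protein_id, .by_group = TRUE) |>
      slice(1L) |>
      ungroup()
    query <- query |> filter(.data$protein_id %in% reps$protein_id)
  }

  if (!"heme_count" %in% names(query)) {
    query$heme_count <- count_heme_motifs(query$sequence)
  }
  if (!"heme_count" %in% names(reference)) {
    reference$heme_count <- count_heme_motifs(reference$sequence)
  }
  if (any(query$protein_id %in% reference$protein_id)) {
    abort("query and reference protein ids must be disjoint.")
  }

  pool <- bind_rows(
    query |> mutate(role = "query",
                    taxonomy = paste0("query:", .data$genome_id)) |>
      select("protein_id", "sequence", "role", "taxonomy", "heme_count"),
    reference |> mutate(role = "reference") |>
      select("protein_id", "sequence", "role", "taxonomy", "heme_count")
  )

  hits <- search_all(pool, pool, params, symmetric = TRUE)
  g <- build_homology_graph(hits, max_evalue = max_evalue,
                            min_identity = min_identity,
                            nodes = pool$protein_id)
  # nodes: every protein on a passing edge, plus isolated *query* nodes
  deg <- igraph::degree(g)
  keep <- names(deg)[deg > 0L |
                       names(deg) %in% query$protein_id]
  g <- igraph::induced_subgraph(g, keep)

  idx <- match(igraph::V(g)$name, pool$protein_id)
  igraph::V(g)$role <- pool$role[idx]
  igraph::V(g)$taxonomy <- pool$taxonomy[idx]
  igraph::V(g)$heme_count <- pool$heme_count[idx]

  new_mhc_network(g, params = list(max_evalue = max_evalue,
                                   min_identity = min_identity,
                                   by_family = !is.null(by_family)))
}

new_mhc_network <- function(graph, params) {
  comp <- igraph::components(graph)
  nodes <- tibble(
    protein_id = igraph::V(graph)$name,
    role = igraph::V(graph)$role,
    taxonomy = igraph::V(graph)$taxonomy,
    heme_count = igraph::V(graph)$heme_count,
    component = unname(comp$membership)
  )
  e <- igraph::as_data_frame(graph, what = "edges")
  edges <- tibble(
    from = e$from, to = e$to,
    pident = e$pident %||% numeric(nrow(e)),
    evalue = e$evalue %||% numeric(nrow(e)),
    bitscore = e$bitscore %||% numeric(nrow(e))
  )
  structure(list(graph = graph, nodes = nodes, edges = edges, params = params),
            class = "mhc_network")
}

#' @export
print.mhc_network <- function(x, ...) {
  cat(sprintf("<mhc_network> %d node(s) (%d query, %d reference), %d edge(s), %d component(s); E<=%g, identity>=%g%%\n",
              nrow(x$nodes), sum(x$nodes$role == "query"),
              sum(x$nodes$role == "reference"), nrow(x$edges),
              length(unique(x$nodes$component)),
              x$params$max_evalue, x$params$min_identity))
  invisible(x)
}

#' Prune single-role components from an MHC network
#'
#' Deletes every connected component that consists solely of query nodes or
#' solely of reference nodes; mixed components are kept intact. The
#' operation is idempotent.
#'
#' @param network An `mhc_network`.
#' @return The pruned `mhc_network`.
#' @export
prune_components <- function(network) {
  stopifnot(inherits(network, "mhc_network"))
  mixed <- network$nodes |>
    group_by(.data$component) |>
    summarise(keep = any(.data$role == "query") && any(.data$role == "reference"),
              .groups = "drop")
  keep_ids <- network$nodes$protein_id[network$nodes$component %in%
                                         mixed$component[mixed$keep]]
  g <- igraph::induced_subgraph(network$graph, keep_ids)
  new_mhc_network(g, network$params)
}

#' Export an MHC network to an interchange format
#'
#' `"graphml"` is round-trip safe (node attributes taxonomy, role and heme
#' count; edge attribute percent identity and E-value survive re-import);
#' `"edgelist"` writes a TSV with one header line and one line per edge;
#' `"sif"` writes Cytoscape simple-interaction lines (`a hom b`), isolated
#' nodes as bare ids.
#'
#' @param network An `mhc_network`.
#' @param path Output file.
#' @param format `"graphml"`, `"edgelist"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("graphml", "edgelist", "sif")) {
  stopifnot(inherits(network, "mhc_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) abort("unknown export format; use graphml, edgelist or sif."))
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else if (format == "edgelist") {
    readr::write_tsv(network$edges, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(network$edges) > 0L) {
      writeLines(sprintf("%s\thom\t%s", network$edges$from, network$edges$to), con)
    }
    iso <- setdiff(network$nodes$protein_id,
                   unique(c(network$edges$from, network$edges$to)))
    if (length(iso) > 0L) writeLines(iso, con)
  }
  invisible(path)
}
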