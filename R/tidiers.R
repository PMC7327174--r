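#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MHC scan
#'
#' One row per protein with motif positions serialised to a
#' semicolon-joined string.
#'
#' @param x An `mhc_scan`.
#' @param ... Unused.
#' @export
tidy.mhc_scan <- function(x, ...) {
  x$annotations |>
    mutate(motif_positions = map_chr(.data$motif_positions,
                                     function(p) paste(p, collapse = ";")))
}

#' @rdname tidy.mhc_scan
#' @export
glance.mhc_scan <- function(x, ...) {
  tibble(
    n_genomes = nrow(x$stats),
    n_proteins = nrow(x$annotations),
    n_mhc = sum(x$annotations$is_mhc),
    max_hemes = if (any(x$annotations$is_mhc)) max(x$annotations$heme_count[x$annotations$is_mhc]) else 0L,
    mean_mhc_per_genome = mean(x$stats$n_mhc),
    min_motifs = x$params$min_motifs
  )
}

#' Tidy an orthologous-family clustering
#'
#' @param x An `mhc_families`.
#' @param ... Unused.
#' @export
tidy.mhc_families <- function(x, ...) x$families

#' @rdname tidy.mhc_families
#' @export
glance.mhc_families <- function(x, ...) {
  sizes <- x$families |> count(.data$family_id)
  tibble(
    n_families = x$n_families,
    n_proteins = nrow(x$families),
    n_genomes = length(unique(x$families$genome_id)),
    largest_family = if (nrow(sizes) > 0L) max(sizes$n) else 0L,
    method = x$method
  )
}

#' Tidy an MHC homology network
#'
#' Returns the edge table; `glance()` summarises nodes, edges and
#' components.
#'
#' @param x An `mhc_network`.
#' @param ... Unused.
#' @export
tidy.mhc_network <- function(x, ...) x$edges

#' @rdname tidy.mhc_network
#' @export
glance.mhc_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_query = sum(x$nodes$role == "query"),
    n_reference = sum(x$nodes$role == "reference"),
    n_edges = nrow(x$edges),
    n_components = length(unique(x$nodes$component)),
    max_evalue = x$params$max_evalue,
    min_identity = x$params$min_identity
  )
}

#' Tidy a pipeline run
#'
#' Returns the per-genome repertoire statistics; `glance()` the run-level
#' summary.
#'
#' @param x An `mhc_run`.
#' @param ... Unused.
#' @export
tidy.mhc_run <- function(x, ...) x$scan$stats

#' @rdname tidy.mhc_run
#' @export
glance.mhc_run <- function(x, ...) {
  s <- x$summary
  tibble(n_genomes = s$n_genomes, n_proteins = s$n_proteins, n_mhc = s$n_mhc,
         max_hemes = s$max_hemes, mean_mhc_per_genome = s$mean_mhc_per_genome,
         n_families = s$n_families, n_core_families = s$n_core_families,
         config_hash = s$config_hash)
}
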