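#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile geom_point
#'   geom_segment geom_histogram scale_fill_viridis_c scale_fill_gradient
#'   labs theme_minimal theme element_text element_blank coord_flip
#' @export
ggplot2::autoplot

#' Plot per-genome MHC repertoires
#'
#' Bar chart of MHC counts per genome from an `mhc_scan`.
#'
#' @param object An `mhc_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mhc_scan <- function(object, ...) {
  ggplot(object$stats, aes(x = stats::reorder(.data$genome_id, .data$n_mhc),
                           y = .data$n_mhc)) +
    geom_col(fill = "#2c7fb8") +
    coord_flip() +
    labs(x = NULL, y = sprintf("putative MHCs (>= %d CXXCH motifs)",
                               object$params$min_motifs)) +
    theme_minimal()
}

#' Heatmap of the genomes-by-families abundance matrix
#'
#' Tile heatmap of family member counts. Row/column ordering by
#' average-linkage clustering is cosmetic and optional; the counts are
#' unchanged.
#'
#' @param matrix_tbl Wide tibble from [abundance_matrix()].
#' @param cluster Apply the cosmetic [heatmap_ordering()] (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_abundance_heatmap <- function(matrix_tbl, cluster = TRUE) {
  long <- matrix_tbl |>
    pivot_longer(-"genome_id", names_to = "family_id", values_to = "count")
  if (cluster) {
    ord <- heatmap_ordering(matrix_tbl)
    long$genome_id <- factor(long$genome_id, levels = ord$genome_order)
    long$family_id <- factor(long$family_id, levels = ord$family_order)
  }
  ggplot(long, aes(x = .data$family_id, y = .data$genome_id,
                   fill = .data$count)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#d7301f") +
    labs(x = "orthologous family", y = NULL, fill = "members") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 5))
}

#' Plot an MHC homology network
#'
#' Deterministic force-directed layout; node colour encodes the taxonomy
#' label, size the heme count, edge alpha the percent identity.
#'
#' @param object An `mhc_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mhc_network <- function(object, seed = 42L, ...) {
  g <- object$graph
  xy <- withr::with_seed(as.integer(seed),
                         igraph::layout_with_fr(g))
  nodes <- object$nodes |>
    mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(nodes |> select("protein_id", x1 = "x", y1 = "y"),
              by = c(from = "protein_id")) |>
    left_join(nodes |> select("protein_id", x2 = "x", y2 = "y"),
              by = c(to = "protein_id"))
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                     yend = .data$y2, alpha = .data$pident),
                 colour = "grey50") +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, colour = .data$taxonomy,
                   size = .data$heme_count)) +
    labs(alpha = "% identity", size = "hemes", colour = NULL) +
    theme_minimal() +
    theme(axis.title = element_blank(), axis.text = element_blank(),
          panel.grid = element_blank())
}

#' Histogram of heme counts across called MHCs
#'
#' @param scan An `mhc_scan`.
#' @param binwidth Histogram bin width (default 2).
#' @return A ggplot object.
#' @export
plot_heme_distribution <- function(scan, binwidth = 2) {
  stopifnot(inherits(scan, "mhc_scan"))
  mhc <- scan$annotations |> filter(.data$is_mhc)
  ggplot(mhc, aes(x = .data$heme_count)) +
    geom_histogram(binwidth = binwidth, fill = "#2c7fb8", colour = "white") +
    labs(x = "CXXCH motifs per MHC", y = "proteins") +
    theme_minimal()
}
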