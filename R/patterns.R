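#' Define a gene-collocation cluster signature
#'
#' A cluster pattern is an unordered multiset of required gene components
#' that must occur together within a gene neighborhood: labelled components
#' (matched against the functional-label column) and `"mhc"` components
#' (matched against scanned heme counts, optionally constrained). Matching is
#' strand-agnostic and order-agnostic by default, with at most `max_gap`
#' intervening non-component genes between consecutive matched genes.
#'
#' @param name Pattern name.
#' @param components A data frame with columns `role` (functional label, or
#'   `"mhc"`), `min_copies`, and optional `min_hemes`/`max_hemes` for `"mhc"`
#'   components.
#' @param max_gap Maximum intervening non-component genes between two
#'   consecutive matched genes (default 2).
#' @param require_order If `TRUE`, the first occurrences of the components
#'   must appear in the listed order.
#' @param require_strand If `TRUE`, all matched genes must share a strand.
#' @return An object of class `cluster_pattern`.
#' @export
cluster_pattern <- function(name, components, max_gap = 2L,
                            require_order = FALSE, require_strand = FALSE) {
  if (!is.character(name) || length(name) != 1L || nchar(name) == 0L) {
    abort("`name` must be a single non-empty string.")
  }
  components <- as_tibble(components)
  if (nrow(components) == 0L || !"role" %in% names(components)) {
    abort("`components` must contain at least one row with a `role` column.")
  }
  if (!"min_copies" %in% names(components)) components$min_copies <- 1L
  if (!"min_hemes" %in% names(components)) components$min_hemes <- NA_integer_
  if (!"max_hemes" %in% names(components)) components$max_hemes <- NA_integer_
  if (!is.numeric(max_gap) || length(max_gap) != 1L || max_gap < 0) {
    abort("`max_gap` must be a single count >= 0.")
  }
  structure(
    list(name = name,
         components = components |>
           mutate(min_copies = as.integer(.data$min_copies),
                  min_hemes = as.integer(.data$min_hemes),
                  max_hemes = as.integer(.data$max_hemes)),
         max_gap = as.integer(max_gap),
         require_order = isTRUE(require_order),
         require_strand = isTRUE(require_strand)),
    class = "cluster_pattern"
  )
}

#' @export
print.cluster_pattern <- function(x, ...) {
  cat(sprintf("<cluster_pattern> %s: %s (max gap %d)\n", x$name,
              paste(sprintf("%dx %s", x$components$min_copies, x$components$role),
                    collapse = " + "),
              x$max_gap))
  invisible(x)
}

#' The five built-in menaquinone:cytochrome c oxidoreductase signatures
#'
#' Gene-cluster signatures of the five putative menaquinone:cytochrome c
#' oxidoreductase neighborhoods found in Methanoperedenaceae genomes:
#' group 1, a noncanonical bc1/b6f complex adjacent to two hypothetical
#' proteins and two 6-heme MHCs; groups 2 and 3, a b-type cytochrome
#' adjacent to a 6-heme MHC; groups 4 and 5, an NrfD-like transmembrane
#' protein adjacent to an electron-transferring 4Fe-4S ferredoxin
#' iron-sulfur protein and MHCs. Groups 2/3 (and 4/5) share one gene
#' composition; the biological distinction between them is phylogenetic,
#' which this package does not model, so matches for one member of such a
#' composition class also satisfy the other.
#'
#' @param max_gap Maximum intervening genes passed to every pattern.
#' @return Named list of five [cluster_pattern()] objects.
#' @export
oxidoreductase_patterns <- function(max_gap = 2L) {
  comp <- function(...) tibble(...)
  list(
    group1 = cluster_pattern("group1", comp(
      role = c("bc_complex", "hypothetical", "mhc"),
      min_copies = c(1L, 2L, 2L),
      min_hemes = c(NA, NA, 6L),
      max_hemes = c(NA, NA, 6L)), max_gap = max_gap),
    group2 = cluster_pattern("group2", comp(
      role = c("cytb", "mhc"),
      min_copies = c(1L, 1L),
      min_hemes = c(NA, 6L),
      max_hemes = c(NA, 6L)), max_gap = max_gap),
    group3 = cluster_pattern("group3", comp(
      role = c("cytb", "mhc"),
      min_copies = c(1L, 1L),
      min_hemes = c(NA, 6L),
      max_hemes = c(NA, 6L)), max_gap = max_gap),
    group4 = cluster_pattern("group4", comp(
      role = c("nrfd_like", "ferredoxin_4fe4s", "mhc"),
      min_copies = c(1L, 1L, 2L),
      min_hemes = c(NA, NA, 3L),
      max_hemes = c(NA, NA, NA)), max_gap = max_gap),
    group5 = cluster_pattern("group5", comp(
      role = c("nrfd_like", "ferredoxin_4fe4s", "mhc"),
      min_copies = c(1L, 1L, 2L),
      min_hemes = c(NA, NA, 3L),
      max_hemes = c(NA, NA, NA)), max_gap = max_gap)
  )
}

# generator-side plan: the concrete genes planted for each pattern instance
# (one conserved MHC family per pattern; NA heme = drawn per family)
cluster_component_plan <- function() {
  list(
    group1 = tibble(role = c("bc_complex", "hypothetical", "hypothetical", "mhc", "mhc"),
                    heme = c(NA, NA, NA, 6L, 6L)),
    group2 = tibble(role = c("cytb", "mhc"), heme = c(NA, 6L)),
    group3 = tibble(role = c("cytb", "mhc"), heme = c(NA, 6L)),
    group4 = tibble(role = c("nrfd_like", "ferredoxin_4fe4s", "mhc", "mhc"),
                    heme = c(NA, NA, NA, NA)),
    group5 = tibble(role = c("nrfd_like", "ferredoxin_4fe4s", "mhc", "mhc"),
                    heme = c(NA, NA, NA, NA))
  )
}

# composition-equivalence classes of the built-in patterns (groups sharing a
# gene composition are indistinguishable without phylogeny)
pattern_composition_class <- function(pattern) {
  cls <- c(group1 = "g1", group2 = "g23", group3 = "g23",
           group4 = "g45", group5 = "g45")
  out <- unname(cls[pattern])
  ifelse(is.na(out), pattern, out)
}
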