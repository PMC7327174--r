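#' Order genes along scaffolds
#'
#' Sorts a gene coordinate table by start coordinate within each scaffold
#' (ties broken by end coordinate, then id) and assigns a per-scaffold
#' `gene_order` index. Strand is retained but never used for ordering.
#'
#' @param genes Gene table (`protein_id`, `genome_id`, `scaffold_id`,
#'   `start`, `end`, optional `strand`), e.g. from [read_gene_gff()].
#' @return The sorted tibble with an added integer `gene_order` column.
#' @export
order_genes <- function(genes) {
  if (!is.data.frame(genes)) abort("`genes` must be a data frame.")
  need <- c("protein_id", "genome_id", "scaffold_id", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0L) abort(sprintf("`genes` is missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(genes) == 0L) return(as_tibble(genes) |> mutate(gene_order = integer(0)))
  if (anyDuplicated(genes$protein_id)) abort("parse error: duplicate gene IDs.")
  if (anyNA(genes$start) || anyNA(genes$end) || any(genes$start > genes$end)) {
    abort("parse error: malformed gene coordinates (missing, or start > end).")
  }
  as_tibble(genes) |>
    arrange(.data$genome_id, .data$scaffold_id, .data$start, .data$end, .data$protein_id) |>
    group_by(.data$genome_id, .data$scaffold_id) |>
    mutate(gene_order = row_number()) |>
    ungroup()
}

#' Match a gene-collocation signature in ordered genomes
#'
#' Scans each scaffold for neighborhoods satisfying a [cluster_pattern()]:
#' genes matching any pattern component are chained while at most `max_gap`
#' non-component genes separate consecutive matched genes, and every maximal
#' chain whose component counts satisfy the pattern's multiset is reported
#' once (overlapping windows merge into the maximal match, so each gene
#' appears in at most one match per pattern). Matching is strand- and
#' order-agnostic unless the pattern requests otherwise.
#'
#' @param genes Ordered gene table from [order_genes()] with a
#'   `functional_label` column (or supplied via `labels`).
#' @param pattern A [cluster_pattern()].
#' @param annotations MHC annotation tibble from [call_mhc()] (supplies heme
#'   counts for `"mhc"` components).
#' @param labels Optional label table (`protein_id`, `label`) overriding
#'   `genes$functional_label`.
#' @return Tibble of matches: `genome_id`, `scaffold_id`, `pattern`,
#'   `gene_ids` (semicolon-joined in gene order), `roles`
#'   (semicolon-joined component roles), `first_index`, `last_index`.
#' @export
match_pattern <- function(genes, pattern, annotations, labels = NULL) {
  stopifnot(inherits(pattern, "cluster_pattern"))
  if (nrow(genes) == 0L) return(empty_matches())
  if (!"gene_order" %in% names(genes)) genes <- order_genes(genes)
  if (!is.null(labels)) {
    stopifnot(all(c("protein_id", "label") %in% names(labels)))
    genes <- genes |>
      select(-any_of("functional_label")) |>
      left_join(labels |> select("protein_id", functional_label = "label"),
                by = "protein_id")
  }
  if (!"functional_label" %in% names(genes)) genes$functional_label <- NA_character_
  genes <- genes |>
    left_join(annotations |> select("protein_id", "heme_count", "is_mhc"),
              by = "protein_id") |>
    mutate(heme_count = as.integer(replace_na(.data$heme_count, 0L)),
           is_mhc = replace_na(.data$is_mhc, FALSE))

  comp <- pattern$components
  # per-gene x per-component predicate matrix
  match_mat <- vapply(seq_len(nrow(comp)), function(ci) {
    role <- comp$role[ci]
    if (role == "mhc") {
      ok <- genes$is_mhc
      if (!is.na(comp$min_hemes[ci])) ok <- ok & genes$heme_count >= comp$min_hemes[ci]
      if (!is.na(comp$max_hemes[ci])) ok <- ok & genes$heme_count <= comp$max_hemes[ci]
      ok
    } else {
      !is.na(genes$functional_label) & genes$functional_label == role
    }
  }, logical(nrow(genes)))
  if (is.null(dim(match_mat))) match_mat <- matrix(match_mat, nrow = nrow(genes))
  any_comp <- rowSums(match_mat) > 0L

  out <- genes |>
    mutate(any_comp = any_comp) |>
    group_by(.data$genome_id, .data$scaffold_id) |>
    group_map(function(sc, key) {
      idx <- which(sc$any_comp)
      if (length(idx) == 0L) return(NULL)
      # chain component genes with <= max_gap intervening non-component genes
      brk <- c(0L, which(diff(idx) > pattern$max_gap + 1L), length(idx))
      chains <- purrr::map(seq_len(length(brk) - 1L), function(b) idx[(brk[b] + 1L):brk[b + 1L]])
      rows <- purrr::map(chains, function(ch) {
        gidx <- match(sc$protein_id[ch], genes$protein_id)
        counts <- colSums(match_mat[gidx, , drop = FALSE])
        if (!all(counts >= comp$min_copies)) return(NULL)
        if (pattern$require_strand && length(unique(sc$strand[ch])) > 1L) return(NULL)
        if (pattern$require_order) {
          first_at <- vapply(seq_len(nrow(comp)), function(ci) {
            hit <- which(match_mat[gidx, ci])
            if (length(hit) == 0L) NA_integer_ else min(hit)
          }, integer(1))
          if (is.unsorted(first_at, na.rm = TRUE)) return(NULL)
        }
        roles <- vapply(seq_along(ch), function(k) {
          paste(comp$role[match_mat[gidx[k], ]], collapse = "+")
        }, character(1))
        tibble(genome_id = key$genome_id, scaffold_id = key$scaffold_id,
               pattern = pattern$name,
               gene_ids = paste(sc$protein_id[ch], collapse = ";"),
               roles = paste(roles, collapse = ";"),
               first_index = sc$gene_order[ch[1L]],
               last_index = sc$gene_order[ch[length(ch)]])
      })
      list_rbind(purrr::compact(rows))
    }) |>
    purrr::compact() |>
    list_rbind()
  if (nrow(out) == 0L) empty_matches() else out
}

empty_matches <- function() {
  tibble(genome_id = character(), scaffold_id = character(), pattern = character(),
         gene_ids = character(), roles = character(),
         first_index = integer(), last_index = integer())
}

#' Match several cluster patterns at once
#'
#' @param genes,annotations,labels As in [match_pattern()].
#' @param patterns List of [cluster_pattern()] objects (default the five
#'   built-in oxidoreductase signatures).
#' @return Row-bound match tibble across patterns.
#' @export
match_patterns <- function(genes, annotations, patterns = oxidoreductase_patterns(),
                           labels = NULL) {
  purrr::map(patterns, function(p) match_pattern(genes, p, annotations, labels)) |>
    list_rbind()
}

#' Default marker definitions for terminal electron acceptor genes
#'
#' Maps marker names to the functional labels that evidence them; one gene
#' matching any listed label sets the marker present. The Arx/Arr catalytic
#' subunits share one column because their labels are routinely conflated.
#'
#' @return Named list of character vectors of labels.
#' @export
default_marker_defs <- function() {
  list(
    NarG = "narG", NrfA = "nrfA", NxrA = "nxrA", SrdA = "srdA",
    SreABC = c("sreA", "sreB", "sreC"),
    `Arx/Arr` = c("arxA", "arrA"),
    FdhAB = c("fdhA", "fdhB"),
    `NiFe group 1` = "nife_group1",
    `NiFe group 3b` = "nife_group3b"
  )
}

#' Presence/absence matrix of marker genes per genome
#'
#' Builds the binary genomes-by-markers matrix from per-gene functional
#' labels: a marker is present in a genome when at least one gene carries
#' one of the marker's labels (idempotent: multiple matching genes still
#' set the marker once). Missing labels simply leave the marker absent.
#'
#' @param labels Label table (`protein_id`, `genome_id`, `label`).
#' @param marker_defs Named list mapping marker names to label vectors
#'   (default [default_marker_defs()]).
#' @param genomes Optional character vector of genomes to report (all-absent
#'   rows kept).
#' @return Wide tibble: `genome_id` plus one 0/1 integer column per marker.
#' @export
marker_matrix <- function(labels, marker_defs = default_marker_defs(),
                          genomes = NULL) {
  stopifnot(all(c("protein_id", "genome_id", "label") %in% names(labels)))
  genomes <- genomes %||% sort(unique(labels$genome_id))
  out <- tibble(genome_id = genomes)
  for (mk in names(marker_defs)) {
    hit <- labels |>
      filter(tolower(.data$label) %in% tolower(marker_defs[[mk]])) |>
      distinct(.data$genome_id)
    out[[mk]] <- as.integer(out$genome_id %in% hit$genome_id)
  }
  out
}
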