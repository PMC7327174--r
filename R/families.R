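#' Build the reciprocal homology graph over MHC proteins
#'
#' Nodes are protein ids; an undirected edge joins two proteins iff a hit
#' exists in both directions and both directed hits pass the E-value and
#' identity thresholds. Per ordered pair only the best hit (by
#' [best_hits()] tie-breaking) is considered. Edge attributes carry the more
#' conservative side of each reciprocal hit pair (minimum identity and bit
#' score, maximum E-value).
#'
#' @param hits Hits tibble from [search_all()].
#' @param max_evalue Maximum E-value per directed hit (default 1e-3).
#' @param min_identity Minimum percent identity per directed hit
#'   (default 50).
#' @param min_coverage Minimum percent coverage of the shorter sequence by
#'   the aligned span (default 50); requires `seq_lengths`. Suppresses
#'   short spurious local matches between unrelated proteins, the standard
#'   companion criterion to identity in homology-graph clustering.
#' @param seq_lengths Named integer vector of sequence lengths per protein
#'   id; when `NULL` the coverage filter is skipped.
#' @param nodes Optional character vector of all node ids (isolated nodes
#'   are kept in the graph).
#' @return An undirected [igraph::igraph] with edge attributes `pident`,
#'   `evalue`, `bitscore`.
#' @export
build_homology_graph <- function(hits, max_evalue = 1e-3, min_identity = 50,
                                 min_coverage = 50, seq_lengths = NULL,
                                 nodes = NULL) {
  pass <- hits |>
    arrange(.data$query_id, .data$subject_id, desc(.data$bitscore),
            desc(.data$length)) |>
    distinct(.data$query_id, .data$subject_id, .keep_all = TRUE) |>
    filter(.data$evalue <= max_evalue, .data$pident >= min_identity,
           .data$query_id != .data$subject_id)
  if (!is.null(seq_lengths) && nrow(pass) > 0L) {
    qlen <- unname(seq_lengths[pass$query_id])
    slen <- unname(seq_lengths[pass$subject_id])
    span <- ifelse(qlen <= slen,
                   pass$qend - pass$qstart + 1L,
                   pass$send - pass$sstart + 1L)
    pass <- pass[100 * span / pmin(qlen, slen) >= min_coverage, , drop = FALSE]
  }

  edges <- if (nrow(pass) == 0L) {
    tibble(a = character(), b = character(), pident = numeric(),
           evalue = numeric(), bitscore = numeric())
  } else {
    pass |>
      mutate(a = pmin(.data$query_id, .data$subject_id),
             b = pmax(.data$query_id, .data$subject_id)) |>
      group_by(.data$a, .data$b) |>
      summarise(n_dir = n(),
                pident = min(.data$pident),
                evalue = max(.data$evalue),
                bitscore = min(.data$bitscore),
                .groups = "drop") |>
      filter(.data$n_dir == 2L) |>
      select(-"n_dir")
  }

  nodes <- nodes %||% unique(c(hits$query_id, hits$subject_id))
  nodes <- union(nodes, c(edges$a, edges$b))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = tibble(name = nodes))
}

#' Cluster MHC proteins into orthologous families
#'
#' Partitions the nodes of a reciprocal homology graph into orthologous
#' families: either the connected components of the graph (default) or a
#' deterministic Markov-clustering-style flow clustering (`"mcl"`,
#' expansion 2, configurable inflation) for finer granularity. Family ids
#' are assigned by descending family size, ties broken by the
#' lexicographically smallest member, so output is stable across runs.
#'
#' @param graph Graph from [build_homology_graph()]; nodes should be all
#'   scanned MHC protein ids (isolated nodes allowed).
#' @param method `"components"` or `"mcl"`.
#' @param genomes Optional named character vector mapping protein id to
#'   genome id (or an annotation data frame with `protein_id` and
#'   `genome_id`); when absent, genome ids are parsed from
#'   `<genome>|...` protein ids.
#' @param inflation Inflation exponent for `"mcl"` (default 2).
#' @return Object of class `mhc_families`: `families` tibble (`family_id`,
#'   `protein_id`, `genome_id`), `method`, `n_families`.
#' @export
cluster_families <- function(graph, method = c("components", "mcl"),
                             genomes = NULL, inflation = 2) {
  method <- tryCatch(match.arg(method),
                     error = function(e) abort("unknown clustering method; use \"components\" or \"mcl\"."))
  ids <- igraph::V(graph)$name
  if (length(ids) == 0L) {
    memb <- integer(0)
  } else if (method == "components") {
    memb <- igraph::components(graph)$membership
  } else {
    memb <- mcl_membership(graph, inflation = inflation)
  }

  if (is.data.frame(genomes)) {
    genomes <- setNames(genomes$genome_id, genomes$protein_id)
  }
  gid <- if (is.null(genomes)) {
    vapply(stringi::stri_split_fixed(ids, "|"), `[`, "", 1L)
  } else {
    unname(genomes[ids])
  }

  fam <- tibble(protein_id = ids, genome_id = gid, cluster = as.integer(memb))
  sizes <- fam |>
    group_by(.data$cluster) |>
    summarise(size = n(), rep = min(.data$protein_id), .groups = "drop") |>
    arrange(desc(.data$size), .data$rep) |>
    mutate(family_id = sprintf("F%04d", row_number()))
  fam <- fam |>
    left_join(sizes |> select("cluster", "family_id"), by = "cluster") |>
    select("family_id", "protein_id", "genome_id") |>
    arrange(.data$family_id, .data$protein_id)

  structure(list(families = fam, method = method,
                 n_families = nrow(sizes)),
            class = "mhc_families")
}

#' @export
print.mhc_families <- function(x, ...) {
  cat(sprintf("<mhc_families> %d protein(s) in %d famil(ies) [%s]\n",
              nrow(x$families), x$n_families, x$method))
  invisible(x)
}

# deterministic MCL-style flow clustering: column-stochastic walk matrix
# with self-loops, expansion (squaring) and inflation until convergence;
# clusters are the connected components of the limiting support
mcl_membership <- function(graph, inflation = 2, max_iter = 100L,
                           tol = 1e-8, prune = 1e-10) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  diag(A) <- 1
  M <- sweep(A, 2L, colSums(A), "/")
  for (i in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      break
    }
    M <- M2
  }
  support <- (M > prune) | (t(M) > prune)
  g2 <- igraph::graph_from_adjacency_matrix(support, mode = "undirected", diag = FALSE)
  igraph::components(g2)$membership
}

#' Genomes-by-families abundance matrix
#'
#' Counts family members per genome: `counts[g, f]` is the number of
#' members of family `f` encoded by genome `g`. Genomes without MHCs are
#' kept as all-zero rows when listed in `genomes`.
#'
#' @param families An `mhc_families` object (or its `families` tibble).
#' @param genomes Optional character vector of all genome ids to report.
#' @return A wide tibble: `genome_id` plus one integer column per family.
#' @export
abundance_matrix <- function(families, genomes = NULL) {
  fam <- if (inherits(families, "mhc_families")) families$families else as_tibble(families)
  stopifnot(all(c("family_id", "protein_id", "genome_id") %in% names(fam)))
  if (anyNA(fam$genome_id)) abort("integrity error: family member with unknown genome.")
  genomes <- genomes %||% sort(unique(fam$genome_id))
  if (!all(fam$genome_id %in% genomes)) {
    abort("integrity error: family member with unknown genome.")
  }
  wide <- fam |>
    count(.data$genome_id, .data$family_id) |>
    pivot_wider(names_from = "family_id", values_from = "n", values_fill = 0L)
  out <- tibble(genome_id = genomes) |>
    left_join(wide, by = "genome_id") |>
    mutate(across(-"genome_id", function(x) as.integer(replace_na(x, 0L))))
  fam_order <- sort(unique(fam$family_id))
  out[, c("genome_id", fam_order), drop = FALSE]
}

# wide abundance tibble -> plain integer matrix (genomes x families)
as_presence_matrix <- function(matrix_tbl) {
  m <- as.matrix(matrix_tbl[, setdiff(names(matrix_tbl), "genome_id"), drop = FALSE])
  rownames(m) <- matrix_tbl$genome_id
  storage.mode(m) <- "integer"
  m
}

#' Conservation summary of an abundance matrix
#'
#' Counts how many families occur in at least `k` genomes and how many are
#' core (present in every genome of the matrix).
#'
#' @param matrix_tbl Wide abundance tibble from [abundance_matrix()].
#' @param k Genome-count threshold, `1 <= k <=` number of genomes.
#' @return One-row tibble: `k`, `n_families_in_ge_k`, `n_core_families`.
#' @export
conservation_summary <- function(matrix_tbl, k) {
  m <- as_presence_matrix(matrix_tbl)
  n_genomes <- nrow(m)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n_genomes) {
    abort(sprintf("`k` must lie in [1, %d].", n_genomes))
  }
  present_in <- colSums(m > 0L)
  tibble(k = as.integer(k),
         n_families_in_ge_k = sum(present_in >= k),
         n_core_families = sum(present_in == n_genomes))
}

#' Conservation profile over all genome-count thresholds
#'
#' @param matrix_tbl Wide abundance tibble from [abundance_matrix()].
#' @return Tibble with one row per `k` in `1..n_genomes`.
#' @export
conservation_profile <- function(matrix_tbl) {
  n_genomes <- nrow(matrix_tbl)
  purrr::map(seq_len(n_genomes), function(k) conservation_summary(matrix_tbl, k)) |>
    list_rbind()
}

#' Cosmetic display ordering for abundance heatmaps
#'
#' Average-linkage hierarchical clustering on Euclidean distances of rows
#' and columns. Display only — the counts themselves are never reordered by
#' the computational core.
#'
#' @param matrix_tbl Wide abundance tibble.
#' @return List with `genome_order` and `family_order` character vectors.
#' @export
heatmap_ordering <- function(matrix_tbl) {
  m <- as_presence_matrix(matrix_tbl)
  ro <- if (nrow(m) > 2L) rownames(m)[hclust(dist(m), method = "average")$order] else rownames(m)
  co <- if (ncol(m) > 2L) colnames(m)[hclust(dist(t(m)), method = "average")$order] else colnames(m)
  list(genome_order = ro, family_order = co)
}
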