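#' Average amino acid identity (AAI) between two proteomes
#'
#' Computes genome-pair AAI as the mean percent identity over reciprocal
#' best hits that pass identity and coverage filters, the standard AAI
#' procedure over RBH orthologs. Coverage is measured on the shorter
#' sequence of each pair. The result is symmetric by construction: the two
#' genomes are ordered canonically (lexicographically) before searching.
#'
#' @param proteome_a,proteome_b Non-empty protein tables (`protein_id`,
#'   `genome_id`, `sequence`).
#' @param params An [alignment_params()].
#' @param min_identity Minimum RBH percent identity (default 30).
#' @param min_coverage Minimum percent coverage of the shorter sequence
#'   (default 70).
#' @return One-row tibble: `genome_a`, `genome_b`, `aai` (`NA` when no RBH
#'   pair qualifies — AAI is then undefined), `n_rbh_pairs`,
#'   `min_identity`, `min_coverage`.
#' @export
compute_aai <- function(proteome_a, proteome_b, params = alignment_params(),
                        min_identity = 30, min_coverage = 70) {
  check_protein_table(proteome_a, require_genome = TRUE)
  check_protein_table(proteome_b, require_genome = TRUE)
  if (nrow(proteome_a) == 0L || nrow(proteome_b) == 0L) {
    abort("both proteomes must be non-empty.")
  }
  ga <- unique(proteome_a$genome_id)
  gb <- unique(proteome_b$genome_id)
  stopifnot(length(ga) == 1L, length(gb) == 1L)

  # canonical ordering makes AAI(a, b) == AAI(b, a) exactly
  if (ga > gb) {
    tmp <- proteome_a; proteome_a <- proteome_b; proteome_b <- tmp
    tmp <- ga; ga <- gb; gb <- tmp
  }

  hits_ab <- search_all(proteome_a, proteome_b, params)
  hits_ba <- search_all(proteome_b, proteome_a, params)
  rbh <- reciprocal_best_hits(hits_ab, hits_ba)

  if (nrow(rbh) > 0L) {
    len_a <- setNames(nchar(proteome_a$sequence), proteome_a$protein_id)
    len_b <- setNames(nchar(proteome_b$sequence), proteome_b$protein_id)
    qlen <- len_a[rbh$query_id]
    slen <- len_b[rbh$subject_id]
    span <- ifelse(qlen <= slen,
                   rbh$qend - rbh$qstart + 1L,
                   rbh$send - rbh$sstart + 1L)
    coverage <- 100 * span / pmin(qlen, slen)
    rbh <- rbh[rbh$pident >= min_identity & coverage >= min_coverage, , drop = FALSE]
  }

  tibble(
    genome_a = ga, genome_b = gb,
    aai = if (nrow(rbh) > 0L) mean(rbh$pident) else NA_real_,
    n_rbh_pairs = nrow(rbh),
    min_identity = min_identity,
    min_coverage = min_coverage
  )
}

#' Pairwise AAI over a set of genomes
#'
#' Runs [compute_aai()] for every unordered genome pair in a multi-genome
#' protein table.
#'
#' @param proteins Protein table with `genome_id`.
#' @inheritParams compute_aai
#' @return Tibble with one row per genome pair (see [compute_aai()]).
#' @export
aai_matrix <- function(proteins, params = alignment_params(),
                       min_identity = 30, min_coverage = 70) {
  check_protein_table(proteins, require_genome = TRUE)
  genomes <- sort(unique(proteins$genome_id))
  if (length(genomes) < 2L) abort("need at least two genomes.")
  pairs <- utils::combn(genomes, 2L)
  purrr::map(seq_len(ncol(pairs)), function(i) {
    compute_aai(proteins[proteins$genome_id == pairs[1L, i], , drop = FALSE],
                proteins[proteins$genome_id == pairs[2L, i], , drop = FALSE],
                params, min_identity, min_coverage)
  }) |> list_rbind()
}
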