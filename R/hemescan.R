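#' Locate CXXCH heme-binding motifs in a protein sequence
#'
#' Scans an amino-acid sequence for the canonical heme c attachment motif
#' CXXCH (cysteine, two arbitrary residues, cysteine, histidine). All
#' occurrences are reported, including overlapping ones; two motif starts can
#' be as close as 3 residues when they share the second cysteine.
#'
#' Matching is case-insensitive. A single terminal stop symbol (`*`) is
#' stripped before scanning; internal stops are rejected. The ambiguity
#' character `X` matches the two wildcard positions but never the anchored
#' C/C/H positions.
#'
#' @param sequence A single amino-acid string.
#' @return Integer vector of 0-based motif start offsets, sorted ascending.
#' @examples
#' find_heme_motifs("CAACHACH")  # overlapping pair -> 0, 3
#' @export
find_heme_motifs <- function(sequence) {
  sequence <- validate_sequence(sequence)
  if (nchar(sequence) < 5L) return(integer(0))
  loc <- stringi::stri_locate_all_regex(sequence, "(?=C[A-Z]{2}CH)")[[1]]
  if (all(is.na(loc[, 1]))) return(integer(0))
  as.integer(loc[, 1]) - 1L
}

# vectorised overlapping motif count (scanner fast path over many sequences)
count_heme_motifs <- function(sequences) {
  sequences <- toupper(sequences)
  as.integer(stringi::stri_count_regex(sequences, "(?=C[A-Z]{2}CH)"))
}

# strip one terminal '*', upper-case, reject anything but letters
validate_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort(sprintf("`%s` must be a single non-missing string.", arg))
  }
  sequence <- toupper(sequence)
  sequence <- sub("\\*$", "", sequence)
  if (stringi::stri_detect_regex(sequence, "[^A-Z]")) {
    abort(sprintf("`%s` contains non-letter characters (internal stops or gaps are not allowed).", arg))
  }
  sequence
}

# greedy left-to-right selection of non-overlapping motifs (>= 5 apart)
disjoint_motifs <- function(offsets) {
  keep <- integer(0)
  last <- -5L
  for (o in offsets) {
    if (o - last >= 5L) {
      keep <- c(keep, o)
      last <- o
    }
  }
  keep
}

#' Call putative multiheme cytochromes from a protein table
#'
#' Annotates every protein with its CXXCH motif positions and heme count and
#' flags proteins with at least `min_motifs` motifs as putative multiheme
#' c-type cytochromes (MHCs).
#'
#' @param proteins Data frame with at least `protein_id` and `sequence`
#'   columns; a `genome_id` column is carried through when present.
#' @param min_motifs Minimum number of CXXCH motifs for the MHC call
#'   (default 3).
#' @param disjoint If `TRUE`, count only greedily selected non-overlapping
#'   motifs instead of all (possibly overlapping) occurrences.
#' @param domains Optional data frame of externally produced domain hits
#'   (`protein_id`, `domain`) used to fill the cytochrome/S-layer domain
#'   flags; when absent both flags are `"untested"`.
#' @return A tibble with one row per protein: `protein_id`, `genome_id`,
#'   `heme_count`, `is_mhc`, `motif_positions` (list column of 0-based
#'   offsets), `has_cyt_domain`, `has_slayer_domain`.
#' @export
call_mhc <- function(proteins, min_motifs = 3L, disjoint = FALSE,
                     domains = NULL) {
  check_protein_table(proteins)
  if (!is.numeric(min_motifs) || length(min_motifs) != 1L || min_motifs < 1) {
    abort("`min_motifs` must be a single count >= 1.")
  }
  min_motifs <- as.integer(min_motifs)

  pos <- map(proteins$sequence, find_heme_motifs)
  if (disjoint) pos <- map(pos, disjoint_motifs)

  ann <- tibble(
    protein_id = proteins$protein_id,
    genome_id = if ("genome_id" %in% names(proteins)) proteins$genome_id else NA_character_,
    heme_count = map_int(pos, length),
    is_mhc = map_int(pos, length) >= min_motifs,
    motif_positions = pos,
    has_cyt_domain = "untested",
    has_slayer_domain = "untested"
  )

  if (!is.null(domains)) {
    stopifnot(all(c("protein_id", "domain") %in% names(domains)))
    cyt <- unique(domains$protein_id[grepl("cytochrom", domains$domain, ignore.case = TRUE)])
    sla <- unique(domains$protein_id[grepl("s[-_ ]?layer", domains$domain, ignore.case = TRUE)])
    ann$has_cyt_domain <- ifelse(ann$protein_id %in% cyt, "yes", "no")
    ann$has_slayer_domain <- ifelse(ann$protein_id %in% sla, "yes", "no")
  }
  ann
}

#' Scan proteomes for MHCs and summarise per-genome repertoires
#'
#' Runs [call_mhc()] over a multi-genome protein table and aggregates
#' per-genome repertoire statistics: number of proteins, number of MHCs,
#' maximum and mean heme count per MHC, and total hemes.
#'
#' @inheritParams call_mhc
#' @param genomes Optional character vector of genome ids to report;
#'   genomes with no proteins get zeroed statistics. Defaults to the genomes
#'   present in `proteins`.
#' @return An object of class `mhc_scan` with elements `annotations` (tibble,
#'   see [call_mhc()]), `stats` (one row per genome) and `params`.
#' @export
scan_proteome <- function(proteins, min_motifs = 3L, disjoint = FALSE,
                          domains = NULL, genomes = NULL) {
  check_protein_table(proteins, require_genome = TRUE)
  dup <- proteins |>
    count(.data$genome_id, .data$protein_id) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate protein_id within a genome: %s",
                  paste(head(dup$protein_id, 3), collapse = ", ")))
  }
  genomes <- genomes %||% unique(proteins$genome_id)

  ann <- call_mhc(proteins, min_motifs = min_motifs, disjoint = disjoint,
                  domains = domains)

  stats <- ann |>
    group_by(genome_id = .data$genome_id) |>
    summarise(
      n_proteins = n(),
      n_mhc = sum(.data$is_mhc),
      max_hemes = if (any(.data$is_mhc)) max(.data$heme_count[.data$is_mhc]) else 0L,
      mean_hemes = if (any(.data$is_mhc)) mean(.data$heme_count[.data$is_mhc]) else 0,
      total_hemes = sum(.data$heme_count[.data$is_mhc]),
      .groups = "drop"
    )
  empty <- setdiff(genomes, stats$genome_id)
  if (length(empty) > 0L) {
    stats <- bind_rows(stats, tibble(
      genome_id = empty, n_proteins = 0L, n_mhc = 0L,
      max_hemes = 0L, mean_hemes = 0, total_hemes = 0L
    ))
  }
  stats <- stats |>
    filter(.data$genome_id %in% genomes) |>
    arrange(match(.data$genome_id, genomes))

  structure(
    list(annotations = ann, stats = stats,
         params = list(min_motifs = as.integer(min_motifs), disjoint = disjoint)),
    class = "mhc_scan"
  )
}

#' @export
print.mhc_scan <- function(x, ...) {
  cat(sprintf("<mhc_scan> %d proteins in %d genome(s); %d MHC(s) at >=%d CXXCH motifs; max %d hemes\n",
              nrow(x$annotations), nrow(x$stats), sum(x$annotations$is_mhc),
              x$params$min_motifs,
              if (any(x$annotations$is_mhc)) max(x$annotations$heme_count[x$annotations$is_mhc]) else 0L))
  invisible(x)
}

check_protein_table <- function(proteins, require_genome = FALSE) {
  if (!is.data.frame(proteins)) abort("`proteins` must be a data frame.")
  need <- c("protein_id", "sequence", if (require_genome) "genome_id")
  miss <- setdiff(need, names(proteins))
  if (length(miss) > 0L) {
    abort(sprintf("`proteins` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  invisible(proteins)
}

#' Check NiFe-hydrogenase L1/L2 binding motifs
#'
#' Tests a catalytic-subunit sequence for the two conserved
#' cysteine-containing motifs (L1, L2) that coordinate the NiFe centre.
#' Patterns use a compact motif syntax: upper-case letters match themselves,
#' `x` matches any residue, and `[...]` is a residue class (e.g. `"[HR]"`).
#'
#' The shipped defaults (`RxCGxCxxxH` and `DPCxxCxxH`) are canonical
#' hydrogenase motif expressions chosen by this package, not values taken
#' from any particular study; override them to match your reference scheme.
#' A message flags when the built-in defaults are used.
#'
#' @param sequence Amino-acid string.
#' @param l1_pattern,l2_pattern Motif expressions for the L1 and L2 sites.
#' @param quiet Suppress the default-pattern message.
#' @return A tibble with logical columns `l1_found` and `l2_found`.
#' @export
check_nife_motifs <- function(sequence,
                              l1_pattern = "RxCGxCxxxH",
                              l2_pattern = "DPCxxCxxH",
                              quiet = FALSE) {
  default_used <- missing(l1_pattern) && missing(l2_pattern)
  if (default_used && !quiet) {
    inform("check_nife_motifs: using built-in default L1/L2 motif patterns (implementation-chosen, override to taste).")
  }
  sequence <- validate_sequence(sequence)
  tibble(
    l1_found = stringi::stri_detect_regex(sequence, motif_to_regex(l1_pattern)),
    l2_found = stringi::stri_detect_regex(sequence, motif_to_regex(l2_pattern))
  )
}

# compact motif expression -> regex; letters literal, x wildcard, [..] class
motif_to_regex <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) || nchar(pattern) == 0L) {
    abort("motif pattern must be a single non-empty string.")
  }
  if (stringi::stri_detect_regex(pattern, "[^A-Zx\\[\\]]")) {
    abort(sprintf("malformed motif pattern '%s': only A-Z, 'x' and [..] classes are allowed.", pattern))
  }
  n_open <- stringi::stri_count_fixed(pattern, "[")
  n_close <- stringi::stri_count_fixed(pattern, "]")
  if (n_open != n_close) abort(sprintf("malformed motif pattern '%s': unbalanced brackets.", pattern))
  gsub("x", "[A-Z]", pattern, fixed = TRUE)
}
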