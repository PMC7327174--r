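#' Read protein FASTA files into a protein table
#'
#' Reads one or more multi-record protein FASTA files. Header text after the
#' first whitespace is ignored. When headers follow the
#' `<genome>|<scaffold>|<gene_index>` convention the genome and scaffold are
#' parsed from the id; otherwise the genome id defaults to the file name
#' without extension (or the matching entry of `genome_ids`).
#'
#' @param paths Character vector of FASTA file paths.
#' @param genome_ids Optional character vector parallel to `paths`.
#' @return Tibble (`protein_id`, `genome_id`, `scaffold_id`, `sequence`).
#' @export
read_proteome_fasta <- function(paths, genome_ids = NULL) {
  stopifnot(length(paths) > 0L)
  if (!is.null(genome_ids)) stopifnot(length(genome_ids) == length(paths))
  purrr::imap(paths, function(path, i) {
    aa <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    parts <- stringi::stri_split_fixed(ids, "|")
    from_header <- lengths(parts) >= 3L
    gid_default <- if (is.null(genome_ids)) {
      sub("\\.[^.]*$", "", basename(path))
    } else {
      genome_ids[i]
    }
    tibble(
      protein_id = ids,
      genome_id = ifelse(from_header, vapply(parts, `[`, "", 1L), gid_default),
      scaffold_id = ifelse(from_header, vapply(parts, `[`, "", 2L), NA_character_),
      sequence = unname(sub("\\*$", "", toupper(as.character(aa))))
    )
  }) |> list_rbind()
}

#' Read gene coordinates from a GFF3 file
#'
#' Imports CDS (or gene) features and returns the coordinate table consumed
#' by [order_genes()]. The `ID` attribute must match the protein ids of the
#' corresponding FASTA.
#'
#' @param path GFF3 file path.
#' @param genome_id Genome id to attach; defaults to the file name.
#' @return Tibble (`protein_id`, `genome_id`, `scaffold_id`, `start`, `end`,
#'   `strand`).
#' @export
read_gene_gff <- function(path, genome_id = sub("\\.[^.]*$", "", basename(path))) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    keep <- as.character(gr$type) %in% c("CDS", "gene")
    if (any(keep)) gr <- gr[keep]
  }
  ids <- gr$ID
  if (is.null(ids)) abort(sprintf("GFF3 parse error: no ID attribute in %s", path))
  if (anyNA(ids)) abort(sprintf("GFF3 parse error: missing ID attribute in %s", path))
  tibble(
    protein_id = as.character(ids),
    genome_id = genome_id,
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
}

# write a per-genome gene table as GFF3 (CDS features, ID = protein_id)
write_gene_gff <- function(proteins, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = proteins$scaffold_id,
    ranges = IRanges::IRanges(start = proteins$start, end = proteins$end),
    strand = proteins$strand
  )
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- proteins$protein_id
  gr$source <- "multiheme_synthetic"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write MHC annotations as TSV
#'
#' Motif positions are serialised as a semicolon-joined list of 0-based
#' offsets.
#'
#' @param annotations Annotation tibble from [call_mhc()].
#' @param path Output file.
#' @export
write_annotations_tsv <- function(annotations, path) {
  out <- annotations |>
    mutate(motif_positions = map_chr(.data$motif_positions,
                                     function(p) paste(p, collapse = ";"))) |>
    select("protein_id", "genome_id", "heme_count", "is_mhc", "motif_positions")
  readr::write_tsv(out, path)
  invisible(path)
}
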