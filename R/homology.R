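#' Parameters for local protein alignment and E-value estimation
#'
#' Bundles the substitution matrix, affine gap penalties, and
#' Karlin-Altschul constants used by [align_pair()], [search_all()] and
#' downstream search operations. The defaults (BLOSUM62, gap open 11,
#' gap extend 1, lambda 0.267, K 0.041) mirror common blastp settings;
#' exact blastp score parity is not a goal — all thresholds in this package
#' are applied to this aligner's own outputs.
#'
#' @param matrix Substitution matrix name (passed to Biostrings).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul constants for the raw-to-bit score
#'   conversion `bits = (lambda * S - ln K) / ln 2`.
#' @param pid_denom Denominator of percent identity: `"alignment"` (all
#'   alignment columns, gaps included; the default, mirroring common blastp
#'   reporting) or `"shorter"` (length of the shorter sequence).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                             lambda = 0.267, K = 0.041,
                             pid_denom = c("alignment", "shorter")) {
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be positive.")
  if (lambda <= 0 || K <= 0) abort("`lambda` and `K` must be positive.")
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, pid_denom = match.arg(pid_denom)),
            class = "alignment_params")
}

# raw Smith-Waterman score -> bit score
bit_score <- function(raw, params) {
  (params$lambda * raw - log(params$K)) / log(2)
}

#' Closed-form E-value from a bit score
#'
#' `E = m * n * 2^(-bits)` for query length `m` and database residue count
#' `n`.
#'
#' @param bit_score Bit score(s).
#' @param m Query length (>= 1).
#' @param n Database residue count (>= 1).
#' @return Numeric E-value(s).
#' @export
evalue <- function(bit_score, m, n) {
  if (any(m < 1) || any(n < 1)) abort("`m` and `n` must be >= 1.")
  as.numeric(m) * as.numeric(n) * 2^(-bit_score)
}

# vectorised core: align one subject sequence against a set of patterns and
# return the per-hit statistics used everywhere downstream
align_set <- function(db_seqs, query_seq, params) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(db_seqs),
    subject = query_seq,
    type = "local",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend
  )
  ni <- Biostrings::nindel(aln)
  alen <- Biostrings::nchar(aln)
  nm <- Biostrings::nmatch(aln)
  tibble(
    raw_score = Biostrings::score(aln),
    nmatch = nm,
    mismatches = Biostrings::nmismatch(aln),
    gapopen = ni@insertion[, 1L] + ni@deletion[, 1L],
    length = alen,
    qstart = BiocGenerics::start(Biostrings::subject(aln)),
    qend = BiocGenerics::end(Biostrings::subject(aln)),
    sstart = BiocGenerics::start(Biostrings::pattern(aln)),
    send = BiocGenerics::end(Biostrings::pattern(aln))
  )
}

hit_pident <- function(stats, qlen, slen, params) {
  denom <- switch(params$pid_denom,
                  alignment = stats$length,
                  shorter = pmin(qlen, slen))
  100 * stats$nmatch / denom
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman-style local alignment under an affine gap model, reported
#' blastp-tabular style: percent identity (identical columns over alignment
#' length, gaps included), alignment length, mismatches, gap opens,
#' coordinates, E-value and bit score.
#'
#' @param a,b Non-empty amino-acid strings (`a` is the query).
#' @param params An [alignment_params()].
#' @param m,n Search-space sizes for the E-value; default to the two
#'   sequence lengths.
#' @return One-row tibble of hit statistics.
#' @export
align_pair <- function(a, b, params = alignment_params(),
                       m = nchar(a), n = nchar(b)) {
  a <- validate_sequence(a, "a")
  b <- validate_sequence(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L) abort("sequences must be non-empty.")
  stats <- align_set(b, a, params)
  bits <- bit_score(stats$raw_score, params)
  tibble(
    pident = hit_pident(stats, nchar(a), nchar(b), params),
    length = stats$length,
    mismatches = stats$mismatches,
    gapopen = stats$gapopen,
    qstart = stats$qstart, qend = stats$qend,
    sstart = stats$sstart, send = stats$send,
    evalue = evalue(bits, m, n),
    bitscore = bits,
    raw_score = stats$raw_score
  )
}

#' All-vs-all local alignment search between two protein sets
#'
#' Aligns every query against every database sequence and returns hits in
#' the standard 12-column blastp tabular layout (plus raw score and genome
#' ids when present). E-values use the query length and the total residue
#' count of the database. Self-hits (identical `protein_id`) are dropped.
#'
#' When `query` and `db` are the same table, set `symmetric = TRUE`: each
#' unordered pair is aligned once and mirrored (scores and identities are
#' symmetric; coordinates are swapped, E-values recomputed per direction).
#'
#' @param query,db Protein tables (`protein_id`, `sequence`, optional
#'   `genome_id`).
#' @param params An [alignment_params()].
#' @param symmetric Mirror hits instead of aligning both directions.
#' @return Tibble with columns `query_id`, `subject_id`, `pident`, `length`,
#'   `mismatches`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`, `raw_score`, and `query_genome`/`subject_genome`.
#' @export
search_all <- function(query, db, params = alignment_params(), symmetric = FALSE) {
  check_protein_table(query)
  check_protein_table(db)
  if (nrow(query) == 0L || nrow(db) == 0L) return(empty_hits())
  qgen <- if ("genome_id" %in% names(query)) query$genome_id else NA_character_
  sgen <- if ("genome_id" %in% names(db)) db$genome_id else NA_character_
  n_db <- sum(nchar(db$sequence))
  n_q <- sum(nchar(query$sequence))

  res <- vector("list", nrow(query))
  for (i in seq_len(nrow(query))) {
    jdx <- if (symmetric) which(seq_len(nrow(db)) > i) else seq_len(nrow(db))
    jdx <- jdx[db$protein_id[jdx] != query$protein_id[i]]
    if (length(jdx) == 0L) next
    stats <- align_set(db$sequence[jdx], query$sequence[i], params)
    bits <- bit_score(stats$raw_score, params)
    qlen <- nchar(query$sequence[i])
    slen <- nchar(db$sequence[jdx])
    fwd <- tibble(
      query_id = query$protein_id[i], subject_id = db$protein_id[jdx],
      pident = hit_pident(stats, qlen, slen, params),
      length = stats$length, mismatches = stats$mismatches,
      gapopen = stats$gapopen,
      qstart = stats$qstart, qend = stats$qend,
      sstart = stats$sstart, send = stats$send,
      evalue = evalue(bits, qlen, n_db),
      bitscore = bits, raw_score = stats$raw_score,
      query_genome = if (length(qgen) > 1L) qgen[i] else qgen,
      subject_genome = if (length(sgen) > 1L) sgen[jdx] else sgen
    )
    if (symmetric) {
      rev <- fwd
      rev$query_id <- fwd$subject_id
      rev$subject_id <- fwd$query_id
      rev$qstart <- fwd$sstart; rev$qend <- fwd$send
      rev$sstart <- fwd$qstart; rev$send <- fwd$qend
      rev$evalue <- evalue(bits, slen, n_q)
      rev$query_genome <- fwd$subject_genome
      rev$subject_genome <- fwd$query_genome
      fwd <- bind_rows(fwd, rev)
    }
    res[[i]] <- fwd
  }
  out <- list_rbind(purrr::compact(res))
  if (nrow(out) == 0L) empty_hits() else out
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(), pident = numeric(),
         length = integer(), mismatches = integer(), gapopen = integer(),
         qstart = integer(), qend = integer(), sstart = integer(), send = integer(),
         evalue = numeric(), bitscore = numeric(), raw_score = numeric(),
         query_genome = character(), subject_genome = character())
}

#' Best hit per query
#'
#' Deterministic tie-breaking: highest bit score, then longest alignment,
#' then lexicographically smallest subject id.
#'
#' @param hits A hits tibble from [search_all()].
#' @return One row per `query_id`.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits |>
    arrange(.data$query_id, desc(.data$bitscore), desc(.data$length), .data$subject_id) |>
    distinct(.data$query_id, .keep_all = TRUE)
}

#' Reciprocal best hits between two proteomes
#'
#' A pair `(x, y)` is reported iff `y` is `x`'s best hit in the A-to-B
#' search and `x` is `y`'s best hit in the B-to-A search; each protein
#' appears in at most one pair.
#'
#' @param hits_ab,hits_ba Hits tibbles for the two search directions.
#' @return Tibble of RBH pairs with the A-to-B hit statistics
#'   (`query_id` = A protein, `subject_id` = B protein).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  ab <- best_hits(hits_ab)
  ba <- best_hits(hits_ba)
  if (nrow(ab) == 0L || nrow(ba) == 0L) return(empty_hits())
  ab |>
    inner_join(ba |> select(rev_query = "query_id", rev_subject = "subject_id"),
               by = c(subject_id = "rev_query")) |>
    filter(.data$query_id == .data$rev_subject) |>
    select(-"rev_subject")
}
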