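# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force CXXCH enumeration: test the three-position condition at every
# offset directly on the character vector
brute_motif_offsets <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 5L) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(L - 4L)) {
    if (chars[i] == "C" && chars[i + 3L] == "C" && chars[i + 4L] == "H") {
      hits <- c(hits, i - 1L)
    }
  }
  hits
}

# independent affine-gap Smith-Waterman (Gotoh) returning the optimal local
# score; a gap of length L costs open + L * extend, matching the package's
# parameterisation
gotoh_local_score <- function(a, b, gap_open = 11, gap_extend = 1,
                              matrix_name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  submat <- get(matrix_name, envir = e)
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ac); m <- length(bc)
  H <- matrix(0, n + 1L, m + 1L)   # best score ending at (i, j)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (deletion from a)
  F_ <- matrix(-Inf, n + 1L, m + 1L) # gap in a
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i, j + 1L] - gap_open - gap_extend,
                               E[i, j + 1L] - gap_extend)
      F_[i + 1L, j + 1L] <- max(H[i + 1L, j] - gap_open - gap_extend,
                                F_[i + 1L, j] - gap_extend)
      s <- H[i, j] + submat[ac[i], bc[j]]
      H[i + 1L, j + 1L] <- max(0, s, E[i + 1L, j + 1L], F_[i + 1L, j + 1L])
      if (H[i + 1L, j + 1L] > best) best <- H[i + 1L, j + 1L]
    }
  }
  best
}

# adjusted Rand index between two labellings (external implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random amino-acid sequence over the full alphabet
random_aa <- function(L, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                      "K", "L", "M", "N", "P", "Q", "R", "S",
                                      "T", "V", "W", "Y")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# random sequence free of C and H (cannot contain a CXXCH motif)
random_bg <- function(L) {
  random_aa(L, alphabet = setdiff(c("A", "C", "D", "E", "F", "G", "H", "I",
                                    "K", "L", "M", "N", "P", "Q", "R", "S",
                                    "T", "V", "W", "Y"), c("C", "H")))
}

# position-wise identity of two equal-length strings (mutation oracle)
positional_identity <- function(a, b) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ac) == length(bc))
  100 * sum(ac == bc) / length(ac)
}
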