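#' Plant an exact number of CXXCH motifs into a sequence
#'
#' Rewrites a sequence, by substitution only (never insertion), so that the
#' returned sequence contains exactly `k` CXXCH heme-binding motifs. Any
#' pre-existing or incidentally created motif outside the planted set is
#' destroyed by a further substitution, and the result is verified with
#' [find_heme_motifs()] before it is returned. With `k = 0` the function
#' simply scrubs all motifs from the input.
#'
#' @param sequence Amino-acid string of length at least `5 * k`.
#' @param k Number of motifs to plant (>= 0).
#' @param seed Integer seed controlling motif placement.
#' @return A string of the same length with exactly `k` scanner-verified
#'   motifs.
#' @export
plant_motifs <- function(sequence, k, seed = 1L) {
  sequence <- validate_sequence(sequence)
  if (!is.numeric(k) || length(k) != 1L || k < 0) abort("`k` must be a single count >= 0.")
  k <- as.integer(k)
  L <- nchar(sequence)
  if (k > 0L && L < 5L * k) {
    abort(sprintf("sequence of length %d is too short to hold %d non-overlapping CXXCH motifs (needs >= %d).",
                  L, k, 5L * k))
  }
  withr::with_seed(as.integer(seed), {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    starts <- integer(0)
    if (k > 0L) {
      starts <- spaced_motif_starts(L, k)
      for (p in starts) {
        chars[p] <- "C"
        for (w in c(p + 1L, p + 2L)) {
          if (chars[w] %in% c("C", "H")) chars[w] <- sample(AA_BG, 1L)
        }
        chars[p + 3L] <- "C"
        chars[p + 4L] <- "H"
      }
    }
    essential <- unique(as.integer(outer(starts, c(0L, 3L, 4L), `+`)))
    for (iter in seq_len(60L)) {
      found <- find_heme_motifs(paste(chars, collapse = "")) + 1L
      spurious <- setdiff(found, starts)
      if (length(spurious) == 0L) break
      for (j in spurious) {
        cand <- setdiff(c(j, j + 3L, j + 4L), essential)
        if (length(cand) == 0L) abort("internal error: cannot scrub a motif overlapping planted sites.")
        chars[cand[1L]] <- "A"
      }
    }
    out <- paste(chars, collapse = "")
    found <- find_heme_motifs(out) + 1L
    if (!identical(sort(found), sort(starts))) {
      abort("internal error: planted motif verification failed.")
    }
    out
  })
}

#' Mutate a sequence to a target percent identity
#'
#' Substitutes exactly `round(L * (1 - target/100))` positions of the input
#' (each to a different residue), so the identity of the output to the input
#' is the rounded target. Positions inside CXXCH motifs are never touched and
#' substitutions never introduce C or H, so the heme count of the sequence is
#' preserved exactly.
#'
#' @param sequence Amino-acid string.
#' @param target Target percent identity in (0, 100].
#' @param seed Integer seed controlling position and residue choice.
#' @return Mutated string of the same length.
#' @export
mutate_to_identity <- function(sequence, target, seed = 1L) {
  sequence <- validate_sequence(sequence)
  if (!is.numeric(target) || length(target) != 1L || target <= 0 || target > 100) {
    abort("`target` must be a percent identity in (0, 100].")
  }
  L <- nchar(sequence)
  n_mut <- round(L * (1 - target / 100))
  if (n_mut == 0L) return(sequence)
  protected <- unique(as.integer(outer(find_heme_motifs(sequence) + 1L, 0:4, `+`)))
  avail <- setdiff(seq_len(L), protected)
  if (n_mut > length(avail)) {
    abort(sprintf("cannot reach %.1f%% identity: only %d positions are outside CXXCH motifs.",
                  target, length(avail)))
  }
  withr::with_seed(as.integer(seed), {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    idx <- sample(avail, n_mut)
    repl <- sample(AA_BG, n_mut, replace = TRUE)
    same <- repl == chars[idx]
    while (any(same)) {
      repl[same] <- sample(AA_BG, sum(same), replace = TRUE)
      same <- repl == chars[idx]
    }
    chars[idx] <- repl
    paste(chars, collapse = "")
  })
}

#' Configuration for the synthetic genome-set generator
#'
#' Defines the study conditions the generator emulates: a family of related
#' archaeal-like genomes whose proteomes carry a minority class of multiheme
#' cytochromes organised into orthologous families, plus collocated
#' oxidoreductase-like gene clusters and motif-free decoys. The defaults
#' mirror the observed conditions in the Methanoperedenaceae comparison the
#' package targets: 16 genomes of 1,700-4,700 proteins, 3-49 MHCs per
#' genome, heme counts spanning 3-113 with a single largest 113-heme
#' protein in the final genome, and 82 planted orthologous families of which
#' five belong to the built-in gene-cluster signatures.
#'
#' @param n_genomes Number of genomes.
#' @param proteins_per_genome Inclusive integer range of proteome sizes.
#' @param mhc_per_genome Inclusive integer range from which each genome's
#'   total MHC count is drawn (ignored when `mhc_fraction` is given).
#' @param mhc_fraction Optional proportion in \[0,1\]; when set, each
#'   genome's MHC count is `round(mhc_fraction * proteome size)`.
#' @param n_families Total number of planted orthologous MHC families,
#'   including one family per planted cluster pattern.
#' @param family_identity Target within-family percent amino-acid identity.
#' @param family_presence Optional `n_families x n_genomes` integer matrix of
#'   planted member counts; overrides the drawn MHC counts.
#' @param heme_count_range Inclusive range of per-family heme counts (min
#'   >= 3); the top of the range is planted exactly once.
#' @param heme_count_mean Mean of the right-skewed heme-count draw.
#' @param planted_clusters `"auto"` (plant each of the five oxidoreductase
#'   signatures in every genome whose MHC budget allows it), `"none"`, or a
#'   data frame with columns `pattern` and `genome_id`.
#' @param decoy_motif_max Maximum CXXCH motifs allowed on a decoy (< 3).
#' @param decoy_motif_fraction Fraction of decoys carrying 1 to
#'   `decoy_motif_max` planted motifs.
#' @param protein_length_range Inclusive range of decoy protein lengths.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genomes = 16L,
                             proteins_per_genome = c(1700L, 4700L),
                             mhc_per_genome = c(3L, 49L),
                             mhc_fraction = NULL,
                             n_families = 82L,
                             family_identity = 85,
                             family_presence = NULL,
                             heme_count_range = c(3L, 113L),
                             heme_count_mean = 12,
                             planted_clusters = "auto",
                             decoy_motif_max = 2L,
                             decoy_motif_fraction = 0.05,
                             protein_length_range = c(100L, 600L),
                             seed = 1L) {
  chk_range <- function(r, name, lo = 0L) {
    if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < lo) {
      abort(sprintf("`%s` must be an increasing 2-vector with minimum >= %d.", name, lo))
    }
    as.integer(r)
  }
  if (!is.numeric(n_genomes) || length(n_genomes) != 1L || n_genomes < 0) {
    abort("`n_genomes` must be a single count >= 0.")
  }
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    proteins_per_genome = chk_range(proteins_per_genome, "proteins_per_genome", 1L),
    mhc_per_genome = chk_range(mhc_per_genome, "mhc_per_genome", 0L),
    mhc_fraction = mhc_fraction,
    n_families = as.integer(n_families),
    family_identity = family_identity,
    family_presence = family_presence,
    heme_count_range = chk_range(heme_count_range, "heme_count_range", 3L),
    heme_count_mean = heme_count_mean,
    planted_clusters = planted_clusters,
    decoy_motif_max = as.integer(decoy_motif_max),
    decoy_motif_fraction = decoy_motif_fraction,
    protein_length_range = chk_range(protein_length_range, "protein_length_range", 25L),
    seed = as.integer(seed)
  )
  if (!is.null(cfg$mhc_fraction) &&
      (cfg$mhc_fraction < 0 || cfg$mhc_fraction > 1)) {
    abort("`mhc_fraction` must lie in [0, 1].")
  }
  if (cfg$family_identity <= 0 || cfg$family_identity > 100) {
    abort("`family_identity` must be a percent in (0, 100].")
  }
  if (cfg$decoy_motif_max > 2L || cfg$decoy_motif_max < 0L) {
    abort("`decoy_motif_max` must be 0, 1 or 2 (decoys are sub-threshold by definition).")
  }
  if (cfg$n_families < 0L) abort("`n_families` must be >= 0.")
  if (!is.null(cfg$family_presence)) {
    fp <- cfg$family_presence
    if (!is.matrix(fp) || ncol(fp) != cfg$n_genomes) {
      abort("`family_presence` must be a matrix with one column per genome.")
    }
    cfg$n_families <- nrow(fp)
  }
  if (is.data.frame(cfg$planted_clusters)) {
    stopifnot(all(c("pattern", "genome_id") %in% names(cfg$planted_clusters)))
    bad <- setdiff(cfg$planted_clusters$pattern, names(cluster_component_plan()))
    if (length(bad) > 0L) abort(sprintf("unknown cluster pattern(s): %s", paste(bad, collapse = ", ")))
  } else if (!identical(cfg$planted_clusters, "auto") && !identical(cfg$planted_clusters, "none")) {
    abort("`planted_clusters` must be \"auto\", \"none\", or a data frame (pattern, genome_id).")
  }
  structure(cfg, class = "synthetic_config")
}

# vectorised background sequence draw: C/H-free alphabet so motifs only
# exist where planted
random_bg_sequences <- function(lengths) {
  if (length(lengths) == 0L) return(character(0))
  total <- sum(lengths)
  pool <- paste(sample(AA_BG, total, replace = TRUE), collapse = "")
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  stringi::stri_sub(pool, starts, ends)
}

# k motif start positions with irregular spacing (>= 5 apart, arbitrary
# offsets). Irregular spacing matters: a fixed grid would give unrelated
# heme-dense proteins a shared C..CH lattice that aligns at spuriously high
# identity. Stars-and-bars: sorted draws with replacement shifted by 5.
spaced_motif_starts <- function(L, k) {
  max_x <- L - 4L - 5L * (k - 1L)
  if (max_x < 1L) abort("sizing error: sequence too short for planted motif count.")
  x <- sort(sample.int(max_x, k, replace = TRUE))
  x + 5L * (seq_len(k) - 1L)
}

# fast motif planting for C/H-free backgrounds: with spacing >= 5 and no
# background C/H, no spurious motif is possible (still verified globally)
plant_motifs_fast <- function(sequence, k) {
  if (k == 0L) return(sequence)
  p <- spaced_motif_starts(nchar(sequence), k)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[p] <- "C"
  chars[p + 3L] <- "C"
  chars[p + 4L] <- "H"
  paste(chars, collapse = "")
}

# family member via the variable-sites construction: a fixed fraction of
# non-motif columns is redrawn iid per member, giving pairwise identity
# concentrated at `identity` between any two members
family_variable_sites <- function(proto, identity) {
  L <- nchar(proto)
  protected <- unique(as.integer(outer(find_heme_motifs(proto) + 1L, 0:4, `+`)))
  avail <- setdiff(seq_len(L), protected)
  n_var <- min(length(avail), round(L * (1 - identity / 100) * 18 / 17))
  sort(sample(avail, n_var))
}

draw_member <- function(proto_chars, var_sites) {
  proto_chars[var_sites] <- sample(AA_BG, length(var_sites), replace = TRUE)
  paste(proto_chars, collapse = "")
}

# uniform integer draw on [lo, hi] that is safe for degenerate ranges
# (sample(45:45, ...) would sample from 1:45)
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

# right-skewed heme count draw on [lo, hi]
draw_heme_counts <- function(n, lo, hi, mean) {
  rate <- 1 / max(mean - lo, 1)
  as.integer(pmin(hi, lo + floor(stats::rexp(n, rate = rate))))
}

#' Generate a seeded synthetic genome set with planted ground truth
#'
#' Emits a multi-genome protein set (with gene coordinates) in which every
#' downstream quantity is known by construction: per-protein heme counts,
#' per-genome MHC repertoires, orthologous family membership at a controlled
#' amino-acid identity, collocated oxidoreductase-like gene clusters matching
#' the built-in signatures, and motif-poor decoys. Backgrounds are drawn over
#' the 20 canonical amino acids with C and H excluded outside planted motifs,
#' so realised motif counts equal the planted truth exactly; a global
#' verification scan enforces this before returning.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, all outputs are also written to
#'   disk via [write_genome_set()].
#' @return An object of class `genome_set`: `proteins` (protein records with
#'   coordinates and labels), `truth` (`proteins`, `genomes`, `clusters`
#'   tibbles), `prototypes` (family prototype sequences) and `config`.
#' @export
generate_genome_set <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  gs <- withr::with_seed(config$seed, generate_genome_set_impl(config))
  if (!is.null(dir)) write_genome_set(gs, dir)
  gs
}

generate_genome_set_impl <- function(cfg) {
  empty <- function() {
    structure(list(
      proteins = tibble(protein_id = character(), genome_id = character(),
                        scaffold_id = character(), start = integer(), end = integer(),
                        strand = character(), sequence = character(),
                        functional_label = character()),
      truth = list(
        proteins = tibble(protein_id = character(), genome_id = character(),
                          role = character(), family_id = character(),
                          heme_count = integer()),
        genomes = tibble(genome_id = character(), n_proteins = integer(),
                         n_mhc = integer(), max_hemes = integer(), total_hemes = integer()),
        clusters = tibble(genome_id = character(), scaffold_id = character(),
                          pattern = character(), gene_ids = character(),
                          first_index = integer(), last_index = integer())
      ),
      prototypes = tibble(family_id = character(), heme_count = integer(),
                          sequence = character()),
      config = cfg
    ), class = "genome_set")
  }
  if (cfg$n_genomes == 0L) return(empty())

  genomes <- sprintf("SYNG%02d", seq_len(cfg$n_genomes))
  plan <- cluster_component_plan()

  n_prot <- sample_range(cfg$proteins_per_genome[1], cfg$proteins_per_genome[2],
                         cfg$n_genomes)
  if (!is.null(cfg$family_presence)) {
    ord_counts <- cfg$family_presence  # n_families x n_genomes member counts
  } else {
    ord_counts <- NULL
  }

  if (is.null(cfg$mhc_fraction)) {
    n_mhc <- sample_range(cfg$mhc_per_genome[1], cfg$mhc_per_genome[2],
                          cfg$n_genomes)
  } else {
    n_mhc <- as.integer(round(cfg$mhc_fraction * n_prot))
  }

  # --- plan cluster instances ---------------------------------------------
  mhc_slots <- vapply(plan, function(p) sum(p$role == "mhc"), integer(1))
  if (identical(cfg$planted_clusters, "none")) {
    inst <- tibble(pattern = character(), genome_id = character())
  } else if (identical(cfg$planted_clusters, "auto")) {
    inst <- purrr::map(seq_len(cfg$n_genomes), function(g) {
      budget <- n_mhc[g]
      planted <- character(0)
      for (p in names(plan)) {
        if (budget >= mhc_slots[[p]]) {
          planted <- c(planted, p)
          budget <- budget - mhc_slots[[p]]
        }
      }
      tibble(pattern = planted, genome_id = genomes[g])
    }) |> list_rbind()
  } else {
    inst <- as_tibble(cfg$planted_clusters[c("pattern", "genome_id")])
    if (!all(inst$genome_id %in% genomes)) abort("planted_clusters references unknown genome ids.")
  }
  cluster_mhc_per_genome <- vapply(genomes, function(g) {
    sum(mhc_slots[inst$pattern[inst$genome_id == g]])
  }, integer(1))

  used_patterns <- unique(inst$pattern)
  cluster_fams <- if (length(used_patterns) > 0L) paste0("CF_", used_patterns) else character(0)
  n_ord_fam <- cfg$n_families - length(cluster_fams)
  if (is.null(ord_counts) && n_ord_fam < 1L) {
    abort("`n_families` too small: it must exceed the number of planted cluster patterns.")
  }
  if (!is.null(ord_counts)) n_ord_fam <- nrow(ord_counts)

  ord_mhc <- n_mhc - cluster_mhc_per_genome
  if (is.null(ord_counts) && any(ord_mhc < 0L)) {
    abort("sizing error: planted cluster MHCs exceed a genome's MHC budget.")
  }

  # --- family definitions --------------------------------------------------
  ord_fam_ids <- sprintf("OF%04d", seq_len(n_ord_fam))
  k_ord <- draw_heme_counts(n_ord_fam, cfg$heme_count_range[1],
                            cfg$heme_count_range[2], cfg$heme_count_mean)
  # the single largest MHC: force the final ordinary family to the range top
  giant_fam <- ord_fam_ids[n_ord_fam]
  k_ord[n_ord_fam] <- cfg$heme_count_range[2]

  k_cf <- setNames(integer(0), character(0))
  for (p in used_patterns) {
    k_cf[paste0("CF_", p)] <- if (any(!is.na(plan[[p]]$heme))) {
      as.integer(plan[[p]]$heme[!is.na(plan[[p]]$heme)][1])
    } else {
      as.integer(draw_heme_counts(1L, 4L, 12L, 7))
    }
  }

  fam_ids <- c(ord_fam_ids, names(k_cf))
  fam_k <- c(setNames(k_ord, ord_fam_ids), k_cf)

  proto_len <- vapply(fam_ids, function(f) {
    max(80L, 30L + 8L * fam_k[[f]] + sample(0:120, 1L))
  }, integer(1))
  proto_seq <- random_bg_sequences(proto_len)
  proto_seq <- vapply(seq_along(fam_ids), function(i) {
    plant_motifs_fast(proto_seq[i], fam_k[[i]])
  }, character(1))
  names(proto_seq) <- fam_ids
  var_sites <- lapply(proto_seq, family_variable_sites, identity = cfg$family_identity)
  proto_chars <- lapply(proto_seq, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  prototypes <- tibble(family_id = fam_ids,
                       heme_count = as.integer(fam_k[fam_ids]),
                       sequence = unname(proto_seq[fam_ids]))

  # --- per-genome ordinary family membership -------------------------------
  if (is.null(ord_counts)) {
    pool <- if (n_ord_fam > 1L) ord_fam_ids[-n_ord_fam] else ord_fam_ids
    # Zipf-like family-size weights: ortholog family sizes are heavy-tailed,
    # with a minority of widespread families and many sporadic ones
    w <- sample(seq_along(pool))^-0.7
    giant_genome <- if (ord_mhc[cfg$n_genomes] >= 1L) cfg$n_genomes else which.max(ord_mhc)
    has_giant <- ord_mhc[giant_genome] >= 1L && n_ord_fam > 1L
    # fixed per-genome slot counts; each family seeds one random slot so every
    # configured family is realised, the rest fill by weighted draw
    slot_genome <- rep(seq_len(cfg$n_genomes),
                       times = ord_mhc - (has_giant & seq_len(cfg$n_genomes) == giant_genome))
    n_slots <- length(slot_genome)
    fams_for_slots <- character(n_slots)
    n_seed <- min(n_slots, length(pool))
    if (n_seed > 0L) {
      seed_at <- sample.int(n_slots, n_seed)
      fams_for_slots[seed_at] <- pool[seq_len(n_seed)]
    }
    open <- which(fams_for_slots == "")
    if (length(open) > 0L) {
      fams_for_slots[open] <- sample(pool, length(open), replace = TRUE, prob = w)
    }
    membership <- lapply(seq_len(cfg$n_genomes), function(g) {
      fams <- fams_for_slots[slot_genome == g]
      if (g == giant_genome && has_giant) {
        fams <- c(giant_fam, fams)  # the single largest MHC, planted exactly once
      }
      fams
    })
  } else {
    membership <- lapply(seq_len(cfg$n_genomes), function(g) {
      rep(ord_fam_ids, times = ord_counts[, g])
    })
    ord_mhc <- vapply(membership, length, integer(1))
    n_mhc <- ord_mhc + cluster_mhc_per_genome
  }

  # --- assemble each genome ------------------------------------------------
  all_prot <- vector("list", cfg$n_genomes)
  all_truth <- vector("list", cfg$n_genomes)
  all_clust <- vector("list", cfg$n_genomes)

  for (g in seq_len(cfg$n_genomes)) {
    gid <- genomes[g]
    inst_g <- inst[inst$genome_id == gid, , drop = FALSE]

    # ordinary family members
    fams_g <- membership[[g]]
    memb_seq <- vapply(fams_g, function(f) draw_member(proto_chars[[f]], var_sites[[f]]), character(1))
    memb <- tibble(sequence = unname(memb_seq), functional_label = NA_character_,
                   role = "ordinary_mhc", family_id = unname(fams_g),
                   heme_count = as.integer(fam_k[fams_g]))

    # cluster blocks (each a contiguous run of component genes)
    blocks <- purrr::pmap(inst_g, function(pattern, genome_id) {
      comp <- plan[[pattern]]
      purrr::pmap(comp, function(role, heme) {
        if (role == "mhc") {
          f <- paste0("CF_", pattern)
          tibble(sequence = draw_member(proto_chars[[f]], var_sites[[f]]),
                 functional_label = NA_character_, role = "cluster_mhc",
                 family_id = f, heme_count = as.integer(fam_k[[f]]))
        } else {
          tibble(sequence = plant_motifs_fast(random_bg_sequences(sample(150:400, 1L)), 0L),
                 functional_label = role, role = "cluster_component",
                 family_id = NA_character_, heme_count = 0L)
        }
      }) |> list_rbind()
    })

    n_comp_genes <- sum(vapply(blocks, nrow, integer(1)))
    n_decoy <- n_prot[g] - nrow(memb) - n_comp_genes
    if (n_decoy < 0L) {
      abort(sprintf("sizing error: genome %s needs %d planted genes but only %d proteins.",
                    gid, nrow(memb) + n_comp_genes, n_prot[g]))
    }
    decoy_len <- sample_range(cfg$protein_length_range[1],
                              cfg$protein_length_range[2], n_decoy)
    decoy_seq <- random_bg_sequences(decoy_len)
    decoy_k <- integer(n_decoy)
    if (cfg$decoy_motif_max > 0L && n_decoy > 0L) {
      n_dm <- round(cfg$decoy_motif_fraction * n_decoy)
      if (n_dm > 0L) {
        which_dm <- sample.int(n_decoy, n_dm)
        decoy_k[which_dm] <- sample_range(1L, cfg$decoy_motif_max, n_dm)
        for (i in which_dm) decoy_seq[i] <- plant_motifs_fast(decoy_seq[i], decoy_k[i])
      }
    }
    decoys <- tibble(sequence = decoy_seq, functional_label = NA_character_,
                     role = ifelse(decoy_k > 0L, "decoy_motif", "decoy"),
                     family_id = NA_character_, heme_count = decoy_k)

    # background order, then insert cluster blocks with >= 4 genes between
    bg <- bind_rows(memb, decoys)
    bg <- bg[sample.int(nrow(bg)), , drop = FALSE]
    n_bg <- nrow(bg)
    n_blocks <- length(blocks)
    if (n_blocks > 0L) {
      if (n_bg >= 6L * n_blocks + 4L) {
        repeat {
          at <- sort(sample(2:(n_bg - 2L), n_blocks))
          if (n_blocks == 1L || all(diff(at) >= 5L)) break
        }
      } else {
        at <- floor(seq(1L, max(n_bg - 1L, 1L), length.out = n_blocks + 2L))[2:(n_blocks + 1L)]
      }
      pieces <- list()
      prev <- 0L
      block_rows <- integer(0)
      for (b in seq_len(n_blocks)) {
        pieces <- c(pieces, list(bg[(prev + 1L):at[b], , drop = FALSE]), list(blocks[[b]]))
        prev <- at[b]
      }
      pieces <- c(pieces, list(bg[(prev + 1L):n_bg, , drop = FALSE]))
      genes <- list_rbind(pieces)
      # recover block row positions
      prev <- 0L
      tag <- rep(0L, nrow(genes))
      pos <- 1L
      for (b in seq_len(n_blocks)) {
        seg <- at[b] - prev
        pos <- pos + seg
        tag[pos:(pos + nrow(blocks[[b]]) - 1L)] <- b
        pos <- pos + nrow(blocks[[b]])
        prev <- at[b]
      }
      genes$block <- tag
    } else {
      genes <- bg
      genes$block <- 0L
    }

    # split into two scaffolds at a non-block boundary near the middle
    n_genes <- nrow(genes)
    brk <- max(1L, n_genes %/% 2L)
    while (brk > 1L && brk < n_genes &&
           genes$block[brk] != 0L && genes$block[brk] == genes$block[brk + 1L]) {
      brk <- brk + 1L
    }
    scaffold <- c(rep("scf1", brk), rep("scf2", n_genes - brk))

    # coordinates: left-to-right, 1-based, 50 bp gaps, alternating strand
    aa_len <- nchar(genes$sequence)
    nt_len <- 3L * (aa_len + 1L)
    genes$scaffold_id <- scaffold
    genes$gene_index <- seq_len(n_genes)
    # per-scaffold position, matching order_genes() numbering downstream
    genes$scaffold_order <- as.integer(ave(genes$gene_index, genes$scaffold_id,
                                           FUN = seq_along))
    starts <- integer(n_genes)
    for (s in unique(scaffold)) {
      i <- which(scaffold == s)
      starts[i] <- cumsum(c(1L, head(nt_len[i] + 50L, -1L)))
    }
    genes$start <- starts
    genes$end <- starts + nt_len - 1L
    genes$strand <- rep_len(c("+", "-"), n_genes)
    genes$genome_id <- gid
    genes$protein_id <- paste(gid, genes$scaffold_id, genes$gene_index, sep = "|")

    all_prot[[g]] <- genes |>
      select("protein_id", "genome_id", "scaffold_id", "start", "end",
             "strand", "sequence", "functional_label")
    all_truth[[g]] <- genes |>
      select("protein_id", "genome_id", "role", "family_id", "heme_count")
    if (n_blocks > 0L) {
      all_clust[[g]] <- genes |>
        filter(.data$block > 0L) |>
        group_by(block = .data$block) |>
        summarise(genome_id = gid,
                  scaffold_id = .data$scaffold_id[1],
                  gene_ids = paste(.data$protein_id, collapse = ";"),
                  first_index = min(.data$scaffold_order),
                  last_index = max(.data$scaffold_order),
                  .groups = "drop") |>
        mutate(pattern = inst_g$pattern[.data$block]) |>
        select("genome_id", "scaffold_id", "pattern", "gene_ids",
               "first_index", "last_index")
    }
  }

  proteins <- list_rbind(all_prot)
  truth_proteins <- list_rbind(all_truth)
  truth_clusters <- if (length(purrr::compact(all_clust)) > 0L) {
    list_rbind(purrr::compact(all_clust))
  } else {
    tibble(genome_id = character(), scaffold_id = character(), pattern = character(),
           gene_ids = character(), first_index = integer(), last_index = integer())
  }

  # --- planted-truth verification scan ------------------------------------
  for (attempt in 1:5) {
    realised <- count_heme_motifs(proteins$sequence)
    bad <- which(realised != truth_proteins$heme_count)
    if (length(bad) == 0L) break
    for (i in bad) {  # regenerate the offending sequence in place
      L <- nchar(proteins$sequence[i])
      s <- random_bg_sequences(L)
      proteins$sequence[i] <- plant_motifs_fast(s, truth_proteins$heme_count[i])
    }
  }
  realised <- count_heme_motifs(proteins$sequence)
  if (!identical(realised, truth_proteins$heme_count)) {
    abort("internal error: synthetic truth verification failed after regeneration.")
  }

  truth_genomes <- truth_proteins |>
    group_by(genome_id = .data$genome_id) |>
    summarise(n_proteins = n(),
              n_mhc = sum(.data$heme_count >= 3L),
              max_hemes = max(c(0L, .data$heme_count[.data$heme_count >= 3L])),
              total_hemes = sum(.data$heme_count[.data$heme_count >= 3L]),
              .groups = "drop") |>
    arrange(match(.data$genome_id, genomes))

  structure(list(
    proteins = proteins,
    truth = list(proteins = truth_proteins, genomes = truth_genomes,
                 clusters = truth_clusters),
    prototypes = prototypes,
    config = cfg
  ), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %d genome(s), %d proteins, %d planted MHCs in %d families, %d planted clusters (seed %d)\n",
              x$config$n_genomes, nrow(x$proteins),
              sum(x$truth$proteins$heme_count >= 3L),
              length(unique(stats::na.omit(x$truth$proteins$family_id))),
              nrow(x$truth$clusters), x$config$seed))
  invisible(x)
}

#' Extract the functional-label table of a genome set
#'
#' @param gs A `genome_set`.
#' @return Tibble (`protein_id`, `genome_id`, `label`) for labelled genes.
#' @export
genome_set_labels <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  gs$proteins |>
    filter(!is.na(.data$functional_label)) |>
    select("protein_id", "genome_id", label = "functional_label")
}

#' Write a genome set to disk
#'
#' Writes one protein FASTA and one GFF3 file per genome (headers and `ID`
#' attributes use the `<genome>|<scaffold>|<gene_index>` convention), the
#' planted-truth tables as TSV, the label table, and a JSON manifest carrying
#' the full configuration and seed. Outputs are byte-identical for a fixed
#' seed.
#'
#' @param gs A `genome_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(gs, dir) {
  stopifnot(inherits(gs, "genome_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gid in unique(gs$proteins$genome_id)) {
    p <- gs$proteins[gs$proteins$genome_id == gid, , drop = FALSE]
    aa <- Biostrings::AAStringSet(setNames(p$sequence, p$protein_id))
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(gid, ".faa")))
    write_gene_gff(p, file.path(dir, paste0(gid, ".gff3")))
  }
  readr::write_tsv(gs$truth$proteins, file.path(dir, "truth_proteins.tsv"))
  readr::write_tsv(gs$truth$genomes, file.path(dir, "truth_genomes.tsv"))
  readr::write_tsv(gs$truth$clusters, file.path(dir, "truth_clusters.tsv"))
  readr::write_tsv(genome_set_labels(gs), file.path(dir, "labels.tsv"))
  cfg <- unclass(gs$config)
  cfg$family_presence <- if (is.null(cfg$family_presence)) NULL else as.data.frame(cfg$family_presence)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Derive a synthetic reference MHC panel from a genome set
#'
#' Builds a small cross-taxon reference panel for homology-network tests:
#' `n_related` sequences derived from planted family prototypes at a
#' controlled percent identity (so network edges to the query MHCs are
#' expected), one pair of mutually homologous reference-only sequences (a
#' reference-only network component), and `n_unrelated` independent MHC-like
#' sequences. Taxonomy strings are synthetic lineage labels.
#'
#' @param gs A `genome_set` with at least `n_related` planted families.
#' @param n_related Number of prototype-derived reference sequences.
#' @param n_unrelated Number of unrelated reference sequences.
#' @param identity Percent identity of related references to their prototype.
#' @param seed Integer seed.
#' @return Tibble (`protein_id`, `taxonomy`, `sequence`, `heme_count`).
#' @export
make_reference_panel <- function(gs, n_related = 10L, n_unrelated = 8L,
                                 identity = 60, seed = gs$config$seed + 1000L) {
  stopifnot(inherits(gs, "genome_set"))
  proto <- gs$prototypes
  if (nrow(proto) < n_related) abort("fewer planted families than `n_related`.")
  # motif positions are conserved, so low target identities are only
  # reachable for motif-sparse prototypes; prefer those
  mutable <- 1 - 5 * proto$heme_count / nchar(proto$sequence)
  proto <- proto[order(-mutable, proto$family_id), , drop = FALSE]
  lineages <- c("d__Bacteria;f__Ref_lineage_A", "d__Bacteria;f__Ref_lineage_B",
                "d__Archaea;f__Ref_lineage_C", "d__Bacteria;f__Ref_lineage_D")
  withr::with_seed(as.integer(seed), {
    rel <- purrr::map(seq_len(n_related), function(i) {
      chars <- strsplit(proto$sequence[i], "", fixed = TRUE)[[1]]
      vs <- family_variable_sites(proto$sequence[i], identity)
      tibble(protein_id = sprintf("REF|related|%03d", i),
             taxonomy = lineages[(i - 1L) %% length(lineages) + 1L],
             sequence = draw_member(chars, vs),
             heme_count = proto$heme_count[i])
    }) |> list_rbind()

    # a reference-only homologous pair (prunable component)
    pk <- 5L
    pL <- 200L
    pproto <- plant_motifs_fast(random_bg_sequences(pL), pk)
    pvs <- family_variable_sites(pproto, 85)
    pchars <- strsplit(pproto, "", fixed = TRUE)[[1]]
    pair <- tibble(protein_id = sprintf("REF|pair|%03d", 1:2),
                   taxonomy = lineages[1:2],
                   sequence = c(draw_member(pchars, pvs), draw_member(pchars, pvs)),
                   heme_count = pk)

    unrel_len <- sample(120:400, n_unrelated, replace = TRUE)
    unrel_k <- sample(3:10, n_unrelated, replace = TRUE)
    unrel_seq <- random_bg_sequences(unrel_len)
    unrel_seq <- vapply(seq_len(n_unrelated), function(i) {
      plant_motifs_fast(unrel_seq[i], unrel_k[i])
    }, character(1))
    unrel <- tibble(protein_id = sprintf("REF|unrelated|%03d", seq_len(n_unrelated)),
                    taxonomy = lineages[(seq_len(n_unrelated) - 1L) %% length(lineages) + 1L],
                    sequence = unrel_seq,
                    heme_count = unrel_k)
    bind_rows(rel, pair, unrel)
  })
}
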