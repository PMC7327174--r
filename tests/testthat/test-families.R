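make_hits <- function(...) {
  rows <- list(...)
  base <- multiheme:::empty_hits()
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(query_id = r[[1]], subject_id = r[[2]],
                   pident = as.numeric(r[[3]]), evalue = as.numeric(r[[4]]),
                   bitscore = as.numeric(r[[5]]),
                   length = 100L, mismatches = 0L, gapopen = 0L,
                   qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                   raw_score = 100, query_genome = NA_character_,
                   subject_genome = NA_character_)
  }))
  dplyr::bind_rows(base, out)
}

test_that("homology graph requires reciprocal threshold-passing hits", {
  # mutual strong hits -> edge
  h <- make_hits(list("a", "b", 80, 1e-30, 120), list("b", "a", 80, 1e-30, 120))
  g <- build_homology_graph(h, max_evalue = 1e-20, min_identity = 50)
  expect_identical(igraph::ecount(g), 1)
  # one-directional hit only -> no edge
  h1 <- make_hits(list("a", "b", 80, 1e-30, 120))
  g1 <- build_homology_graph(h1, max_evalue = 1e-20, min_identity = 50)
  expect_identical(igraph::ecount(g1), 0)
  # one direction failing a threshold -> no edge
  h2 <- make_hits(list("a", "b", 80, 1e-30, 120), list("b", "a", 45, 1e-30, 120))
  expect_identical(igraph::ecount(build_homology_graph(h2, 1e-20, 50)), 0)
  h3 <- make_hits(list("a", "b", 80, 1e-10, 120), list("b", "a", 80, 1e-30, 120))
  expect_identical(igraph::ecount(build_homology_graph(h3, 1e-20, 50)), 0)
  # no hits at all -> isolated nodes only
  g0 <- build_homology_graph(multiheme:::empty_hits(), nodes = c("x", "y", "z"))
  expect_identical(igraph::vcount(g0), 3)
  expect_identical(igraph::ecount(g0), 0)
})

test_that("edgeless graphs give singletons and cliques give one family", {
  g0 <- build_homology_graph(multiheme:::empty_hits(), nodes = paste0("p", 1:5))
  fam0 <- cluster_families(g0, genomes = setNames(rep("g", 5), paste0("p", 1:5)))
  expect_identical(fam0$n_families, 5L)
  expect_true(all(table(fam0$families$family_id) == 1))

  ids <- paste0("q", 1:5)
  pairs <- t(utils::combn(ids, 2))
  h <- do.call(make_hits, c(
    lapply(seq_len(nrow(pairs)), function(i) list(pairs[i, 1], pairs[i, 2], 90, 1e-40, 150)),
    lapply(seq_len(nrow(pairs)), function(i) list(pairs[i, 2], pairs[i, 1], 90, 1e-40, 150))
  ))
  g <- build_homology_graph(h)
  fam <- cluster_families(g, genomes = setNames(rep("g", 5), ids))
  expect_identical(fam$n_families, 1L)
  expect_identical(nrow(fam$families), 5L)
})

test_that("unknown clustering method is a configuration error", {
  g <- build_homology_graph(multiheme:::empty_hits(), nodes = "p1")
  expect_error(cluster_families(g, method = "louvain"), "unknown clustering method")
})

test_that("mcl clustering is deterministic and splits weakly joined cliques", {
  # two 4-cliques joined by a single bridge edge
  ids <- c(paste0("a", 1:4), paste0("b", 1:4))
  cl <- function(v) t(utils::combn(v, 2))
  edges <- rbind(cl(ids[1:4]), cl(ids[5:8]), c("a1", "b1"))
  h <- do.call(make_hits, c(
    lapply(seq_len(nrow(edges)), function(i) list(edges[i, 1], edges[i, 2], 90, 1e-40, 150)),
    lapply(seq_len(nrow(edges)), function(i) list(edges[i, 2], edges[i, 1], 90, 1e-40, 150))
  ))
  g <- build_homology_graph(h)
  gen <- setNames(rep("g", 8), ids)
  fam_comp <- cluster_families(g, "components", genomes = gen)
  expect_identical(fam_comp$n_families, 1L)  # bridge merges the components
  fam_mcl <- cluster_families(g, "mcl", genomes = gen)
  expect_identical(fam_mcl$n_families, 2L)   # flow clustering cuts the bridge
  # determinism
  fam_mcl2 <- cluster_families(g, "mcl", genomes = gen)
  expect_identical(fam_mcl$families, fam_mcl2$families)
})

test_that("planted families are recovered exactly at >=70%/<=30% separation", {
  for (seed in 1:2) {
    gs <- generate_genome_set(small_config(seed = seed, n_families = 20L,
                                           family_identity = 75,
                                           mhc_per_genome = c(15L, 25L),
                                           planted_clusters = "none"))
    run <- run_pipeline(gs$proteins)
    truth <- gs$truth$proteins
    fam <- run$families$families
    tf <- truth$family_id[match(fam$protein_id, truth$protein_id)]
    expect_equal(ari(tf, fam$family_id), 1.0, info = paste("seed", seed))
  }
})

test_that("families partition the MHC set and matrix margins agree", {
  gs <- generate_genome_set(small_config(seed = 4))
  run <- run_pipeline(gs$proteins)
  fam <- run$families$families
  scan <- run$scan
  mhc_ids <- scan$annotations$protein_id[scan$annotations$is_mhc]
  # partition property
  expect_setequal(fam$protein_id, mhc_ids)
  expect_false(any(duplicated(fam$protein_id)))
  # column sums = family sizes; row sums = per-genome MHC counts
  m <- run$abundance
  counts <- as.matrix(m[, -1])
  expect_identical(as.integer(colSums(counts)[sort(unique(fam$family_id))]),
                   unname(vapply(split(fam$protein_id, fam$family_id), length, integer(1))))
  expect_identical(unname(rowSums(counts)),
                   as.numeric(scan$stats$n_mhc[match(m$genome_id, scan$stats$genome_id)]))
})

test_that("abundance matrix keeps all-zero rows and flags unknown genomes", {
  fam <- tibble::tibble(family_id = c("F1", "F1", "F2"),
                        protein_id = c("p1", "p2", "p3"),
                        genome_id = c("gA", "gB", "gA"))
  m <- abundance_matrix(fam, genomes = c("gA", "gB", "gC"))
  expect_identical(m$genome_id, c("gA", "gB", "gC"))
  expect_identical(unname(unlist(m[m$genome_id == "gC", -1])), c(0L, 0L))
  expect_identical(unname(unlist(m[m$genome_id == "gA", -1])), c(1L, 1L))
  expect_error(abundance_matrix(fam, genomes = c("gA")), "unknown genome")
  # single genome, three singleton families -> 1 x 3 matrix of ones
  fam1 <- tibble::tibble(family_id = c("F1", "F2", "F3"),
                         protein_id = c("p1", "p2", "p3"),
                         genome_id = "gA")
  m1 <- abundance_matrix(fam1)
  expect_identical(unname(unlist(m1[1, -1])), c(1L, 1L, 1L))
})

test_that("conservation summary counts >=k and core families correctly", {
  m <- tibble::tibble(genome_id = c("g1", "g2", "g3"),
                      F1 = c(1L, 2L, 1L),   # in all three (core)
                      F2 = c(1L, 1L, 0L),   # in two
                      F3 = c(0L, 0L, 3L))   # in one
  expect_identical(conservation_summary(m, 1)$n_families_in_ge_k, 3L)
  expect_identical(conservation_summary(m, 2)$n_families_in_ge_k, 2L)
  expect_identical(conservation_summary(m, 3)$n_families_in_ge_k, 1L)
  expect_identical(conservation_summary(m, 2)$n_core_families, 1L)
  expect_error(conservation_summary(m, 0), "must lie in")
  expect_error(conservation_summary(m, 4), "must lie in")
  # single-genome matrix: every family is core at k = 1
  m1 <- tibble::tibble(genome_id = "g1", F1 = 1L, F2 = 2L)
  s1 <- conservation_summary(m1, 1)
  expect_identical(s1$n_families_in_ge_k, 2L)
  expect_identical(s1$n_core_families, 2L)
  prof <- conservation_profile(m)
  expect_identical(nrow(prof), 3L)
  expect_true(all(diff(prof$n_families_in_ge_k) <= 0))
})

test_that("tightening thresholds never merges families", {
  gs <- generate_genome_set(small_config(seed = 12))
  run <- run_pipeline(gs$proteins)
  hits <- run$hits
  mhc_ids <- run$families$families$protein_id
  lens <- setNames(nchar(gs$proteins$sequence), gs$proteins$protein_id)
  part <- function(max_e, min_id) {
    g <- build_homology_graph(hits, max_evalue = max_e, min_identity = min_id,
                              seq_lengths = lens, nodes = mhc_ids)
    f <- cluster_families(g)$families
    setNames(f$family_id, f$protein_id)[mhc_ids]
  }
  loose <- part(1e-3, 50)
  for (tight in list(part(1e-10, 50), part(1e-3, 70), part(1e-20, 80))) {
    # every tight family must sit inside one loose family (refinement)
    crossing <- tapply(loose, tight, function(x) length(unique(x)))
    expect_true(all(crossing == 1))
  }
})
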