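test_that("plant_motifs yields the exact requested motif count", {
  withr::with_seed(21, {
    # nothing planted: existing motifs are scrubbed too
    s0 <- plant_motifs(random_aa(120), 0, seed = 4)
    expect_identical(find_heme_motifs(s0), integer(0))
    # C/H-free 200-mer, 3 motifs, verified by exhaustive enumeration
    s3 <- plant_motifs(random_bg(200), 3, seed = 1)
    expect_length(brute_motif_offsets(s3), 3)
    expect_identical(nchar(s3), 200L)
    # the largest observed MHC scale: 113 motifs on a 600-mer
    s113 <- plant_motifs(random_bg(600), 113, seed = 7)
    expect_length(brute_motif_offsets(s113), 113)
    expect_identical(nchar(s113), 600L)
    # arbitrary (C/H-containing) backgrounds still come out exact
    for (k in c(1, 5, 9)) {
      s <- plant_motifs(random_aa(150), k, seed = k)
      expect_length(brute_motif_offsets(s), k)
    }
  })
})

test_that("plant_motifs rejects sequences too short for k motifs", {
  expect_error(plant_motifs(strrep("A", 24), 5, seed = 1), "too short")
  expect_silent(s <- plant_motifs(strrep("A", 25), 5, seed = 1))
  expect_length(find_heme_motifs(s), 5)
})

test_that("mutate_to_identity hits the target and preserves motifs", {
  withr::with_seed(31, {
    base <- plant_motifs(random_bg(100), 4, seed = 2)
    # identity case
    expect_identical(mutate_to_identity(base, 100, seed = 1), base)
    # 80% target on length 100: exactly 80 identical positions
    m80 <- mutate_to_identity(base, 80, seed = 3)
    expect_true(abs(positional_identity(base, m80) - 80) <= 2)
    # motifs survive any mutation load
    m60 <- mutate_to_identity(base, 60, seed = 5)
    expect_length(find_heme_motifs(m60), 4)
    expect_identical(find_heme_motifs(m60), find_heme_motifs(base))
    expect_error(mutate_to_identity(base, 0, seed = 1), "percent")
    expect_error(mutate_to_identity(base, 101, seed = 1), "percent")
  })
})

test_that("generator is deterministic: identical seeds give byte-identical files", {
  cfg <- small_config(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_genome_set(cfg, dir = d1)
  generate_genome_set(cfg, dir = d2)
  files <- list.files(d1)
  expect_gt(length(files), 4)
  expect_identical(sort(files), sort(list.files(d2)))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("scanning emitted proteomes recovers the planted truth exactly", {
  gs <- generate_genome_set(small_config(seed = 2))
  scan <- scan_proteome(gs$proteins)
  # per-protein heme counts match the truth table one-for-one
  truth <- gs$truth$proteins
  ann <- scan$annotations
  expect_identical(ann$heme_count[match(truth$protein_id, ann$protein_id)],
                   as.integer(truth$heme_count))
  # per-genome aggregates
  expect_identical(scan$stats$n_mhc, as.integer(gs$truth$genomes$n_mhc))
  expect_identical(scan$stats$max_hemes, as.integer(gs$truth$genomes$max_hemes))
  expect_identical(scan$stats$n_proteins, as.integer(gs$truth$genomes$n_proteins))
})

test_that("planted family members sit near the configured identity", {
  gs <- generate_genome_set(small_config(seed = 8, n_families = 8,
                                         family_identity = 75))
  fam_members <- gs$truth$proteins |>
    dplyr::filter(!is.na(family_id)) |>
    dplyr::left_join(gs$proteins[, c("protein_id", "sequence")], by = "protein_id")
  picked <- fam_members |>
    dplyr::group_by(family_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::slice(1:2) |>
    dplyr::ungroup()
  fams <- split(picked$sequence, picked$family_id)
  ids <- vapply(fams, function(ss) {
    if (length(ss) < 2) return(NA_real_)
    positional_identity(ss[1], ss[2])
  }, numeric(1))
  ids <- ids[!is.na(ids)]
  expect_gt(length(ids), 3)
  expect_true(all(abs(ids - 75) <= 3),
              info = paste(round(ids, 1), collapse = ", "))
})

test_that("empty and infeasible configurations are handled", {
  gs0 <- generate_genome_set(synthetic_config(n_genomes = 0))
  expect_identical(nrow(gs0$proteins), 0L)
  expect_identical(nrow(gs0$truth$genomes), 0L)
  # more planted genes than proteins
  expect_error(
    generate_genome_set(synthetic_config(
      n_genomes = 2, proteins_per_genome = c(10L, 10L),
      mhc_per_genome = c(10L, 10L), n_families = 7L, seed = 1)),
    "sizing")
  expect_error(synthetic_config(decoy_motif_max = 3), "sub-threshold")
  expect_error(synthetic_config(heme_count_range = c(2, 10)), "minimum >= 3")
  expect_error(synthetic_config(mhc_fraction = 1.5), "\\[0, 1\\]")
})

test_that("explicit family presence vectors are honoured exactly", {
  pres <- matrix(c(1L, 0L, 1L,
                   0L, 2L, 1L,
                   1L, 1L, 0L), nrow = 3, byrow = TRUE)
  cfg <- synthetic_config(n_genomes = 3, proteins_per_genome = c(60L, 60L),
                          family_presence = pres, planted_clusters = "none",
                          family_identity = 80, seed = 4)
  gs <- generate_genome_set(cfg)
  got <- gs$truth$proteins |>
    dplyr::filter(!is.na(family_id)) |>
    dplyr::count(family_id, genome_id) |>
    tidyr::pivot_wider(names_from = genome_id, values_from = n,
                       values_fill = 0L)
  m <- as.matrix(got[order(got$family_id), sort(unique(gs$proteins$genome_id))])
  expect_identical(unname(m), unname(pres))
})

test_that("decoys stay below the MHC threshold", {
  gs <- generate_genome_set(small_config(seed = 6))
  decoys <- gs$truth$proteins[grepl("decoy", gs$truth$proteins$role), ]
  expect_true(all(decoys$heme_count <= 2))
  expect_true(any(decoys$heme_count > 0))  # some decoys do carry 1-2 motifs
})

test_that("written outputs round-trip through the package readers", {
  d <- withr::local_tempdir()
  gs <- generate_genome_set(small_config(seed = 9), dir = d)
  faa <- list.files(d, pattern = "\\.faa$", full.names = TRUE)
  expect_length(faa, 4)
  prot <- read_proteome_fasta(faa)
  expect_identical(nrow(prot), nrow(gs$proteins))
  merged <- dplyr::inner_join(prot, gs$proteins[, c("protein_id", "sequence")],
                              by = "protein_id", suffix = c("", ".orig"))
  expect_identical(merged$sequence, merged$sequence.orig)
  gff <- list.files(d, pattern = "\\.gff3$", full.names = TRUE)[1]
  genes <- read_gene_gff(gff)
  gid <- genes$genome_id[1]
  orig <- gs$proteins[gs$proteins$genome_id == sub("\\..*", "", basename(gff)), ]
  expect_identical(nrow(genes), nrow(orig))
  m2 <- dplyr::inner_join(genes |> dplyr::select(-genome_id), orig,
                          by = "protein_id", suffix = c("", ".orig"))
  expect_identical(m2$start, m2$start.orig)
  expect_identical(m2$end, m2$end.orig)
  expect_identical(m2$strand, m2$strand.orig)
})

test_that("gene layout is ordered, non-overlapping, with 50 bp gaps", {
  gs <- generate_genome_set(small_config(seed = 10))
  by_scaffold <- split(gs$proteins, paste(gs$proteins$genome_id,
                                          gs$proteins$scaffold_id))
  for (sc in by_scaffold) {
    sc <- sc[order(sc$start), ]
    expect_true(all(sc$start <= sc$end))
    if (nrow(sc) > 1) {
      expect_true(all(diff(sc$start) > 0))
      expect_identical(unique(sc$start[-1] - sc$end[-nrow(sc)]), 51L)
    }
  }
})
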