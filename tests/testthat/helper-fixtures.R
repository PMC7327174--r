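# Shared small synthetic study configurations. Sizes are chosen so the whole
# suite runs in minutes on one core while still exercising every stage.

small_config <- function(seed = 1L, ...) {
  args <- list(
    n_genomes = 4L, proteins_per_genome = c(120L, 160L),
    mhc_per_genome = c(8L, 20L), n_families = 12L,
    family_identity = 80, protein_length_range = c(100L, 300L),
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# ortholog-rich proteomes for AAI runs: every family planted in both
# genomes (so each protein has a true ortholog) plus a handful of decoys
aai_config <- function(seed = 1L, identity = 75, n_fam = 18L) {
  synthetic_config(
    n_genomes = 2L, proteins_per_genome = c(26L, 26L),
    family_presence = matrix(1L, nrow = n_fam, ncol = 2L),
    family_identity = identity, planted_clusters = "none",
    protein_length_range = c(100L, 250L), seed = seed
  )
}

empty_hits_tbl <- function() multiheme:::empty_hits()

# a tiny hand-rolled proteome table
toy_proteins <- function() {
  tibble::tibble(
    protein_id = c("gA|s1|1", "gA|s1|2", "gA|s1|3", "gB|s1|1"),
    genome_id = c("gA", "gA", "gA", "gB"),
    sequence = c(
      strrep("CAACHLMKTV", 3),            # 3 motifs
      paste0("MKLV", strrep("A", 40)),     # none
      paste0(strrep("CAACH", 2), strrep("L", 30)),  # 2 motifs (sub-threshold)
      strrep("CAACHLMKTV", 5)              # 5 motifs
    )
  )
}
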