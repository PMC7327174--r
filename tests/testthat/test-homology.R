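test_that("self-alignment gives 100% identity and symmetric scores", {
  withr::with_seed(41, {
    for (i in 1:10) {
      s <- random_aa(sample(20:80, 1))
      hit <- align_pair(s, s)
      expect_equal(hit$pident, 100)
      expect_identical(hit$mismatches, 0L)
    }
    # symmetry of score and identity
    a <- random_aa(60); b <- random_aa(70)
    ab <- align_pair(a, b); ba <- align_pair(b, a)
    expect_equal(ab$raw_score, ba$raw_score)
    expect_equal(ab$pident, ba$pident)
  })
})

test_that("two substitutions in ten residues give 80% identity", {
  a <- "ACDEFGHIKL"
  b <- "ACDEYGHIKV"  # substitutions at positions 5 and 10
  hit <- align_pair(a, b)
  expect_equal(hit$pident, 80)
  expect_identical(hit$length, 10L)
  expect_identical(hit$mismatches, 2L)
})

test_that("appending an identical block never decreases the raw score", {
  withr::with_seed(43, {
    for (i in 1:10) {
      a <- random_aa(40); b <- random_aa(40)
      block <- random_aa(20)
      s0 <- align_pair(a, b)$raw_score
      s1 <- align_pair(paste0(a, block), paste0(b, block))$raw_score
      expect_gte(s1, s0)
    }
  })
})

test_that("local alignment score matches an independent Gotoh oracle", {
  withr::with_seed(47, {
    for (i in 1:200) {
      a <- random_aa(sample(5:40, 1))
      b <- random_aa(sample(5:40, 1))
      expect_equal(align_pair(a, b)$raw_score,
                   gotoh_local_score(a, b),
                   info = paste(a, b))
    }
  })
})

test_that("E-value follows the closed form m * n * 2^-bits", {
  p <- alignment_params()
  # identity case: zero bits on a 1x1 space
  expect_equal(evalue(0, 1, 1), 1)
  # +10 bits shrinks E by exactly 2^10
  expect_equal(evalue(30, 50, 1000) / evalue(40, 50, 1000), 2^10)
  # direct formula on arbitrary triples
  withr::with_seed(3, {
    for (i in 1:20) {
      S <- runif(1, 10, 300); m <- sample(10:500, 1); n <- sample(100:1e5, 1)
      bits <- (p$lambda * S - log(p$K)) / log(2)
      expect_equal(evalue(bits, m, n), m * n * 2^(-bits))
    }
  })
  expect_error(evalue(10, 0, 5), ">= 1")
  # ordering preserved under positive scaling of m*n
  e1 <- evalue(c(50, 60, 70), 100, 1000)
  e2 <- evalue(c(50, 60, 70), 300, 3000)
  expect_identical(order(e1), order(e2))
})

test_that("search_all mirrors symmetric searches consistently", {
  withr::with_seed(51, {
    prot <- tibble::tibble(
      protein_id = paste0("p", 1:6),
      genome_id = rep(c("g1", "g2"), each = 3),
      sequence = replicate(6, random_aa(60))
    )
    sym <- search_all(prot, prot, symmetric = TRUE)
    # every ordered pair once, no self hits
    expect_identical(nrow(sym), 30L)
    key <- paste(sym$query_id, sym$subject_id)
    rev_key <- paste(sym$subject_id, sym$query_id)
    expect_true(all(rev_key %in% key))
    # mirrored raw scores agree
    sc <- setNames(sym$raw_score, key)
    expect_equal(unname(sc[key]), unname(sc[rev_key]))
  })
})

test_that("reciprocal best hits recover identity and planted orthologs", {
  expect_identical(nrow(reciprocal_best_hits(empty_hits_tbl(), empty_hits_tbl())), 0L)
  withr::with_seed(53, {
    # identical proteomes pair up one-to-one
    pa <- tibble::tibble(protein_id = paste0("a", 1:10), genome_id = "A",
                         sequence = replicate(10, random_aa(80)))
    pb <- pa
    pb$protein_id <- paste0("b", 1:10)
    pb$genome_id <- "B"
    rbh <- reciprocal_best_hits(search_all(pa, pb), search_all(pb, pa))
    expect_identical(nrow(rbh), 10L)
    expect_identical(sub("b", "a", rbh$subject_id), rbh$query_id)
    expect_true(all(rbh$pident == 100))
    # each protein appears at most once
    expect_false(any(duplicated(rbh$query_id)))
    expect_false(any(duplicated(rbh$subject_id)))
  })
})

test_that("planted orthologs at 75% identity dominate decoys in RBH", {
  withr::with_seed(57, {
    base <- replicate(8, random_bg(120))
    pa <- tibble::tibble(protein_id = paste0("a", 1:12), genome_id = "A",
                         sequence = c(base, replicate(4, random_bg(120))))
    pb <- tibble::tibble(protein_id = paste0("b", 1:12), genome_id = "B",
                         sequence = c(vapply(seq_along(base), function(i) {
                           mutate_to_identity(base[i], 75, seed = i)
                         }, character(1)), replicate(4, random_bg(120))))
    rbh <- reciprocal_best_hits(search_all(pa, pb), search_all(pb, pa))
    planted <- rbh[rbh$query_id %in% paste0("a", 1:8), ]
    expect_identical(nrow(planted), 8L)
    expect_identical(planted$subject_id, sub("a", "b", planted$query_id))
  })
})

test_that("AAI of identical proteomes is 100 and argument order is irrelevant", {
  withr::with_seed(61, {
    pa <- tibble::tibble(protein_id = paste0("a", 1:8), genome_id = "A",
                         sequence = replicate(8, random_aa(90)))
    pb <- pa
    pb$protein_id <- paste0("b", 1:8)
    pb$genome_id <- "B"
    r1 <- compute_aai(pa, pb)
    r2 <- compute_aai(pb, pa)
    expect_equal(r1$aai, 100)
    expect_identical(r1, r2)  # canonical ordering makes AAI symmetric
    expect_identical(r1$n_rbh_pairs, 8L)
  })
})

test_that("AAI recovers the planted family identity within 3 points", {
  gs <- generate_genome_set(aai_config(seed = 3, identity = 75))
  split_p <- split(gs$proteins, gs$proteins$genome_id)
  res <- compute_aai(split_p[[1]], split_p[[2]])
  expect_false(is.na(res$aai))
  expect_gt(res$n_rbh_pairs, 10)
  expect_true(abs(res$aai - 75) <= 3, info = sprintf("AAI = %.2f", res$aai))
})

test_that("AAI is undefined (NA) with no qualifying pairs", {
  withr::with_seed(63, {
    pa <- tibble::tibble(protein_id = "a1", genome_id = "A",
                         sequence = random_bg(60))
    pb <- tibble::tibble(protein_id = "b1", genome_id = "B",
                         sequence = random_bg(60))
    res <- compute_aai(pa, pb, min_identity = 99.5, min_coverage = 99)
    expect_true(is.na(res$aai))
    expect_identical(res$n_rbh_pairs, 0L)
    expect_error(compute_aai(pa[0, ], pb), "non-empty")
  })
})

test_that("raising min_identity never increases the qualifying pair count", {
  gs <- generate_genome_set(aai_config(seed = 5, identity = 70))
  split_p <- split(gs$proteins, gs$proteins$genome_id)
  n_pairs <- vapply(c(30, 50, 70, 90), function(mi) {
    compute_aai(split_p[[1]], split_p[[2]], min_identity = mi)$n_rbh_pairs
  }, integer(1))
  expect_true(all(diff(n_pairs) <= 0))
})

test_that("alignment_params validates its inputs", {
  expect_error(alignment_params(gap_open = 0), "positive")
  expect_error(alignment_params(lambda = -1), "positive")
  expect_error(align_pair("", "AA"), "non-missing|non-empty")
})
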