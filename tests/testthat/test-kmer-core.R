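test_that("occ counts overlapping occurrences", {
  expect_equal(occ("AA", "AAAA"), 3)
  expect_equal(occ("ACG", "TTTT"), 0)
  for (w in c("A", "ACGT", "TTT")) expect_equal(occ(w, w), 1)
  expect_equal(occ("ACGT", "AC"), 0)
  expect_error(occ("", "ACGT"), "nonempty")
})

test_that("enumerate_kmers scans windows, drops non-ACGT, stays in-record", {
  ms <- enumerate_kmers("AAAT", 2, canonical = FALSE)
  expect_equal(ms$counts[order(names(ms$counts))], c(AA = 2, AT = 1))
  expect_equal(ms$total, 3)
  expect_equal(ms$n_windows, ms$total)

  ms_n <- enumerate_kmers("ANAT", 2, canonical = FALSE)
  expect_equal(ms_n$counts, c(AT = 1))

  two <- as_sequence_records(c(r1 = "AC", r2 = "GT"))
  ms2 <- enumerate_kmers(two, 2, canonical = FALSE)
  expect_false("CG" %in% names(ms2$counts))
  expect_equal(sort(names(ms2$counts)), c("AC", "GT"))

  expect_equal(enumerate_kmers(character(0), 3)$total, 0)
  expect_equal(enumerate_kmers("acgt", 2, canonical = FALSE)$counts,
               enumerate_kmers("ACGT", 2, canonical = FALSE)$counts)
})

test_that("canonical counting collapses strands", {
  ms <- enumerate_kmers("ACGT", 2, canonical = TRUE)
  # windows AC, CG, GT; canonical forms AC, CG, AC
  expect_equal(ms$counts[order(names(ms$counts))], c(AC = 2, CG = 1))
  fwd <- enumerate_kmers("ACGGTTACG", 3, canonical = TRUE)
  rev <- enumerate_kmers(revcomp("ACGGTTACG"), 3, canonical = TRUE)
  expect_equal(fwd$counts[order(names(fwd$counts))],
               rev$counts[order(names(rev$counts))])
})

test_that("pckm is asymmetric containment with unit self-score", {
  mi <- enumerate_kmers("AAAT", 2, canonical = FALSE)
  mj <- enumerate_kmers("AAAA", 2, canonical = FALSE)
  expect_equal(pckm(mi, mj), 1)        # AAAA's 2-mers all occur in AAAT
  expect_equal(pckm(mj, mi), 2 / 3)    # AT of AAAT missing from AAAA
  expect_equal(pckm(mi, mi), 1)
  md <- enumerate_kmers("CCCC", 2, canonical = FALSE)
  expect_equal(pckm(mi, md), 0)
  expect_error(pckm(mi, enumerate_kmers("AAAT", 3)), "differ")
})

test_that("common k-mer matrix matches the brute-force window-scan oracle", {
  set.seed(401)
  for (rep in 1:6) {
    k <- sample(c(3, 5, 11, 31), 1)
    n1 <- sample(50:2000, 1); n2 <- sample(50:2000, 1)
    g1 <- raw_dna(n1, 500 + rep); g2 <- raw_dna(n2, 600 + rep)
    A <- build_common_kmer_matrix(list(a = g1, b = g2), k, canonical = FALSE)
    expect_identical(A$values[1, 1], 1)
    expect_identical(A$values[2, 2], 1)
    expect_equal(A$values[1, 2], naive_pckm(g1, g2, k), tolerance = 0)
    expect_equal(A$values[2, 1], naive_pckm(g2, g1, k), tolerance = 0)
  }
  # canonical mode against the canonical oracle
  g1 <- raw_dna(400, 777); g2 <- raw_dna(300, 778)
  A <- build_common_kmer_matrix(list(a = g1, b = g2), 5, canonical = TRUE)
  expect_equal(A$values[1, 2], naive_pckm(g1, g2, 5, canonical = TRUE))
})

test_that("matrix invariants: diagonal one, range, order preserved", {
  gs <- list(x = raw_dna(500, 1), y = raw_dna(500, 2), z = raw_dna(500, 3))
  A <- build_common_kmer_matrix(gs, 7)
  expect_equal(unname(diag(A$values)), rep(1, 3))
  expect_true(all(A$values >= 0 & A$values <= 1))
  expect_equal(A$genome_ids, c("x", "y", "z"))
  one <- build_common_kmer_matrix(gs[1], 7)
  expect_equal(unname(one$values), matrix(1))
  dup <- build_common_kmer_matrix(list(a = gs$x, b = gs$x), 7)
  expect_equal(unname(dup$values), matrix(1, 2, 2))
})

test_that("genomes with no valid window are reported by name", {
  expect_error(
    build_common_kmer_matrix(list(ok = "ACGTACGT", bad = "NNNN"), 4),
    "bad"
  )
})

test_that("multi-record genomes pool windows without spanning records", {
  multi <- as_sequence_records(c(c1 = "ACGTAC", c2 = "GGGTTT"))
  ms <- enumerate_kmers(multi, 4, canonical = FALSE)
  joined <- enumerate_kmers("ACGTACGGGTTT", 4, canonical = FALSE)
  expect_lt(ms$n_windows, joined$n_windows)
  expect_equal(ms$n_windows, (6 - 4 + 1) * 2)
})

test_that("pckm decays in k and follows the substitution survival law", {
  g <- random_genome(3e4, 901, id = "g")
  mut <- mutate_genome(g, 0.01, seed = 902)
  ks <- c(11, 21, 31)
  obs <- vapply(ks, function(k) {
    pckm(enumerate_kmers(g, k), enumerate_kmers(mut, k))
  }, numeric(1))
  expect_true(all(diff(obs) < 0))          # monotone decay in k
  expect_equal(obs, 0.99^ks, tolerance = 0.05)
})

test_that("matrix CSV round-trips", {
  gs <- list(x = raw_dna(300, 11), y = raw_dna(300, 12))
  A <- build_common_kmer_matrix(gs, 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ckm_csv(A, path)
  B <- read_ckm_csv(path)
  expect_equal(B$k, A$k)
  expect_equal(B$genome_ids, A$genome_ids)
  expect_equal(B$values, A$values)
})
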