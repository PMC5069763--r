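test_that("random genomes are reproducible with the requested composition", {
  g1 <- random_genome(1000, 5)
  g2 <- random_genome(1000, 5)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, random_genome(1000, 6)$seq))
  big <- random_genome(1e5, 7, gc = 0.5)
  gc <- sum(strsplit(big$seq, "")[[1]] %in% c("G", "C")) / 1e5
  expect_gt(gc, 0.49); expect_lt(gc, 0.51)
  expect_equal(nchar(random_genome(1, 8)$seq), 1)
})

test_that("mutation preserves length and hits at the requested rate", {
  g <- random_genome(5e4, 9)
  expect_identical(mutate_genome(g, 0, seed = 1)$seq, g$seq)
  m <- mutate_genome(g, 0.05, seed = 2)
  expect_equal(nchar(m$seq), nchar(g$seq))
  diffs <- sum(strsplit(g$seq, "")[[1]] != strsplit(m$seq, "")[[1]])
  expect_equal(diffs / 5e4, 0.05, tolerance = 0.1)
  # heavy mutation destroys k-mer sharing
  heavy <- mutate_genome(g, 0.5, seed = 3)
  expect_lt(pckm(enumerate_kmers(g, 30), enumerate_kmers(heavy, 30)), 1e-3)
})

test_that("community spec validates its inputs", {
  gs <- list(a = random_genome(500, 11, id = "a"), b = random_genome(500, 12, id = "b"))
  expect_error(community_spec(gs, c(0.5, 0.6)), "sum to 1")
  expect_error(community_spec(gs, c(1)), "one mixture weight")
  expect_error(community_spec(gs, c(0.5, 0.5), read_length = 600), "read_length")
})

test_that("simulated reads are deterministic exact substrings when error-free", {
  g <- random_genome(3000, 13, id = "g")
  spec <- community_spec(list(g = g), 1, read_length = 80, n_reads = 200,
                         error_rate = 0, seed = 21)
  sim1 <- simulate_reads(spec)
  sim2 <- simulate_reads(spec)
  expect_identical(sim1$reads, sim2$reads)
  for (r in head(sim1$reads$seq, 30)) {
    expect_true(grepl(r, g$seq, fixed = TRUE) ||
                  grepl(revcomp(r), g$seq, fixed = TRUE))
  }
  expect_true(all(nchar(sim1$reads$seq) == 80))
  expect_true(all(nchar(sim1$reads$qual) == 80))
})

test_that("read counts follow the mixture proportions", {
  gs <- list(a = random_genome(2000, 14, id = "a"),
             b = random_genome(2000, 15, id = "b"))
  sim <- simulate_reads(community_spec(gs, c(0.7, 0.3), read_length = 60,
                                       n_reads = 5000, error_rate = 0, seed = 31))
  n_a <- sim$truth$n_reads[sim$truth$genome_id == "a"]
  # binomial 99 percent bounds around 0.7 * 5000
  bounds <- qbinom(c(0.005, 0.995), 5000, 0.7)
  expect_gte(n_a, bounds[1]); expect_lte(n_a, bounds[2])
  expect_equal(sum(sim$truth$proportion), 1)
})

test_that("sequencing errors are encoded in the Phred strings", {
  g <- random_genome(3000, 16, id = "g")
  sim <- simulate_reads(community_spec(list(g = g), 1, read_length = 100,
                                       n_reads = 300, error_rate = 0.01, seed = 41))
  q <- utf8ToInt(substr(sim$reads$qual[1], 1, 1)) - 33
  expect_equal(q, 20)  # -10 log10(0.01)
  # with e=0.01 and L=100 about 63 percent of reads carry >= 1 error
  with_error <- vapply(sim$reads$seq[1:100], function(r) {
    !(grepl(r, g$seq, fixed = TRUE) || grepl(revcomp(r), g$seq, fixed = TRUE))
  }, logical(1))
  expect_gt(sum(with_error), 30)
  expect_lt(sum(with_error), 90)
})

test_that("polynomial calibration recovers the substitution survival link", {
  p <- calibrate_similarity_polynomial(length = 2e4,
                                       s30_grid = seq(0.9, 0.1, by = -0.2),
                                       seed = 3)
  # the simulator's true link is s50 = s30^(50/30)
  xs <- seq(0.1, 0.9, by = 0.1)
  expect_equal(eval_polynomial(p, xs), xs^(50 / 30), tolerance = 0.05)
})

test_that("truth profiles carry realized proportions up the lineage", {
  trio <- make_trio(length = 2000)
  sim <- simulate_reads(community_spec(trio$genomes, c(0.5, 0.3, 0.2),
                                       read_length = 100, n_reads = 2000,
                                       error_rate = 0, seed = 51))
  prof <- truth_profile(sim$truth, trio$taxonomy)
  expect_equal(sum(prof$percentage[prof$rank == "strain"]), 100, tolerance = 1e-9)
  expect_equal(sum(prof$percentage[prof$rank == "superkingdom"]), 100)
  genus <- prof[prof$rank == "genus", ]
  expect_equal(nrow(genus), 2)  # two of the three genomes share a genus
})
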