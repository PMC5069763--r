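tax3 <- function() make_trio()$taxonomy

test_that("lineage LCA finds the deepest shared rank", {
  tax <- tax3()
  la <- kmerpalette:::lineage_of(tax, "gA")
  lb <- kmerpalette:::lineage_of(tax, "gB")
  lc <- kmerpalette:::lineage_of(tax, "gC")
  expect_equal(lca_rank(la, la)$rank, "strain")
  expect_equal(lca_rank(la, lb)$rank, "genus")   # same genus, different species
  expect_equal(lca_rank(la, lc)$rank, "superkingdom")
  other <- setNames(rep("x", 8), names(la))
  expect_equal(lca_rank(la, other)$rank, "root")
  expect_equal(lca_rank(la, other)$depth, 0)
  expect_error(lca_rank(la[1:3], lb), "fixed ranks")
})

test_that("hypothetical columns map through the delta-matched partner", {
  tax <- tax3()
  vals <- matrix(c(1, 0.9, 0.05,
                   0.9, 1, 0.05,
                   0.05, 0.05, 1), 3, 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), c("gA", "gB", "gC")))
  A30 <- kmerpalette:::new_common_kmer_matrix(30, c("gA", "gB", "gC"), vals)
  # h = 0.9 matches gB exactly: same-genus partner -> genus LCA
  m <- map_hypothetical(1, 0.9, A30, tax)
  expect_equal(m$partner, "gB")
  expect_equal(m$rank, "genus")
  # reference column maps to the strain
  ref <- map_hypothetical(1, 1, A30, tax)
  expect_equal(ref$rank, "strain")
  expect_equal(ref$taxid, "375.1")
  # h = 0.1 only has a cross-superkingdom-level partner near 0.05
  far <- map_hypothetical(1, 0.1, A30, tax)
  expect_equal(far$partner, "gC")
  expect_equal(far$rank, "superkingdom")
})

test_that("hybrid modes bracket the default LCA depth", {
  tax <- tax3()
  vals <- matrix(c(1, 0.3, 0.05,
                   0.3, 1, 0.05,
                   0.05, 0.05, 1), 3, 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), c("gA", "gB", "gC")))
  A30 <- kmerpalette:::new_common_kmer_matrix(30, c("gA", "gB", "gC"), vals)
  for (h in c(0.9, 0.5, 0.3)) {
    d_def <- map_hypothetical(1, h, A30, tax, mode = "default")$depth
    d_sen <- map_hypothetical(1, h, A30, tax, mode = "sensitive")$depth
    d_spe <- map_hypothetical(1, h, A30, tax, mode = "specific")$depth
    expect_gte(d_sen, d_def)
    expect_lte(d_spe, d_def)
  }
})

test_that("profiles sum upward and conserve mass", {
  tax <- tax3()
  vals <- diag(3); vals[1, 2] <- vals[2, 1] <- 0.9
  dimnames(vals) <- list(tax$genome_id, tax$genome_id)
  A30 <- kmerpalette:::new_common_kmer_matrix(30, tax$genome_id, vals)

  # single reference genome at 1.0: full lineage at 100 percent
  ab1 <- tibble::tibble(genome_id = "gA", genome_index = 1L, bin = 1, abundance = 1)
  prof1 <- build_profile(ab1, tax, A30)
  expect_equal(nrow(prof1), 8)
  expect_equal(unique(prof1$percentage), 100)

  # two strains of one genus at 0.5 each
  ab2 <- tibble::tibble(genome_id = c("gA", "gB"), genome_index = 1:2,
                        bin = 1, abundance = c(0.5, 0.5))
  prof2 <- build_profile(ab2, tax, A30)
  genus <- prof2[prof2$rank == "genus", ]
  expect_equal(genus$percentage, 100)
  strains <- prof2[prof2$rank == "strain", ]
  expect_equal(sort(strains$percentage), c(50, 50))

  # hypothetical at bin 0.9 mapped to gB's species level via partner gB
  ab3 <- tibble::tibble(genome_id = c("gA", "gA"), genome_index = c(1L, 1L),
                        bin = c(1, 0.9), abundance = c(0.8, 0.2))
  prof3 <- build_profile(ab3, tax, A30)
  # upward consistency at every rank
  for (rk in seq_along(kmerpalette:::PALETTE_RANKS)[-8]) {
    parents <- prof3[prof3$rank == kmerpalette:::PALETTE_RANKS[rk], ]
    kids <- prof3[prof3$rank == kmerpalette:::PALETTE_RANKS[rk + 1], ]
    for (i in seq_len(nrow(parents))) {
      child_sum <- sum(kids$percentage[startsWith(kids$taxpath,
                                                  parents$taxpath[i])])
      expect_gte(parents$percentage[i], child_sum - 1e-9)
    }
  }
  # strain-level mass is the reference share; the rest sits higher up
  expect_equal(sum(prof3$percentage[prof3$rank == "strain"]), 80)
  expect_gte(sum(prof3$percentage[prof3$rank == "species"]), 80)
  expect_equal(sum(prof3$percentage[prof3$rank == "superkingdom"]), 100)
})

test_that("Bioboxes profiles round-trip bit-compatibly", {
  tax <- tax3()
  vals <- diag(3); dimnames(vals) <- list(tax$genome_id, tax$genome_id)
  A30 <- kmerpalette:::new_common_kmer_matrix(30, tax$genome_id, vals)
  ab <- tibble::tibble(genome_id = c("gA", "gC"), genome_index = c(1L, 3L),
                       bin = 1, abundance = c(0.25, 0.75))
  prof <- build_profile(ab, tax, A30, sample_id = "S1")
  path <- withr::local_tempfile(fileext = ".profile")
  write_profile(prof, path)
  lines <- readLines(path)
  expect_equal(lines[2], "@Version:0.9.1")
  expect_equal(lines[3],
    "@Ranks:superkingdom|phylum|class|order|family|genus|species|strain")
  expect_match(lines[4], "^@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE$")
  back <- read_profile(path)
  expect_equal(attr(back, "sample_id"), "S1")
  expect_equal(as.data.frame(back), as.data.frame(prof))
})

test_that("taxonomy table validates and round-trips", {
  tax <- tax3()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, path)
  back <- read_taxonomy(path)
  expect_equal(as.data.frame(back), as.data.frame(tax))
  expect_error(taxonomy_table("g1", "a|b", "a|b"), "incomplete lineage")
  expect_error(taxonomy_table(c("g1", "g1"), rep("a|b|c|d|e|f|g|h", 2),
                              rep("a|b|c|d|e|f|g|h", 2)), "duplicate")
})
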