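# Shared synthetic fixtures, built in code at test time.

# small random DNA string without going through the package generator
raw_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# three well-separated reference genomes plus taxonomy, used by the
# mixture-recovery and profile tests
make_trio <- function(length = 2e4, seed = 300) {
  genomes <- list(
    gA = random_genome(length, seed + 1, id = "gA"),
    gB = random_genome(length, seed + 2, id = "gB"),
    gC = random_genome(length, seed + 3, id = "gC")
  )
  tax <- taxonomy_table(
    genome_id = c("gA", "gB", "gC"),
    taxpath = c(
      "2|1224|28211|356|41294|374|375|375.1",
      "2|1224|28211|356|41294|374|376|376.1",
      "2|1239|91061|1385|186817|1386|1396|1396.1"
    ),
    taxpath_names = c(
      "Bacteria|Proteobacteria|Alpha|Rhizobiales|Brady|Bradyrhizobium|sp1|sp1 str",
      "Bacteria|Proteobacteria|Alpha|Rhizobiales|Brady|Bradyrhizobium|sp2|sp2 str",
      "Bacteria|Firmicutes|Bacilli|Bacillales|Bacillaceae|Bacillus|cereus|cereus str"
    )
  )
  list(genomes = genomes, taxonomy = tax)
}

# graded-divergence strain panel: five strains at increasing substitution
# distance from a common ancestor; the study condition for novelty tests
make_strain_panel <- function(length = 1e5, seed = 42,
                              mus = c(0.015, 0.03, 0.045, 0.06, 0.075)) {
  anc <- random_genome(length, seed, id = "anc")
  strains <- lapply(seq_along(mus), function(i) {
    mutate_genome(anc, mus[i], seed = seed + 100 + i, id = paste0("s", i))
  })
  names(strains) <- paste0("s", seq_along(mus))
  tax <- taxonomy_table(
    genome_id = names(strains),
    taxpath = sprintf("2|1239|91061|1385|186822|44249|%d|%d.1",
                      1000 + seq_along(mus), 1000 + seq_along(mus)),
    taxpath_names = sprintf(
      "Bacteria|Firmicutes|Bacilli|Bacillales|Paenibacillaceae|Paenibacillus|sp%d|sp%d strain",
      seq_along(mus), seq_along(mus))
  )
  list(ancestor = anc, strains = strains, taxonomy = tax, mus = mus)
}

# write a genome list as per-genome FASTA files plus a manifest tibble
write_genome_files <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(genomes), function(id) {
    p <- file.path(dir, paste0(id, ".fasta"))
    write_sequences(genomes[[id]], p)
    p
  }, "")
  tibble::tibble(genome_id = names(genomes), fasta_path = unname(paths))
}
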