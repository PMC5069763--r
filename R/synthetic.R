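#' Deterministic random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`, reproducible per seed. Used to
#' build reference databases for tests and simulations without downloads.
#'
#' @param length genome length (>= 1).
#' @param seed integer seed (local to this call; the global RNG state is
#'   untouched).
#' @param gc GC content in (0, 1).
#' @param id record id.
#' @return a one-row sequence records tibble.
#' @export
random_genome <- function(length, seed, gc = 0.5, id = paste0("genome_", seed)) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  bases <- withr::with_seed(seed, {
    sample(c("A", "T", "G", "C"), length, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  })
  tibble(id = id, seq = paste(bases, collapse = ""))
}

#' Point-mutated genome copy
#'
#' Each base is independently substituted (uniformly over the three
#' alternatives) with probability `mu`; no indels, so a k-mer survives
#' mutation with probability exactly `(1 - mu)^k` — the calibration
#' behind the containment-vs-divergence relationship.
#'
#' @param genome one-row records tibble (or anything
#'   [as_sequence_records()] accepts; first record used).
#' @param mu per-base substitution rate in `[0, 1)`.
#' @param seed integer seed.
#' @param id id for the mutated record; default appends `_mut`.
#' @return a one-row sequence records tibble.
#' @export
mutate_genome <- function(genome, mu, seed, id = NULL) {
  stopifnot(mu >= 0, mu < 1)
  rec <- as_sequence_records(genome)[1, ]
  if (is.null(id)) id <- paste0(rec$id, "_mut")
  if (mu == 0) return(tibble(id = id, seq = rec$seq))
  bases <- strsplit(rec$seq, "")[[1]]
  bases <- withr::with_seed(seed, {
    hit <- which(runif(length(bases)) < mu)
    for (i in hit) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
    }
    bases
  })
  tibble(id = id, seq = paste(bases, collapse = ""))
}

#' Specification of a synthetic community
#'
#' @param genomes named list of one-row records tibbles (names are genome
#'   ids), or a records tibble with one row per genome.
#' @param mixture nonnegative proportions summing to 1, one per genome.
#' @param read_length read length; every genome must be at least this long.
#' @param n_reads number of reads to draw.
#' @param error_rate per-base substitution error rate of the simulated
#'   sequencer.
#' @param seed integer seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(genomes, mixture, read_length = 100, n_reads = 10000,
                           error_rate = 0, seed = 1) {
  if (is.data.frame(genomes)) {
    genomes <- split(as_sequence_records(genomes), seq_len(nrow(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id[1], "")
  }
  if (is.null(names(genomes))) abort("genomes must be named")
  if (length(mixture) != length(genomes)) abort("one mixture weight per genome")
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-9) {
    abort("mixture proportions must be nonnegative and sum to 1")
  }
  lens <- vapply(genomes, function(g) nchar(as_sequence_records(g)$seq[1]), 0)
  if (any(lens < read_length)) abort("read_length exceeds a genome length")
  structure(
    list(genomes = genomes, mixture = mixture, read_length = read_length,
         n_reads = n_reads, error_rate = error_rate, seed = seed),
    class = "community_spec"
  )
}

#' Simulate reads from a synthetic community
#'
#' Reads are drawn from genomes with probabilities equal to the mixture
#' proportions (the uniform-sampling assumption behind the linear mixture
#' model), with uniform start positions on the forward strand of a linear
#' genome, random strand, independent substitution errors at
#' `error_rate`, and Phred strings encoding that error rate
#' (`Q = -10 log10(e)`, capped at 40 for error-free reads). Byte-identical
#' output for a fixed spec.
#'
#' @param spec a [community_spec()].
#' @return list with `reads` (records tibble with `qual`) and `truth`
#'   (tibble `genome_id`, `n_reads`, `proportion` — the realized read
#'   counts; `mixture` carries the nominal proportions).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  ids <- names(spec$genomes)
  seqs <- vapply(spec$genomes, function(g) as_sequence_records(g)$seq[1], "")
  L <- spec$read_length
  q <- if (spec$error_rate > 0) min(40L, round(-10 * log10(spec$error_rate))) else 40L
  qual_str <- paste(rep(rawToChar(as.raw(33L + q)), L), collapse = "")
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))

  out <- withr::with_seed(spec$seed, {
    origin <- sample.int(length(ids), spec$n_reads, replace = TRUE,
                         prob = spec$mixture)
    reads <- character(spec$n_reads)
    for (r in seq_len(spec$n_reads)) {
      g <- seqs[origin[r]]
      start <- sample.int(nchar(g) - L + 1L, 1L)
      frag <- substr(g, start, start + L - 1L)
      if (spec$error_rate > 0) {
        b <- strsplit(frag, "")[[1]]
        hit <- which(runif(L) < spec$error_rate & b %in% names(alt))
        for (i in hit) b[i] <- sample(alt[[b[i]]], 1)
        frag <- paste(b, collapse = "")
      }
      if (runif(1) < 0.5) frag <- revcomp(frag)
      reads[r] <- frag
    }
    list(origin = origin, reads = reads)
  })

  truth <- tibble(genome_id = ids,
                  n_reads = as.integer(tabulate(out$origin, length(ids))),
                  mixture = unname(spec$mixture)) |>
    mutate(proportion = .data$n_reads / sum(.data$n_reads))
  list(
    reads = tibble(id = sprintf("read_%06d|%s", seq_len(spec$n_reads),
                                ids[out$origin]),
                   seq = out$reads, qual = qual_str),
    truth = truth
  )
}

#' Calibrate the similarity polynomial for the simulator's genome universe
#'
#' The 30/50-mer link polynomial is a property of the genome collection it
#' is fitted on. For synthetic databases built with [random_genome()] and
#' [mutate_genome()], this generates ancestor/mutant genome pairs spanning
#' a grid of 30-mer similarities, computes their containment at both k
#' sizes, and refits the polynomial by the same no-intercept cubic
#' least-squares procedure used for the published coefficients.
#'
#' @param length genome length per pair (default 50 kb).
#' @param s30_grid target 30-mer similarity levels; the substitution rate
#'   for each pair is `1 - s^(1/k1)`.
#' @param kmer_sizes the two k sizes (default 30, 50).
#' @param seed integer seed.
#' @param canonical see [enumerate_kmers()].
#' @return a fitted [similarity_polynomial()].
#' @export
calibrate_similarity_polynomial <- function(length = 5e4,
                                            s30_grid = seq(0.95, 0.05, by = -0.1),
                                            kmer_sizes = c(30L, 50L),
                                            seed = 1, canonical = TRUE) {
  k1 <- kmer_sizes[1]; k2 <- kmer_sizes[2]
  pairs <- purrr::map_dfr(seq_along(s30_grid), function(i) {
    anc <- random_genome(length, seed + 1000 * i, id = "anc")
    mut <- mutate_genome(anc, 1 - s30_grid[i]^(1 / k1), seed + 1000 * i + 1)
    a1 <- enumerate_kmers(anc, k1, canonical); m1 <- enumerate_kmers(mut, k1, canonical)
    a2 <- enumerate_kmers(anc, k2, canonical); m2 <- enumerate_kmers(mut, k2, canonical)
    tibble(s30 = pckm(a1, m1), s50 = pckm(a2, m2))
  })
  fit_similarity_polynomial(pairs)
}

#' Reverse complement of a DNA string
#' @param x character vector of ACGT strings.
#' @return reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a ground-truth community profile
#'
#' Converts the realized read proportions of [simulate_reads()] into a
#' Bioboxes `tax_profile` using the training taxonomy (each genome's full
#' lineage at its realized proportion, summed upward).
#'
#' @param truth truth tibble from [simulate_reads()].
#' @param taxonomy a [taxonomy_table()] covering the community genomes.
#' @param sample_id profile label.
#' @return a `tax_profile`.
#' @export
truth_profile <- function(truth, taxonomy, sample_id = "truth") {
  present <- dplyr::filter(truth, .data$proportion > 0)
  ab <- tibble(genome_id = present$genome_id,
               genome_index = match(present$genome_id, taxonomy$genome_id),
               bin = 1, abundance = present$proportion)
  # reference-only abundances need no containment matrix: build directly
  acc <- list()
  for (r in seq_len(nrow(ab))) {
    tax_ids <- lineage_of(taxonomy, ab$genome_id[r], "taxpath")
    tax_nms <- lineage_of(taxonomy, ab$genome_id[r], "taxpath_names")
    for (d in seq_along(PALETTE_RANKS)) {
      acc[[length(acc) + 1L]] <- tibble(
        rank = PALETTE_RANKS[d], taxid = unname(tax_ids[d]),
        taxpath = paste(tax_ids[seq_len(d)], collapse = "|"),
        taxpath_names = paste(tax_nms[seq_len(d)], collapse = "|"),
        percentage = 100 * ab$abundance[r])
    }
  }
  entries <- bind_rows(acc) |>
    group_by(.data$rank, .data$taxid, .data$taxpath, .data$taxpath_names) |>
    summarise(percentage = sum(.data$percentage), .groups = "drop") |>
    mutate(rank = factor(.data$rank, levels = PALETTE_RANKS)) |>
    arrange(.data$rank, dplyr::desc(.data$percentage)) |>
    mutate(rank = as.character(.data$rank))
  new_tax_profile(entries, sample_id)
}
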