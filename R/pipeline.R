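#' Run configuration
#'
#' Bundles the tunable parameters of the profiler with validation.
#'
#' @param kmer_sizes strictly increasing pair of k-mer sizes; the default
#'   (30, 50) is the pair the default similarity polynomial was fitted for.
#' @param bins strictly decreasing hypothetical similarity levels in (0, 1).
#' @param lambda deconvolution regularization weight (default 200).
#' @param delta taxon-matching half-width (default 0.05).
#' @param qmin optional minimum Phred score for sample k-mer counting.
#' @param mode profile assignment scheme: `"default"`, `"sensitive"` or
#'   `"specific"`.
#' @param canonical strand-collapsed k-mers (default TRUE).
#' @param prune_eps relative abundance pruning threshold.
#' @param seed integer seed for any stochastic step.
#' @return a `run_config` list.
#' @export
run_config <- function(kmer_sizes = c(30L, 50L), bins = seq(0.9, 0.1, by = -0.1),
                       lambda = 200, delta = 0.05, qmin = NULL,
                       mode = c("default", "sensitive", "specific"),
                       canonical = TRUE, prune_eps = 1e-4, seed = 1L) {
  mode <- match.arg(mode)
  if (length(kmer_sizes) != 2 || kmer_sizes[1] >= kmer_sizes[2]) {
    abort("`kmer_sizes` must be a strictly increasing pair")
  }
  if (length(bins) > 0 && (any(bins <= 0 | bins >= 1) ||
                           is.unsorted(rev(bins), strictly = TRUE))) {
    abort("`bins` must be strictly decreasing values in (0, 1)")
  }
  structure(
    list(kmer_sizes = as.integer(kmer_sizes), bins = bins, lambda = lambda,
         delta = delta, qmin = qmin, mode = mode, canonical = canonical,
         prune_eps = prune_eps, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Train a palette database bundle
#'
#' Counts each reference genome's k-mers at both k sizes, builds the two
#' common k-mer matrices, and writes a versioned bundle directory:
#' `manifest.json`, `A<k1>.csv`, `A<k2>.csv`, `polynomial.json`,
#' `taxonomy.tsv` and `genomes.tsv` (id-to-FASTA map, used at profiling
#' time to rebuild the genome k-mer sets). Deterministic: re-running on
#' identical input reproduces identical matrices.
#'
#' @param manifest tibble with `genome_id` and `fasta_path` columns, or a
#'   path to a two-column tab-separated file without header.
#' @param taxonomy a [taxonomy_table()] (or TSV path) covering every
#'   genome.
#' @param out_dir bundle directory to create.
#' @param config a [run_config()].
#' @param fit_polynomial refit the similarity polynomial on the
#'   off-diagonal matrix entries (requires enough distinct similarity
#'   levels); by default the published coefficients are used.
#' @param polynomial optional [similarity_polynomial()] to store in the
#'   bundle (e.g. from [calibrate_similarity_polynomial()] for synthetic
#'   databases); overrides the default, ignored when `fit_polynomial` is
#'   set.
#' @return the bundle, invisibly (see [read_bundle()]).
#' @export
train_palette <- function(manifest, taxonomy, out_dir, config = run_config(),
                          fit_polynomial = FALSE, polynomial = NULL) {
  if (is.character(manifest)) {
    manifest <- read.table(manifest, sep = "\t", header = FALSE,
                           col.names = c("genome_id", "fasta_path"),
                           colClasses = "character")
  }
  manifest <- as_tibble(manifest)
  if (!all(c("genome_id", "fasta_path") %in% names(manifest))) {
    abort("manifest needs `genome_id` and `fasta_path` columns")
  }
  dup <- manifest$genome_id[duplicated(manifest$genome_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate genome_id in manifest: ", paste(unique(dup), collapse = ", ")))
  }
  missing <- manifest$fasta_path[!file.exists(manifest$fasta_path)]
  if (length(missing) > 0) {
    abort(paste0("missing genome file(s): ", paste(missing, collapse = ", ")))
  }
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  absent <- setdiff(manifest$genome_id, taxonomy$genome_id)
  if (length(absent) > 0) {
    abort(paste0("genome(s) missing from taxonomy: ", paste(absent, collapse = ", ")))
  }

  genomes <- lapply(manifest$fasta_path, read_sequences)
  names(genomes) <- manifest$genome_id
  k1 <- config$kmer_sizes[1]; k2 <- config$kmer_sizes[2]
  A30 <- build_common_kmer_matrix(genomes, k1, config$canonical)
  A50 <- build_common_kmer_matrix(genomes, k2, config$canonical)

  p <- if (is.null(polynomial)) similarity_polynomial() else polynomial
  if (fit_polynomial) {
    off <- upper.tri(A30$values) | lower.tri(A30$values)
    pairs <- tibble(s30 = A30$values[off], s50 = A50$values[off])
    p <- fit_similarity_polynomial(pairs)
  }

  # write atomically: build in a staging dir, then rename into place
  stage <- paste0(out_dir, ".staging")
  if (dir.exists(stage)) unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE))
  write_ckm_csv(A30, file.path(stage, paste0("A", k1, ".csv")))
  write_ckm_csv(A50, file.path(stage, paste0("A", k2, ".csv")))
  jsonlite::write_json(
    list(coeffs = as.list(p$coeffs), rmse = p$rmse, r_squared = p$r_squared),
    file.path(stage, "polynomial.json"), auto_unbox = TRUE, digits = NA, na = "null")
  write_taxonomy(taxonomy, file.path(stage, "taxonomy.tsv"))
  write.table(as.data.frame(manifest), file.path(stage, "genomes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(format = "kmerpalette-bundle", format_version = 1L,
         kmer_sizes = config$kmer_sizes, bins = config$bins,
         canonical = config$canonical, genome_ids = manifest$genome_id),
    file.path(stage, "manifest.json"), auto_unbox = TRUE, digits = NA)
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  file.rename(stage, out_dir)
  ok <- TRUE
  invisible(read_bundle(out_dir))
}

#' Read a trained bundle directory
#'
#' @param dir bundle directory written by [train_palette()].
#' @return a `palette_bundle`: list with `A30`, `A50`, `polynomial`,
#'   `taxonomy`, `manifest` (genome-to-FASTA map), `bins`, `kmer_sizes`,
#'   `canonical`.
#' @export
read_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort(paste0("not a bundle directory: ", dir))
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(man$format, "kmerpalette-bundle")) {
    abort("unrecognized bundle format")
  }
  k1 <- man$kmer_sizes[1]; k2 <- man$kmer_sizes[2]
  poly <- jsonlite::read_json(file.path(dir, "polynomial.json"),
                              simplifyVector = TRUE)
  structure(
    list(
      A30 = read_ckm_csv(file.path(dir, paste0("A", k1, ".csv"))),
      A50 = read_ckm_csv(file.path(dir, paste0("A", k2, ".csv"))),
      polynomial = similarity_polynomial(
        poly$coeffs$c3, poly$coeffs$c2, poly$coeffs$c1,
        rmse = poly$rmse %||% NA_real_,
        r_squared = poly$r_squared %||% NA_real_),
      taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
      manifest = as_tibble(read.table(file.path(dir, "genomes.tsv"), sep = "\t",
                                      header = TRUE, colClasses = "character")),
      bins = man$bins, kmer_sizes = as.integer(man$kmer_sizes),
      canonical = isTRUE(man$canonical), dir = dir
    ),
    class = "palette_bundle"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.palette_bundle <- function(x, ...) {
  cat("<palette_bundle>", length(x$A30$genome_ids), "genomes | k =",
      paste(x$kmer_sizes, collapse = "/"), "|", length(x$bins), "bins\n")
  invisible(x)
}

#' Profile a metagenomic sample against a trained bundle
#'
#' Runs the full deconvolution: counts sample k-mers at both k sizes
#' (optionally Phred-filtered), forms the measurement vectors, assembles
#' the hypothetical-organism system, solves the sparsity-promoting
#' nonnegative least-squares problem, prunes and normalizes, and maps the
#' result to a rank-wise Bioboxes profile.
#'
#' @param bundle a `palette_bundle` (or bundle directory path).
#' @param reads sample reads: FASTA/FASTQ path (gz/bz2 accepted) or a
#'   records tibble.
#' @param config a [run_config()]; its `kmer_sizes`/`bins`/`canonical`
#'   must match the bundle (bundle values win).
#' @param sample_id label for the output profile.
#' @return list with `profile` (`tax_profile`), `abundances` (pruned
#'   tibble), `solution` (`abundance_solution`), `signatures` (list of the
#'   two `sample_signature`s).
#' @export
profile_sample <- function(bundle, reads, config = run_config(),
                           sample_id = "sample") {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "palette_bundle"))
  if (is.character(reads)) reads <- read_sequences(reads)
  reads <- as_sequence_records(reads)
  if (nrow(reads) == 0) abort("no reads to profile")

  k1 <- bundle$kmer_sizes[1]; k2 <- bundle$kmer_sizes[2]
  genomes <- lapply(bundle$manifest$fasta_path, read_sequences)
  names(genomes) <- bundle$manifest$genome_id
  gms1 <- genome_kmer_multisets(genomes, k1, bundle$canonical)
  gms2 <- genome_kmer_multisets(genomes, k2, bundle$canonical)

  s1 <- count_sample_kmers(reads, k1, bundle$canonical, config$qmin)
  s2 <- count_sample_kmers(reads, k2, bundle$canonical, config$qmin)
  if (s1$total < 1 || s2$total < 1) abort("sample contains no countable k-mers")
  y1 <- sample_vector(s1, gms1)
  y2 <- sample_vector(s2, gms2)

  sys <- assemble_system(bundle$A30, bundle$A50, bundle$polynomial, bundle$bins)
  sol <- solve_nnreg(sys, stack_signatures(y1, y2), config$lambda)
  ab <- postprocess_abundances(sol, config$prune_eps)
  prof <- build_profile(ab, bundle$taxonomy, bundle$A30, config$mode,
                        config$delta, sample_id)
  list(profile = prof, abundances = ab, solution = sol,
       signatures = list(y1, y2), system = sys)
}

#' Strain tree with placed sample mass
#'
#' Builds the neighbor-joining tree over (a filtered subset of) the
#' bundle genomes from the averaged 30/50-mer similarity matrices and
#' places the sample's solved reference and hypothetical mass on it.
#'
#' @param bundle a `palette_bundle`.
#' @param abundances pruned abundance tibble from [profile_sample()].
#' @param genomes optional character vector restricting the tree to a
#'   genome subset (>= 2 genomes).
#' @param delta see [map_hypothetical()].
#' @return a `strain_tree`.
#' @export
strain_tree_report <- function(bundle, abundances, genomes = NULL, delta = 0.05) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  ids <- bundle$A30$genome_ids
  if (!is.null(genomes)) {
    keep <- match(genomes, ids)
    if (anyNA(keep)) abort("unknown genome id in filter")
    if (length(keep) < 2) abort("genome filter must keep at least 2 genomes")
    A30 <- new_common_kmer_matrix(bundle$A30$k, ids[keep],
                                  bundle$A30$values[keep, keep, drop = FALSE])
    A50 <- new_common_kmer_matrix(bundle$A50$k, ids[keep],
                                  bundle$A50$values[keep, keep, drop = FALSE])
    abundances <- dplyr::filter(abundances, .data$genome_id %in% ids[keep]) |>
      mutate(genome_index = match(.data$genome_id, ids[keep]))
  } else {
    A30 <- bundle$A30; A50 <- bundle$A50
  }
  tree <- neighbor_joining(similarity_to_distance(A30, A50))
  place_hypotheticals(tree, abundances, A30, delta)
}
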