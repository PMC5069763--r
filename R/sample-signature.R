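#' Count sample k-mers with optional Phred filtering
#'
#' Counts the length-`k` windows of a whole read set (no per-read
#' assignment). A window is counted iff all its bases are ACGT and — when
#' `qmin` is set and the records carry qualities — every base's Phred score
#' is at least `qmin` (strict all-bases reading of the quality gate).
#'
#' @inheritParams enumerate_kmers
#' @return a `kmer_multiset`.
#' @export
count_sample_kmers <- function(records, k, canonical = TRUE, qmin = NULL) {
  enumerate_kmers(records, k, canonical = canonical, qmin = qmin)
}

#' Sample measurement vector against a genome database
#'
#' For each genome *i*, the fraction of all counted sample k-mers (with
#' multiplicity) that also occur in genome *i*. The denominator is the
#' total sample k-mer count, including k-mers matching no genome, so
#' unmatched sample content depresses every entry equally.
#'
#' @param sample_ms `kmer_multiset` of the sample (see
#'   [count_sample_kmers()]); must be nonempty.
#' @param genome_ms named list of `kmer_multiset`s (or k-mer key sets) for
#'   the M training genomes, all at `sample_ms$k`.
#' @return a `sample_signature`: list with `k`, named numeric `y` in
#'   `[0, 1]`, `total_kmers`, `qmin`.
#' @export
sample_vector <- function(sample_ms, genome_ms) {
  stopifnot(inherits(sample_ms, "kmer_multiset"))
  if (sample_ms$total < 1) abort("sample contains no countable k-mers")
  keysets <- lapply(genome_ms, function(g) {
    if (inherits(g, "kmer_multiset")) {
      if (g$k != sample_ms$k) abort("genome multiset k differs from sample k")
      names(g$counts)
    } else {
      as.character(g)
    }
  })
  skmers <- names(sample_ms$counts)
  scounts <- unname(sample_ms$counts)
  y <- vapply(keysets, function(ks) {
    sum(scounts[skmers %in% ks]) / sample_ms$total
  }, numeric(1))
  structure(
    list(k = sample_ms$k, y = y, total_kmers = sample_ms$total,
         qmin = sample_ms$qmin),
    class = "sample_signature"
  )
}

#' @export
print.sample_signature <- function(x, ...) {
  cat("<sample_signature> k =", x$k, "|", length(x$y), "genomes |",
      format(x$total_kmers, big.mark = ","), "sample k-mers\n")
  invisible(x)
}

#' @export
tidy.sample_signature <- function(x, ...) {
  tibble(genome_id = names(x$y), k = x$k, y = unname(x$y))
}

#' Stack the two k-mer measurement vectors
#'
#' @param y30,y50 `sample_signature`s over the same genomes in the same
#'   order.
#' @return numeric vector `c(y30, y50)` of length 2M.
#' @export
stack_signatures <- function(y30, y50) {
  stopifnot(inherits(y30, "sample_signature"), inherits(y50, "sample_signature"))
  if (length(y30$y) != length(y50$y) || !identical(names(y30$y), names(y50$y))) {
    abort("signatures cover different genomes (or a different order)")
  }
  c(unname(y30$y), unname(y50$y))
}
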