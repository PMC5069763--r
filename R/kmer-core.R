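#' Overlapping occurrence count
#'
#' Number of (possibly overlapping) occurrences of the subword `v` in the
#' word `w`. Case-sensitive; callers normally pass uppercased DNA.
#'
#' @param v nonempty subword.
#' @param w word to scan; returns 0 when `nchar(v) > nchar(w)`.
#' @return nonnegative count.
#' @export
#' @examples
#' occ("AA", "AAAA") # 3
occ <- function(v, w) {
  stopifnot(is.character(v), is.character(w), length(v) == 1, length(w) == 1)
  if (!nzchar(v)) abort("subword `v` must be nonempty")
  occ_cpp(v, w)
}

#' Enumerate k-mers of a sequence set
#'
#' Exact, overlap-counted enumeration of the length-`k` windows of every
#' record. Windows never span record boundaries and any window containing a
#' non-ACGT letter (after uppercasing) is dropped. With `canonical = TRUE`
#' each k-mer is replaced by the lexicographic minimum of itself and its
#' reverse complement before counting, collapsing the two strands.
#'
#' @param records anything [as_sequence_records()] accepts.
#' @param k k-mer length (>= 1).
#' @param canonical collapse strands? Default `TRUE`: shotgun reads come
#'   from both strands, so training and sample counting default to the
#'   strand-collapsed representation.
#' @param qmin optional minimum Phred score; when set (and a `qual` column
#'   is present) a window is counted only if all `k` bases have quality
#'   `>= qmin`.
#' @return a `kmer_multiset`: list with `k`, named numeric `counts`,
#'   `total` (sum of counts) and `n_windows` (valid windows scanned;
#'   equal to `total` by construction).
#' @export
enumerate_kmers <- function(records, k, canonical = TRUE, qmin = NULL) {
  stopifnot(length(k) == 1, k >= 1)
  k <- as.integer(k)
  records <- as_sequence_records(records)
  quals <- NULL
  q <- -1L
  if (!is.null(qmin)) {
    if (!"qual" %in% names(records)) {
      warn("`qmin` given but records carry no quality strings; ignored")
    } else {
      quals <- records$qual
      q <- as.integer(qmin)
    }
  }
  res <- kmer_count_cpp(records$seq, k, isTRUE(canonical), quals, q, 33L)
  new_kmer_multiset(k, res$counts, res$n_windows, qmin = if (q >= 0) q else NULL)
}

new_kmer_multiset <- function(k, counts, n_windows, qmin = NULL) {
  structure(
    list(k = as.integer(k), counts = counts, total = sum(counts),
         n_windows = n_windows, qmin = qmin),
    class = "kmer_multiset"
  )
}

#' @export
print.kmer_multiset <- function(x, ...) {
  cat("<kmer_multiset> k =", x$k, "|", length(x$counts), "distinct k-mers |",
      format(x$total, big.mark = ","), "windows\n")
  invisible(x)
}

#' @export
tidy.kmer_multiset <- function(x, ...) {
  tibble(kmer = names(x$counts), count = unname(x$counts))
}

#' Common k-mer containment score (pckm)
#'
#' The fraction of genome *j*'s k-mers (with multiplicity) that also occur
#' in genome *i*: `sum over shared distinct k-mers of count_j / n_windows_j`.
#' The score is asymmetric — it measures containment of `ms_j` in `ms_i` —
#' and lies in `[0, 1]`, with `pckm(ms, ms) == 1`.
#'
#' @param ms_i,ms_j `kmer_multiset`s at the same `k`; `ms_j` must be
#'   nonempty (it supplies the denominator).
#' @return real in `[0, 1]`.
#' @export
pckm <- function(ms_i, ms_j) {
  stopifnot(inherits(ms_i, "kmer_multiset"), inherits(ms_j, "kmer_multiset"))
  if (ms_i$k != ms_j$k) abort("k-mer sizes differ between the two multisets")
  if (ms_j$n_windows < 1) abort("`ms_j` has no valid windows")
  shared <- names(ms_j$counts) %in% names(ms_i$counts)
  sum(ms_j$counts[shared]) / ms_j$n_windows
}

#' Common k-mer matrix over a genome database
#'
#' Builds the M-by-M matrix whose (i, j) entry is the containment of genome
#' j's k-mers in genome i (see [pckm()]). The matrix is not symmetric in
#' general; the diagonal is exactly 1.
#'
#' @param genomes named list of record sets (one per genome; each element is
#'   anything [as_sequence_records()] accepts), or a `DNAStringSet` where
#'   each element is a single-record genome. Names become `genome_ids`.
#' @param k k-mer length.
#' @param canonical see [enumerate_kmers()].
#' @return a `common_kmer_matrix`: list with `k`, `genome_ids`, and the
#'   numeric `values` matrix (dimnames set to the ids).
#' @export
build_common_kmer_matrix <- function(genomes, k, canonical = TRUE) {
  ms <- genome_kmer_multisets(genomes, k, canonical)
  ids <- names(ms)
  M <- length(ms)
  vals <- matrix(0, M, M, dimnames = list(ids, ids))
  for (j in seq_len(M)) {
    for (i in seq_len(M)) {
      vals[i, j] <- if (i == j) 1 else pckm(ms[[i]], ms[[j]])
    }
  }
  new_common_kmer_matrix(k, ids, vals)
}

# shared helper: one multiset per genome, errors naming empty genomes
genome_kmer_multisets <- function(genomes, k, canonical = TRUE, qmin = NULL) {
  if (inherits(genomes, "DNAStringSet")) {
    ids <- names(genomes)
    genomes <- lapply(seq_along(genomes), function(i) genomes[i])
    names(genomes) <- ids
  }
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    abort("genomes must be a named list (names are the genome ids)")
  }
  ms <- lapply(genomes, enumerate_kmers, k = k, canonical = canonical, qmin = qmin)
  empty <- vapply(ms, function(m) m$n_windows < 1, logical(1))
  if (any(empty)) {
    abort(paste0("genome(s) with no valid length-", k, " window: ",
                 paste(names(ms)[empty], collapse = ", ")))
  }
  ms
}

new_common_kmer_matrix <- function(k, genome_ids, values) {
  stopifnot(nrow(values) == length(genome_ids), ncol(values) == length(genome_ids))
  structure(list(k = as.integer(k), genome_ids = genome_ids, values = values),
            class = "common_kmer_matrix")
}

#' @export
print.common_kmer_matrix <- function(x, ...) {
  cat("<common_kmer_matrix> k =", x$k, "|", length(x$genome_ids), "genomes\n")
  print(round(x$values[seq_len(min(6, nrow(x$values))),
                       seq_len(min(6, ncol(x$values))), drop = FALSE], 4))
  invisible(x)
}

#' @describeIn build_common_kmer_matrix long-format view: one row per
#'   ordered genome pair with its containment value.
#' @param x a `common_kmer_matrix`.
#' @param ... unused.
#' @export
tidy.common_kmer_matrix <- function(x, ...) {
  ids <- x$genome_ids
  tibble(
    genome_i = rep(ids, times = length(ids)),
    genome_j = rep(ids, each = length(ids)),
    pckm = as.vector(x$values)
  )
}

#' Write / read a common k-mer matrix as CSV
#'
#' Plain CSV with genome ids as header row and first column; `k` is stored
#' in a `# k=<k>` comment on the first line.
#'
#' @param x a `common_kmer_matrix`.
#' @param path file path.
#' @return `write_ckm_csv` returns `path` invisibly; `read_ckm_csv` returns
#'   the matrix object.
#' @export
write_ckm_csv <- function(x, path) {
  stopifnot(inherits(x, "common_kmer_matrix"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# k=", x$k), con)
  df <- data.frame(genome_id = x$genome_ids, x$values, check.names = FALSE)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ckm_csv
#' @export
read_ckm_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# k=", first)) abort("not a common k-mer matrix CSV (missing # k= header)")
  k <- as.integer(sub("^# k=", "", first))
  df <- read.table(path, sep = ",", header = TRUE, skip = 1L,
                   check.names = FALSE, colClasses = c(genome_id = "character"))
  ids <- df$genome_id
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(ids, ids)
  new_common_kmer_matrix(k, ids, vals)
}
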