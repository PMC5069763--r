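#' Hypothetical-organism columns at one similarity bin
#'
#' A hypothetical organism "h-similar" to genome *i* has genome *i*'s
#' 30-mer containment column capped at `h` (entries above `h` are rounded
#' down; entries already below are untouched, preserving the genome's
#' k-mer sharing pattern with more distant outgroup taxa). Its 50-mer
#' column is the polynomial image of the capped 30-mer column — the cap is
#' applied before the map, so the two k-mer sizes describe the same
#' hypothetical organism.
#'
#' @param col30 genome *i*'s column of the 30-mer matrix (length M, values
#'   in `[0, 1]`).
#' @param h similarity bin in `(0, 1)`.
#' @param p a [similarity_polynomial()].
#' @return list with `col30_h` (capped) and `col50_h` (polynomial image).
#' @export
make_hypothetical_columns <- function(col30, h, p = similarity_polynomial()) {
  stopifnot(is.numeric(col30))
  if (length(h) != 1 || h <= 0 || h >= 1) abort("`h` must lie strictly in (0, 1)")
  if (any(col30 < 0 | col30 > 1)) abort("`col30` entries must lie in [0, 1]")
  col30_h <- pmin(h, col30)
  list(col30_h = col30_h, col50_h = eval_polynomial(p, col30_h))
}

#' Assemble the stacked two-k-mer mixture system
#'
#' Stacks the 30-mer and 50-mer common k-mer matrices row-wise and appends,
#' for each similarity bin, one hypothetical column per genome (see
#' [make_hypothetical_columns()]). With the default nine bins the result is
#' the 2M-by-10M system whose nonnegative solution is the organism
#' abundance vector.
#'
#' @param A30,A50 `common_kmer_matrix` objects at k = 30 and k = 50 (any
#'   strictly increasing k pair is accepted) over the same genomes in the
#'   same order.
#' @param p the similarity polynomial linking the two k sizes.
#' @param bins decreasing similarity levels in `(0, 1)`;
#'   default `0.9, 0.8, ..., 0.1`.
#' @return an `augmented_system`: list with `matrix` (2M x M(1+|bins|)),
#'   `col_meta` tibble (`column`, `genome_id`, `genome_index`, `bin` — bin
#'   1 marks the unthresholded reference column), `bins`, `genome_ids`,
#'   `k_sizes`.
#' @export
assemble_system <- function(A30, A50, p = similarity_polynomial(),
                            bins = seq(0.9, 0.1, by = -0.1)) {
  stopifnot(inherits(A30, "common_kmer_matrix"), inherits(A50, "common_kmer_matrix"))
  if (!identical(A30$genome_ids, A50$genome_ids)) {
    abort("the two matrices cover different genomes (or a different order)")
  }
  if (length(bins) > 0 && (any(bins <= 0 | bins >= 1) || is.unsorted(rev(bins), strictly = TRUE))) {
    abort("`bins` must be strictly decreasing values in (0, 1)")
  }
  ids <- A30$genome_ids
  M <- length(ids)
  blocks30 <- vector("list", 1 + length(bins))
  blocks50 <- vector("list", 1 + length(bins))
  blocks30[[1]] <- A30$values
  blocks50[[1]] <- A50$values
  for (b in seq_along(bins)) {
    cols <- lapply(seq_len(M), function(j) {
      make_hypothetical_columns(A30$values[, j], bins[b], p)
    })
    blocks30[[b + 1]] <- do.call(cbind, lapply(cols, `[[`, "col30_h"))
    blocks50[[b + 1]] <- do.call(cbind, lapply(cols, `[[`, "col50_h"))
  }
  mat <- rbind(do.call(cbind, blocks30), do.call(cbind, blocks50))
  col_meta <- tibble(
    column = seq_len(M * (1 + length(bins))),
    genome_id = rep(ids, times = 1 + length(bins)),
    genome_index = rep(seq_len(M), times = 1 + length(bins)),
    bin = rep(c(1, bins), each = M)
  )
  colnames(mat) <- paste0(col_meta$genome_id, "@", col_meta$bin)
  structure(
    list(matrix = mat, col_meta = col_meta, bins = bins, genome_ids = ids,
         k_sizes = c(A30$k, A50$k), polynomial = p),
    class = "augmented_system"
  )
}

#' @export
print.augmented_system <- function(x, ...) {
  cat("<augmented_system>", nrow(x$matrix), "x", ncol(x$matrix),
      "| k =", paste(x$k_sizes, collapse = "/"),
      "|", length(x$genome_ids), "genomes,", length(x$bins), "bins\n")
  invisible(x)
}

#' @export
tidy.augmented_system <- function(x, ...) x$col_meta
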