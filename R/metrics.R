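#' Profile divergence
#'
#' Signed sum of log2 ratios of predicted to true taxon frequency over the
#' taxa positive in both profiles:
#' `sum over {i : x_true[i] > 0 and x_pred[i] > 0} of log2(x_pred[i] / x_true[i])`.
#' With `absolute = TRUE` the absolute value of each term is summed
#' instead, so over- and under-estimates cannot cancel.
#'
#' @param x_true,x_pred aligned nonnegative vectors over a shared taxon
#'   index at one rank.
#' @param absolute sum `|log2|` terms instead of signed terms.
#' @return real; 0 (with a warning) when no taxon is positive in both.
#' @export
divergence <- function(x_true, x_pred, absolute = FALSE) {
  stopifnot(is.numeric(x_true), is.numeric(x_pred))
  if (length(x_true) != length(x_pred)) abort("profiles have different lengths")
  if (any(x_true < 0) || any(x_pred < 0)) abort("profile entries must be nonnegative")
  both <- x_true > 0 & x_pred > 0
  if (!any(both)) {
    warn("no taxon is positive in both profiles; divergence is 0")
    return(0)
  }
  terms <- log2(x_pred[both] / x_true[both])
  if (absolute) sum(abs(terms)) else sum(terms)
}

#' False-positive taxon count
#'
#' Number of taxa predicted present (`x_pred > 0`) but truly absent
#' (`x_true == 0`). Invariant to rescaling of either profile.
#'
#' @inheritParams divergence
#' @return nonnegative integer.
#' @export
false_positives <- function(x_true, x_pred) {
  stopifnot(is.numeric(x_true), is.numeric(x_pred))
  if (length(x_true) != length(x_pred)) abort("profiles have different lengths")
  sum(x_pred > 0 & x_true == 0)
}

#' Compare two taxonomic profiles at one rank
#'
#' Aligns a truth and a predicted `tax_profile` by taxid at the chosen
#' rank (unmatched taxa get 0 on the missing side) and reports the
#' divergence, absolute divergence and false-positive count.
#'
#' @param truth,pred `tax_profile` objects (see [read_profile()]).
#' @param rank rank at which to compare, e.g. `"genus"`.
#' @return one-row tibble with `rank`, `n_taxa`, `divergence`,
#'   `divergence_abs`, `false_positives`.
#' @export
compare_profiles <- function(truth, pred, rank = "genus") {
  tt <- dplyr::filter(as_tibble(truth), .data$rank == !!rank)
  pp <- dplyr::filter(as_tibble(pred), .data$rank == !!rank)
  taxa <- union(tt$taxid, pp$taxid)
  x_true <- setNames(rep(0, length(taxa)), taxa)
  x_pred <- x_true
  x_true[tt$taxid] <- tt$percentage
  x_pred[pp$taxid] <- pp$percentage
  tibble(
    rank = rank,
    n_taxa = length(taxa),
    divergence = suppressWarnings(divergence(x_true, x_pred)),
    divergence_abs = suppressWarnings(divergence(x_true, x_pred, absolute = TRUE)),
    false_positives = false_positives(x_true, x_pred)
  )
}
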