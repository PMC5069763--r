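#' Sparsity-promoting nonnegative deconvolution
#'
#' Solves `min ||z||_1^2 + lambda^2 ||A z - y||_2^2  s.t. z >= 0`, the
#' nonnegative basis-pursuit-denoising surrogate whose large-`lambda` limit
#' is the nonnegative minimum-l1 solution of `A z = y`. The problem reduces
#' exactly to nonnegative least squares on the augmented pair
#' `A~ = rbind(1, lambda * A)`, `y~ = c(0, lambda * y)`, which is solved by
#' the Lawson–Hanson active-set algorithm. Deterministic for fixed input.
#'
#' @param A numeric matrix (typically an `augmented_system`'s matrix, or
#'   the object itself).
#' @param y numeric vector, `length(y) == nrow(A)`.
#' @param lam regularization weight `> 0`; default 200 trades sparsity
#'   against fit of the k-mer counts.
#' @return an `abundance_solution`: list with nonnegative `x` aligned with
#'   the columns of `A` (and with `col_meta` when an `augmented_system` was
#'   given), `lam`, and `residual` = `||Ax - y||_2`.
#' @export
solve_nnreg <- function(A, y, lam = 200) {
  col_meta <- NULL
  if (inherits(A, "augmented_system")) {
    col_meta <- A$col_meta
    A <- A$matrix
  }
  stopifnot(is.matrix(A), is.numeric(y))
  if (nrow(A) != length(y)) abort("nrow(A) must equal length(y)")
  if (length(lam) != 1 || lam <= 0) abort("`lam` must be a positive scalar")
  if (all(y == 0)) {
    x <- setNames(numeric(ncol(A)), colnames(A))
  } else {
    A_aug <- rbind(rep(1, ncol(A)), lam * A)
    y_aug <- c(0, lam * y)
    x <- pracma::lsqnonneg(A_aug, y_aug)$x
    x <- pmax(x, 0)
    names(x) <- colnames(A)
  }
  structure(
    list(x = x, lam = lam,
         residual = sqrt(sum((A %*% x - y)^2)),
         col_meta = col_meta),
    class = "abundance_solution"
  )
}

#' @export
print.abundance_solution <- function(x, ...) {
  cat("<abundance_solution>", sum(x$x > 0), "of", length(x$x),
      "columns active | lambda =", x$lam,
      "| residual =", signif(x$residual, 4), "\n")
  invisible(x)
}

#' @export
tidy.abundance_solution <- function(x, ...) {
  out <- tibble(column = seq_along(x$x), abundance = unname(x$x))
  if (!is.null(x$col_meta)) {
    out <- left_join(x$col_meta, out, by = "column")
  }
  out
}

#' @export
glance.abundance_solution <- function(x, ...) {
  tibble(lambda = x$lam, residual = x$residual,
         n_active = sum(x$x > 0), l1 = sum(x$x))
}

#' Solution view: abundance by genome and similarity bin
#'
#' @param object an `abundance_solution` solved on an `augmented_system`.
#' @param ... unused.
#' @return a ggplot of nonzero column abundances, faceted impression by
#'   bin via fill.
#' @export
autoplot.abundance_solution <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$abundance > 0)
  ggplot(df, aes(x = .data$genome_id, y = .data$abundance,
                 fill = factor(.data$bin))) +
    geom_col() +
    labs(x = NULL, y = "abundance", fill = "bin") +
    theme_minimal()
}

#' Prune and renormalize a deconvolution solution
#'
#' Zeroes entries below `eps * max(x)` and rescales the survivors to sum
#' to 1, yielding relative organism proportions per (genome, bin) column.
#'
#' @param sol an `abundance_solution`.
#' @param eps relative pruning threshold (>= 0), default `1e-4`.
#' @return tibble with `genome_id`, `genome_index`, `bin` (1 = reference
#'   column) and `abundance` summing to 1 — or zero rows (with a warning)
#'   if everything was pruned.
#' @export
postprocess_abundances <- function(sol, eps = 1e-4) {
  stopifnot(inherits(sol, "abundance_solution"))
  if (length(eps) != 1 || eps < 0) abort("`eps` must be a nonnegative scalar")
  x <- sol$x
  keep <- x >= eps * max(x) & x > 0
  if (!any(keep)) {
    warn("all abundance entries pruned; returning an empty table")
    return(tibble(genome_id = character(), genome_index = integer(),
                  bin = numeric(), abundance = numeric()))
  }
  x[!keep] <- 0
  x <- x / sum(x)
  meta <- sol$col_meta
  if (is.null(meta)) {
    meta <- tibble(column = seq_along(x),
                   genome_id = as.character(seq_along(x)),
                   genome_index = seq_along(x), bin = 1)
  }
  meta |>
    mutate(abundance = unname(x)) |>
    filter(.data$abundance > 0) |>
    select("genome_id", "genome_index", "bin", "abundance") |>
    arrange(.data$genome_index, dplyr::desc(.data$bin))
}
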