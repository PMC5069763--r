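#' The 30-mer / 50-mer similarity link polynomial
#'
#' A cubic through the origin, `p(x) = c3*x^3 + c2*x^2 + c1*x`, predicting
#' 50-mer containment from 30-mer containment between two genomes. The
#' default coefficients are the published fit over a large bacterial
#' database; they are only meaningful for the (30, 50) k-mer size pair.
#'
#' @param c3,c2,c1 coefficients (cubic, quadratic, linear).
#' @param rmse,r_squared,n_pairs optional fit diagnostics (filled by
#'   [fit_similarity_polynomial()]).
#' @return a `similarity_polynomial` object.
#' @export
similarity_polynomial <- function(c3 = -0.5141, c2 = 1.0932, c1 = 0.3824,
                                  rmse = NA_real_, r_squared = NA_real_,
                                  n_pairs = NA_integer_) {
  structure(
    list(coeffs = c(c3 = c3, c2 = c2, c1 = c1), rmse = rmse,
         r_squared = r_squared, n_pairs = n_pairs),
    class = "similarity_polynomial"
  )
}

#' @export
print.similarity_polynomial <- function(x, ...) {
  cf <- x$coeffs
  cat(sprintf("<similarity_polynomial> p(x) = %.4f x^3 + %.4f x^2 + %.4f x\n",
              cf["c3"], cf["c2"], cf["c1"]))
  if (!is.na(x$rmse)) cat(sprintf("  fit: RMSE %.4g, R^2 %.4g on %d pairs\n",
                                  x$rmse, x$r_squared, x$n_pairs))
  invisible(x)
}

#' @export
tidy.similarity_polynomial <- function(x, ...) {
  tibble(term = c("x^3", "x^2", "x"), estimate = unname(x$coeffs))
}

#' @export
glance.similarity_polynomial <- function(x, ...) {
  tibble(rmse = x$rmse, r.squared = x$r_squared, n_pairs = x$n_pairs)
}

#' Curve view of the similarity link polynomial
#'
#' @param object a `similarity_polynomial`.
#' @param ... unused.
#' @return a ggplot of p over `[0, 1]` with the identity for reference.
#' @export
autoplot.similarity_polynomial <- function(object, ...) {
  x <- seq(0, 1, by = 0.01)
  df <- tibble(s30 = x, s50 = eval_polynomial(object, x))
  ggplot(df, aes(x = .data$s30, y = .data$s50)) +
    geom_line(color = "steelblue") +
    geom_line(aes(y = .data$s30), linetype = "dashed", color = "grey50") +
    labs(x = "30-mer containment", y = "predicted 50-mer containment") +
    theme_minimal()
}

#' Evaluate the similarity polynomial
#'
#' @param p a `similarity_polynomial`.
#' @param x values in `[0, 1]` (30-mer containment).
#' @return `p(x)` clipped to `[0, 1]`; `p(0) == 0` by construction.
#' @export
eval_polynomial <- function(p, x) {
  stopifnot(inherits(p, "similarity_polynomial"), is.numeric(x))
  if (any(x < 0 | x > 1)) abort("polynomial input must lie in [0, 1]")
  cf <- p$coeffs
  pmin(1, pmax(0, cf[["c3"]] * x^3 + cf[["c2"]] * x^2 + cf[["c1"]] * x))
}

#' Fit the similarity polynomial from paired containment values
#'
#' No-intercept least squares of `s50` on `(s30^3, s30^2, s30)`; the zero
#' constant term guarantees `p(0) = 0` (genomes sharing no 30-mers share no
#' 50-mers).
#'
#' @param pairs data frame with columns `s30` and `s50`, all in `[0, 1]`;
#'   at least 3 distinct design points are required.
#' @return a `similarity_polynomial` with `rmse`, `r_squared`, `n_pairs`.
#' @export
fit_similarity_polynomial <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("s30", "s50") %in% names(pairs))) {
    abort("`pairs` needs columns `s30` and `s50`")
  }
  if (nrow(pairs) < 3) abort("at least 3 (s30, s50) pairs are required")
  if (any(pairs$s30 < 0 | pairs$s30 > 1 | pairs$s50 < 0 | pairs$s50 > 1)) {
    abort("containment values must lie in [0, 1]")
  }
  X <- cbind(pairs$s30^3, pairs$s30^2, pairs$s30)
  if (qr(X)$rank < 3) abort("design is rank-deficient: need >= 3 distinct s30 levels")
  fit <- stats::lm.fit(X, pairs$s50)
  cf <- unname(fit$coefficients)
  res <- fit$residuals
  tss <- sum((pairs$s50 - mean(pairs$s50))^2)
  similarity_polynomial(
    c3 = cf[1], c2 = cf[2], c1 = cf[3],
    rmse = sqrt(mean(res^2)),
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    n_pairs = nrow(pairs)
  )
}
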