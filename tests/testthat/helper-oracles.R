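# Independent oracles: deliberately naive, shared by unit and acceptance
# tests. They never call the package's counting or solving paths.

# all length-k windows of a set of sequences, dropping non-ACGT windows
naive_windows <- function(seqs, k, canonical = FALSE) {
  out <- character(0)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    w <- substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    w <- w[!grepl("[^ACGT]", w)]
    out <- c(out, w)
  }
  if (canonical && length(out) > 0) {
    rc <- kmerpalette::revcomp(out)
    out <- pmin(out, rc)
  }
  out
}

# brute-force containment: fraction of j's windows present in i's window set
naive_pckm <- function(seq_i, seq_j, k, canonical = FALSE) {
  wi <- naive_windows(seq_i, k, canonical)
  wj <- naive_windows(seq_j, k, canonical)
  sum(wj %in% unique(wi)) / length(wj)
}

# projected-gradient (FISTA) solver for min ||Bz - c||^2, z >= 0; run to
# tight tolerance on small systems as the convex-optimization oracle
pg_nnls <- function(B, c, max_iter = 200000, tol = 1e-12) {
  L <- norm(B, "2")^2
  z <- rep(0, ncol(B))
  v <- z
  t_prev <- 1
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    grad <- 2 * crossprod(B, B %*% v - c)
    z_new <- pmax(0, v - as.vector(grad) / (2 * L))
    t_new <- (1 + sqrt(1 + 4 * t_prev^2)) / 2
    v <- z_new + ((t_prev - 1) / t_new) * (z_new - z)
    z <- z_new
    t_prev <- t_new
    if (it %% 500 == 0) {
      obj <- sum((B %*% z - c)^2)
      if (abs(obj_prev - obj) < tol * max(1, obj)) break
      obj_prev <- obj
    }
  }
  z
}

# NNREG objective for a given solution
nnreg_objective <- function(A, y, z, lam) {
  sum(z)^2 + lam^2 * sum((A %*% z - y)^2)
}
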