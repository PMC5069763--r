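#' Distance matrix from the two common k-mer matrices
#'
#' Averages the 30-mer and 50-mer matrices, symmetrizes (the containment
#' score is asymmetric), and maps similarity to distance as
#' `D = 1 - (S + t(S)) / 2`, so identical genomes are at distance 0.
#'
#' @param A30,A50 `common_kmer_matrix` objects over the same genomes.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
similarity_to_distance <- function(A30, A50) {
  stopifnot(inherits(A30, "common_kmer_matrix"), inherits(A50, "common_kmer_matrix"))
  if (!identical(A30$genome_ids, A50$genome_ids)) {
    abort("the two matrices cover different genomes (or a different order)")
  }
  S <- (A30$values + A50$values) / 2
  D <- 1 - (S + t(S)) / 2
  diag(D) <- 0
  D
}

#' Neighbor-joining strain tree
#'
#' Standard Saitou–Nei agglomeration on a symmetric distance matrix;
#' negative branch lengths (a known NJ artifact) are clamped to 0.
#' Degenerate sizes are handled directly: one leaf gives a single-node
#' tree, two leaves a single edge.
#'
#' @param D symmetric numeric matrix with nonnegative off-diagonal entries
#'   and row/column names (the genome ids).
#' @return a `strain_tree`: list with `phylo` (the [ape] tree) and an empty
#'   `placements` tibble.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-9) abort("distance matrix must be symmetric")
  if (any(D[upper.tri(D)] < 0)) abort("distances must be nonnegative")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(D)))
  n <- nrow(D)
  if (n == 1) {
    phy <- ape::read.tree(text = paste0("(", ids[1], ":0);"))
  } else if (n == 2) {
    phy <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         ids[1], D[1, 2] / 2, ids[2], D[1, 2] / 2))
  } else {
    phy <- ape::nj(stats::as.dist(D))
    phy$edge.length <- pmax(phy$edge.length, 0)
  }
  new_strain_tree(phy)
}

new_strain_tree <- function(phylo, placements = NULL) {
  if (is.null(placements)) {
    placements <- tibble(genome_id = character(), bin = numeric(),
                         mass = numeric(), edge = integer(),
                         position = numeric(), side = character())
  }
  structure(list(phylo = phylo, placements = placements), class = "strain_tree")
}

#' @export
print.strain_tree <- function(x, ...) {
  cat("<strain_tree>", length(x$phylo$tip.label), "leaves,",
      nrow(x$placements), "placements\n")
  invisible(x)
}

#' @export
tidy.strain_tree <- function(x, ...) x$placements

#' Place solved mass onto the strain tree
#'
#' Reference-column mass attaches at its genome's leaf. Hypothetical mass
#' for (genome *i*, bin `h`) attaches on the path between leaf *i* and the
#' most recent common ancestor of *i* and its matched partner *j* (found as
#' in [map_hypothetical()]), with the tree midpoint-rooted for
#' orientation: at the ancestor node when `h` equals the observed
#' containment `A30[i, j]`, strictly toward the leaf ("below" the LCA)
#' when `h` is larger (the organism is closer to *i* than *j* is), and
#' strictly toward the root ("above") when `h` is smaller. The strict
#' offsets sit 25% along the adjacent edge (a display convention).
#'
#' @param tree a `strain_tree` over the training genomes.
#' @param abundances tibble from [postprocess_abundances()].
#' @param A30 the 30-mer `common_kmer_matrix`.
#' @param delta partner-matching half-width, see [map_hypothetical()].
#' @return the `strain_tree` with a filled `placements` tibble
#'   (`genome_id`, `bin`, `mass`, `node`, `edge`, `position` in `[0, 1]`
#'   from child end, `side`).
#' @export
place_hypotheticals <- function(tree, abundances, A30, delta = 0.05) {
  stopifnot(inherits(tree, "strain_tree"))
  phy <- tree$phylo
  if (length(phy$tip.label) >= 3) phy <- phangorn::midpoint(phy)
  ids <- A30$genome_ids
  rows <- list()
  for (r in seq_len(nrow(abundances))) {
    gid <- abundances$genome_id[r]
    h <- abundances$bin[r]
    mass <- abundances$abundance[r]
    tip <- match(gid, phy$tip.label)
    if (is.na(tip)) next
    if (h >= 1) {
      rows[[length(rows) + 1L]] <- tibble(
        genome_id = gid, bin = 1, mass = mass, node = tip,
        edge = NA_integer_, position = 0, side = "leaf")
      next
    }
    i <- match(gid, ids)
    sims <- A30$values[i, -i]
    j <- ids[-i][which.min(abs(sims - h))]
    a_ij <- A30$values[i, match(j, ids)]
    tipj <- match(j, phy$tip.label)
    anc <- if (is.na(tipj) || length(phy$tip.label) < 2) tip else
      ape::getMRCA(phy, c(tip, tipj))
    if (is.null(anc) || length(anc) == 0) anc <- tip
    path <- ape::nodepath(phy, tip, anc)
    if (abs(h - a_ij) < 1e-9 || length(path) < 2) {
      # at the ancestor node itself
      rows[[length(rows) + 1L]] <- tibble(
        genome_id = gid, bin = h, mass = mass, node = anc,
        edge = NA_integer_, position = 0, side = "at")
    } else if (h > a_ij) {
      # below the LCA: toward the leaf, on the first edge under the ancestor
      child <- path[length(path) - 1L]
      e <- which(phy$edge[, 1] == anc & phy$edge[, 2] == child)
      rows[[length(rows) + 1L]] <- tibble(
        genome_id = gid, bin = h, mass = mass, node = child,
        edge = as.integer(e[1]), position = 0.25, side = "below")
    } else {
      # above the LCA: toward the root, on the ancestor's parent edge
      e <- which(phy$edge[, 2] == anc)
      parent <- if (length(e) > 0) phy$edge[e[1], 1] else anc
      rows[[length(rows) + 1L]] <- tibble(
        genome_id = gid, bin = h, mass = mass, node = parent,
        edge = if (length(e) > 0) as.integer(e[1]) else NA_integer_,
        position = 0.75, side = "above")
    }
  }
  new_strain_tree(phy, bind_rows(rows))
}

#' Export a strain tree as Newick plus a placements TSV
#'
#' @param tree a `strain_tree`.
#' @param newick_path Newick output path.
#' @param placements_path optional TSV path for the placements table.
#' @export
write_strain_tree <- function(tree, newick_path, placements_path = NULL) {
  stopifnot(inherits(tree, "strain_tree"))
  ape::write.tree(tree$phylo, file = newick_path)
  if (!is.null(placements_path)) {
    write.table(as.data.frame(tree$placements), placements_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(newick_path)
}

#' Plot a strain tree with placed hypothetical mass
#'
#' Base-graphics plot ([ape::plot.phylo()]) with placement points scaled by
#' mass; bins are printed beside the points.
#'
#' @param x a `strain_tree`.
#' @param ... passed to [ape::plot.phylo()].
#' @method plot strain_tree
#' @export
plot.strain_tree <- function(x, ...) {
  ape::plot.phylo(x$phylo, ...)
  pl <- x$placements
  if (nrow(pl) > 0) {
    last <- get("last_plot.phylo", envir = ape::.PlotPhyloEnv)
    for (r in seq_len(nrow(pl))) {
      node <- pl$node[r]
      graphics::points(last$xx[node], last$yy[node],
                       cex = 0.5 + 3 * sqrt(pl$mass[r]), pch = 21,
                       bg = grDevices::adjustcolor("firebrick", 0.6))
      graphics::text(last$xx[node], last$yy[node],
                     labels = sprintf("h=%.1f", pl$bin[r]), pos = 3, cex = 0.7)
    }
  }
  invisible(x)
}
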