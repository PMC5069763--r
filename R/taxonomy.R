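#' Fixed-rank taxonomy table
#'
#' Maps each training genome to a complete lineage over the eight fixed
#' ranks superkingdom, phylum, class, order, family, genus, species,
#' strain. Lineages are pipe-separated taxid and name paths; placeholder
#' taxids are allowed but every genome must resolve down to strain.
#'
#' @param genome_id character vector of genome ids.
#' @param taxpath pipe-separated taxid paths (8 fields each).
#' @param taxpath_names pipe-separated name paths (8 fields each).
#' @return a `taxonomy_table` tibble.
#' @export
taxonomy_table <- function(genome_id, taxpath, taxpath_names) {
  tab <- tibble(genome_id = as.character(genome_id),
                taxpath = as.character(taxpath),
                taxpath_names = as.character(taxpath_names))
  if (anyDuplicated(tab$genome_id)) abort("duplicate genome_id in taxonomy")
  nfld <- function(x) lengths(strsplit(x, "|", fixed = TRUE))
  bad <- nfld(tab$taxpath) != length(PALETTE_RANKS) |
    nfld(tab$taxpath_names) != length(PALETTE_RANKS)
  if (any(bad)) {
    abort(paste0("incomplete lineage (need ", length(PALETTE_RANKS),
                 " ranks) for: ", paste(tab$genome_id[bad], collapse = ", ")))
  }
  class(tab) <- c("taxonomy_table", class(tab))
  tab
}

#' Read / write a taxonomy table as TSV
#'
#' Three tab-separated columns: `genome_id`, `taxpath` (pipe-separated
#' taxids, superkingdom to strain), `taxpath_names`.
#'
#' @param path file path.
#' @export
read_taxonomy <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE, comment.char = "")
  taxonomy_table(df$genome_id, df$taxpath, df$taxpath_names)
}

#' @rdname read_taxonomy
#' @param taxonomy a `taxonomy_table`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(as.data.frame(taxonomy), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# lineage of one genome as a named character vector (rank -> taxid)
lineage_of <- function(taxonomy, genome_id, what = c("taxpath", "taxpath_names")) {
  what <- match.arg(what)
  row <- which(taxonomy$genome_id == genome_id)
  if (length(row) != 1) abort(paste0("genome not in taxonomy: ", genome_id))
  setNames(strsplit(taxonomy[[what]][row], "|", fixed = TRUE)[[1]], PALETTE_RANKS)
}

#' Least common ancestor of two lineages
#'
#' The deepest rank at which two complete fixed-rank lineages carry the
#' same taxid. Returns depth 0 (`rank = "root"`) when even the
#' superkingdoms differ.
#'
#' @param lineage_a,lineage_b character vectors of taxids over the fixed
#'   ranks (as from lineages in a [taxonomy_table()]).
#' @return list with `rank` (name or `"root"`), `depth` (0–8), `taxid`.
#' @export
lca_rank <- function(lineage_a, lineage_b) {
  nr <- length(PALETTE_RANKS)
  if (length(lineage_a) != nr || length(lineage_b) != nr) {
    abort("lineages must cover all fixed ranks")
  }
  agree <- lineage_a == lineage_b & nzchar(lineage_a)
  depth <- if (!agree[1]) 0L else max(which(cumsum(!agree) == 0))
  list(
    rank = if (depth == 0) "root" else PALETTE_RANKS[depth],
    depth = depth,
    taxid = if (depth == 0) NA_character_ else unname(lineage_a[depth])
  )
}

# fixed-rank depth for a similarity bin: 1 -> strain, 0.9 -> species, ...
fixed_rank_depth <- function(h) {
  if (h >= 1) return(8L)
  depth <- 8L - round((1 - h) * 10)
  max(1L, as.integer(depth))
}

#' Map a hypothetical column to a taxon
#'
#' A solved hypothetical column (genome *i*, bin `h`) represents an
#' organism whose 30-mer containment with genome *i* is `h`. To name it,
#' find a partner genome *j* whose containment with *i* is closest to `h`
#' (within `delta` if possible, else the global nearest) and assign the
#' least common ancestor of the two lineages; an organism as similar to
#' *i* as *j* is plausibly in their shared clade. Reference columns
#' (`h = 1`) map to genome *i*'s strain.
#'
#' @param genome_index index of genome *i* (1-based).
#' @param h similarity bin; `1` for the reference column.
#' @param A30 the 30-mer `common_kmer_matrix` (bins are defined on 30-mer
#'   similarity).
#' @param taxonomy a [taxonomy_table()].
#' @param delta matching half-width on containment (default 0.05).
#' @param mode `"default"` (LCA), `"sensitive"` (deeper of LCA and the
#'   fixed-rank map), or `"specific"` (shallower of the two).
#' @return list with `rank`, `depth`, `taxid`, `partner` (genome id or NA).
#' @export
map_hypothetical <- function(genome_index, h, A30, taxonomy, delta = 0.05,
                             mode = c("default", "sensitive", "specific")) {
  mode <- match.arg(mode)
  if (delta <= 0) abort("`delta` must be positive")
  ids <- A30$genome_ids
  gid <- ids[genome_index]
  lin_i <- lineage_of(taxonomy, gid)
  if (h >= 1) {
    return(list(rank = "strain", depth = 8L, taxid = unname(lin_i["strain"]),
                partner = gid))
  }
  if (h <= 0) abort("`h` must be positive")
  M <- length(ids)
  if (M == 1) {
    depth <- fixed_rank_depth(h)
    return(list(rank = PALETTE_RANKS[depth], depth = depth,
                taxid = unname(lin_i[depth]), partner = NA_character_))
  }
  sims <- A30$values[genome_index, -genome_index]
  others <- ids[-genome_index]
  gap <- abs(sims - h)
  j <- others[which.min(gap)]  # within delta when possible, else nearest
  lca <- lca_rank(lin_i, lineage_of(taxonomy, j))
  depth <- lca$depth
  if (mode != "default") {
    fr <- fixed_rank_depth(h)
    depth <- if (mode == "sensitive") max(depth, fr) else min(depth, fr)
  }
  list(
    rank = if (depth == 0) "root" else PALETTE_RANKS[depth],
    depth = depth,
    taxid = if (depth == 0) NA_character_ else unname(lin_i[depth]),
    partner = j
  )
}

#' Build a rank-wise taxonomic profile
#'
#' Assigns every abundance entry a taxon and rank — reference columns to
#' their genome's strain, hypothetical columns per [map_hypothetical()] —
#' then sums mass upward so each taxon's ancestors carry at least its
#' mass. Mass assigned above strain (or at root) is left unassigned at the
#' deeper ranks, so per-rank percentages sum to at most 100.
#'
#' @param abundances tibble from [postprocess_abundances()] (columns
#'   `genome_id`, `genome_index`, `bin`, `abundance` summing to 1).
#' @param taxonomy a [taxonomy_table()].
#' @param A30 the 30-mer `common_kmer_matrix`.
#' @param mode assignment scheme, see [map_hypothetical()].
#' @param delta see [map_hypothetical()].
#' @param sample_id label stored in the profile header.
#' @return a `tax_profile` tibble with columns `rank`, `taxid`, `taxpath`,
#'   `taxpath_names`, `percentage` (0–100).
#' @export
build_profile <- function(abundances, taxonomy, A30,
                          mode = c("default", "sensitive", "specific"),
                          delta = 0.05, sample_id = "sample") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(abundances))
  if (nrow(abundances) == 0) {
    return(new_tax_profile(tibble(rank = character(), taxid = character(),
                                  taxpath = character(), taxpath_names = character(),
                                  percentage = numeric()), sample_id))
  }
  total <- sum(abundances$abundance)
  if (abs(total - 1) > 1e-6) abort("abundances must be normalized to sum to 1")

  acc <- list()
  for (r in seq_len(nrow(abundances))) {
    gi <- abundances$genome_index[r]
    h <- abundances$bin[r]
    mass <- abundances$abundance[r]
    asg <- map_hypothetical(gi, h, A30, taxonomy, delta, mode)
    if (asg$depth == 0) next  # no shared clade: fully unassigned
    tax_ids <- lineage_of(taxonomy, A30$genome_ids[gi], "taxpath")
    tax_nms <- lineage_of(taxonomy, A30$genome_ids[gi], "taxpath_names")
    for (d in seq_len(asg$depth)) {
      acc[[length(acc) + 1L]] <- tibble(
        rank = PALETTE_RANKS[d],
        taxid = unname(tax_ids[d]),
        taxpath = paste(tax_ids[seq_len(d)], collapse = "|"),
        taxpath_names = paste(tax_nms[seq_len(d)], collapse = "|"),
        percentage = 100 * mass
      )
    }
  }
  entries <- bind_rows(acc)
  if (nrow(entries) > 0) {
    entries <- entries |>
      group_by(.data$rank, .data$taxid, .data$taxpath, .data$taxpath_names) |>
      summarise(percentage = sum(.data$percentage), .groups = "drop") |>
      mutate(rank = factor(.data$rank, levels = PALETTE_RANKS)) |>
      arrange(.data$rank, dplyr::desc(.data$percentage)) |>
      mutate(rank = as.character(.data$rank))
  }
  new_tax_profile(entries, sample_id)
}

new_tax_profile <- function(entries, sample_id) {
  out <- as_tibble(entries)
  attr(out, "sample_id") <- sample_id
  attr(out, "ranks") <- PALETTE_RANKS
  class(out) <- c("tax_profile", class(out))
  out
}

#' @export
print.tax_profile <- function(x, ...) {
  cat("<tax_profile> sample:", attr(x, "sample_id"), "\n")
  NextMethod()
}

#' Write / read a Bioboxes v0.9 taxonomic profile
#'
#' Tab-separated exchange format: `@`-prefixed header lines (`@SampleID`,
#' `@Version:0.9.1`, `@Ranks:...`), a `@@`-prefixed column header, then one
#' row per taxon with TAXID, RANK, TAXPATH, TAXPATHSN and PERCENTAGE.
#'
#' @param profile a `tax_profile`.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "tax_profile"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("@SampleID:", attr(profile, "sample_id")),
    "@Version:0.9.1",
    paste0("@Ranks:", paste(PALETTE_RANKS, collapse = "|")),
    "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE"
  ), con)
  if (nrow(profile) > 0) {
    writeLines(sprintf("%s\t%s\t%s\t%s\t%.10g",
                       profile$taxid, profile$rank, profile$taxpath,
                       profile$taxpath_names, profile$percentage), con)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  sid <- sub("^@SampleID:", "", grep("^@SampleID:", lines, value = TRUE)[1])
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0) {
    return(new_tax_profile(tibble(rank = character(), taxid = character(),
                                  taxpath = character(), taxpath_names = character(),
                                  percentage = numeric()), sid))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  entries <- tibble(
    rank = vapply(fields, `[[`, "", 2),
    taxid = vapply(fields, `[[`, "", 1),
    taxpath = vapply(fields, `[[`, "", 3),
    taxpath_names = vapply(fields, `[[`, "", 4),
    percentage = as.numeric(vapply(fields, `[[`, "", 5))
  )
  new_tax_profile(entries, sid)
}

#' Bar-chart view of a taxonomic profile
#'
#' @param object a `tax_profile`.
#' @param rank single rank to show, default `"species"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tax_profile <- function(object, rank = "species", ...) {
  df <- dplyr::filter(as_tibble(object), .data$rank == !!rank)
  nm <- vapply(strsplit(df$taxpath_names, "|", fixed = TRUE),
               function(v) v[length(v)], "")
  df$label <- ifelse(nzchar(nm), nm, df$taxid)
  ggplot(df, aes(x = stats::reorder(.data$label, -.data$percentage),
                 y = .data$percentage)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "relative abundance (%)",
         title = paste0(attr(object, "sample_id"), " — ", rank)) +
    theme_minimal()
}
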