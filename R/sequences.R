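#' Sequence records as a tibble
#'
#' The package's working representation of sequence data is a tibble with an
#' `id` column and a `seq` column (plus an optional `qual` column holding
#' Phred+33 quality strings for FASTQ input). This coercer accepts a
#' character vector (optionally named), a `Biostrings::DNAStringSet`, or an
#' existing records tibble/data frame.
#'
#' @param x character vector, `DNAStringSet`, or data frame with `id`/`seq`.
#' @return A tibble with columns `id`, `seq` and, when present, `qual`.
#' @export
as_sequence_records <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x))) {
      abort("sequence records need `id` and `seq` columns")
    }
    out <- as_tibble(x)
    if (any(!nzchar(out$id)) || anyNA(out$id)) abort("sequence ids must be nonempty")
    return(out)
  }
  if (inherits(x, "DNAStringSet") || inherits(x, "QualityScaledDNAStringSet")) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    out <- tibble(id = ids, seq = unname(as.character(x)))
    if (inherits(x, "QualityScaledDNAStringSet")) {
      out$qual <- unname(as.character(Biostrings::quality(x)))
    }
    return(out)
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(tibble(id = ids, seq = unname(x)))
  }
  abort("cannot interpret `x` as sequence records")
}

# decompress .bz2 to a tempfile so Biostrings (plain/gzip only) can read it
.maybe_bunzip <- function(path) {
  if (!grepl("\\.bz2$", path)) return(path)
  con <- bzfile(path, "rb")
  on.exit(close(con))
  raw <- raw(0)
  repeat {
    chunk <- readBin(con, "raw", n = 1024L * 1024L)
    if (length(chunk) == 0L) break
    raw <- c(raw, chunk)
  }
  out <- tempfile(fileext = paste0(".", sub("\\.bz2$", "", basename(path))))
  writeBin(raw, out)
  out
}

#' Read sequences from FASTA or FASTQ
#'
#' Reads plain, gzip- or bzip2-compressed FASTA/FASTQ into a records tibble.
#' FASTQ input carries a `qual` column of Phred+33 strings.
#'
#' @param path file path; format sniffed from the first non-empty character
#'   (`>` FASTA, `@` FASTQ) unless `format` is given.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return records tibble (see [as_sequence_records()]).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  real <- .maybe_bunzip(path)
  if (format == "auto") {
    con <- gzfile(real, "rt")
    first <- readLines(con, n = 1L)
    close(con)
    if (length(first) == 0L) abort(paste0("empty sequence file: ", path))
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  if (format == "fastq") {
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(real),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  } else {
    x <- Biostrings::readDNAStringSet(real, format = "fasta")
  }
  recs <- as_sequence_records(x)
  # Biostrings keeps the full description line; ids are the first token
  recs$id <- sub("\\s.*$", "", recs$id)
  recs
}

#' Write sequence records to FASTA or FASTQ
#'
#' @param records records tibble; a `qual` column is required for FASTQ.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  records <- as_sequence_records(records)
  compress <- grepl("\\.gz$", path)
  if (format == "fastq") {
    if (!"qual" %in% names(records)) abort("FASTQ output needs a `qual` column")
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(records$seq, records$id)),
      Biostrings::PhredQuality(records$qual)
    )
    # qualities ride along in mcols; the writer warns while dropping them
    # from the sequence line even though they land in the quality line
    withCallingHandlers(
      Biostrings::writeQualityScaledXStringSet(x, path, compress = compress),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  } else {
    x <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
    Biostrings::writeXStringSet(x, path, compress = compress)
  }
  invisible(path)
}
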