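#' A set of sequencing reads with per-base qualities
#'
#' @param read_id Character vector of read identifiers.
#' @param bases Character vector of base strings over `{A,C,G,T,N}`.
#' @param quals List of integer vectors of Phred quality scores, one per
#'   read, each the same length as its base string.
#'
#' @return An object of class `read_set` (list with `read_id`, `bases`,
#'   `quals`).
#' @export
read_set <- function(read_id = character(), bases = character(),
                     quals = list()) {
  read_id <- as.character(read_id); bases <- as.character(bases)
  stopifnot(length(read_id) == length(bases),
            length(bases) == length(quals))
  quals <- lapply(quals, as.integer)
  len_ok <- nchar(bases) == lengths(quals)
  if (!all(len_ok))
    stop_fmt("read %s: bases and qualities differ in length",
             read_id[which(!len_ok)[1L]])
  if (length(quals) && min(unlist(quals), 0L) < 0L)
    stop_fmt("negative Phred quality")
  structure(list(read_id = read_id, bases = bases, quals = quals),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$read_id)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, %d bases\n",
              length(x), sum(nchar(x$bases))))
  invisible(x)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to an uncompressed 4-line-per-record FASTQ file.
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTQ file not found: %s", path)
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) return(read_set())
  if (n_lines %% 4L != 0L)
    stop_fmt("truncated FASTQ record at record %d in %s",
             n_lines %/% 4L + 1L, path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  quals <- as.list(methods::as(Biostrings::PhredQuality(q), "IntegerList"))
  # keep only the id up to the first whitespace, like most fastq tooling
  ids <- sub("\\s.*$", "", names(x))
  read_set(ids, as.character(x), quals)
}

#' Write a FASTQ file (Phred+33)
#'
#' `write_fastq()` followed by [read_fastq()] is the identity on
#' `(read_id, bases, quals)`.
#'
#' @param rs A [read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  if (length(rs) == 0L) { file.create(path); return(invisible(path)) }
  qs <- vapply(rs$quals,
               function(q) rawToChar(as.raw(q + 33L)), character(1L))
  x <- Biostrings::DNAStringSet(rs$bases)
  names(x) <- rs$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qs))
  invisible(path)
}

#' Read a BED3 file of target regions
#'
#' Coordinates follow the BED convention: 0-based start (inclusive),
#' end exclusive.
#'
#' @param path Path to a 3-column BED file (no header).
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_fmt("BED file not found: %s", path)
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 3L) stop_fmt("BED3 needs at least 3 columns")
  b <- b[, 1:3]; names(b) <- c("chrom", "start", "end")
  b$start <- as.integer(b$start); b$end <- as.integer(b$end)
  if (any(b$start >= b$end)) stop_fmt("BED region with start >= end")
  b
}
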