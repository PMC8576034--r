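#' Filter reads by adapter, low-quality and N-base rules
#'
#' Applies the three clean-data rules of targeted-sequencing
#' preprocessing: a read is removed iff it contains the adapter as an
#' exact substring, or its fraction of bases at Phred quality
#' `<= lowq_threshold` is strictly greater than `lowq_frac`, or its
#' fraction of `N` bases is strictly greater than `n_frac`.  A read
#' violating several rules is attributed to the first rule in the order
#' adapter, low_quality, high_N.
#'
#' @param rs A [read_set()].
#' @param adapter Adapter sequence (required, non-empty).
#' @param lowq_threshold Phred score at or below which a base counts as
#'   low-quality (default 5).
#' @param lowq_frac Maximum tolerated low-quality base fraction
#'   (default 0.5; "more than 50%" is removed).
#' @param n_frac Maximum tolerated N-base fraction (default 0.1).
#' @param max_mismatch Maximum mismatches allowed in the adapter match
#'   (default 0: exact substring).
#' @return List with `clean` (a [read_set()]) and `report`, a
#'   `read_qc_report`: `n_raw`, `n_clean`, `raw_bases`, `clean_bases`,
#'   `gc_content` (of the clean reads), `removed_by` (named counts per
#'   rule) and `removed` (`data.frame`: `read_id`, `rule`).
#' @export
filter_reads <- function(rs, adapter, lowq_threshold = 5L, lowq_frac = 0.5,
                         n_frac = 0.1, max_mismatch = 0L) {
  stopifnot(inherits(rs, "read_set"))
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter))
    stop_fmt("a non-empty adapter sequence is required")
  stopifnot(lowq_frac >= 0, lowq_frac <= 1, n_frac >= 0, n_frac <= 1)
  n <- length(rs)
  if (n == 0L) {
    report <- structure(list(
      n_raw = 0L, n_clean = 0L, raw_bases = 0L, clean_bases = 0L,
      gc_content = NA_real_,
      removed_by = c(adapter = 0L, low_quality = 0L, high_N = 0L),
      removed = data.frame(read_id = character(), rule = character())),
      class = "read_qc_report")
    return(list(clean = rs, report = report))
  }
  has_adapter <- if (max_mismatch == 0L) {
    grepl(adapter, rs$bases, fixed = TRUE)
  } else {
    Biostrings::vcountPattern(adapter, Biostrings::DNAStringSet(rs$bases),
                              max.mismatch = max_mismatch) > 0L
  }
  lowq <- vapply(rs$quals, function(q) mean(q <= lowq_threshold), 0)
  n_ratio <- vapply(strsplit(rs$bases, "", fixed = TRUE),
                    function(b) mean(b == "N"), 0)
  rule <- rep(NA_character_, n)
  rule[n_ratio > n_frac] <- "high_N"
  rule[lowq > lowq_frac] <- "low_quality"
  rule[has_adapter] <- "adapter"
  keep <- is.na(rule)
  clean <- read_set(rs$read_id[keep], rs$bases[keep], rs$quals[keep])
  removed_by <- vapply(c(adapter = "adapter", low_quality = "low_quality",
                         high_N = "high_N"),
                       function(r) sum(rule == r, na.rm = TRUE), 0L)
  report <- structure(list(
    n_raw = n, n_clean = length(clean),
    raw_bases = sum(nchar(rs$bases)),
    clean_bases = sum(nchar(clean$bases)),
    gc_content = gc_content(clean),
    removed_by = removed_by,
    removed = data.frame(read_id = rs$read_id[!keep], rule = rule[!keep],
                         stringsAsFactors = FALSE)),
    class = "read_qc_report")
  list(clean = clean, report = report)
}

#' @export
print.read_qc_report <- function(x, ...) {
  cat(sprintf("read_qc_report: %d/%d reads kept (%d bases), GC %.2f%%\n",
              x$n_clean, x$n_raw, x$clean_bases, 100 * x$gc_content))
  cat(sprintf("  removed: adapter %d, low_quality %d, high_N %d\n",
              x$removed_by[["adapter"]], x$removed_by[["low_quality"]],
              x$removed_by[["high_N"]]))
  invisible(x)
}

#' GC content of a read set
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` bases are excluded from the
#' denominator.  `NA` if there is no non-N base.
#'
#' @param rs A [read_set()].
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
gc_content <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  if (length(rs) == 0L) return(NA_real_)
  b <- unlist(strsplit(rs$bases, "", fixed = TRUE))
  gc <- sum(b == "G" | b == "C")
  acgt <- sum(b %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}
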