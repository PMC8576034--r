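#' Unphased genotype matrix with cohort labels
#'
#' Stores, for each individual and each marker of a [marker_panel()], an
#' unordered pair of alleles, or missing (`NA`).  Allele pairs are stored
#' sorted so that the representation is phase-free.
#'
#' @param panel A [marker_panel()].
#' @param samples `data.frame` with columns `sample_id` (unique) and
#'   `cohort` (`"case"` or `"control"`).
#' @param a1,a2 Character matrices (individuals x markers) holding the two
#'   alleles of each genotype; `NA` in both for a missing genotype.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `panel`, `samples`, `a1`, `a2`.
#' @export
genotype_matrix <- function(panel, samples, a1, a2) {
  stopifnot(inherits(panel, "marker_panel"))
  samples <- data.frame(sample_id = as.character(samples$sample_id),
                        cohort = as.character(samples$cohort),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop_fmt("duplicate sample_id: %s",
             samples$sample_id[duplicated(samples$sample_id)][1L])
  if (!all(samples$cohort %in% c("case", "control")))
    stop_fmt("cohort labels must be 'case' or 'control'")
  n <- nrow(samples); m <- nrow(panel)
  a1 <- matrix(as.character(a1), n, m); a2 <- matrix(as.character(a2), n, m)
  # store unordered pairs canonically (a1 <= a2 byte-wise)
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  for (j in seq_len(m)) {
    ok <- is.na(a1[, j]) |
      (a1[, j] %in% c(panel$ref_allele[j], panel$alt_allele[j]) &
       a2[, j] %in% c(panel$ref_allele[j], panel$alt_allele[j]))
    if (!all(ok))
      stop_fmt("invalid allele for marker %s in sample %s",
               panel$id[j], samples$sample_id[which(!ok)[1L]])
    if (any(is.na(a1[, j]) != is.na(a2[, j])))
      stop_fmt("half-missing genotype at marker %s", panel$id[j])
  }
  dimnames(a1) <- dimnames(a2) <- list(samples$sample_id, panel$id)
  structure(list(panel = panel, samples = samples, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals (%d case / %d control), %d markers\n",
              nrow(x$samples), sum(x$samples$cohort == "case"),
              sum(x$samples$cohort == "control"), nrow(x$panel)))
  invisible(x)
}

#' Read an unphased genotype table (TSV)
#'
#' The canonical exchange format for array genotypes: a tab-separated file
#' with header `sample_id`, `cohort`, then one column per marker (in panel
#' order) holding `"A1/A2"` allele pairs or `"./."` for missing.
#'
#' @param path Path to the TSV file.
#' @param panel The [marker_panel()] the columns refer to.
#' @return A [genotype_matrix()].  Missing genotypes are preserved as `NA`.
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path, panel) {
  if (!file.exists(path)) stop_fmt("genotype file not found: %s", path)
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "cohort", panel$id)
  if (!identical(names(tab), need))
    stop_fmt("genotype table header must be: %s", paste(need, collapse = ", "))
  n <- nrow(tab); m <- nrow(panel)
  a1 <- a2 <- matrix(NA_character_, n, m)
  for (j in seq_len(m)) {
    cell <- tab[[panel$id[j]]]
    parts <- strsplit(cell, "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop_fmt("malformed genotype '%s' (row %d, column %s)",
               cell[which(bad)[1L]], which(bad)[1L], panel$id[j])
    x1 <- vapply(parts, `[[`, "", 1L); x2 <- vapply(parts, `[[`, "", 2L)
    miss <- x1 == "." & x2 == "."
    alleles <- c(panel$ref_allele[j], panel$alt_allele[j])
    bad <- !miss & (!(x1 %in% alleles) | !(x2 %in% alleles))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop_fmt("unknown allele '%s' for marker %s (row %d, sample %s); expected {%s}",
               cell[i], panel$id[j], i, tab$sample_id[i],
               paste(alleles, collapse = ","))
    }
    a1[!miss, j] <- x1[!miss]; a2[!miss, j] <- x2[!miss]
  }
  genotype_matrix(panel, tab[c("sample_id", "cohort")], a1, a2)
}

#' Write an unphased genotype table (TSV)
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path) {
  cells <- matrix(paste(gm$a1, gm$a2, sep = "/"),
                  nrow(gm$samples), nrow(gm$panel))
  cells[is.na(gm$a1)] <- "./."
  out <- cbind(gm$samples, as.data.frame(cells, stringsAsFactors = FALSE))
  names(out) <- c("sample_id", "cohort", gm$panel$id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
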