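# FASTA, count-table and limiting-dilution incidence I/O.

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return A tibble with columns `name` and `sequence` (upper-case).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(name = names(ss), sequence = unname(toupper(as.character(ss))))
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with columns `name` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gene-by-sample count table
#'
#' @param path TSV with a `gene_id` column followed by one integer column
#'   per sample.
#' @return A wide tibble (`gene_id` + sample columns).
#' @export
read_count_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene_id" %in% names(x)) abort(sprintf("%s: missing gene_id column", path))
  num <- setdiff(names(x), "gene_id")
  bad <- num[!vapply(x[num], is.numeric, logical(1))]
  if (length(bad) > 0) abort(sprintf("%s: non-numeric count column '%s'", path, bad[1]))
  if (any(as.matrix(x[num]) < 0)) abort(sprintf("%s: negative counts", path))
  x
}

#' Write a gene-by-sample count table
#' @param counts Wide tibble with `gene_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a limiting-dilution incidence table
#'
#' @param path TSV with columns `group`, `dose` (cells injected), `n`
#'   (animals injected), `k` (tumor takes).
#' @return A validated incidence tibble.
#' @export
read_incidence <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  validate_incidence(x)
  x
}

#' Validate a limiting-dilution incidence table
#' @param x A data frame with columns `group`, `dose`, `n`, `k`.
#' @return `x`, invisibly, if valid.
#' @export
validate_incidence <- function(x) {
  miss <- setdiff(c("group", "dose", "n", "k"), names(x))
  if (length(miss) > 0) {
    abort(sprintf("incidence table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(x$dose <= 0)) abort("dose must be positive")
  if (any(x$n <= 0)) abort("n (animals injected) must be positive")
  if (any(x$k < 0 | x$k > x$n)) abort("takes k must satisfy 0 <= k <= n")
  invisible(x)
}

#' Write a limiting-dilution incidence table
#' @param x Incidence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(x, path) {
  validate_incidence(x)
  readr::write_tsv(x, path)
  invisible(path)
}
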