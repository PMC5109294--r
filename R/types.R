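# Shared tabular genomic types.
#
# All coordinates are 0-based, half-open (BED convention); GTF input is
# converted at the boundary. A peak table has columns chrom, start, end,
# name, score, strand, summit (absolute bp of the pinnacle) and optionally
# factor. A gene table has columns gene_id, chrom, start, end, strand
# (+/- only) and list-columns exon_starts / exon_ends.

validate_intervals <- function(x, what = "interval") {
  if (!is.data.frame(x)) abort(sprintf("%s table must be a data frame", what))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s table is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!nzchar(x$chrom))) abort("chrom must be non-empty")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("invalid interval (need 0 <= start < end) at row %d", bad[1]))
  }
  invisible(x)
}

#' Validate a peak table
#'
#' Checks the peak-table contract: 0-based half-open intervals with
#' `start <= summit < end` and non-negative scores.
#'
#' @param peaks A data frame with columns `chrom`, `start`, `end`, `summit`,
#'   `score` (and usually `name`, `strand`, `factor`).
#' @return `peaks`, invisibly, if valid; otherwise an error.
#' @export
validate_peaks <- function(peaks) {
  validate_intervals(peaks, "peak")
  if (!"summit" %in% names(peaks)) abort("peak table is missing column: summit")
  if (nrow(peaks) == 0) return(invisible(peaks))
  bad <- which(!(peaks$start <= peaks$summit & peaks$summit < peaks$end))
  if (length(bad) > 0) {
    abort(sprintf("summit outside [start, end) at row %d", bad[1]))
  }
  if ("score" %in% names(peaks) && any(peaks$score < 0)) abort("peak scores must be non-negative")
  invisible(peaks)
}

#' Validate a gene-model table
#'
#' Checks strand-awareness (`+`/`-` only; `.` has no transcription start
#' site) and that exons are sorted, non-overlapping and contained in the
#' gene span.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` and list-columns `exon_starts`, `exon_ends`.
#' @return `genes`, invisibly, if valid; otherwise an error.
#' @export
validate_genes <- function(genes) {
  validate_intervals(genes, "gene")
  need <- c("gene_id", "strand", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    abort(sprintf("gene table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(genes) == 0) return(invisible(genes))
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-' (strand '.' leaves the TSS undefined)")
  }
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    if (length(es) != length(ee) || length(es) == 0) {
      abort(sprintf("gene '%s': exon start/end lists must be non-empty and equal length", genes$gene_id[i]))
    }
    if (any(ee <= es)) abort(sprintf("gene '%s': empty or inverted exon", genes$gene_id[i]))
    if (is.unsorted(es, strictly = TRUE)) abort(sprintf("gene '%s': exons must be sorted", genes$gene_id[i]))
    if (length(es) > 1 && any(es[-1] < ee[-length(ee)])) {
      abort(sprintf("gene '%s': overlapping exons", genes$gene_id[i]))
    }
    if (es[1] < genes$start[i] || ee[length(ee)] > genes$end[i]) {
      abort(sprintf("gene '%s': exons outside gene span", genes$gene_id[i]))
    }
  }
  invisible(genes)
}

#' Strand-aware gene anchors
#'
#' Adds `tss` and `tes` columns: the transcription start site is the genomic
#' start for `+` genes and the genomic end for `-` genes, and vice versa for
#' the transcription end site.
#'
#' @param genes A validated gene table.
#' @return `genes` with numeric `tss` and `tes` columns appended.
#' @export
gene_anchors <- function(genes) {
  validate_genes(genes)
  mutate(as_tibble(genes),
    tss = ifelse(.data$strand == "+", .data$start, .data$end),
    tes = ifelse(.data$strand == "+", .data$end, .data$start)
  )
}

# GRanges helpers used wherever interval overlap is delegated to IRanges.
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}
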