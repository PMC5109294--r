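# Multi-factor co-occupancy classes, binned occupancy correlation,
# peak-centered signal matrices and non-promoter profiles.

#' Classify primary peaks by partner co-occupancy
#'
#' A partner factor is "present" at a primary peak when at least
#' `min_overlap` bp of interval intersection exists with any peak of that
#' partner. The class of a primary peak is the set of present partners
#' (empty set = primary-only).
#'
#' @param primary Peak tibble of the primary factor.
#' @param others Named list of partner peak tibbles.
#' @param min_overlap Minimum intersection in bp (default 1).
#' @return `primary` with columns `partners` (present partner names joined
#'   by `+`, `""` when none) and `n_partners` appended.
#' @export
overlap_classify <- function(primary, others, min_overlap = 1) {
  validate_peaks(primary)
  if (is.null(names(others)) || any(!nzchar(names(others)))) {
    abort("others must be a named list of partner peak tables")
  }
  gr_p <- peaks_to_granges(primary)
  present <- matrix(FALSE, nrow = nrow(primary), ncol = length(others),
                    dimnames = list(NULL, names(others)))
  for (f in names(others)) {
    validate_peaks(others[[f]])
    if (nrow(others[[f]]) == 0) next
    hits <- GenomicRanges::findOverlaps(gr_p, peaks_to_granges(others[[f]]),
                                        minoverlap = min_overlap)
    present[unique(S4Vectors::queryHits(hits)), f] <- TRUE
  }
  partners <- apply(present, 1, function(r) paste(names(others)[r], collapse = "+"))
  mutate(as_tibble(primary),
         partners = as.character(partners),
         n_partners = rowSums(present))
}

#' Co-occupancy class proportions
#'
#' @param classes Output of [overlap_classify()].
#' @return A tibble with `partners`, `n` and `fraction` (fractions over all
#'   primary peaks, summing to 1).
#' @export
cooccupancy_proportions <- function(classes) {
  if (!"partners" %in% names(classes)) abort("classes must carry a 'partners' column")
  classes |>
    count(.data$partners, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(dplyr::desc(.data$fraction))
}

#' Genome-binned Pearson correlation of occupancy tracks
#'
#' Tracks are re-binned to `bin_size` (mean of constituent bins) and the
#' Pearson correlation computed across all genome bins, pairwise-complete
#' over `NA`s. A constant track has undefined correlation: its entries are
#' `NA` with a warning.
#'
#' @param tracks Named list of [signal_track()] objects on the same grid.
#' @param bin_size Correlation bin in bp (multiple of the track bin;
#'   default 10 kb).
#' @param log1p Apply `log1p` to bin values before correlating.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
binned_correlation <- function(tracks, bin_size = 10000, log1p = FALSE) {
  if (length(tracks) < 2) abort("need at least two tracks")
  tb <- tracks[[1]]$bin_size
  if (bin_size %% tb != 0) abort("bin_size must be a multiple of the track bin size")
  same_grid <- vapply(tracks, function(t) t$bin_size == tb &&
                        identical(t$chrom_sizes, tracks[[1]]$chrom_sizes), logical(1))
  if (!all(same_grid)) abort("all tracks must share bin size and chromosome sizes")
  agg <- do.call(cbind, lapply(tracks, function(t) {
    unlist(lapply(names(t$values), function(ch) {
      v <- t$values[[ch]]
      grp <- (seq_along(v) - 1) %/% (bin_size %/% tb)
      as.numeric(tapply(v, grp, mean))
    }), use.names = FALSE)
  }))
  if (log1p) agg <- log1p(agg)
  const <- apply(agg, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(const)) {
    warn(sprintf("constant track(s): %s; correlation undefined (NA)",
                 paste(names(tracks)[const], collapse = ", ")))
  }
  cm <- suppressWarnings(cor(agg, use = "pairwise.complete.obs"))
  cm[const, ] <- NA_real_
  cm[, const] <- NA_real_
  d <- diag(cm)
  d[!const] <- 1
  diag(cm) <- d
  dimnames(cm) <- list(names(tracks), names(tracks))
  cm
}

#' Peak-centered signal matrix
#'
#' Builds the heatmap matrix of signal around peak summits: row i, column j
#' holds the mean track signal in
#' `[summit_i - flank + (j-1) * bin, summit_i - flank + j * bin)`. Rows are
#' sorted by descending peak score (ties by chromosome then start); bins
#' extending beyond a chromosome are `NA`.
#'
#' @param track A [signal_track()].
#' @param peaks A validated peak tibble.
#' @param flank Half-window around the summit in bp (default 10 kb).
#' @param bin Output column width in bp (multiple of the track bin).
#' @return A numeric matrix of class `centered_matrix` with attributes
#'   `offsets` (column left edges relative to the summit), `peaks` (the
#'   sorted peak tibble), `flank`, `bin`.
#' @export
peak_centered_matrix <- function(track, peaks, flank = 10000, bin = 100) {
  stopifnot(inherits(track, "signal_track"))
  validate_peaks(peaks)
  tb <- track$bin_size
  if (bin %% tb != 0) abort("bin must be a multiple of the track bin size")
  peaks <- arrange(as_tibble(peaks), dplyr::desc(.data$score), .data$chrom, .data$start)
  per_col <- bin %/% tb
  n_cols <- as.integer(2 * flank / bin)
  n_sub <- n_cols * per_col
  out <- matrix(NA_real_, nrow = nrow(peaks), ncol = n_cols)
  for (ch in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == ch)
    if (!ch %in% names(track$values)) next
    v <- track$values[[ch]]
    first_bin <- floor((peaks$summit[sel] - flank) / tb)  # 0-based track bin
    idx <- outer(first_bin, seq_len(n_sub) - 1L, "+")
    ok <- idx >= 0 & idx < length(v)
    vals <- matrix(NA_real_, nrow = length(sel), ncol = n_sub)
    vals[ok] <- v[idx[ok] + 1L]
    grp <- rep(seq_len(n_cols), each = per_col)
    for (j in seq_len(n_cols)) {
      out[sel, j] <- rowMeans(vals[, grp == j, drop = FALSE])
    }
  }
  structure(out,
            offsets = seq(-flank, flank - bin, by = bin),
            peaks = peaks, flank = flank, bin = bin,
            class = c("centered_matrix", "matrix", "array"))
}

#' Mean signal profile at non-promoter peaks
#'
#' Drops peaks whose summit lies in any gene's extended promoter
#' (`[TSS - upstream, TSS + downstream)` in transcription direction),
#' RPKM-normalizes the track, and returns the column mean of the centered
#' matrix with a bootstrap band over peaks.
#'
#' @param track A raw [signal_track()].
#' @param peaks A validated peak tibble.
#' @param genes A validated gene tibble.
#' @param upstream,downstream Extended promoter window (default 8 kb/2 kb).
#' @param flank,bin Profile window geometry (default +/-10 kb, 100 bp).
#' @param n_boot Bootstrap resamples for the band (default 1000).
#' @param conf Band coverage (default 0.95).
#' @return A tibble with `offset`, `mean`, `lower`, `upper` (RPKM units);
#'   zero rows (with a warning) when every peak is promoter-resident.
#' @export
nonpromoter_profile <- function(track, peaks, genes, upstream = 8000,
                                downstream = 2000, flank = 10000, bin = 100,
                                n_boot = 1000, conf = 0.95) {
  validate_peaks(peaks)
  validate_genes(genes)
  ga <- gene_anchors(genes)
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(ga))) {
    same <- peaks$chrom == ga$chrom[i]
    pos <- (peaks$summit - ga$tss[i]) * ifelse(ga$strand[i] == "+", 1, -1)
    keep <- keep & !(same & pos >= -upstream & pos < downstream)
  }
  if (!any(keep)) {
    warn("all peaks fall in extended promoters; profile is empty")
    return(tibble(offset = numeric(0), mean = numeric(0),
                  lower = numeric(0), upper = numeric(0)))
  }
  cm <- peak_centered_matrix(normalize_rpkm(track), peaks[keep, , drop = FALSE],
                             flank = flank, bin = bin)
  prof <- colMeans(cm, na.rm = TRUE)
  n <- nrow(cm)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = ncol(cm))
  for (b in seq_len(n_boot)) {
    boot[b, ] <- colMeans(cm[sample.int(n, n, replace = TRUE), , drop = FALSE],
                          na.rm = TRUE)
  }
  a <- (1 - conf) / 2
  tibble(
    offset = attr(cm, "offsets"),
    mean = prof,
    lower = apply(boot, 2, quantile, probs = a, na.rm = TRUE),
    upper = apply(boot, 2, quantile, probs = 1 - a, na.rm = TRUE)
  )
}
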