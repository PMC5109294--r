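# SignalTrack: fixed-bin per-chromosome coverage container.

#' Construct a binned signal track
#'
#' A signal track stores one non-negative numeric vector per chromosome on a
#' fixed bin grid, plus a normalization tag (`"raw"` or `"rpkm"`). Bin `i`
#' (1-based) covers genomic interval `[(i-1)*bin_size, i*bin_size)`.
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome; lengths must equal `ceiling(chrom_size / bin_size)`.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named integer vector of chromosome lengths in bp.
#' @param normalization `"raw"` or `"rpkm"`.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, chrom_sizes, normalization = "raw") {
  stopifnot(is.list(values), !is.null(names(values)))
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0) abort("bin_size must be positive")
  normalization <- match.arg(normalization, c("raw", "rpkm"))
  chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  for (ch in names(values)) {
    if (!ch %in% names(chrom_sizes)) abort(sprintf("no chromosome size for '%s'", ch))
    exp_len <- ceiling(chrom_sizes[[ch]] / bin_size)
    v <- values[[ch]]
    if (length(v) != exp_len) {
      abort(sprintf("chromosome '%s': expected %d bins, got %d", ch, exp_len, length(v)))
    }
    if (any(!is.finite(v))) abort(sprintf("chromosome '%s': non-finite signal values", ch))
    if (any(v < 0)) abort(sprintf("chromosome '%s': negative signal values", ch))
  }
  structure(
    list(values = values, bin_size = bin_size, chrom_sizes = chrom_sizes,
         normalization = normalization),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d chromosome(s), bin %d bp, %s\n",
              length(x$values), x$bin_size, x$normalization))
  cat(sprintf("  total signal: %.4g over %d bins\n",
              sum(vapply(x$values, sum, numeric(1))),
              sum(lengths(x$values))))
  invisible(x)
}

#' Tidy a signal track into a long tibble
#'
#' @param x A `signal_track`.
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `start`, `end`, `value` (one row
#'   per bin).
#' @method as_tibble signal_track
#' @export
as_tibble.signal_track <- function(x, ...) {
  purrr::map_dfr(names(x$values), function(ch) {
    v <- x$values[[ch]]
    tibble(
      chrom = ch,
      start = (seq_along(v) - 1) * x$bin_size,
      end = pmin(seq_along(v) * x$bin_size, x$chrom_sizes[[ch]]),
      value = v
    )
  })
}

#' Total signal of a track
#' @param x A `signal_track`.
#' @return Sum of all bin values.
#' @export
track_total <- function(x) {
  stopifnot(inherits(x, "signal_track"))
  sum(vapply(x$values, sum, numeric(1)))
}

#' RPKM-like normalization of a track
#'
#' Rescales bin values to reads-per-kilobase-per-million units treating the
#' track total as the mapped-read mass: `value * 1e9 / (bin_size * total)`.
#'
#' @param x A raw `signal_track`.
#' @return A `signal_track` with `normalization = "rpkm"`.
#' @export
normalize_rpkm <- function(x) {
  stopifnot(inherits(x, "signal_track"))
  tot <- track_total(x)
  if (tot <= 0) abort("cannot RPKM-normalize an all-zero track")
  vals <- lapply(x$values, function(v) v * 1e9 / (x$bin_size * tot))
  signal_track(vals, x$bin_size, x$chrom_sizes, normalization = "rpkm")
}

# Mean signal of track bins overlapping [lo, hi) on one chromosome; NA when
# the window leaves the chromosome.
track_bin_index <- function(track, chrom, pos) {
  floor(pos / track$bin_size) + 1L
}
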