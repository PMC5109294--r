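# bedGraph <-> binned signal track.

#' Read a bedGraph file onto a fixed bin grid
#'
#' Each bin's value is the coverage-weighted mean of overlapping bedGraph
#' intervals with uncovered bases contributing zero, i.e.
#' `sum(value * overlap_bp) / bin_size`. Intervals must lie within the
#' chromosome bounds given by `chrom_sizes`.
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return A raw [signal_track()].
#' @export
read_signal <- function(path, bin_size, chrom_sizes) {
  bin_size <- as.integer(bin_size)
  lines <- read_lines_checked(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  fields <- stringr::str_split(lines, "\t")
  bad <- which(lengths(fields) < 4)
  if (length(bad) > 0) abort(sprintf("%s: malformed line %d", path, bad[1]))
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  ln <- seq_along(lines)
  chrom <- m[, 1]
  start <- parse_num(m[, 2], ln, "start", path)
  end <- parse_num(m[, 3], ln, "end", path)
  value <- parse_num(m[, 4], ln, "value", path)
  bad <- which(end <= start)
  if (length(bad) > 0) abort(sprintf("%s: end <= start at line %d", path, bad[1]))
  unknown <- which(!chrom %in% names(chrom_sizes))
  if (length(unknown) > 0) {
    abort(sprintf("%s: unknown chromosome '%s' at line %d", path, chrom[unknown[1]], unknown[1]))
  }
  beyond <- which(end > chrom_sizes[chrom])
  if (length(beyond) > 0) {
    abort(sprintf("%s: interval beyond chromosome length at line %d", path, beyond[1]))
  }
  vals <- lapply(names(chrom_sizes), function(ch) {
    nb <- ceiling(chrom_sizes[[ch]] / bin_size)
    acc <- numeric(nb)
    sel <- which(chrom == ch)
    for (i in sel) {
      b0 <- floor(start[i] / bin_size)
      b1 <- floor((end[i] - 1) / bin_size)
      bins <- b0:b1
      lo <- pmax(start[i], bins * bin_size)
      hi <- pmin(end[i], (bins + 1) * bin_size)
      acc[bins + 1] <- acc[bins + 1] + value[i] * (hi - lo)
    }
    acc / bin_size
  })
  signal_track(setNames(vals, names(chrom_sizes)), bin_size, chrom_sizes)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal-valued bins are merged into single intervals; zero bins are
#' omitted (read back as zero). Values round-trip within 1e-9.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  out <- character(0)
  emit <- function(ch, s, e, v) {
    sprintf("%s\t%d\t%d\t%s", ch, as.integer(s), as.integer(e),
            formatC(v, format = "g", digits = 15))
  }
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    csize <- track$chrom_sizes[[ch]]
    partial <- csize %% track$bin_size != 0
    n_full <- if (partial) length(v) - 1L else length(v)
    if (n_full > 0) {
      r <- rle(v[seq_len(n_full)])
      ends_bin <- cumsum(r$lengths)
      starts_bin <- ends_bin - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        out <- c(out, emit(ch, starts_bin[keep] * track$bin_size,
                           ends_bin[keep] * track$bin_size, r$values[keep]))
      }
    }
    if (partial && v[length(v)] != 0) {
      # last bin is short: rescale so the coverage-weighted read restores it
      s <- n_full * track$bin_size
      out <- c(out, emit(ch, s, csize,
                         v[length(v)] * track$bin_size / (csize - s)))
    }
  }
  readr::write_lines(out, path)
  invisible(path)
}
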