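# Peak and chromosome-size I/O (BED6 / ENCODE narrowPeak / chrom.sizes).

read_lines_checked <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines[nzchar(lines)]
}

parse_num <- function(x, line_no, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed %s at line %d", path, what, line_no[bad[1]]))
  }
  out
}

#' Read a peak set from BED6 or narrowPeak
#'
#' For narrowPeak the summit is `start + offset` (10th column); an offset of
#' -1 (ENCODE convention for "no summit called") and every BED6 peak get the
#' interval midpoint `floor((start + end) / 2)` instead.
#'
#' @param path Path to a tab-separated BED6 or 10-column narrowPeak file.
#' @param dialect `"narrowPeak"` or `"bed6"`.
#' @param factor Optional factor name stored in a `factor` column.
#' @return A peak tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit` (and `factor` if given).
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed6"), factor = NULL) {
  dialect <- match.arg(dialect)
  lines <- read_lines_checked(path)
  fields <- stringr::str_split(lines, "\t")
  ncols <- if (dialect == "narrowPeak") 10L else 6L
  bad <- which(lengths(fields) < ncols)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (expected >= %d tab-separated fields)",
                  path, bad[1], ncols))
  }
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncols)))
  ln <- seq_along(lines)
  start <- parse_num(m[, 2], ln, "start", path)
  end <- parse_num(m[, 3], ln, "end", path)
  bad <- which(end <= start)
  if (length(bad) > 0) abort(sprintf("%s: end <= start at line %d", path, bad[1]))
  peaks <- tibble(
    chrom = m[, 1],
    start = start,
    end = end,
    name = m[, 4],
    score = parse_num(m[, 5], ln, "score", path),
    strand = m[, 6]
  )
  if (dialect == "narrowPeak") {
    offset <- parse_num(m[, 10], ln, "summit offset", path)
    bad <- which(offset < -1)
    if (length(bad) > 0) abort(sprintf("%s: summit offset < -1 at line %d", path, bad[1]))
    peaks$summit <- ifelse(offset == -1,
                           floor((peaks$start + peaks$end) / 2),
                           peaks$start + offset)
  } else {
    peaks$summit <- floor((peaks$start + peaks$end) / 2)
  }
  if (!is.null(factor)) peaks$factor <- factor
  validate_peaks(peaks)
  peaks
}

#' Write a peak set to BED6 or narrowPeak
#'
#' The narrowPeak signalValue/pValue/qValue columns are filled with the
#' score and -1 placeholders; the summit is emitted as an offset from start.
#'
#' @param peaks A validated peak tibble.
#' @param path Output path.
#' @param dialect `"narrowPeak"` or `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "bed6")) {
  dialect <- match.arg(dialect)
  validate_peaks(peaks)
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep(".", nrow(peaks))
  name <- if ("name" %in% names(peaks)) peaks$name else sprintf("peak_%d", seq_len(nrow(peaks)))
  base <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                  peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                  name, format(peaks$score, trim = TRUE, scientific = FALSE), strand)
  if (dialect == "narrowPeak") {
    lines <- sprintf("%s\t%s\t-1\t-1\t%d", base,
                     format(peaks$score, trim = TRUE, scientific = FALSE),
                     as.integer(peaks$summit - peaks$start))
  } else {
    lines <- base
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a tab-separated file with chromosome name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  lines <- read_lines_checked(path)
  fields <- stringr::str_split(lines, "\t")
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) abort(sprintf("%s: malformed line %d", path, bad[1]))
  nm <- vapply(fields, `[`, character(1), 1)
  sz <- parse_num(vapply(fields, `[`, character(1), 2), seq_along(lines), "size", path)
  if (any(sz <= 0)) abort(sprintf("%s: non-positive chromosome size", path))
  setNames(sz, nm)
}

#' Write a chrom.sizes table
#' @param sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  readr::write_lines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}
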