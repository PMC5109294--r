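# Position weight matrices: construction and MEME-minimal text I/O.

#' Construct a position weight matrix object
#'
#' Columns are motif positions; rows are A, C, G, T probabilities. A
#' pseudocount of 1e-4 is mixed in and columns renormalized so every
#' probability is strictly positive (log-odds stay finite).
#'
#' @param matrix A 4 x m numeric matrix of base probabilities (rows in
#'   A, C, G, T order; each column summing to 1 within 1e-6).
#' @param id Motif identifier.
#' @param background Length-4 background base frequencies (default uniform).
#' @param pseudocount Mixing weight for the uniform pseudocount.
#' @return An object of class `pwm` with elements `id`, `matrix`,
#'   `background`.
#' @export
pwm <- function(matrix, id = "motif", background = rep(0.25, 4), pseudocount = 1e-4) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) abort("PWM matrix must have 4 rows (A, C, G, T)")
  if (any(matrix < 0)) abort("PWM probabilities must be non-negative")
  sums <- colSums(matrix)
  if (any(abs(sums - 1) > 1e-6)) abort("each PWM column must sum to 1 (within 1e-6)")
  if (length(background) != 4 || any(background <= 0) || abs(sum(background) - 1) > 1e-6) {
    abort("background must be 4 positive frequencies summing to 1")
  }
  m <- sweep(matrix, 2, sums, "/")
  m <- (m + pseudocount) / (1 + 4 * pseudocount)
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(id = id, matrix = m, background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n", x$id, ncol(x$matrix),
              pwm_consensus(x)))
  invisible(x)
}

#' Motif width
#' @param x A `pwm`.
#' @return Integer number of positions.
#' @export
pwm_width <- function(x) ncol(x$matrix)

#' Consensus sequence of a PWM
#' @param x A `pwm`.
#' @return Character string of the per-column most probable base.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Log-odds score matrix of a PWM
#'
#' @param x A `pwm`.
#' @return A 4 x m matrix of `log2(p / background)` scores.
#' @export
pwm_log_odds <- function(x) {
  log2(sweep(x$matrix, 1, x$background, "/"))
}

#' Reverse complement of a PWM
#' @param x A `pwm`.
#' @return A `pwm` scoring the reverse strand.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[4:1, rev(seq_len(ncol(x$matrix))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  out <- x
  out$matrix <- m
  out$background <- x$background[4:1]
  out
}

#' Build a PWM from a consensus word
#'
#' Each position puts `1 - 3 * mismatch_prob` on the consensus base.
#'
#' @param word Character string over ACGT.
#' @param id Motif id.
#' @param mismatch_prob Per-alternative-base probability.
#' @return A `pwm`.
#' @export
pwm_from_consensus <- function(word, id = word, mismatch_prob = 0.02) {
  bases <- strsplit(toupper(word), "")[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) abort("consensus word must be over ACGT")
  m <- matrix(mismatch_prob, nrow = 4, ncol = length(idx))
  m[cbind(idx, seq_along(idx))] <- 1 - 3 * mismatch_prob
  pwm(m, id = id)
}

#' Read motifs from MEME-minimal text
#'
#' Parses the minimal motif format: a `MEME version` header, optional
#' background frequency line, and one `letter-probability matrix` block per
#' `MOTIF`.
#'
#' @param path Path to a MEME-minimal text file.
#' @return A named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- trimws(readr::read_lines(path))
  if (!any(startsWith(lines, "MEME version"))) {
    abort(sprintf("%s: not a MEME-minimal file (missing 'MEME version')", path))
  }
  background <- rep(0.25, 4)
  bg_i <- which(startsWith(lines, "Background letter frequencies"))
  if (length(bg_i) == 1) {
    j <- bg_i + 1
    while (j <= length(lines) && !nzchar(lines[j])) j <- j + 1
    toks <- strsplit(lines[j], "\\s+")[[1]]
    freq <- suppressWarnings(as.numeric(toks[seq(2, length(toks), by = 2)]))
    names(freq) <- toks[seq(1, length(toks), by = 2)]
    background <- unname(freq[c("A", "C", "G", "T")])
  }
  motif_i <- which(startsWith(lines, "MOTIF"))
  if (length(motif_i) == 0) abort(sprintf("%s: no MOTIF blocks", path))
  out <- list()
  for (mi in motif_i) {
    id <- strsplit(lines[mi], "\\s+")[[1]][2]
    hi <- mi + which(startsWith(lines[(mi + 1):length(lines)], "letter-probability matrix"))[1]
    if (is.na(hi)) abort(sprintf("%s: motif %s lacks a letter-probability matrix", path, id))
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hi]))
    rows <- lines[(hi + 1):(hi + w)]
    vals <- lapply(rows, function(r) as.numeric(strsplit(r, "\\s+")[[1]]))
    if (any(lengths(vals) != 4)) abort(sprintf("%s: malformed matrix row in motif %s", path, id))
    mat <- t(do.call(rbind, vals))  # 4 x w, rows A C G T
    out[[id]] <- pwm(mat, id = id, background = background)
  }
  out
}

#' Write motifs as MEME-minimal text
#'
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.8f C %.8f G %.8f T %.8f", bg[1], bg[2], bg[3], bg[4]), "")
  for (p in pwms) {
    out <- c(out, sprintf("MOTIF %s", p$id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     ncol(p$matrix)),
             apply(p$matrix, 2, function(col) sprintf(" %.8f %.8f %.8f %.8f",
                                                      col[1], col[2], col[3], col[4])),
             "")
  }
  readr::write_lines(out, path)
  invisible(path)
}
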