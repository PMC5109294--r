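# PWM scanning with exact score-threshold calibration and CentriMo-style
# central positional enrichment.

# Exact distribution of the log-odds score of a random background word,
# computed by dynamic programming over integer-rounded scores.
# Returns list(min_int, prob) where prob[i] is P(score == (min_int+i-1)*g).
pwm_score_dp <- function(pwm, granularity = 0.001) {
  lo <- pwm_log_odds(pwm)
  ki <- round(lo / granularity)  # 4 x m integer score matrix
  bg <- pwm$background
  min_i <- sum(apply(ki, 2, min))
  max_i <- sum(apply(ki, 2, max))
  width <- max_i - min_i + 1
  prob <- numeric(width)
  # start: before any column, score 0 at offset -min contributions handled
  # incrementally: maintain distribution over sum of processed columns.
  cur_min <- 0
  cur <- 1
  for (j in seq_len(ncol(ki))) {
    cmin <- min(ki[, j])
    new_min <- cur_min + cmin
    new_len <- length(cur) + (max(ki[, j]) - cmin)
    nxt <- numeric(new_len)
    for (b in 1:4) {
      off <- ki[b, j] - cmin
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt
    cur_min <- new_min
  }
  list(min_int = cur_min, prob = cur, granularity = granularity)
}

# Upper-tail P(score >= s) on the DP grid for a numeric score s.
pwm_score_tail <- function(dp, score) {
  tail_cum <- rev(cumsum(rev(dp$prob)))
  k <- ceiling(round(score / dp$granularity, 6))
  i <- k - dp$min_int + 1
  out <- numeric(length(score))
  out[i <= 1] <- 1
  out[i > length(dp$prob)] <- 0
  inside <- i >= 1 & i <= length(dp$prob)
  out[inside] <- tail_cum[i[inside]]
  out
}

#' Calibrate a PWM score threshold at an exact type-I level
#'
#' Computes the exact null distribution of the log2-odds score of a random
#' word drawn from the PWM's background model by dynamic programming over
#' scores rounded to a fixed granularity, and returns the smallest score
#' whose upper-tail probability is at most `alpha`.
#'
#' @param pwm A [pwm()].
#' @param alpha Per-position type-I level (0 < alpha < 1].
#' @param granularity Score rounding step for the DP (default 0.001).
#' @return Numeric threshold (log2-odds units) with attributes `tail_prob`
#'   (the attained level) and `granularity`. If `alpha` is below the
#'   smallest attainable positive tail the maximum score is returned with a
#'   warning.
#' @export
calibrate_threshold <- function(pwm, alpha, granularity = 0.001) {
  if (!(alpha > 0 && alpha <= 1)) abort("alpha must be in (0, 1]")
  dp <- pwm_score_dp(pwm, granularity)
  tail_cum <- rev(cumsum(rev(dp$prob)))
  ok <- which(tail_cum <= alpha + 1e-15)
  if (length(ok) == 0) {
    warn(sprintf("alpha = %g below the smallest attainable tail; returning the maximum score", alpha))
    i <- length(dp$prob)
  } else {
    i <- min(ok)
  }
  if (alpha >= 1) i <- 1
  thr <- (dp$min_int + i - 1) * granularity
  structure(thr, tail_prob = tail_cum[i], granularity = granularity)
}

encode_sequences <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1) abort("all sequences must have the same length")
  chars <- strsplit(toupper(sequences), "", fixed = TRUE)
  matrix(match(unlist(chars), c("A", "C", "G", "T")), nrow = length(sequences),
         ncol = L, byrow = TRUE)
}

# Score every start position of every sequence with a log-odds matrix.
# Non-ACGT characters contribute the minimum column score.
score_positions <- function(enc, lo) {
  m <- ncol(lo)
  P <- ncol(enc) - m + 1
  if (P < 1) abort("sequences shorter than the motif")
  S <- matrix(0, nrow = nrow(enc), ncol = P)
  for (i in seq_len(m)) {
    sub <- enc[, i:(i + P - 1), drop = FALSE]
    contrib <- lo[, i][sub]
    contrib[is.na(contrib)] <- min(lo[, i])
    S <- S + matrix(contrib, nrow = nrow(enc))
  }
  S
}

#' Scan equal-length sequences for the best motif site
#'
#' Both strands are scanned with the calibrated log2-odds score; each
#' sequence contributes at most one site: the maximum-scoring position at or
#' above `threshold`, ties broken by smaller absolute offset from the
#' sequence center, then leftmost position, then `+` strand.
#'
#' @param seqs A tibble with `name` and `sequence` columns (or a character
#'   vector of sequences), all of one length `L >=` motif width.
#' @param pwm A [pwm()].
#' @param threshold Score threshold from [calibrate_threshold()].
#' @return A tibble with one row per sequence that has a site:
#'   `sequence_index`, `name`, `offset` (site center minus sequence center,
#'   bp), `strand`, `score`, `p_value` (exact upper-tail probability of the
#'   score under the background model).
#' @export
scan_sequences <- function(seqs, pwm, threshold) {
  if (is.character(seqs)) seqs <- tibble(name = sprintf("seq_%d", seq_along(seqs)), sequence = seqs)
  enc <- encode_sequences(seqs$sequence)
  L <- ncol(enc)
  m <- pwm_width(pwm)
  fwd <- score_positions(enc, pwm_log_odds(pwm))
  rev_ <- score_positions(enc, pwm_log_odds(pwm_revcomp(pwm)))
  P <- ncol(fwd)
  center <- (L - 1) / 2
  offsets <- (seq_len(P) - 1) + (m - 1) / 2 - center
  dp <- pwm_score_dp(pwm, attr(threshold, "granularity") %||% 0.001)
  # tie-break priority per (position, strand): smaller |offset|, then
  # leftmost, then '+' strand
  off_all <- rep(offsets, 2)
  strand_minus <- rep(c(FALSE, TRUE), each = P)
  prio <- integer(2 * P)
  prio[order(abs(off_all), off_all, strand_minus)] <- seq_len(2 * P)
  n_seq <- nrow(enc)
  hit <- logical(n_seq)
  best_j <- integer(n_seq)
  best_score <- numeric(n_seq)
  for (i in seq_len(n_seq)) {
    sc <- c(fwd[i, ], rev_[i, ])
    b <- max(sc)
    if (b < threshold) next
    cand <- which(sc >= b - 1e-9)
    j <- cand[which.min(prio[cand])]
    hit[i] <- TRUE
    best_j[i] <- j
    best_score[i] <- sc[j]
  }
  idx <- which(hit)
  out <- tibble(
    sequence_index = idx,
    name = seqs$name[idx],
    offset = off_all[best_j[idx]],
    strand = ifelse(strand_minus[best_j[idx]], "-", "+"),
    score = best_score[idx]
  )
  out$p_value <- if (nrow(out)) pwm_score_tail(dp, out$score) else numeric(0)
  out
}

#' Central positional enrichment of motif sites
#'
#' CentriMo-style statistic: for every odd central window of width `w`
#' (`w <= L - m + 1` possible site-center positions), counts the sites whose
#' center lies within `(w-1)/2` bp of the sequence center and compares that
#' count against the binomial null in which each site lands uniformly among
#' the possible positions (`p0 = w / (L - m + 1)`). The minimum upper-tail
#' p over windows is Bonferroni-corrected by the number of windows tested.
#'
#' @param sites Output of [scan_sequences()] (uses the `offset` column).
#' @param L Sequence length in bp.
#' @param m Motif width in bp.
#' @return One-row tibble: `best_width`, `k_in_window`, `n_sites`,
#'   `p_value` (Bonferroni-corrected, capped at 1), `log10_p` (uncapped
#'   corrected log10 p, robust below double underflow), `n_widths`. With
#'   zero sites returns `best_width = NA`, `p_value = 1`.
#' @export
central_enrichment <- function(sites, L, m) {
  n <- nrow(sites)
  n_pos <- L - m + 1
  widths <- seq(1, n_pos, by = 2)
  if (n == 0) {
    return(tibble(best_width = NA_real_, k_in_window = 0L, n_sites = 0L,
                  p_value = 1, log10_p = 0, n_widths = length(widths)))
  }
  abs_off <- abs(sites$offset)
  logp <- vapply(widths, function(w) {
    k <- sum(abs_off <= (w - 1) / 2 + 1e-9)
    if (k == 0) return(0)
    pbinom(k - 1, n, w / n_pos, lower.tail = FALSE, log.p = TRUE)
  }, numeric(1))
  best <- which.min(logp)
  log10_corrected <- logp[best] / log(10) + log10(length(widths))
  k_best <- sum(abs_off <= (widths[best] - 1) / 2 + 1e-9)
  tibble(
    best_width = widths[best],
    k_in_window = as.integer(k_best),
    n_sites = as.integer(n),
    p_value = min(1, exp(logp[best]) * length(widths)),
    log10_p = min(0, log10_corrected),
    n_widths = length(widths)
  )
}

#' Fraction of peaks with a detectable motif site
#'
#' Calibrates the score threshold at `alpha` and reports the fraction of
#' sequences (one per peak) carrying at least one above-threshold site on
#' either strand.
#'
#' @param seqs Sequence tibble or character vector (equal lengths).
#' @param pwm A [pwm()].
#' @param alpha Per-position score level (default 0.001).
#' @return One-row tibble: `n_with_site`, `n_total`, `fraction`,
#'   `threshold`.
#' @export
motif_fraction <- function(seqs, pwm, alpha = 0.001) {
  if (is.character(seqs)) seqs <- tibble(name = sprintf("seq_%d", seq_along(seqs)), sequence = seqs)
  thr <- calibrate_threshold(pwm, alpha)
  sites <- scan_sequences(seqs, pwm, thr)
  tibble(
    n_with_site = nrow(sites),
    n_total = nrow(seqs),
    fraction = nrow(sites) / nrow(seqs),
    threshold = as.numeric(thr)
  )
}
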