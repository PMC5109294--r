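# Small in-code fixtures and independent oracles shared across tests.

make_gene <- function(id, chrom, start, end, strand,
                      exon_starts = list(start), exon_ends = list(end)) {
  tibble::tibble(gene_id = id, chrom = chrom, start = start, end = end,
                 strand = strand, exon_starts = exon_starts, exon_ends = exon_ends)
}

make_peak <- function(chrom, start, end, summit = floor((start + end) / 2),
                      score = 1, name = "p", strand = ".") {
  tibble::tibble(chrom = chrom, start = start, end = end, name = name,
                 score = score, strand = strand, summit = summit)
}

random_genes <- function(n, chrom_length = 2e6, chroms = c("chrA", "chrB")) {
  rows <- lapply(seq_len(n), function(i) {
    len <- sample(2000:20000, 1)
    start <- sample.int(chrom_length - len, 1)
    n_ex <- sample(1:4, 1)
    if (n_ex == 1) {
      es <- start
      ee <- start + len
    } else {
      internal <- sort(sample((start + 1):(start + len - 1), 2 * n_ex - 2))
      bounds <- c(start, internal, start + len)
      es <- bounds[seq(1, length(bounds), by = 2)]
      ee <- bounds[seq(2, length(bounds), by = 2)]
    }
    make_gene(sprintf("g%04d", i), sample(chroms, 1), start, start + len,
              sample(c("+", "-"), 1), list(es), list(ee))
  })
  dplyr::bind_rows(rows)
}

random_peaks <- function(n, chrom_length = 2e6, chroms = c("chrA", "chrB")) {
  width <- sample(200:600, n, replace = TRUE)
  start <- sapply(width, function(w) sample.int(chrom_length - w, 1))
  summit <- start + sapply(width, function(w) sample.int(w, 1)) - 1
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width,
    name = sprintf("p%04d", seq_len(n)),
    score = stats::runif(n, 1, 100), strand = ".", summit = summit
  )
}

# Brute-force region classifier: plain re-statement of the window scheme,
# evaluated gene by gene with no vectorization tricks.
oracle_classify <- function(peak_summit, peak_chrom, genes,
                            promoter = c(5000, 500), distal = 15000,
                            proximal = 5000) {
  cand <- genes[genes$chrom == peak_chrom, , drop = FALSE]
  if (nrow(cand) == 0) return(list(region = "gene_desert", gene = NA_character_))
  best_d <- Inf
  best_g <- NULL
  for (i in order(cand$gene_id)) {
    tss <- if (cand$strand[i] == "+") cand$start[i] else cand$end[i]
    tes <- if (cand$strand[i] == "+") cand$end[i] else cand$start[i]
    d <- min(abs(peak_summit - tss), abs(peak_summit - tes))
    if (d < best_d) {
      best_d <- d
      best_g <- cand[i, ]
    }
  }
  dir <- if (best_g$strand == "+") 1 else -1
  tss <- if (best_g$strand == "+") best_g$start else best_g$end
  tes <- if (best_g$strand == "+") best_g$end else best_g$start
  ptss <- (peak_summit - tss) * dir
  ptes <- (peak_summit - tes) * dir
  in_body <- peak_summit >= best_g$start && peak_summit < best_g$end
  in_exon <- any(peak_summit >= best_g$exon_starts[[1]] &
                   peak_summit < best_g$exon_ends[[1]])
  region <-
    if (ptss >= -promoter[1] && ptss < promoter[2]) "promoter"
    else if (in_body && in_exon) "exon"
    else if (in_body) "intron"
    else if (ptes >= -500 && ptes < proximal) "three_prime_proximal"
    else if (ptss >= -distal && ptss < -promoter[1]) "five_prime_distal"
    else if (ptes >= proximal && ptes < distal) "three_prime_distal"
    else "gene_desert"
  list(region = region, gene = best_g$gene_id)
}

# O(n^2) interval-overlap scan used against overlap_classify().
oracle_overlap <- function(primary, partner, min_overlap = 1) {
  sapply(seq_len(nrow(primary)), function(i) {
    any(partner$chrom == primary$chrom[i] &
          pmin(partner$end, primary$end[i]) -
            pmax(partner$start, primary$start[i]) >= min_overlap)
  })
}

# Enumerate all 4^m words to get the exact score tail of a PWM.
oracle_score_tail <- function(pwm, threshold) {
  m <- pwm_width(pwm)
  lo <- pwm_log_odds(pwm)
  words <- as.matrix(expand.grid(rep(list(1:4), m)))
  scores <- words %*% rep(0, m)  # placeholder, filled below
  scores <- apply(words, 1, function(w) sum(lo[cbind(w, seq_len(m))]))
  probs <- apply(words, 1, function(w) prod(pwm$background[w]))
  sum(probs[scores >= threshold - 1e-12])
}

# One-sided Fisher p by explicit enumeration of all tables with the
# observed margins (probabilities from factorial products).
oracle_fisher_p <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  r1 <- a + b
  k <- a + c_
  a_vals <- max(0, r1 + k - n):min(r1, k)
  logp <- lchoose(r1, a_vals) + lchoose(n - r1, k - a_vals) - lchoose(n, k)
  sum(exp(logp[a_vals >= a]))
}

adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c_ / choose(n, 2)
  (a - expected) / ((b + c_) / 2 - expected)
}
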