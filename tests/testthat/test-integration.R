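# Peak-to-gene windows, Fisher enrichment, BH adjustment.

test_that("peak-to-gene windows are half-open around the gene span", {
  genes <- make_gene("g1", "chr1", 200000, 210000, "+")
  pk_at <- function(pos, partners = "AR") {
    dplyr::mutate(make_peak("chr1", pos - 50, pos + 50, summit = pos),
                  partners = partners, factor = "NP8")
  }
  expect_equal(nrow(assign_peaks_to_genes(pk_at(200000 - 49999), genes)), 1)
  expect_equal(nrow(assign_peaks_to_genes(pk_at(200000 - 50000), genes)), 0)
  expect_equal(nrow(assign_peaks_to_genes(pk_at(210000 + 49999), genes)), 1)
  expect_equal(nrow(assign_peaks_to_genes(pk_at(210000 + 50000), genes)), 0)
  got <- assign_peaks_to_genes(pk_at(205000, partners = ""), genes)
  expect_equal(got$class, "NP8_only")
})

test_that("assignment agrees with the all-pairs distance oracle", {
  set.seed(71)
  genes <- random_genes(60)
  peaks <- dplyr::mutate(random_peaks(250),
                         partners = sample(c("", "AR", "AR+FOXA1"), 250, replace = TRUE),
                         factor = "NP8")
  got <- assign_peaks_to_genes(peaks, genes, window = 50000)
  lab <- ifelse(peaks$partners == "", "NP8_only",
                paste("NP8", gsub("\\+", "_", peaks$partners), sep = "_"))
  for (i in seq_len(nrow(genes))) {
    for (cls in unique(lab)) {
      pk <- peaks[lab == cls, ]
      want <- any(pk$chrom == genes$chrom[i] &
                    pk$summit >= genes$start[i] - 50000 &
                    pk$summit < genes$end[i] + 50000)
      has <- any(got$gene_id == genes$gene_id[i] & got$class == cls)
      expect_equal(has, want)
    }
  }
})

test_that("fisher p matches hypergeometric enumeration exactly", {
  occ <- tibble::tibble(gene_id = sprintf("g%02d", 1:5), class = "K")
  bg <- sprintf("g%02d", 1:10)
  res <- fisher_enrichment(sprintf("g%02d", 1:5), bg, occ, "K")
  expect_equal(res$a, 5)
  expect_equal(res$d, 5)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  # random tables vs the enumeration oracle and fisher.test
  set.seed(72)
  for (rep in 1:20) {
    N <- sample(10:50, 1)
    bg <- sprintf("g%03d", seq_len(N))
    cl <- sample(bg, sample(2:(N - 1), 1))
    k_genes <- sample(bg, sample(1:N, 1))
    occ <- tibble::tibble(gene_id = k_genes, class = "K")
    res <- fisher_enrichment(cl, bg, occ, "K")
    expect_equal(res$p_value, oracle_fisher_p(res$a, res$b, res$c, res$d),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(res$a, res$b, res$c, res$d), 2,
                                    byrow = TRUE), alternative = "greater")
    expect_equal(res$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate tables and empty clusters are handled explicitly", {
  bg <- sprintf("g%02d", 1:10)
  occ_all <- tibble::tibble(gene_id = bg, class = "K")
  res <- fisher_enrichment(bg[1:4], bg, occ_all, "K")
  expect_equal(res$p_value, 1)
  expect_equal(res$odds_ratio, 1)  # Haldane-corrected no-contrast table
  expect_error(fisher_enrichment(character(0), bg, occ_all, "K"), "empty")
  expect_error(fisher_enrichment("not_in_bg", bg, occ_all, "K"), "subset")
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.5, 0.02)
  expect_true(all(adjust_bh(p) >= p))
})

test_that("planted enrichment is detected and the grid stays order-invariant", {
  set.seed(73)
  bg <- sprintf("g%04d", 1:800)
  cluster_genes <- bg[1:100]
  in_k <- c(runif(100) < 0.8, runif(700) < 0.2)
  occ <- tibble::tibble(gene_id = bg[in_k], class = "NP8_AR")
  assign <- tibble::tibble(gene_id = bg,
                           cluster = c(rep(1, 100), rep(2, 700)))
  grid <- enrichment_grid(assign, bg, occ)
  q1 <- grid$q_value[grid$cluster == 1]
  expect_lt(q1, 1e-6)
  grid2 <- enrichment_grid(assign, rev(bg), occ)
  expect_equal(dplyr::arrange(grid, cluster, class)$p_value,
               dplyr::arrange(grid2, cluster, class)$p_value)
})
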