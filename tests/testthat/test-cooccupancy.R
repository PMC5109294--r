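# Overlap classes, proportions, binned correlation and centered matrices.

test_that("one-basepair interval overlap marks a partner as present", {
  primary <- make_peak("chr1", 100, 400, summit = 250)
  ar <- make_peak("chr1", 399, 600, summit = 500)
  cl <- overlap_classify(primary, list(AR = ar))
  expect_equal(cl$partners, "AR")
  cl2 <- overlap_classify(primary, list(AR = make_peak("chr1", 400, 600, summit = 500)))
  expect_equal(cl2$partners, "")
  cl3 <- overlap_classify(primary, list(AR = ar), min_overlap = 2)
  expect_equal(cl3$partners, "")
})

test_that("overlap classification agrees with the all-pairs oracle", {
  set.seed(15)
  primary <- random_peaks(200, chrom_length = 3e5)
  others <- list(AR = random_peaks(200, chrom_length = 3e5),
                 FOXA1 = random_peaks(150, chrom_length = 3e5))
  cl <- overlap_classify(primary, others)
  for (f in names(others)) {
    want <- oracle_overlap(primary, others[[f]])
    got <- vapply(strsplit(cl$partners, "+", fixed = TRUE),
                  function(p) f %in% p, logical(1))
    expect_equal(got, want)
  }
})

test_that("proportions partition to one and ignore peak order", {
  set.seed(16)
  primary <- random_peaks(300, chrom_length = 5e5)
  others <- list(AR = random_peaks(300, chrom_length = 5e5))
  pr <- cooccupancy_proportions(overlap_classify(primary, others))
  expect_equal(sum(pr$fraction), 1, tolerance = 1e-12)
  shuffled <- primary[sample.int(nrow(primary)), ]
  pr2 <- cooccupancy_proportions(overlap_classify(shuffled, others))
  expect_equal(dplyr::arrange(pr, partners), dplyr::arrange(pr2, partners))
})

test_that("binned correlation is exact for self and symmetric", {
  cfg <- sim_config(seed = 41, n_chrom = 1, chrom_length = 1e6, n_peaks = 100)
  pk <- random_peaks(100, chrom_length = 1e6, chroms = "chr1")
  tr <- simulate_signal(pk, cfg)
  cm <- binned_correlation(list(a = tr, b = tr), bin_size = 10000)
  expect_equal(cm["a", "b"], 1)
  tr2 <- simulate_signal(random_peaks(100, chrom_length = 1e6, chroms = "chr1"),
                         cfg, seed_offset = 5L)
  cm2 <- binned_correlation(list(a = tr, b = tr2), bin_size = 5000)
  expect_identical(cm2, t(cm2))
  expect_equal(diag(cm2), c(a = 1, b = 1))
})

test_that("a constant track yields NA correlation with a warning", {
  sizes <- c(chr1 = 1e4)
  flat <- signal_track(list(chr1 = rep(2, 100)), 100, sizes)
  set.seed(2)
  bumpy <- signal_track(list(chr1 = runif(100)), 100, sizes)
  expect_warning(cm <- binned_correlation(list(f = flat, b = bumpy), bin_size = 100),
                 "constant")
  expect_true(is.na(cm["f", "b"]))
  expect_equal(cm["b", "b"], 1)
})

test_that("centered matrix averages bins, sorts by score and NAs edges", {
  sizes <- c(chr1 = 1e4)
  flat <- signal_track(list(chr1 = rep(3, 100)), 100, sizes)
  pk <- dplyr::bind_rows(
    make_peak("chr1", 4900, 5100, summit = 5000, score = 5, name = "low"),
    make_peak("chr1", 3900, 4100, summit = 4000, score = 9, name = "high")
  )
  cm <- peak_centered_matrix(flat, pk, flank = 1000, bin = 200)
  expect_equal(dim(cm), c(2, 10))
  expect_true(all(cm == 3))
  expect_equal(attr(cm, "peaks")$name, c("high", "low"))
  # delta signal peaks in the two central columns
  v <- rep(0, 100)
  v[51] <- 10  # bin covering [5000, 5100)
  delta <- signal_track(list(chr1 = v), 100, sizes)
  cmd <- peak_centered_matrix(delta, make_peak("chr1", 4900, 5100, summit = 5000),
                              flank = 1000, bin = 200)
  expect_equal(which.max(cmd[1, ]), 6)  # column starting at the summit
  # out-of-chromosome bins are NA
  edge <- peak_centered_matrix(flat, make_peak("chr1", 100, 300, summit = 200),
                               flank = 1000, bin = 200)
  expect_true(anyNA(edge[1, 1:4]))
  expect_false(anyNA(edge[1, 6:10]))
})

test_that("non-promoter profile is flat for uniform coverage and excludes promoters", {
  sizes <- c(chr1 = 2e5)
  uni <- signal_track(list(chr1 = rep(4, 2000)), 100, sizes)
  genes <- make_gene("g", "chr1", 100000, 120000, "+")
  pk <- dplyr::bind_rows(
    make_peak("chr1", 49900, 50100, summit = 50000, name = "far"),
    make_peak("chr1", 99900, 100100, summit = 100000, name = "at_tss")
  )
  set.seed(3)
  prof <- nonpromoter_profile(uni, pk, genes, flank = 2000, bin = 200, n_boot = 50)
  # only the far peak survives; uniform coverage -> flat at the global RPKM
  global_rpkm <- 4 * 1e9 / (100 * sum(uni$values$chr1))
  expect_equal(unique(round(prof$mean, 9)), round(global_rpkm, 9))
  expect_true(all(prof$lower <= prof$mean + 1e-12 & prof$mean <= prof$upper + 1e-12))
  expect_warning(
    empty <- nonpromoter_profile(uni, pk[2, ], genes, flank = 2000, bin = 200,
                                 n_boot = 10),
    "promoter")
  expect_equal(nrow(empty), 0)
})

test_that("bootstrap band contains the point profile on noisy data", {
  cfg <- sim_config(seed = 77, n_chrom = 1, chrom_length = 2e5, background_rate = 1)
  pk <- random_peaks(40, chrom_length = 2e5, chroms = "chr1")
  tr <- simulate_signal(pk, cfg)
  genes <- make_gene("g", "chr1", 150000, 160000, "+")
  set.seed(4)
  prof <- nonpromoter_profile(tr, pk, genes, flank = 2000, bin = 200, n_boot = 200)
  expect_true(all(prof$lower <= prof$mean + 1e-9))
  expect_true(all(prof$upper >= prof$mean - 1e-9))
})
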