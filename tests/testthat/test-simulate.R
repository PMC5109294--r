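# Generator contracts: determinism, planted structure, degenerate modes.

test_that("genome simulation is deterministic and non-overlapping", {
  cfg <- sim_config(seed = 11, n_genes = 60, chrom_length = 4e6)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 60)
  for (ch in unique(g1$chrom)) {
    gs <- dplyr::arrange(g1[g1$chrom == ch, ], start)
    if (nrow(gs) > 1) expect_true(all(gs$start[-1] >= gs$end[-nrow(gs)]))
  }
  expect_equal(nrow(simulate_genome(sim_config(n_genes = 0))), 0)
  expect_error(simulate_genome(sim_config(n_genes = 500, chrom_length = 1e6)),
               "cannot fit")
})

test_that("cistrome simulation plants the requested co-occupancy structure", {
  cfg <- sim_config(seed = 5, n_genes = 20, n_peaks = 300, chrom_length = 5e6,
                    cooccupancy_fractions = c("NP8+AR+FOXA1" = 1.0))
  cis <- simulate_cistromes(simulate_genome(cfg), cfg)
  cl <- overlap_classify(cis$peaks$NP8, cis$peaks[c("AR", "FOXA1")])
  expect_true(all(cl$partners == "AR+FOXA1"))

  cfg0 <- sim_config(seed = 5, n_genes = 20, n_peaks = 300, chrom_length = 5e6,
                     cooccupancy_fractions = c("NP8" = 1.0))
  cis0 <- simulate_cistromes(simulate_genome(cfg0), cfg0)
  cl0 <- overlap_classify(cis0$peaks$NP8, cis0$peaks[c("AR", "FOXA1")])
  expect_true(all(cl0$partners == ""))

  expect_error(sim_config(cooccupancy_fractions = c("NP8+AR" = 0.7, "NP8" = 0.5)),
               "sum")
})

test_that("signal simulation gives flat background with no peaks and bumps at summits", {
  cfg <- sim_config(seed = 9, n_chrom = 1, chrom_length = 1e5,
                    background_rate = 0)
  empty <- make_peak("chr1", 1, 2)[0, ]
  tr0 <- simulate_signal(empty, cfg)
  expect_true(all(tr0$values$chr1 == 0))
  pk <- make_peak("chr1", 49800, 50200, summit = 50000, score = 100)
  tr1 <- simulate_signal(pk, cfg)
  expect_equal(which.max(tr1$values$chr1), 50000 %/% cfg$bin_size + 1)
})

test_that("sequence planting respects mode contracts", {
  p <- example_pwms()$FOXA
  ab <- simulate_peak_sequences(20, 201, p, "absent", seed = 3)
  expect_true(all(is.na(ab$planted_offset)))
  ct <- simulate_peak_sequences(20, 201, p, "central", motif_sd = 0, seed = 3)
  expect_true(all(ct$planted_offset == 0))
  # deterministic PWM -> planted sites match the consensus word
  det <- pwm(diag(4)[, c(1, 2, 3, 4, 1)], id = "det")
  ds <- simulate_peak_sequences(10, 101, det, "central", motif_sd = 0, seed = 4)
  expect_true(all(substr(ds$sequence, 49, 53) == "ACGTA"))
  expect_identical(simulate_peak_sequences(5, 101, p, "uniform", seed = 8),
                   simulate_peak_sequences(5, 101, p, "uniform", seed = 8))
})

test_that("count simulation is reproducible and nulls share means", {
  cfg <- sim_config(seed = 21, n_expr_genes = 300, deg_fraction = 0)
  s1 <- simulate_counts(character(0), cfg)
  s2 <- simulate_counts(character(0), cfg)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$truth$cluster == 0))
  # paper design: triplicates everywhere except the duplicate condition
  reps <- dplyr::count(s1$meta, group, condition)
  expect_equal(reps$n[reps$group == "NP8" & reps$condition == "AD_d12"], 2)
  expect_true(all(reps$n[!(reps$group == "NP8" & reps$condition == "AD_d12")] == 3))
})

test_that("planted fold changes are recovered at low dispersion", {
  cfg <- sim_config(seed = 22, n_expr_genes = 400, deg_fraction = 0.5,
                    nb_dispersion = 1e-3, baseline_log_mean = log(2000),
                    baseline_log_sd = 0.2, library_size_cv = 0)
  sim <- simulate_counts(character(0), cfg)
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$gene_id
  meta <- sim$meta
  sa <- meta$sample[meta$group == "NP8" & meta$condition == "AI_d22"]
  sb <- meta$sample[meta$group == "pLVX" & meta$condition == "AI_d22"]
  emp <- log2(rowMeans(m[, sa]) / rowMeans(m[, sb]))
  planted <- sim$truth$AI_d22
  expect_lt(max(abs(emp - planted)), 0.25)
})

test_that("limiting-dilution takes follow the single-hit saturation limits", {
  cfg <- sim_config(seed = 31)
  none <- simulate_ld_experiment(cfg, frequency = 0)
  expect_true(all(none$k == 0))
  all_take <- simulate_ld_experiment(cfg, frequency = 0.5)
  expect_true(all(all_take$k == all_take$n))
  expect_identical(simulate_ld_experiment(cfg), simulate_ld_experiment(cfg))
})
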