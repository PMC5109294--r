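# CPM, NB exact test, DEG rule, trajectory clustering and archetypes.

test_that("CPM normalization scales and is invariant to count doubling", {
  m <- matrix(c(2, 1999998, 0, 1000000), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- normalize_counts(m)
  expect_equal(cpm["g1", "s1"], 1)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  expect_equal(normalize_counts(m * 2)[, "s1"], cpm[, "s1"])
  expect_error(normalize_counts(cbind(m, s3 = c(0, 0))), "zero library")
})

test_that("identical groups give near-zero fold change and calm p-values", {
  set.seed(61)
  mu <- rlnorm(400, log(100), 1)
  m <- sapply(1:6, function(j) rnbinom(400, size = 10, mu = mu))
  dimnames(m) <- list(paste0("g", 1:400), paste0("s", 1:6))
  de <- test_de(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_lt(abs(median(de$log2fc)), 0.1)
  expect_gt(mean(de$p_value > 0.1), 0.8)
  expect_error(test_de(m, "s1", "s4"), "dispersion")
  de1 <- test_de(m, "s1", "s4", dispersion = 0.1)
  expect_equal(nrow(de1), 400)
})

test_that("the exact test agrees qualitatively with edgeR on shared input", {
  skip_if_not_installed("edgeR")
  set.seed(62)
  mu <- rlnorm(300, log(150), 0.8)
  fc <- rep(1, 300)
  fc[1:30] <- 4
  m <- cbind(sapply(1:3, function(j) rnbinom(300, size = 10, mu = mu * fc)),
             sapply(1:3, function(j) rnbinom(300, size = 10, mu = mu)))
  dimnames(m) <- list(paste0("g", 1:300), paste0("s", 1:6))
  de <- test_de(m, paste0("s", 1:3), paste0("s", 4:6))
  y <- edgeR::DGEList(counts = m, group = rep(c("a", "b"), each = 3))
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y, pair = c("b", "a"))
  expect_gt(cor(log10(de$p_value + 1e-300), log10(et$table$PValue + 1e-300)), 0.9)
  expect_gt(cor(de$log2fc, et$table$logFC), 0.98)
})

test_that("DEG rule applies strict thresholds in both directions", {
  de <- tibble::tibble(
    gene_id = c("at_fc", "p_too_big", "down", "clear_up"),
    log2fc = c(log2(1.5), 1, -1, 1.6),
    p_value = c(0.01, 0.06, 0.01, 0.001)
  )
  out <- call_degs(de)
  expect_equal(out$is_deg, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$direction, c("ns", "ns", "down", "up"))
})

test_that("trajectory assembly takes the DEG union and imputes untested conditions", {
  d1 <- call_degs(tibble::tibble(gene_id = c("a", "b"), log2fc = c(2, 0),
                                 p_value = c(0.001, 0.9)))
  d2 <- call_degs(tibble::tibble(gene_id = c("b", "c"), log2fc = c(-2, 1.2),
                                 p_value = c(0.001, 0.01)))
  traj <- deg_trajectories(list(c1 = d1, c2 = d2))
  expect_setequal(traj$gene_id, c("a", "b", "c"))
  expect_equal(traj$c2[traj$gene_id == "a"], 0)
  expect_equal(traj$n_imputed[traj$gene_id == "c"], 1)
})

test_that("clustering is deterministic, order-invariant and exact at k = 1", {
  set.seed(63)
  traj <- tibble::tibble(gene_id = sprintf("g%03d", 1:60),
                         c1 = rnorm(60), c2 = rnorm(60),
                         c3 = rnorm(60), c4 = rnorm(60))
  one <- cluster_trajectories(traj, k = 1)
  expect_true(all(one$cluster == 1))
  a <- cluster_trajectories(traj, k = 4)
  b <- cluster_trajectories(traj[sample.int(60), ], k = 4)
  expect_identical(a, b)
  expect_equal(nrow(cluster_centroids(a)), 4)
})

test_that("planted archetypes are recovered and labelled as intended", {
  tmpl <- default_deg_templates()
  set.seed(64)
  n_per <- 40
  m <- tmpl[rep(1:6, each = n_per), ] + matrix(rnorm(6 * n_per * 4, 0, 0.3),
                                               ncol = 4)
  traj <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%03d", 1:(6 * n_per))),
                           tibble::as_tibble(as.data.frame(m)))
  cl <- cluster_trajectories(traj, k = 6)
  truth <- rep(1:6, each = n_per)[order(traj$gene_id)]
  expect_gte(adjusted_rand_index(cl$cluster, truth), 0.9)
  labs <- label_clusters(cluster_centroids(cl))
  expect_setequal(unique(labs$archetype),
                  c("persistently_repressed", "early_up_then_down",
                    "persistently_activated", "gradually_induced"))
})

test_that("archetype labelling follows the dead-band rules", {
  cents <- tibble::tibble(cluster = 1:5,
                          c1 = c(-1, 0.1, 1, 0, 1.5),
                          c2 = c(-1, 0.4, 1, 0, 0.9),
                          c3 = c(-1, 0.8, 1, 0, -0.6),
                          c4 = c(-1, 1.5, 1, 0, -1.5))
  labs <- label_clusters(cents)
  expect_equal(labs$archetype,
               c("persistently_repressed", "gradually_induced",
                 "persistently_activated", "other", "early_up_then_down"))
})
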