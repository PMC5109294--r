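# Single-hit frequency estimation, group comparison, incidence chi-square.

ld_table <- function(dose, n, k, group = "g") {
  tibble::tibble(group = group, dose = dose, n = n, k = k)
}

test_that("single-dose MLE equals the closed form", {
  fit <- fit_single_hit(ld_table(100, 8, 6))
  expect_equal(fit$f_hat, -log(1 - 6 / 8) / 100, tolerance = 1e-9)
  expect_equal(fit$one_in, 100 / log(4), tolerance = 1e-6)
  td <- tidy(fit)
  expect_true(td$conf.low < fit$f_hat && fit$f_hat < td$conf.high)
})

test_that("multi-dose MLE matches a grid-search oracle", {
  tab <- ld_table(c(10, 100), c(10, 10), c(1, 6))
  fit <- fit_single_hit(tab)
  grid <- exp(seq(log(1e-6), log(1), length.out = 200000))
  ll <- vapply(grid, function(f) {
    sum(tab$k * log(1 - exp(-tab$dose * f)) - (tab$n - tab$k) * tab$dose * f)
  }, numeric(1))
  expect_equal(fit$f_hat, grid[which.max(ll)], tolerance = 1e-4)
  expect_gte(fit$loglik, max(ll))
})

test_that("the MLE agrees with the cloglog binomial GLM", {
  tab <- ld_table(c(1000, 10000), c(10, 10), c(3, 9))
  fit <- fit_single_hit(tab)
  glm_fit <- stats::glm(cbind(k, n - k) ~ offset(log(dose)),
                        family = stats::binomial(link = "cloglog"), data = tab)
  expect_equal(fit$f_hat, exp(unname(stats::coef(glm_fit))), tolerance = 1e-6)
})

test_that("boundary tables produce one-sided intervals", {
  none <- fit_single_hit(ld_table(c(1000, 10000), c(10, 10), c(0, 0)))
  expect_equal(none$f_hat, 0)
  expect_equal(none$one_in, Inf)
  expect_equal(unname(none$ci["upper"]), 3.841459 / (2 * (10 * 1000 + 10 * 10000)),
               tolerance = 1e-6)
  expect_warning(sat <- fit_single_hit(ld_table(1000, 10, 10)), "unbounded")
  expect_equal(sat$f_hat, Inf)
  expect_true(is.finite(sat$ci["lower"]))
})

test_that("log-likelihood is concave so the optimum is global", {
  tab <- ld_table(c(500, 5000, 50000), c(8, 8, 8), c(1, 4, 8))
  fit <- fit_single_hit(tab)
  fs <- exp(seq(log(fit$f_hat / 100), log(fit$f_hat * 100), length.out = 400))
  ll <- vapply(fs, function(f) {
    sum(tab$k * log(1 - exp(-tab$dose * f)) - (tab$n - tab$k) * tab$dose * f)
  }, numeric(1))
  d2 <- diff(ll, differences = 2)
  expect_true(all(d2 < 1e-6))
  expect_true(all(ll <= fit$loglik + 1e-9))
})

test_that("frequency comparison is null at identity and powered at contrast", {
  tab <- ld_table(c(1000, 10000), c(10, 10), c(4, 10))
  null <- compare_frequencies(tab, tab)
  expect_equal(null$statistic, 0, tolerance = 1e-6)
  expect_equal(null$p_value, 1, tolerance = 1e-6)
  strong <- compare_frequencies(ld_table(c(1000, 10000), c(10, 10), c(9, 10)),
                                ld_table(c(1000, 10000), c(10, 10), c(0, 2)))
  expect_lt(strong$p_value, 0.001)
  expect_gte(strong$statistic, 0)
})

test_that("incidence chi-square matches the hand computation and base R", {
  perfect <- chi_square_incidence(ld_table(1000, 8, 8), ld_table(1000, 8, 0))
  expect_equal(perfect$pooled$statistic, 16)
  expect_equal(perfect$pooled$p_value, stats::pchisq(16, 1, lower.tail = FALSE))
  same <- chi_square_incidence(ld_table(1000, 8, 8), ld_table(1000, 8, 8))
  expect_equal(same$pooled$statistic, 0)
  expect_equal(same$pooled$p_value, 1)
  a <- ld_table(c(1000, 10000), c(10, 12), c(3, 9))
  b <- ld_table(c(1000, 10000), c(11, 10), c(1, 4))
  ours <- chi_square_incidence(a, b)
  base_tab <- matrix(c(sum(a$k), sum(a$n) - sum(a$k),
                       sum(b$k), sum(b$n) - sum(b$k)), 2, byrow = TRUE)
  base <- stats::chisq.test(base_tab, correct = FALSE)
  expect_equal(ours$pooled$statistic, unname(base$statistic))
  expect_equal(ours$pooled$p_value, base$p.value)
  expect_equal(nrow(ours$per_dose), 2)
  # symmetry under swapping both rows and both columns
  swapped <- chi_square_incidence(
    dplyr::mutate(b, k = .data$n - .data$k),
    dplyr::mutate(a, k = .data$n - .data$k))
  expect_equal(swapped$pooled$statistic, ours$pooled$statistic)
})

test_that("estimation is consistent as replicate experiments accumulate", {
  cfg <- sim_config(seed = 99)
  f_true <- 1 / 2000
  set.seed(99)
  pooled <- dplyr::bind_rows(lapply(1:1000, function(i) {
    simulate_ld_experiment(cfg, frequency = f_true, seed = sample.int(1e8, 1))
  }))
  fit <- fit_single_hit(pooled)
  expect_lt(abs(fit$f_hat / f_true - 1), 0.05)
  expect_true(fit$ci["lower"] <= f_true && f_true <= fit$ci["upper"])
})
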