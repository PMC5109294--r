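# Single-hit Poisson limiting-dilution analysis: maximum-likelihood
# tumor-initiating cell frequency, profile-likelihood CIs, likelihood-ratio
# group comparison, and Pearson chi-square incidence tests.
#
# Model: an injection of d cells takes with probability 1 - exp(-d * f),
# where f is the per-cell initiation frequency. Log-likelihood over doses:
#   l(f) = sum_i [ k_i * log(1 - exp(-d_i f)) - (n_i - k_i) * d_i * f ]
# l is concave on f > 0, so the safeguarded Newton iteration below finds
# the global maximum.

ld_loglik <- function(f, dose, n, k) {
  if (f < 0) return(-Inf)
  if (f == 0) return(if (all(k == 0)) 0 else -Inf)
  p <- -expm1(-dose * f)
  sum(k * log(p) - (n - k) * dose * f)
}

ld_score <- function(f, dose, n, k) {
  e <- exp(-dose * f)
  sum(k * dose * e / (1 - e) - (n - k) * dose)
}

#' Fit the single-hit Poisson model to a limiting-dilution table
#'
#' Maximizes the single-hit log-likelihood by a bisection-safeguarded
#' Newton iteration (relative tolerance 1e-12) and reports a 95%
#' profile-likelihood confidence interval
#' (`{f : 2 * (l(f_hat) - l(f)) <= qchisq(0.95, 1) = 3.841}`). With no
#' takes anywhere the estimate is the boundary `f = 0` with a one-sided
#' upper limit; with takes in every animal at every dose the likelihood is
#' unbounded above and the fit reports `f_hat = Inf` with a lower limit and
#' a warning.
#'
#' @param table Incidence tibble with columns `dose`, `n`, `k` (a `group`
#'   column, if present, must be a single group).
#' @return An object of class `single_hit_fit`: list with `f_hat`, `one_in`
#'   (`1 / f_hat`), `ci` (named lower/upper on f), `loglik`, `data`,
#'   `boundary` flag.
#' @export
fit_single_hit <- function(table) {
  validate_incidence(mutate(as_tibble(table),
                            group = if ("group" %in% names(table)) .data$group else "g"))
  if ("group" %in% names(table) && length(unique(table$group)) > 1) {
    abort("fit_single_hit() expects a single group; see compare_frequencies()")
  }
  dose <- as.numeric(table$dose)
  n <- as.numeric(table$n)
  k <- as.numeric(table$k)
  crit <- 3.841459  # qchisq(0.95, 1)
  if (all(k == 0)) {
    # boundary: l(f) = -sum(n d) f, so the profile upper limit is explicit
    upper <- crit / (2 * sum(n * dose))
    fit <- list(f_hat = 0, one_in = Inf, ci = c(lower = 0, upper = upper),
                loglik = 0, data = as_tibble(table), boundary = "zero")
    class(fit) <- "single_hit_fit"
    return(fit)
  }
  if (all(k == n)) {
    warn("every animal took at every dose: frequency unbounded above")
    dev <- function(f) -2 * ld_loglik(f, dose, n, k)
    lo <- 1 / max(dose) * 1e-8
    while (dev(lo) < crit) lo <- lo / 10
    lower <- uniroot(function(f) dev(f) - crit, c(lo, 1e6 / max(dose)),
                     tol = 1e-14)$root
    fit <- list(f_hat = Inf, one_in = 0, ci = c(lower = lower, upper = Inf),
                loglik = 0, data = as_tibble(table), boundary = "saturated")
    class(fit) <- "single_hit_fit"
    return(fit)
  }
  # bracket the root of the score: score > 0 near 0, < 0 for large f
  hi <- 1 / min(dose)
  while (ld_score(hi, dose, n, k) > 0) hi <- hi * 4
  lo <- hi * 1e-12
  while (ld_score(lo, dose, n, k) < 0) lo <- lo / 4
  f <- sqrt(lo * hi)
  for (iter in 1:200) {
    s <- ld_score(f, dose, n, k)
    if (s > 0) lo <- f else hi <- f
    e <- exp(-dose * f)
    d2 <- -sum(k * dose^2 * e / (1 - e)^2)
    step <- s / d2
    f_new <- f - step
    if (!is.finite(f_new) || f_new <= lo || f_new >= hi) f_new <- sqrt(lo * hi)
    if (abs(f_new - f) <= 1e-12 * f) {
      f <- f_new
      break
    }
    f <- f_new
  }
  ll <- ld_loglik(f, dose, n, k)
  dev <- function(x) 2 * (ll - ld_loglik(x, dose, n, k))
  lower <- uniroot(function(x) dev(x) - crit, c(f * 1e-12, f), tol = 1e-14)$root
  hi_ci <- f * 2
  while (dev(hi_ci) < crit && hi_ci < 1e9 / min(dose)) hi_ci <- hi_ci * 2
  upper <- uniroot(function(x) dev(x) - crit, c(f, hi_ci), tol = 1e-14)$root
  fit <- list(f_hat = f, one_in = 1 / f, ci = c(lower = lower, upper = upper),
              loglik = ll, data = as_tibble(table), boundary = "none")
  class(fit) <- "single_hit_fit"
  fit
}

#' @export
print.single_hit_fit <- function(x, ...) {
  cat("<single_hit_fit> tumor-initiating cell frequency\n")
  if (is.finite(x$one_in)) {
    cat(sprintf("  1 in %s (f = %.4g), 95%% CI on f: [%.4g, %.4g]\n",
                format(round(x$one_in), big.mark = ","), x$f_hat,
                x$ci["lower"], x$ci["upper"]))
  } else {
    cat(sprintf("  no takes: f = 0, 95%% upper limit %.4g\n", x$ci["upper"]))
  }
  invisible(x)
}

#' @rdname fit_single_hit
#' @param x A `single_hit_fit`.
#' @param ... Unused.
#' @method tidy single_hit_fit
#' @export
tidy.single_hit_fit <- function(x, ...) {
  tibble(
    term = "frequency",
    estimate = x$f_hat,
    one_in = x$one_in,
    conf.low = unname(x$ci["lower"]),
    conf.high = unname(x$ci["upper"])
  )
}

#' @rdname fit_single_hit
#' @method glance single_hit_fit
#' @export
glance.single_hit_fit <- function(x, ...) {
  tibble(
    f_hat = x$f_hat,
    one_in = x$one_in,
    conf.low = unname(x$ci["lower"]),
    conf.high = unname(x$ci["upper"]),
    logLik = x$loglik,
    n_doses = nrow(x$data),
    n_animals = sum(x$data$n),
    boundary = x$boundary
  )
}

#' Compare tumor-initiating frequencies of two groups
#'
#' Likelihood-ratio test of a common frequency against group-specific
#' frequencies, referred to chi-square with 1 degree of freedom.
#'
#' @param table_a,table_b Incidence tibbles (single group each).
#' @return One-row tibble: `f_a`, `f_b`, `f_pooled`, `statistic`, `df`,
#'   `p_value`.
#' @export
compare_frequencies <- function(table_a, table_b) {
  fa <- fit_single_hit(table_a)
  fb <- fit_single_hit(table_b)
  pooled <- bind_rows(
    select(as_tibble(table_a), "dose", "n", "k"),
    select(as_tibble(table_b), "dose", "n", "k")
  )
  fp <- fit_single_hit(pooled)
  ll_p <- if (is.finite(fp$f_hat)) fp$loglik else 0
  stat <- max(0, 2 * (fa$loglik + fb$loglik - ll_p))
  tibble(
    f_a = fa$f_hat, f_b = fb$f_hat, f_pooled = fp$f_hat,
    statistic = stat, df = 1L,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

# Pearson chi-square on a 2x2 without continuity correction; cells whose
# expectation is zero (degenerate margins) contribute nothing, so identical
# saturated incidences give statistic 0 rather than NaN.
pearson_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- E > 0
  stat <- sum((tab[ok] - E[ok])^2 / E[ok])
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Chi-square tests of tumor incidence between two groups
#'
#' Pearson chi-square (no continuity correction) on the takes/non-takes
#' 2x2, pooled across matched doses, plus per-dose tables.
#'
#' @param table_a,table_b Incidence tibbles (single group each).
#' @return List with `pooled` (one-row tibble `statistic`, `df`, `p_value`)
#'   and `per_dose` (tibble with one test per dose present in both groups).
#' @export
chi_square_incidence <- function(table_a, table_b) {
  validate_incidence(mutate(as_tibble(table_a), group = "a"))
  validate_incidence(mutate(as_tibble(table_b), group = "b"))
  pool <- matrix(c(sum(table_a$k), sum(table_a$n) - sum(table_a$k),
                   sum(table_b$k), sum(table_b$n) - sum(table_b$k)),
                 nrow = 2, byrow = TRUE)
  pc <- pearson_chisq(pool)
  doses <- intersect(table_a$dose, table_b$dose)
  per_dose <- purrr::map_dfr(doses, function(d) {
    a <- table_a[table_a$dose == d, ][1, ]
    b <- table_b[table_b$dose == d, ][1, ]
    t2 <- matrix(c(a$k, a$n - a$k, b$k, b$n - b$k), nrow = 2, byrow = TRUE)
    pd <- pearson_chisq(t2)
    tibble(dose = d, statistic = pd$statistic, df = 1L, p_value = pd$p_value)
  })
  list(
    pooled = tibble(statistic = pc$statistic, df = 1L, p_value = pc$p_value),
    per_dose = per_dose
  )
}
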