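# Counts-per-million normalization, conditional negative-binomial exact
# test, fold-change/p-value DEG calls, and trajectory clustering.

counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  if (!is.data.frame(counts)) abort("counts must be a matrix or data frame")
  if (!"gene_id" %in% names(counts)) abort("count table must have a gene_id column")
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  m
}

#' Counts-per-million normalization
#'
#' @param counts Gene-by-sample matrix, or wide tibble with `gene_id`.
#' @return Object of the same shape with every sample scaled to sum to 1e6.
#' @export
normalize_counts <- function(counts) {
  m <- counts_to_matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("zero library size in sample '%s'", colnames(m)[which(lib == 0)[1]]))
  }
  cpm <- sweep(m, 2, lib, "/") * 1e6
  if (is.data.frame(counts)) {
    out <- as_tibble(as.data.frame(cpm))
    out <- dplyr::bind_cols(tibble(gene_id = counts$gene_id), out)
    return(out)
  }
  cpm
}

# Median-of-ratios effective library sizes (robust to asymmetric
# differential expression, which biases total-count scaling). Falls back to
# total counts when no gene is expressed in every sample.
effective_lib_sizes <- function(m) {
  tot <- colSums(m)
  logm <- log(m)
  ok <- rowSums(is.finite(logm)) == ncol(m)
  if (!any(ok)) return(tot)
  ref <- rowMeans(logm[ok, , drop = FALSE])
  sf <- apply(logm[ok, , drop = FALSE], 2, function(x) exp(stats::median(x - ref)))
  sf / exp(mean(log(sf))) * exp(mean(log(tot)))
}

#' Common negative-binomial dispersion by method of moments
#'
#' Counts are scaled to a common library size (median-of-ratios effective
#' sizes, geometric-mean centred); the pooled ratio estimator
#' `sum(var - mean) / sum(mean^2)` over genes and groups is returned,
#' floored at `1e-4`.
#'
#' @param counts Gene-by-sample matrix or wide tibble.
#' @param groups Character/factor vector assigning samples to groups; only
#'   groups with >= 2 replicates contribute.
#' @return Common dispersion estimate (numeric scalar).
#' @export
estimate_common_dispersion <- function(counts, groups) {
  m <- counts_to_matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) abort("groups must have one entry per sample")
  lib <- effective_lib_sizes(m)
  geo <- exp(mean(log(lib)))
  scaled <- sweep(m, 2, geo / lib, "*")
  num <- 0
  den <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    mu <- rowMeans(scaled[, idx, drop = FALSE])
    v <- apply(scaled[, idx, drop = FALSE], 1, stats::var)
    num <- num + sum(v - mu)
    den <- den + sum(mu^2)
  }
  if (den == 0) abort("dispersion estimation needs at least one group with >= 2 replicates")
  max(num / den, 1e-4)
}

# Conditional NB exact test for one gene: group sums a, b with nA, nB
# (equalized) replicates and common dispersion phi. Under the null the two
# sums are NB with sizes nA/phi, nB/phi and a common success probability,
# so the conditional law of a given t = a + b is free of the mean. The
# two-sided p sums the probabilities of all outcomes no more likely than
# the observed one.
nb_exact_p <- function(a, b, nA, nB, phi) {
  t <- a + b
  if (t == 0) return(1)
  rA <- nA / phi
  rB <- nB / phi
  x <- 0:t
  logw <- lchoose(x + rA - 1, x) + lchoose(t - x + rB - 1, t - x)
  logw <- logw - max(logw)
  w <- exp(logw)
  w <- w / sum(w)
  min(1, sum(w[w <= w[a + 1] * (1 + 1e-10)]))
}

#' Differential expression by conditional NB exact test
#'
#' Tests each gene between two sample sets. Counts are scaled to the
#' geometric-mean library size and rounded; the per-gene group sums are
#' compared by a conditional negative-binomial exact test with a common
#' dispersion (method of moments across genes, floor 1e-4). The fold
#' change is `(mean CPM_a + 0.5) / (mean CPM_b + 0.5)`; counts-per-million
#' here use the median-of-ratios effective library sizes, which stay
#' calibrated when differential expression is asymmetric.
#'
#' @param counts Gene-by-sample matrix or wide tibble with `gene_id`.
#' @param samples_a,samples_b Column names (or indices) of the two groups.
#' @param dispersion Common dispersion; estimated from the data when `NULL`
#'   (requires >= 2 replicates in at least one group; with single-replicate
#'   groups a value must be supplied).
#' @return A tibble with `gene_id`, `log2fc` (a over b), `p_value`,
#'   `mean_cpm_a`, `mean_cpm_b`, plus the dispersion used as an attribute
#'   `dispersion`.
#' @export
test_de <- function(counts, samples_a, samples_b, dispersion = NULL) {
  m <- counts_to_matrix(counts)
  ma <- m[, samples_a, drop = FALSE]
  mb <- m[, samples_b, drop = FALSE]
  if (ncol(ma) < 1 || ncol(mb) < 1) abort("each group needs at least one sample")
  if (is.null(dispersion)) {
    if (ncol(ma) < 2 && ncol(mb) < 2) {
      abort("single-replicate groups: a dispersion value must be supplied")
    }
    sub <- cbind(ma, mb)
    dispersion <- estimate_common_dispersion(
      sub, c(rep("a", ncol(ma)), rep("b", ncol(mb))))
  }
  if (dispersion <= 0) abort("dispersion must be positive")
  both <- cbind(ma, mb)
  lib <- effective_lib_sizes(both)
  cpm <- sweep(both, 2, lib, "/") * 1e6
  mu_a <- rowMeans(cpm[, seq_len(ncol(ma)), drop = FALSE])
  mu_b <- rowMeans(cpm[, ncol(ma) + seq_len(ncol(mb)), drop = FALSE])
  geo <- exp(mean(log(lib)))
  eq <- round(sweep(both, 2, geo / lib, "*"))
  sum_a <- rowSums(eq[, seq_len(ncol(ma)), drop = FALSE])
  sum_b <- rowSums(eq[, ncol(ma) + seq_len(ncol(mb)), drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_p(sum_a[i], sum_b[i], ncol(ma), ncol(mb), dispersion)
  }, numeric(1))
  out <- tibble(
    gene_id = rownames(m) %||% sprintf("gene_%d", seq_len(nrow(m))),
    log2fc = log2((mu_a + 0.5) / (mu_b + 0.5)),
    p_value = p,
    mean_cpm_a = mu_a,
    mean_cpm_b = mu_b
  )
  attr(out, "dispersion") <- dispersion
  out
}

#' Call differentially expressed genes
#'
#' Applies the fold-change/p-value rule: a gene is differentially expressed
#' when its fold change exceeds `fc_threshold` in either direction
#' (strictly) and its p-value is below `p_threshold` (strictly).
#'
#' @param de Output of [test_de()] (or any tibble with `log2fc`, `p_value`).
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 1.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @return `de` with columns `is_deg` and `direction` (`"up"`, `"down"`,
#'   `"ns"`) appended.
#' @export
call_degs <- function(de, fc_threshold = 1.5, p_threshold = 0.05) {
  lfc_thr <- log2(fc_threshold)
  mutate(as_tibble(de),
    is_deg = (abs(.data$log2fc) > lfc_thr) & (.data$p_value < p_threshold),
    direction = dplyr::case_when(
      .data$is_deg & .data$log2fc > 0 ~ "up",
      .data$is_deg ~ "down",
      TRUE ~ "ns"
    )
  )
}

#' Log2 fold-change trajectory matrix of DEGs
#'
#' Binds per-condition differential-expression results into the gene-by-
#' condition log2 fold-change matrix used for clustering, keeping genes
#' called differentially expressed in at least one condition. Fold changes
#' of genes not tested in a condition are imputed as 0 and flagged.
#'
#' @param de_list Named list of [call_degs()] outputs, in condition order.
#' @return A tibble with `gene_id`, one `log2fc` column per condition, and
#'   `n_imputed`.
#' @export
deg_trajectories <- function(de_list) {
  if (is.null(names(de_list))) abort("de_list must be named by condition")
  degs <- sort(unique(unlist(lapply(de_list, function(d) d$gene_id[d$is_deg]))))
  if (length(degs) == 0) {
    return(tibble(gene_id = character(0), n_imputed = integer(0)))
  }
  out <- tibble(gene_id = degs)
  imput <- integer(length(degs))
  for (cond in names(de_list)) {
    v <- de_list[[cond]]$log2fc[match(degs, de_list[[cond]]$gene_id)]
    imput <- imput + is.na(v)
    v[is.na(v)] <- 0
    out[[cond]] <- v
  }
  out$n_imputed <- imput
  out
}

#' Cluster DEG fold-change trajectories
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward linkage
#' via `ward.D2`) of the gene-by-condition log2 fold-change matrix, cut at
#' `k` clusters. Rows are ordered by gene id before clustering and cluster
#' ids relabelled by first appearance in that order, so the partition is
#' deterministic and invariant to input row order.
#'
#' @param traj Tibble from [deg_trajectories()] (or any tibble with
#'   `gene_id` and numeric condition columns).
#' @param k Number of clusters (default 6).
#' @return A tibble `gene_id`, `cluster` with attribute `centroids` (k-row
#'   tibble of per-cluster mean trajectories and sizes).
#' @export
cluster_trajectories <- function(traj, k = 6) {
  cond_cols <- setdiff(names(traj), c("gene_id", "n_imputed"))
  if (length(cond_cols) == 0) abort("no condition columns to cluster on")
  traj <- arrange(as_tibble(traj), .data$gene_id)
  m <- as.matrix(traj[cond_cols])
  if (anyNA(m)) abort("trajectory matrix must not contain missing values")
  if (nrow(m) < k) abort(sprintf("cannot cut %d genes into %d clusters", nrow(m), k))
  if (k == 1) {
    cl <- rep(1L, nrow(m))
  } else {
    hc <- hclust(dist(m), method = "ward.D2")
    raw <- cutree(hc, k = k)
    cl <- as.integer(factor(raw, levels = unique(raw)))
  }
  centroids <- tibble(cluster = seq_len(k))
  for (cc in cond_cols) {
    centroids[[cc]] <- as.numeric(tapply(m[, cc], cl, mean))
  }
  centroids$n_genes <- as.integer(table(cl))
  out <- tibble(gene_id = traj$gene_id, cluster = cl)
  attr(out, "centroids") <- centroids
  out
}

#' Cluster centroid trajectories
#' @param assignment Output of [cluster_trajectories()].
#' @return The `centroids` attribute tibble.
#' @export
cluster_centroids <- function(assignment) {
  attr(assignment, "centroids") %||% abort("no centroids attribute; run cluster_trajectories()")
}

#' Label cluster centroids with trajectory archetypes
#'
#' Maps each centroid trajectory (conditions in time order) to one of the
#' archetypes: `persistently_repressed` (all entries below `-delta`),
#' `persistently_activated` (all above `delta`), `early_up_then_down`
#' (first entry above `delta`, last below `-delta`), `gradually_induced`
#' (monotone non-decreasing with last entry above `delta`), else `other`.
#'
#' @param centroids Tibble from [cluster_centroids()] (columns `cluster`,
#'   conditions, optionally `n_genes`).
#' @param delta Dead-band on the log2 scale (default 0.2).
#' @return `centroids` with an `archetype` column appended.
#' @export
label_clusters <- function(centroids, delta = 0.2) {
  cond_cols <- setdiff(names(centroids), c("cluster", "n_genes", "archetype"))
  m <- as.matrix(centroids[cond_cols])
  lab <- apply(m, 1, function(v) {
    last <- v[length(v)]
    if (all(v < -delta)) "persistently_repressed"
    else if (all(v > delta)) "persistently_activated"
    else if (v[1] > delta && last < -delta) "early_up_then_down"
    else if (!is.unsorted(v) && last > delta) "gradually_induced"
    else "other"
  })
  mutate(as_tibble(centroids), archetype = as.character(lab))
}
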