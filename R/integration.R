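# Peak-to-gene assignment in +/-50 kb windows and Fisher exact enrichment
# of DEG clusters in co-occupancy classes, with BH control.

#' Assign classified peaks to genes within a window
#'
#' A gene carries co-occupancy class `k` when at least one class-`k` peak
#' summit lies strictly within `window` bp of the gene span, i.e. in
#' `(gene_start - window, gene_end + window)` on the gene's chromosome
#' (gene-body anchored; a summit exactly `window` bp away on either side
#' does not count).
#'
#' @param classified_peaks Output of [overlap_classify()] (needs `chrom`,
#'   `summit`, `partners`).
#' @param genes A validated gene tibble.
#' @param window Extension in bp on each side (default 50 kb).
#' @param class_label Function mapping a `partners` string to a class name;
#'   the default prefixes the primary factor of the peaks (`factor` column)
#'   or uses the partner string itself.
#' @return A tibble `gene_id`, `class` (one row per gene x class present).
#' @export
assign_peaks_to_genes <- function(classified_peaks, genes, window = 50000,
                                  class_label = NULL) {
  if (!"partners" %in% names(classified_peaks)) {
    abort("classified_peaks must carry a 'partners' column (run overlap_classify())")
  }
  validate_genes(genes)
  primary <- unique(classified_peaks$factor) %||% NULL
  lab <- if (!is.null(class_label)) {
    class_label(classified_peaks$partners)
  } else if (!is.null(primary) && length(primary) == 1 && !is.na(primary[1])) {
    ifelse(classified_peaks$partners == "", paste0(primary, "_only"),
           paste(primary, gsub("\\+", "_", classified_peaks$partners), sep = "_"))
  } else {
    ifelse(classified_peaks$partners == "", "primary_only",
           classified_peaks$partners)
  }
  out <- list()
  for (cls in sort(unique(lab))) {
    pk <- classified_peaks[lab == cls, , drop = FALSE]
    for (ch in unique(genes$chrom)) {
      gi <- which(genes$chrom == ch)
      summits <- sort(pk$summit[pk$chrom == ch])
      if (length(summits) == 0 || length(gi) == 0) next
      lo <- genes$start[gi] - window
      hi <- genes$end[gi] + window
      n_lo <- findInterval(lo + 0.5, summits)
      n_hi <- findInterval(hi - 0.5, summits)
      has <- n_hi > n_lo
      if (any(has)) {
        out[[length(out) + 1]] <- tibble(gene_id = genes$gene_id[gi][has], class = cls)
      }
    }
  }
  if (length(out) == 0) return(tibble(gene_id = character(0), class = character(0)))
  bind_rows(out) |> arrange(.data$gene_id, .data$class)
}

#' Fisher exact enrichment of a gene set in an occupancy class
#'
#' One-sided (enrichment) hypergeometric test of the 2x2 table
#' in-cluster/out-cluster vs class-present/class-absent over the background
#' gene universe. The odds ratio uses the Haldane correction (+0.5 to every
#' cell) when any cell is zero.
#'
#' @param cluster_genes Character vector (must be a subset of
#'   `background_genes`, non-empty).
#' @param background_genes Character vector: the tested gene universe.
#' @param occupancy Tibble from [assign_peaks_to_genes()].
#' @param class Class name to test.
#' @return One-row tibble: `class`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`.
#' @export
fisher_enrichment <- function(cluster_genes, background_genes, occupancy, class) {
  cluster_genes <- unique(cluster_genes)
  background_genes <- unique(background_genes)
  if (length(cluster_genes) == 0) abort("cluster is empty")
  if (!all(cluster_genes %in% background_genes)) {
    abort("cluster_genes must be a subset of background_genes")
  }
  with_class <- unique(occupancy$gene_id[occupancy$class == class])
  with_class <- intersect(with_class, background_genes)
  in_cl <- background_genes %in% cluster_genes
  in_k <- background_genes %in% with_class
  a <- sum(in_cl & in_k)
  b <- sum(in_cl & !in_k)
  c_ <- sum(!in_cl & in_k)
  d <- sum(!in_cl & !in_k)
  p <- phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) {
    or <- 1  # degenerate margin: no contrast to estimate
  } else {
    cells <- c(a, b, c_, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  }
  tibble(class = class, a = a, b = b, c = c_, d = d,
         odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control across a vector of p-values (thin
#' wrapper over [stats::p.adjust()] kept as the pipeline's documented
#' correction step).
#'
#' @param p Numeric vector of p-values.
#' @return Vector of BH-adjusted q-values.
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")

#' Cluster-by-class enrichment grid
#'
#' Runs [fisher_enrichment()] for every cluster x class combination and
#' BH-adjusts across the whole grid.
#'
#' @param cluster_assignment Tibble `gene_id`, `cluster` (e.g. from
#'   [cluster_trajectories()]).
#' @param background_genes Character vector: the tested gene universe.
#' @param occupancy Tibble from [assign_peaks_to_genes()].
#' @param classes Classes to test (default: all in `occupancy`).
#' @return Tibble with one row per cluster x class: counts, odds ratio,
#'   `p_value`, `q_value`.
#' @export
enrichment_grid <- function(cluster_assignment, background_genes, occupancy,
                            classes = NULL) {
  classes <- classes %||% sort(unique(occupancy$class))
  res <- purrr::map_dfr(sort(unique(cluster_assignment$cluster)), function(cl) {
    genes_cl <- cluster_assignment$gene_id[cluster_assignment$cluster == cl]
    purrr::map_dfr(classes, function(k) {
      mutate(fisher_enrichment(genes_cl, background_genes, occupancy, k),
             cluster = cl, .before = 1)
    })
  })
  mutate(res, q_value = adjust_bh(.data$p_value))
}
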