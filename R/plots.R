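# ggplot2 views of the main result types.

#' Bar chart of peak region classes
#' @param annotated Output of [classify_peaks()].
#' @return A ggplot.
#' @export
plot_region_distribution <- function(annotated) {
  annotated |>
    count(.data$region) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$region, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a peak-centered signal matrix
#' @param object A `centered_matrix` from [peak_centered_matrix()].
#' @param max_rows Rows drawn (top by score; default 1000).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot centered_matrix
#' @export
autoplot.centered_matrix <- function(object, max_rows = 1000, ...) {
  m <- unclass(object)
  keep <- seq_len(min(nrow(m), max_rows))
  df <- tidyr::expand_grid(row = keep, col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  df$offset <- attr(object, "offsets")[df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "distance from summit (bp)", y = "peaks (by score)",
                  fill = "signal") +
    ggplot2::theme_minimal()
}

#' Mean profile with bootstrap band
#' @param profile Output of [nonpromoter_profile()].
#' @return A ggplot.
#' @export
plot_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "distance from summit (bp)", y = "signal (RPKM)") +
    ggplot2::theme_minimal()
}

#' Positional distribution of motif sites
#' @param sites Output of [scan_sequences()].
#' @param binwidth Histogram bin (bp).
#' @return A ggplot.
#' @export
plot_site_positions <- function(sites, binwidth = 25) {
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            color = "white") +
    ggplot2::labs(x = "site offset from summit (bp)", y = "sites") +
    ggplot2::theme_minimal()
}

#' Cluster trajectory profiles
#' @param traj Output of [deg_trajectories()].
#' @param assignment Output of [cluster_trajectories()].
#' @return A ggplot.
#' @export
plot_trajectories <- function(traj, assignment) {
  cond_cols <- setdiff(names(traj), c("gene_id", "n_imputed"))
  df <- traj |>
    left_join(assignment, by = "gene_id") |>
    tidyr::pivot_longer(all_of(cond_cols), names_to = "condition",
                        values_to = "log2fc") |>
    mutate(condition = factor(.data$condition, levels = cond_cols))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$log2fc,
                                   group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.1) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", color = "red", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Cluster-by-class enrichment heat map
#' @param grid Output of [enrichment_grid()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$class, y = factor(.data$cluster),
                                     fill = -log10(pmax(.data$q_value, 1e-300)))) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = "cluster", fill = "-log10 q") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dose-response view of a single-hit fit
#' @param object A `single_hit_fit`.
#' @param ... Unused.
#' @return A ggplot with observed take fractions and the fitted single-hit
#'   curve.
#' @method autoplot single_hit_fit
#' @export
autoplot.single_hit_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble(dose = exp(seq(log(min(d$dose) / 2), log(max(d$dose) * 2),
                                 length.out = 200)))
  f <- if (is.finite(object$f_hat)) object$f_hat else object$ci["lower"]
  curve$p <- -expm1(-curve$dose * f)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dose, y = .data$k / .data$n)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p),
                       color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cells injected", y = "take fraction") +
    ggplot2::theme_minimal()
}
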