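# End-to-end orchestration of the synthetic-to-report run.

#' Example position weight matrices
#'
#' Synthetic PWMs shaped after the field's consensus words, with
#' heterogeneous per-position information content (as real motifs have, so
#' log-odds scores are effectively continuous and score ties negligible):
#' a forkhead-family site (`FOXA`, TGTTTAC), an androgen-response half-site
#' (`ARE_half`, AGAACA) and a nuclear-factor-I half-site (`NFI_half`,
#' TTGGC). These are constructed motifs for simulation and testing, not
#' database entries.
#'
#' @return Named list of [pwm()] objects.
#' @export
example_pwms <- function() {
  mk <- function(word, confidence, id) {
    idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
    # uneven split of the off-consensus mass breaks score degeneracy
    split <- c(0.55, 0.30, 0.15)
    m <- vapply(seq_along(idx), function(j) {
      col <- numeric(4)
      col[idx[j]] <- confidence[j]
      col[setdiff(1:4, idx[j])] <- (1 - confidence[j]) * split
      col
    }, numeric(4))
    pwm(m, id = id)
  }
  list(
    FOXA = mk("TGTTTAC", c(0.97, 0.94, 0.88, 0.93, 0.84, 0.91, 0.79), "FOXA"),
    ARE_half = mk("AGAACA", c(0.95, 0.90, 0.86, 0.92, 0.83, 0.78), "ARE_half"),
    NFI_half = mk("TTGGC", c(0.93, 0.88, 0.95, 0.90, 0.81), "NFI_half")
  )
}

#' Pipeline configuration
#'
#' Stage parameters default to the reference analysis windows: the
#' -5 kb/+0.5 kb promoter class with 15 kb distal limits, the -8 kb/+2 kb
#' extended promoter, +/-10 kb signal flank, +/-500 bp motif windows on the
#' top 800 peaks at alpha 0.001, fold change > 1.5 and p < 0.05 for DEG
#' calls, six trajectory clusters, and a +/-50 kb integration window.
#'
#' @param sim A [sim_config()] controlling the synthetic inputs.
#' @param promoter_up,promoter_down Extended promoter window (bp).
#' @param flank,signal_bin Centered-matrix geometry (bp).
#' @param correlation_bin Genome bin for occupancy correlation (bp).
#' @param n_motif_peaks Peaks (top by score) used in the motif stage.
#' @param motif_alpha Score calibration level.
#' @param fc_threshold,p_threshold DEG rule.
#' @param k_clusters Trajectory clusters.
#' @param integration_window Peak-to-gene window (bp).
#' @param ld_frequency_a,ld_frequency_b Planted frequencies of the two
#'   limiting-dilution groups (control and knockdown).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            promoter_up = 8000, promoter_down = 2000,
                            flank = 10000, signal_bin = 100,
                            correlation_bin = 10000,
                            n_motif_peaks = 800,
                            motif_alpha = 0.001,
                            fc_threshold = 1.5, p_threshold = 0.05,
                            k_clusters = 6,
                            integration_window = 50000,
                            ld_frequency_a = 1 / 2000,
                            ld_frequency_b = 1 / 100000) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage <- function(x, out_dir, name) {
  readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
}

#' Run the full synthetic-to-report pipeline
#'
#' Simulates a genome, cistromes, coverage tracks, peak sequences, a count
#' table and limiting-dilution incidences; then annotates peaks, classifies
#' co-occupancy, correlates occupancy tracks, builds the centered signal
#' matrix and non-promoter profile, scans motifs with central enrichment,
#' calls and clusters DEGs, tests cluster-by-class enrichment, and fits the
#' single-hit frequency model. Each stage's table is written as TSV along
#' with a machine-readable `manifest.json`; the run is fully deterministic
#' under the config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Report directory (created if missing).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a named list with every stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  primary <- sim$factors[1]

  say("[simulate] genome: %d genes on %d chromosome(s)", sim$n_genes, sim$n_chrom)
  genes <- simulate_genome(sim)
  chrom_sizes <- sim_chrom_sizes(sim)
  cis <- simulate_cistromes(genes, sim)
  tracks <- lapply(seq_along(sim$factors), function(i) {
    simulate_signal(cis$peaks[[i]], sim, chrom_sizes, seed_offset = i)
  })
  names(tracks) <- sim$factors
  counts_sim <- simulate_counts(genes$gene_id, sim)
  ld_a <- simulate_ld_experiment(sim, frequency = config$ld_frequency_a,
                                 group = "control",
                                 seed = derive_seed(sim$seed, 61L))
  ld_b <- simulate_ld_experiment(sim, frequency = config$ld_frequency_b,
                                 group = "knockdown",
                                 seed = derive_seed(sim$seed, 62L))
  write_stage(cis$truth, out_dir, "truth_cistromes")
  write_stage(counts_sim$truth, out_dir, "truth_counts")

  say("[annotate] classifying %d %s peaks", nrow(cis$peaks[[primary]]), primary)
  annotated <- classify_peaks(cis$peaks[[primary]], genes)
  write_stage(select(annotated, "name", "chrom", "summit", "region",
                     "nearest_gene", "dist_tss"), out_dir, "peak_annotation")
  occ_maps <- lapply(cis$peaks, promoter_occupancy, genes = genes,
                     upstream = config$promoter_up, downstream = config$promoter_down)
  venn <- shared_promoter_sets(occ_maps)
  write_stage(select(venn, "subset", "n_genes"), out_dir, "promoter_venn")

  say("[cooccupy] classifying overlaps and correlating tracks")
  classified <- overlap_classify(cis$peaks[[primary]], cis$peaks[-1])
  proportions <- cooccupancy_proportions(classified)
  write_stage(proportions, out_dir, "cooccupancy_proportions")
  cor_mat <- binned_correlation(tracks, bin_size = config$correlation_bin)
  write_stage(as_tibble(cor_mat, rownames = "factor"), out_dir, "occupancy_correlation")
  cm <- peak_centered_matrix(tracks[[primary]], cis$peaks[[primary]],
                             flank = config$flank, bin = config$signal_bin)
  cm_tbl <- as_tibble(as.data.frame(`colnames<-`(unclass(cm)[, , drop = FALSE],
                                                 attr(cm, "offsets"))))
  write_stage(dplyr::bind_cols(tibble(peak = attr(cm, "peaks")$name), cm_tbl),
              out_dir, "centered_matrix")
  profile <- withr::with_seed(derive_seed(sim$seed, 63L),
    nonpromoter_profile(tracks[[primary]], cis$peaks[[primary]], genes,
                        upstream = config$promoter_up,
                        downstream = config$promoter_down,
                        flank = config$flank, bin = config$signal_bin))
  write_stage(profile, out_dir, "nonpromoter_profile")

  say("[motif] scanning top %d peaks", config$n_motif_peaks)
  n_top <- min(config$n_motif_peaks, nrow(cis$peaks[[primary]]))
  pwm_use <- example_pwms()$FOXA
  seqs <- simulate_peak_sequences(n_top, sim$seq_length, pwm_use,
                                  mode = sim$motif_mode, motif_sd = sim$motif_sd,
                                  base_composition = sim$base_composition,
                                  seed = derive_seed(sim$seed, 64L))
  thr <- calibrate_threshold(pwm_use, config$motif_alpha)
  sites <- scan_sequences(seqs, pwm_use, thr)
  centrality <- central_enrichment(sites, sim$seq_length, pwm_width(pwm_use))
  frac <- tibble(n_with_site = nrow(sites), n_total = n_top,
                 fraction = nrow(sites) / n_top, threshold = as.numeric(thr))
  write_stage(sites, out_dir, "motif_sites")
  write_stage(dplyr::bind_cols(frac, centrality), out_dir, "motif_summary")

  say("[expression] testing %d genes x %d conditions", nrow(counts_sim$counts),
      length(sim$conditions))
  de_list <- lapply(sim$conditions, function(cond) {
    meta <- counts_sim$meta
    sa <- meta$sample[meta$group == "NP8" & meta$condition == cond]
    sb <- meta$sample[meta$group == "pLVX" & meta$condition == cond]
    call_degs(test_de(counts_sim$counts, sa, sb),
              fc_threshold = config$fc_threshold, p_threshold = config$p_threshold)
  })
  names(de_list) <- sim$conditions
  de_all <- bind_rows(de_list, .id = "condition")
  write_stage(de_all, out_dir, "differential_expression")
  traj <- deg_trajectories(de_list)
  clusters <- cluster_trajectories(traj, k = config$k_clusters)
  labels <- label_clusters(cluster_centroids(clusters))
  write_stage(clusters, out_dir, "deg_clusters")
  write_stage(labels, out_dir, "cluster_archetypes")

  say("[integrate] %d DEGs vs occupancy classes", nrow(clusters))
  occupancy <- assign_peaks_to_genes(classified, genes,
                                     window = config$integration_window)
  background <- intersect(counts_sim$counts$gene_id, genes$gene_id)
  clusters_bg <- filter(clusters, .data$gene_id %in% background)
  enrichment <- if (nrow(clusters_bg) > 0 && length(unique(clusters_bg$cluster)) > 0) {
    enrichment_grid(clusters_bg, background, occupancy)
  } else {
    tibble()
  }
  write_stage(occupancy, out_dir, "gene_occupancy")
  write_stage(enrichment, out_dir, "cluster_enrichment")

  say("[lda] single-hit frequency fits")
  fit_a <- fit_single_hit(ld_a)
  fit_b <- fit_single_hit(ld_b)
  lrt <- compare_frequencies(ld_a, ld_b)
  chisq <- chi_square_incidence(ld_a, ld_b)
  ld_report <- dplyr::bind_cols(
    tibble(group = c("control", "knockdown")),
    bind_rows(glance(fit_a), glance(fit_b))
  )
  write_stage(ld_report, out_dir, "ld_frequencies")
  write_stage(dplyr::bind_cols(
    lrt,
    dplyr::rename_with(chisq$pooled, ~ paste0("chisq_", .x))
  ), out_dir, "ld_comparison")

  manifest <- list(
    package = "cistromer",
    version = as.character(utils::packageVersion("cistromer")),
    seed = sim$seed,
    parameters = config[setdiff(names(config), "sim")],
    sim_parameters = sim[!vapply(sim, is.function, logical(1)) &
                           !vapply(sim, is.data.frame, logical(1))],
    ld_doses = as.list(sim$ld_doses),
    deg_templates = as.data.frame(sim$deg_templates),
    stage_rows = list(
      genes = nrow(genes), peaks_per_factor = vapply(cis$peaks, nrow, numeric(1)),
      annotated = nrow(annotated), degs = nrow(traj), clusters = nrow(clusters),
      enrichment_tests = nrow(enrichment)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    genes = genes, cistromes = cis, tracks = tracks,
    annotated = annotated, promoter_venn = venn,
    classified = classified, proportions = proportions,
    correlation = cor_mat, centered_matrix = cm, profile = profile,
    motif_sites = sites, motif_summary = dplyr::bind_cols(frac, centrality),
    de = de_list, trajectories = traj, clusters = clusters,
    cluster_labels = labels, occupancy = occupancy, enrichment = enrichment,
    ld = list(fit_a = fit_a, fit_b = fit_b, lrt = lrt, chisq = chisq),
    counts = counts_sim
  ))
}
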