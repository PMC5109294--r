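# Synthetic-data generators with planted ground truth. Every generator is
# deterministic under the config seed; one global seed fans out to
# per-generator substreams so components stay independently reproducible.

# substream offsets (documented, fixed)
SEED_GENOME <- 1L
SEED_CISTROME <- 2L
SEED_SIGNAL <- 3L
SEED_SEQS <- 4L
SEED_COUNTS <- 5L
SEED_LD <- 6L

derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 131 + 7919 * stream) %% 2147483629)
}

#' Default trajectory archetype templates
#'
#' Six planted log2 fold-change trajectories over the four conditions
#' (AD d5, AD d12, AI d7, AI d22), matching the archetype vocabulary of
#' [label_clusters()]: two persistently repressed shapes, two
#' early-up-then-down shapes, one persistently activated and one gradually
#' induced, with peak effect size 1.5 on the log2 scale.
#'
#' @return A 6 x 4 numeric matrix (clusters x conditions).
#' @export
default_deg_templates <- function() {
  m <- rbind(
    c(-1.5, -1.5, -1.5, -1.5),  # persistently_repressed
    c( 1.5, -0.3, -1.5, -1.5),  # early_up_then_down
    c(-1.5, -0.4, -1.5, -0.4),  # persistently_repressed (milder late)
    c( 1.5,  1.5,  1.5,  1.5),  # persistently_activated
    c( 0.1,  0.6,  1.1,  1.5),  # gradually_induced
    c( 1.5,  1.0, -0.5, -1.5)   # early_up_then_down (slower decline)
  )
  dimnames(m) <- list(paste0("cluster_", 1:6),
                      c("AD_d5", "AD_d12", "AI_d7", "AI_d22"))
  m
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module. Defaults emulate the
#' study design: a two-chromosome 10-Mb-per-chromosome genome; three
#' factors with the primary first; co-occupancy fractions reproducing the
#' published proportions (three-way 0.52, +AR 0.19, +FOXA1 0.08,
#' primary-only 0.21); counts over four conditions in two groups with
#' triplicates (duplicate for NP8 at AD d12, as in the study); a planted
#' tumor-initiating frequency of 1/2000 at doses of 1000 and 10000 cells
#' with 10 animals each.
#'
#' @param seed Global integer seed.
#' @param n_chrom,chrom_length Genome shape.
#' @param n_genes Genes in the simulated genome.
#' @param gene_length_range,min_gene_gap Gene geometry in bp.
#' @param factors Factor names, primary first.
#' @param cooccupancy_fractions Named fractions over anchor subsets
#'   (`"A+B"` strings); must lie in `[0,1]` and sum to <= 1 (remainder =
#'   primary-only).
#' @param n_peaks Peaks per factor.
#' @param peak_width_range,anchor_jitter Peak geometry in bp.
#' @param bin_size,peak_sd,background_rate Signal-track shape (bin bp,
#'   Gaussian enrichment sd bp, Poisson background per bin).
#' @param motif_mode,motif_sd `"central"`, `"uniform"` or `"absent"`
#'   planting with positional sd in bp.
#' @param seq_length Peak-anchored sequence length in bp.
#' @param base_composition Background base frequencies (A, C, G, T).
#' @param n_expr_genes Genes in the expression universe (>= `n_genes`; the
#'   genomic genes are its first members).
#' @param conditions,n_reps Condition labels (time order) and replicates.
#' @param duplicate_condition Condition with one fewer treatment replicate.
#' @param deg_templates Cluster x condition log2 fold-change matrix.
#' @param deg_fraction Fraction of expression genes planted as DEGs.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline expression.
#' @param nb_dispersion Negative-binomial dispersion (> 0).
#' @param library_size_cv Half-range of the uniform library-size factor.
#' @param ld_true_frequency Planted per-cell initiation frequency.
#' @param ld_doses Tibble with `dose`, `n` (animals per dose).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length = 1e7,
                       n_genes = 500L,
                       gene_length_range = c(2000, 20000),
                       min_gene_gap = 5000,
                       factors = c("NP8", "AR", "FOXA1"),
                       cooccupancy_fractions = c("NP8+AR+FOXA1" = 0.52,
                                                 "NP8+AR" = 0.19,
                                                 "NP8+FOXA1" = 0.08),
                       n_peaks = 5000L,
                       peak_width_range = c(200, 600),
                       anchor_jitter = 50,
                       bin_size = 100L,
                       peak_sd = 150,
                       background_rate = 0.2,
                       motif_mode = c("central", "uniform", "absent"),
                       motif_sd = 20,
                       seq_length = 1001L,
                       base_composition = c(0.25, 0.25, 0.25, 0.25),
                       n_expr_genes = 2000L,
                       conditions = c("AD_d5", "AD_d12", "AI_d7", "AI_d22"),
                       n_reps = 3L,
                       duplicate_condition = "AD_d12",
                       deg_templates = default_deg_templates(),
                       deg_fraction = 0.3,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1,
                       nb_dispersion = 0.1,
                       library_size_cv = 0.2,
                       ld_true_frequency = 1 / 2000,
                       ld_doses = tibble(dose = c(1000, 10000), n = c(10, 10))) {
  motif_mode <- match.arg(motif_mode)
  fr <- cooccupancy_fractions
  if (any(fr < 0 | fr > 1)) abort("co-occupancy fractions must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-9) abort("co-occupancy fractions must sum to <= 1")
  if (nb_dispersion <= 0) abort("nb_dispersion must be positive")
  if (!(ld_true_frequency >= 0 && ld_true_frequency < 1)) {
    abort("ld_true_frequency must be in [0, 1)")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate non-overlapping gene models
#'
#' Places `n_genes` genes across the chromosomes with random strands,
#' uniform lengths, at least `min_gene_gap` bp between genes, and 1-10
#' exons per gene (first and last exon flush with the gene ends).
#'
#' @param config A [sim_config()].
#' @return A validated gene tibble (empty when `n_genes = 0`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  empty <- tibble(gene_id = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0), strand = character(0),
                  exon_starts = list(), exon_ends = list())
  if (n == 0) return(empty)
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chrom + 1)))
  max_need <- max(per_chrom) * (config$gene_length_range[2] + config$min_gene_gap)
  if (max_need > config$chrom_length) {
    abort(sprintf("cannot fit %d genes of up to %d bp with %d bp gaps in a %g bp chromosome",
                  max(per_chrom), config$gene_length_range[2], config$min_gene_gap,
                  config$chrom_length))
  }
  withr::with_seed(derive_seed(config$seed, SEED_GENOME), {
    rows <- list()
    gid <- 0
    for (ci in seq_len(config$n_chrom)) {
      ng <- per_chrom[ci]
      if (ng == 0) next
      len <- round(runif(ng, config$gene_length_range[1], config$gene_length_range[2]))
      slack <- config$chrom_length - sum(len) - config$min_gene_gap * (ng + 1)
      cuts <- sort(runif(ng + 1))
      extra <- round(slack * diff(c(0, cuts)) / cuts[ng + 1])
      gaps <- config$min_gene_gap + extra[seq_len(ng)]
      starts <- cumsum(gaps) + cumsum(c(0, len[-ng]))
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      n_ex <- sample.int(10, ng, replace = TRUE)
      for (j in seq_len(ng)) {
        gid <- gid + 1
        s <- starts[j]
        e <- s + len[j]
        if (n_ex[j] == 1) {
          es <- s
          ee <- e
        } else {
          internal <- sort(sample((s + 1):(e - 1), 2 * n_ex[j] - 2))
          bounds <- c(s, internal, e)
          es <- bounds[seq(1, length(bounds), by = 2)]
          ee <- bounds[seq(2, length(bounds), by = 2)]
        }
        rows[[gid]] <- tibble(
          gene_id = sprintf("gene_%04d", gid),
          chrom = sprintf("chr%d", ci),
          start = s, end = e, strand = strand[j],
          exon_starts = list(es), exon_ends = list(ee)
        )
      }
    }
    genes <- bind_rows(rows)
  })
  validate_genes(genes)
  genes
}

#' Chromosome sizes implied by a config
#' @param config A [sim_config()].
#' @return Named numeric vector (`chr1`, `chr2`, ...).
#' @export
sim_chrom_sizes <- function(config) {
  setNames(rep(config$chrom_length, config$n_chrom),
           sprintf("chr%d", seq_len(config$n_chrom)))
}

subset_members <- function(subset) strsplit(subset, "+", fixed = TRUE)[[1]]

#' Simulate multi-factor cistromes with planted co-occupancy
#'
#' Draws anchor positions on a 2-kb grid (so distinct anchors are separated
#' by well over 1 kb), assigns each primary anchor a factor subset with the
#' configured probabilities (remainder = primary-only), and emits one peak
#' per anchor per member factor, jittered by at most `anchor_jitter` bp so
#' all peaks of an anchor mutually overlap. Partner factors additionally
#' receive partner-only anchors so every factor has `n_peaks` peaks.
#'
#' @param genes Gene tibble (unused for placement; accepted so callers can
#'   thread the genome through the pipeline).
#' @param config A [sim_config()].
#' @return List with `peaks` (named list of peak tibbles, one per factor)
#'   and `truth` (tibble `anchor_id`, `chrom`, `anchor`, `subset`).
#' @export
simulate_cistromes <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  primary <- config$factors[1]
  partners <- config$factors[-1]
  fr <- config$cooccupancy_fractions
  bad <- names(fr)[!vapply(names(fr), function(s) primary %in% subset_members(s), logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("co-occupancy fractions must name subsets containing the primary factor ('%s'): %s",
                  primary, paste(bad, collapse = ", ")))
  }
  subsets <- c(names(fr), primary)
  probs <- c(unname(fr), 1 - sum(fr))
  withr::with_seed(derive_seed(config$seed, SEED_CISTROME), {
    # primary anchors
    subset_of <- sample(subsets, config$n_peaks, replace = TRUE, prob = probs)
    # partner-only anchors to bring each partner up to n_peaks
    extra <- lapply(partners, function(f) {
      have <- sum(vapply(subset_of, function(s) f %in% subset_members(s), logical(1)))
      n_extra <- max(0, config$n_peaks - have)
      rep(f, n_extra)
    })
    subset_all <- c(subset_of, unlist(extra))
    n_anchor <- length(subset_all)
    grid_step <- 2000
    margin <- 1000
    per_chrom_slots <- floor((config$chrom_length - 2 * margin) / grid_step)
    if (n_anchor > per_chrom_slots * config$n_chrom) {
      abort("too many peaks for the genome: anchors cannot keep 1 kb separation")
    }
    chrom_of <- sample(rep(sprintf("chr%d", seq_len(config$n_chrom)),
                           length.out = n_anchor))
    anchor <- numeric(n_anchor)
    for (ch in unique(chrom_of)) {
      idx <- which(chrom_of == ch)
      slots <- sample.int(per_chrom_slots, length(idx))
      anchor[idx] <- margin + (slots - 1) * grid_step + grid_step / 2
    }
    truth <- tibble(
      anchor_id = sprintf("anchor_%05d", seq_len(n_anchor)),
      chrom = chrom_of, anchor = anchor, subset = subset_all,
      is_primary = seq_len(n_anchor) <= config$n_peaks
    )
    peaks <- lapply(config$factors, function(f) {
      sel <- which(vapply(subset_all, function(s) f %in% subset_members(s), logical(1)))
      width <- round(runif(length(sel), config$peak_width_range[1], config$peak_width_range[2]))
      center <- anchor[sel] + round(runif(length(sel), -config$anchor_jitter, config$anchor_jitter))
      score <- stats::rgamma(length(sel), shape = 2, scale = 30)
      tibble(
        chrom = chrom_of[sel],
        start = center - floor(width / 2),
        end = center - floor(width / 2) + width,
        name = sprintf("%s_%s", f, truth$anchor_id[sel]),
        score = score,
        strand = ".",
        summit = center,
        factor = f,
        anchor_id = truth$anchor_id[sel]
      )
    })
    names(peaks) <- config$factors
  })
  for (p in peaks) validate_peaks(p)
  list(peaks = peaks, truth = truth)
}

#' Simulate a coverage track from a peak set
#'
#' Gaussian-shaped enrichment (height = peak score / 10, sd `peak_sd`)
#' at each summit over a Poisson background of rate `background_rate` per
#' bin.
#'
#' @param peaks Peak tibble (may be empty: flat background track).
#' @param config A [sim_config()].
#' @param chrom_sizes Named chromosome lengths (default from config).
#' @param seed_offset Extra substream offset so per-factor tracks differ.
#' @return A raw [signal_track()].
#' @export
simulate_signal <- function(peaks, config, chrom_sizes = sim_chrom_sizes(config),
                            seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  bs <- config$bin_size
  withr::with_seed(derive_seed(config$seed, SEED_SIGNAL + 100L * seed_offset), {
    vals <- lapply(names(chrom_sizes), function(ch) {
      nb <- ceiling(chrom_sizes[[ch]] / bs)
      v <- as.numeric(rpois(nb, config$background_rate))
      sel <- which(peaks$chrom == ch)
      if (length(sel) > 0) {
        half <- ceiling(4 * config$peak_sd / bs)
        rel <- (-half):half
        kern_pos <- rel * bs
        for (i in sel) {
          cbin <- floor(peaks$summit[i] / bs)
          bins <- cbin + rel
          ok <- bins >= 0 & bins < nb
          amp <- peaks$score[i] / 10
          v[bins[ok] + 1] <- v[bins[ok] + 1] +
            amp * exp(-kern_pos[ok]^2 / (2 * config$peak_sd^2))
        }
      }
      v
    })
    track <- signal_track(setNames(vals, names(chrom_sizes)), bs, chrom_sizes)
  })
  track
}

#' Simulate a pair of tracks with a controlled shared-anchor fraction
#'
#' Two factors share `shared_fraction` of their peak anchors; the rest are
#' independent. Increasing the shared fraction increases the genome-binned
#' occupancy correlation monotonically.
#'
#' @param config A [sim_config()].
#' @param shared_fraction Fraction of anchors common to the two factors.
#' @param n_peaks Peaks per factor (default from config).
#' @return List of two [signal_track()] objects (`a`, `b`).
#' @export
simulate_track_pair <- function(config, shared_fraction, n_peaks = config$n_peaks) {
  stopifnot(inherits(config, "sim_config"))
  if (shared_fraction < 0 || shared_fraction > 1) abort("shared_fraction must be in [0, 1]")
  n_shared <- round(n_peaks * shared_fraction)
  chrom_sizes <- sim_chrom_sizes(config)
  withr::with_seed(derive_seed(config$seed, SEED_SIGNAL + 17L), {
    draw_anchors <- function(n) {
      tibble(
        chrom = sample(names(chrom_sizes), n, replace = TRUE),
        summit = round(runif(n, 1000, config$chrom_length - 1000))
      )
    }
    shared <- draw_anchors(n_shared)
    mk <- function(own) {
      anchors <- bind_rows(shared, own)
      mutate(anchors,
             start = .data$summit - 250, end = .data$summit + 250,
             name = sprintf("p%d", seq_len(nrow(anchors))),
             score = stats::rgamma(nrow(anchors), shape = 2, scale = 30),
             strand = ".")
    }
    pa <- mk(draw_anchors(n_peaks - n_shared))
    pb <- mk(draw_anchors(n_peaks - n_shared))
  })
  list(a = simulate_signal(pa, config, chrom_sizes, seed_offset = 1L),
       b = simulate_signal(pb, config, chrom_sizes, seed_offset = 2L))
}

#' Simulate summit-anchored sequences with planted motif sites
#'
#' Backgrounds are i.i.d. draws from `base_composition`. In `central` mode
#' one site (drawn column-wise from the PWM) is planted per sequence at an
#' offset `~ Normal(0, motif_sd)` (rounded, clipped to fit); `uniform`
#' plants at a uniform position; `absent` plants nothing.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param pwm A [pwm()].
#' @param mode `"central"`, `"uniform"` or `"absent"`.
#' @param motif_sd Positional sd for `central` mode (bp).
#' @param base_composition Background base frequencies.
#' @param seed Integer seed.
#' @return A tibble `name`, `sequence`, `planted_offset` (site center minus
#'   sequence center; `NA` in `absent` mode).
#' @export
simulate_peak_sequences <- function(n, length, pwm, mode = c("central", "uniform", "absent"),
                                    motif_sd = 20, base_composition = rep(0.25, 4),
                                    seed = 1L) {
  mode <- match.arg(mode)
  m <- pwm_width(pwm)
  if (length < m) abort("sequences must be at least as long as the motif")
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    mat <- matrix(sample(bases, n * length, replace = TRUE, prob = base_composition),
                  nrow = n)
    planted <- rep(NA_real_, n)
    if (mode != "absent") {
      center <- (length - 1) / 2          # 0-based center
      max_start <- length - m             # 0-based start range [0, max_start]
      site_center_of <- function(start) start + (m - 1) / 2
      for (i in seq_len(n)) {
        if (mode == "central") {
          off <- round(rnorm(1, 0, motif_sd))
          start <- round(center + off - (m - 1) / 2)
          start <- min(max(start, 0), max_start)
        } else {
          start <- sample.int(max_start + 1, 1) - 1
        }
        site <- vapply(seq_len(m), function(j) sample(bases, 1, prob = pwm$matrix[, j]),
                       character(1))
        mat[i, (start + 1):(start + m)] <- site
        planted[i] <- site_center_of(start) - center
      }
    }
    seqs <- apply(mat, 1, paste, collapse = "")
  })
  tibble(name = sprintf("peakseq_%05d", seq_len(n)), sequence = seqs,
         planted_offset = planted)
}

#' Simulate a count table with planted trajectory archetypes
#'
#' Counts are negative binomial with mean `baseline * 2^(template log2FC)`
#' for treated samples of planted genes and `baseline` otherwise; library
#' sizes vary by a uniform factor of `1 +/- library_size_cv`. The control
#' group shares means across conditions, so non-planted genes are true
#' nulls.
#'
#' @param gene_ids Character vector of genomic gene ids that anchor the
#'   expression universe (extended with synthetic ids up to
#'   `n_expr_genes`).
#' @param config A [sim_config()].
#' @return List with `counts` (wide tibble), `meta` (sample metadata
#'   tibble: `sample`, `group`, `condition`, `replicate`) and `truth`
#'   (tibble `gene_id`, `cluster` (0 = null), per-condition planted
#'   log2fc columns).
#' @export
simulate_counts <- function(gene_ids, config) {
  stopifnot(inherits(config, "sim_config"))
  n_expr <- max(config$n_expr_genes, length(gene_ids))
  ids <- c(gene_ids, sprintf("xgene_%04d", seq_len(n_expr - length(gene_ids))))
  tmpl <- config$deg_templates
  if (!identical(colnames(tmpl), config$conditions)) {
    abort("deg_templates columns must match the configured conditions")
  }
  k <- nrow(tmpl)
  withr::with_seed(derive_seed(config$seed, SEED_COUNTS), {
    n_deg <- round(config$deg_fraction * n_expr)
    deg_idx <- sample.int(n_expr, n_deg)
    cluster <- integer(n_expr)
    cluster[deg_idx] <- rep(seq_len(k), length.out = n_deg)[sample.int(n_deg)]
    baseline <- stats::rlnorm(n_expr, config$baseline_log_mean, config$baseline_log_sd)
    meta <- purrr::map_dfr(c("pLVX", "NP8"), function(gr) {
      purrr::map_dfr(config$conditions, function(cond) {
        nr <- if (gr == "NP8" && cond == config$duplicate_condition) {
          config$n_reps - 1L
        } else {
          config$n_reps
        }
        tibble(group = gr, condition = cond, replicate = seq_len(nr))
      })
    })
    meta$sample <- sprintf("%s_%s_r%d", meta$group, meta$condition, meta$replicate)
    lib_factor <- runif(nrow(meta), 1 - config$library_size_cv, 1 + config$library_size_cv)
    counts <- matrix(0L, nrow = n_expr, ncol = nrow(meta),
                     dimnames = list(ids, meta$sample))
    for (s in seq_len(nrow(meta))) {
      lfc <- numeric(n_expr)
      if (meta$group[s] == "NP8") {
        has <- cluster > 0
        lfc[has] <- tmpl[cluster[has], meta$condition[s]]
      }
      mu <- baseline * 2^lfc * lib_factor[s]
      counts[, s] <- rnbinom(n_expr, size = 1 / config$nb_dispersion, mu = mu)
    }
  })
  truth <- tibble(gene_id = ids, cluster = cluster)
  for (cond in config$conditions) {
    v <- numeric(n_expr)
    v[cluster > 0] <- tmpl[cluster[cluster > 0], cond]
    truth[[cond]] <- v
  }
  list(
    counts = dplyr::bind_cols(tibble(gene_id = ids),
                              as_tibble(as.data.frame(counts))),
    meta = select(meta, "sample", "group", "condition", "replicate"),
    truth = truth
  )
}

#' Simulate a limiting-dilution experiment
#'
#' Takes are binomial with take probability `1 - exp(-dose * frequency)`
#' per the single-hit Poisson model.
#'
#' @param config A [sim_config()] (uses `ld_true_frequency`, `ld_doses`).
#' @param frequency,doses Optional overrides of the config values.
#' @param group Group label.
#' @param seed Integer seed (default derived from the config seed).
#' @return An incidence tibble (`group`, `dose`, `n`, `k`).
#' @export
simulate_ld_experiment <- function(config, frequency = config$ld_true_frequency,
                                   doses = config$ld_doses, group = "sim",
                                   seed = derive_seed(config$seed, SEED_LD)) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    p_take <- -expm1(-doses$dose * frequency)
    k <- rbinom(nrow(doses), doses$n, p_take)
  })
  tibble(group = group, dose = doses$dose, n = doses$n, k = k)
}
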