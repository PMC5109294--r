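# Summit-anchored peak annotation against gene models.
#
# Region scheme (strand-aware, distances in transcription direction):
#   promoter            TSS -5 kb .. TSS +0.5 kb
#   5' distal           TSS -15 kb .. TSS -5 kb
#   3' proximal         TES -0.5 kb .. TES +5 kb
#   3' distal           TES +5 kb .. TES +15 kb
#   exon / intron       summit inside the gene body
#   gene desert         everything else
# All windows are half-open on their downstream edge. When windows of the
# nearest gene overlap, precedence is promoter > exon > intron >
# 3' proximal > 5' distal > 3' distal > gene desert.

region_levels <- function() {
  c("promoter", "exon", "intron", "three_prime_proximal",
    "five_prime_distal", "three_prime_distal", "gene_desert")
}

#' Classify peaks into genomic regions relative to the nearest gene
#'
#' Each peak is assigned to its nearest gene (minimum of the absolute
#' summit-to-TSS and summit-to-TES distances on the same chromosome, ties
#' broken by lexicographically smaller gene id) and then classified by where
#' the summit falls in that gene's strand-aware windows (see Details in the
#' package vignette). A chromosome without genes yields `gene_desert` with
#' `NA` nearest gene.
#'
#' @param peaks A validated peak tibble.
#' @param genes A validated gene tibble (must be non-empty).
#' @param promoter_window `c(upstream, downstream)` of the promoter class in
#'   bp (default the -5 kb/+0.5 kb scheme).
#' @param distal_limit Outer edge of the distal windows in bp (default 15 kb).
#' @param proximal_limit Outer edge of the 3' proximal window (default 5 kb).
#' @return `peaks` with columns `region` (factor), `nearest_gene` and
#'   `dist_tss` (signed bp from the nearest gene's TSS, positive downstream)
#'   appended.
#' @export
classify_peaks <- function(peaks, genes,
                           promoter_window = c(5000, 500),
                           distal_limit = 15000,
                           proximal_limit = 5000) {
  validate_peaks(peaks)
  validate_genes(genes)
  if (nrow(genes) == 0) abort("gene table is empty")
  ga <- gene_anchors(genes)
  out_region <- character(nrow(peaks))
  out_gene <- rep(NA_character_, nrow(peaks))
  out_dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gch <- ga[ga$chrom == ch, , drop = FALSE]
    if (nrow(gch) == 0) {
      out_region[pi] <- "gene_desert"
      next
    }
    s <- peaks$summit[pi]
    # nearest gene by min(|summit - TSS|, |summit - TES|); ties -> smaller id
    d_tss <- abs(outer(s, gch$tss, "-"))
    d_tes <- abs(outer(s, gch$tes, "-"))
    d <- pmin(d_tss, d_tes)
    ord <- order(gch$gene_id)
    nearest <- apply(d[, ord, drop = FALSE], 1, which.min)
    gi <- ord[nearest]
    g <- gch[gi, , drop = FALSE]
    sign_dir <- ifelse(g$strand == "+", 1, -1)
    pos_tss <- (s - g$tss) * sign_dir
    pos_tes <- (s - g$tes) * sign_dir
    in_body <- s >= g$start & s < g$end
    in_exon <- vapply(seq_along(pi), function(j) {
      any(s[j] >= g$exon_starts[[j]] & s[j] < g$exon_ends[[j]])
    }, logical(1))
    region <- rep("gene_desert", length(pi))
    region[pos_tes >= proximal_limit & pos_tes < distal_limit] <- "three_prime_distal"
    region[pos_tss >= -distal_limit & pos_tss < -promoter_window[1]] <- "five_prime_distal"
    region[pos_tes >= -500 & pos_tes < proximal_limit] <- "three_prime_proximal"
    region[in_body & !in_exon] <- "intron"
    region[in_body & in_exon] <- "exon"
    region[pos_tss >= -promoter_window[1] & pos_tss < promoter_window[2]] <- "promoter"
    out_region[pi] <- region
    out_gene[pi] <- g$gene_id
    out_dist[pi] <- pos_tss
  }
  mutate(as_tibble(peaks),
    region = factor(out_region, levels = region_levels()),
    nearest_gene = out_gene,
    dist_tss = out_dist
  )
}

#' Promoter occupancy of genes by a peak set
#'
#' A gene is occupied when at least one peak summit falls in the extended
#' promoter `[TSS - upstream, TSS + downstream)` measured in the direction
#' of transcription (defaults -8 kb/+2 kb).
#'
#' @param peaks A validated peak tibble.
#' @param genes A validated gene tibble.
#' @param upstream,downstream Extended promoter half-widths in bp (both >= 0).
#' @return A tibble with columns `gene_id` and logical `occupied`.
#' @export
promoter_occupancy <- function(peaks, genes, upstream = 8000, downstream = 2000) {
  validate_peaks(peaks)
  validate_genes(genes)
  if (upstream < 0 || downstream < 0) abort("promoter window sizes must be >= 0")
  ga <- gene_anchors(genes)
  occ <- logical(nrow(ga))
  for (ch in unique(ga$chrom)) {
    gi <- which(ga$chrom == ch)
    summits <- sort(peaks$summit[peaks$chrom == ch])
    if (length(summits) == 0) next
    plus <- ga$strand[gi] == "+"
    lo <- ifelse(plus, ga$tss[gi] - upstream, ga$tss[gi] - downstream + 1)
    hi <- ifelse(plus, ga$tss[gi] + downstream, ga$tss[gi] + upstream + 1)
    # occupied iff some summit s satisfies lo <= s < hi
    n_lo <- findInterval(lo - 0.5, summits)
    n_hi <- findInterval(hi - 0.5, summits)
    occ[gi] <- n_hi > n_lo
  }
  tibble(gene_id = ga$gene_id, occupied = occ)
}

#' Venn cells of shared promoter occupancy across factors
#'
#' @param occupancy_maps Named list of [promoter_occupancy()] outputs, one
#'   per factor, over the same gene universe.
#' @return A tibble with one row per non-empty factor subset: `subset`
#'   (factor names joined by `+`), `factors` (list column) and `n_genes`.
#'   The cells partition the union of occupied genes.
#' @export
shared_promoter_sets <- function(occupancy_maps) {
  if (is.null(names(occupancy_maps)) || any(!nzchar(names(occupancy_maps)))) {
    abort("occupancy_maps must be a named list (one entry per factor)")
  }
  fac <- names(occupancy_maps)
  occ <- purrr::map(occupancy_maps, function(m) m$gene_id[m$occupied])
  universe <- sort(unique(unlist(occ)))
  if (length(universe) == 0) {
    return(tibble(subset = character(0), factors = list(), n_genes = integer(0)))
  }
  member <- vapply(occ, function(g) universe %in% g, logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  key <- apply(member, 1, function(r) paste(fac[r], collapse = "+"))
  tab <- table(key)
  tibble(
    subset = names(tab),
    factors = strsplit(names(tab), "+", fixed = TRUE),
    n_genes = as.integer(tab)
  ) |> arrange(dplyr::desc(.data$n_genes))
}
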