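# Gene-model I/O: BED12 and a GTF subset (gene/exon features).

#' Read gene models from BED12 or a GTF subset
#'
#' BED12 blocks become exons directly. For GTF, `exon` features are grouped
#' by `gene_id` (1-based closed coordinates converted to 0-based half-open);
#' the gene span is the exon envelope unless a `gene` feature is present.
#' Strand must be `+` or `-`: an unstranded gene has no TSS and is rejected.
#'
#' @param path Input path.
#' @param dialect `"bed12"` or `"gtf_subset"`.
#' @return A gene tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and list-columns `exon_starts`, `exon_ends`.
#' @export
read_gene_models <- function(path, dialect = c("bed12", "gtf_subset")) {
  dialect <- match.arg(dialect)
  genes <- if (dialect == "bed12") read_bed12(path) else read_gtf_subset(path)
  validate_genes(genes)
  genes
}

read_bed12 <- function(path) {
  lines <- read_lines_checked(path)
  fields <- stringr::str_split(lines, "\t")
  bad <- which(lengths(fields) < 12)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (expected 12 tab-separated fields)", path, bad[1]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  ln <- seq_along(lines)
  start <- parse_num(m[, 2], ln, "start", path)
  end <- parse_num(m[, 3], ln, "end", path)
  strand <- m[, 6]
  if (!all(strand %in% c("+", "-"))) {
    abort(sprintf("%s: gene strand must be '+' or '-' (line %d)", path,
                  which(!strand %in% c("+", "-"))[1]))
  }
  n_blocks <- as.integer(parse_num(m[, 10], ln, "blockCount", path))
  exon_starts <- vector("list", length(lines))
  exon_ends <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    sizes <- as.numeric(strsplit(sub(",$", "", m[i, 11]), ",")[[1]])
    offs <- as.numeric(strsplit(sub(",$", "", m[i, 12]), ",")[[1]])
    if (length(sizes) != n_blocks[i] || length(offs) != n_blocks[i]) {
      abort(sprintf("%s: block list lengths disagree with blockCount at line %d", path, i))
    }
    ord <- order(offs)
    exon_starts[[i]] <- start[i] + offs[ord]
    exon_ends[[i]] <- start[i] + offs[ord] + sizes[ord]
  }
  tibble(
    gene_id = m[, 4], chrom = m[, 1], start = start, end = end,
    strand = strand, exon_starts = exon_starts, exon_ends = exon_ends
  )
}

read_gtf_subset <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  if (!"gene_id" %in% names(meta)) abort(sprintf("%s: GTF records lack gene_id", path))
  ex <- meta[meta$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) abort(sprintf("%s: no exon features", path))
  if (any(!as.character(ex$strand) %in% c("+", "-"))) {
    abort("GTF exon strand must be '+' or '-' (strand '.' leaves the TSS undefined)")
  }
  gene_rows <- meta[meta$type == "gene", , drop = FALSE]
  split_ex <- split(ex, ex$gene_id)
  purrr::map_dfr(names(split_ex), function(g) {
    e <- split_ex[[g]]
    ord <- order(e$start)
    # GTF is 1-based closed; convert to 0-based half-open
    es <- e$start[ord] - 1
    ee <- e$end[ord]
    gi <- gene_rows[gene_rows$gene_id == g, , drop = FALSE]
    span <- if (nrow(gi) >= 1) c(gi$start[1] - 1, gi$end[1]) else c(min(es), max(ee))
    tibble(
      gene_id = g, chrom = as.character(e$seqnames[1]),
      start = span[1], end = span[2], strand = as.character(e$strand[1]),
      exon_starts = list(es), exon_ends = list(ee)
    )
  }) |> arrange(.data$gene_id)
}

#' Write gene models as BED12
#'
#' @param genes A validated gene tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  validate_genes(genes)
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            genes$chrom[i], as.integer(genes$start[i]), as.integer(genes$end[i]),
            genes$gene_id[i], genes$strand[i],
            as.integer(genes$start[i]), as.integer(genes$end[i]),
            length(es),
            paste0(paste(as.integer(ee - es), collapse = ","), ","),
            paste0(paste(as.integer(es - genes$start[i]), collapse = ","), ","))
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
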