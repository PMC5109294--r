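# Region classification, promoter occupancy and Venn partitions.

test_that("region windows follow the published scheme on both strands", {
  genes <- dplyr::bind_rows(
    make_gene("gPlus", "chr1", 100000, 120000, "+"),
    make_gene("gMinus", "chr2", 100000, 120000, "-")
  )
  at <- function(chrom, pos) {
    cl <- classify_peaks(make_peak(chrom, pos - 50, pos + 50, summit = pos), genes)
    as.character(cl$region)
  }
  expect_equal(at("chr1", 100000 - 3000), "promoter")
  expect_equal(at("chr1", 100000 - 10000), "five_prime_distal")
  expect_equal(at("chr1", 120000 + 3000), "three_prime_proximal")
  expect_equal(at("chr1", 120000 + 10000), "three_prime_distal")
  expect_equal(at("chr1", 160000), "gene_desert")
  # strand symmetry: minus-strand TSS sits at the genomic end
  expect_equal(at("chr2", 120000 + 3000), "promoter")
  expect_equal(at("chr2", 100000 - 3000), "three_prime_proximal")
  expect_error(classify_peaks(make_peak("chr1", 0, 10), genes[0, ]), "empty")
})

test_that("summit-in-exon vs intron is resolved within the gene body", {
  g <- make_gene("g", "chr1", 1000, 9000, "+",
                 list(c(1000, 5000)), list(c(3000, 9000)))
  cl <- classify_peaks(make_peak("chr1", 3900, 4100, summit = 4000), g)
  expect_equal(as.character(cl$region), "intron")
  cl2 <- classify_peaks(make_peak("chr1", 5900, 6100, summit = 6000), g)
  expect_equal(as.character(cl2$region), "exon")
  # promoter wins over exon for a summit just downstream of the TSS
  cl3 <- classify_peaks(make_peak("chr1", 1100, 1300, summit = 1200), g)
  expect_equal(as.character(cl3$region), "promoter")
})

test_that("classification matches the brute-force oracle on random inputs", {
  set.seed(101)
  genes <- random_genes(40)
  peaks <- random_peaks(300)
  got <- classify_peaks(peaks, genes)
  for (i in seq_len(nrow(peaks))) {
    want <- oracle_classify(peaks$summit[i], peaks$chrom[i], genes)
    expect_equal(as.character(got$region[i]), want$region)
    expect_equal(got$nearest_gene[i], want$gene)
  }
  # partition: every peak gets exactly one label
  expect_equal(sum(table(got$region)), nrow(peaks))
})

test_that("promoter occupancy uses the half-open strand-aware window", {
  genes <- dplyr::bind_rows(
    make_gene("gP", "chr1", 50000, 70000, "+"),
    make_gene("gM", "chr1", 200000, 220000, "-")
  )
  occ <- function(pos) {
    promoter_occupancy(make_peak("chr1", pos - 10, pos + 10, summit = pos), genes)
  }
  expect_true(occ(50000)$occupied[1])           # exactly at TSS
  expect_false(occ(52000)$occupied[1])          # TSS+2000 excluded (half-open)
  expect_true(occ(51999)$occupied[1])
  expect_true(occ(50000 - 8000)$occupied[1])
  expect_false(occ(50000 - 8001)$occupied[1])
  # minus strand: upstream is to the genomic right of the TSS at 220000
  expect_true(occ(220000 + 3000)$occupied[2])
  expect_false(occ(220000 - 2000)$occupied[2])
  none <- promoter_occupancy(make_peak("chr1", 1, 2)[0, ], genes)
  expect_true(all(!none$occupied))
})

test_that("venn cells partition the occupied union and match set algebra", {
  mk <- function(ids, occupied) tibble::tibble(gene_id = ids, occupied = occupied)
  ids <- sprintf("g%03d", 1:200)
  set.seed(7)
  maps <- list(A = mk(ids, runif(200) < 0.4),
               B = mk(ids, runif(200) < 0.3),
               C = mk(ids, runif(200) < 0.2))
  cells <- shared_promoter_sets(maps)
  union_n <- length(unique(unlist(lapply(maps, function(m) m$gene_id[m$occupied]))))
  expect_equal(sum(cells$n_genes), union_n)
  # exhaustive set-algebra oracle per subset
  for (i in seq_len(nrow(cells))) {
    members <- cells$factors[[i]]
    inside <- Reduce(intersect, lapply(members, function(f) maps[[f]]$gene_id[maps[[f]]$occupied]))
    outside <- unlist(lapply(setdiff(names(maps), members),
                             function(f) maps[[f]]$gene_id[maps[[f]]$occupied]))
    expect_equal(cells$n_genes[i], length(setdiff(inside, outside)))
  }
  ident <- shared_promoter_sets(list(X = maps$A, Y = maps$A))
  expect_equal(nrow(ident), 1)
  expect_equal(ident$subset, "X+Y")
})
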