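test_that("TE midpoints annotate with the fixed priority order", {
  # gene g1 on chr1 at [10000, 20000), + strand, exon1 [10000,12000),
  # exon2 [15000,20000); gene g2 at [21000, 30000) so g1's 3' region is
  # inside g2's promoter window
  exons <- list(matrix(c(10000, 12000, 15000, 20000), 2, byrow = TRUE,
                       dimnames = list(NULL, c("start", "end"))),
                matrix(c(21000, 30000), 1,
                       dimnames = list(NULL, c("start", "end"))))
  genes <- make_genes(c("g1", "g2"), "chr1", "+", c(10000, 21000),
                      c(20000, 30000), exons = exons)
  tes <- te_copies(c("in_exon_and_promoter", "intron", "intergenic"),
                   "chr1",
                   c(19000, 13000, 50000), c(19200, 13200, 50200),
                   te_class = "SINE")
  ann <- annotate_te(tes, genes)
  # midpoint 19100 is in g1's exon2 but also within g2's promoter
  # ([18000, 24000)): promoter wins
  expect_equal(ann$label,
               c("Promoter", "Intron", "Intergenic"))
  expect_equal(ann$nearest_gene_id[3], "g2")
  # feature labels partition every TE
  expect_true(all(ann$label %in% c("Promoter", "5UTR", "3UTR", "Exon",
                                   "Intron", "Downstream", "Intergenic")))
})

test_that("UTR and downstream labels follow strand", {
  exons <- list(matrix(c(1000, 5000), 1,
                       dimnames = list(NULL, c("start", "end"))))
  cds <- list(matrix(c(2000, 4000), 1,
                     dimnames = list(NULL, c("start", "end"))))
  genes <- make_genes("g1", "chr1", "+", 1000, 5000, exons = exons,
                      cds = cds)
  # with a 500 bp promoter window, exonic midpoints left/right of the CDS
  # are the 5' and 3' UTR on the + strand
  tes <- te_copies(c("five", "three", "down"), "chr1",
                   c(1600, 4500, 5200), c(1700, 4600, 5300),
                   te_class = "SINE")
  ann <- annotate_te(tes, genes, promoter_flank = 500,
                     downstream_flank = 3000)
  expect_equal(ann$label, c("5UTR", "3UTR", "Downstream"))

  # on the minus strand the TSS sits at the right end, so exonic
  # midpoints right of the CDS are the 5' UTR and left of it the 3' UTR
  genes_m <- make_genes("g1", "chr1", "-", 1000, 5000, exons = exons,
                        cds = cds)
  tes_m <- te_copies(c("left_of_cds", "right_of_cds"), "chr1",
                     c(1600, 4150), c(1700, 4250), te_class = "SINE")
  ann_m <- annotate_te(tes_m, genes_m, promoter_flank = 500)
  expect_equal(ann_m$label, c("3UTR", "5UTR"))
})

test_that("enriched and specific gene sets obey flank boundaries and set
           algebra", {
  genes <- make_genes(c("g1", "g2", "g3"), "chr1", "+",
                      c(10000, 50000, 100000), c(12000, 52000, 102000))
  tes <- te_copies(
    c("line_near_g1", "sine_near_g1", "line_far_g2", "line_near_g3"),
    "chr1",
    c(5000, 12500, 57001, 95000),
    c(5100, 12600, 57100, 95500),
    te_class = c("LINE", "SINE", "LINE", "LINE"))
  # line_near_g1 ends 4900 bp upstream of g1 -> enriched;
  # line_far_g2 starts 5001 bp downstream of g2 -> not enriched
  sets <- enriched_genes(tes, genes, flank = 5000)
  expect_true("g1" %in% sets$LINE_enriched)
  expect_false("g2" %in% sets$LINE_enriched)
  expect_equal(sets$SINE_enriched, "g1")
  expect_equal(sets$LINE_specific, "g3")
  expect_equal(intersect(sets$LINE_specific, sets$SINE_enriched),
               character(0))
})

test_that("genic overlap fractions count TEs and genes", {
  genes <- make_genes("g1", "chr1", "+", 10000, 20000)
  tes_in <- te_copies(c("a", "b"), "chr1", c(11000, 15000),
                      c(11100, 15100), te_class = "LINE")
  ov <- genic_overlap_fraction(tes_in, genes)
  expect_equal(ov$te_fraction, 1.0)
  expect_equal(ov$gene_fraction, 1.0)

  tes_out <- te_copies("c", "chr1", 50000, 50100, te_class = "LINE")
  ov0 <- genic_overlap_fraction(tes_out, genes)
  expect_equal(ov0$te_fraction, 0.0)
  expect_equal(ov0$gene_fraction, 0.0)

  # 4 of 10 TEs within 3 kb
  starts <- c(seq(10500, 11200, length.out = 4), seq(40000, 48000,
                                                     length.out = 6))
  tes10 <- te_copies(paste0("t", 1:10), "chr1", starts, starts + 50,
                     te_class = "LINE")
  expect_equal(genic_overlap_fraction(tes10, genes)$te_fraction, 0.4)
})

test_that("repeat percentage matrices measure flanked-span coverage", {
  # flanked span of g1 with flank 500: [500, 2500), length 2000
  genes <- make_genes("g1", "chr1", "+", 1000, 2000)
  tes <- te_copies("a", "chr1", 500, 1500, family = "L1",
                   te_class = "LINE")
  m <- repeat_percent_matrix(tes, genes, flank = 500)
  expect_equal(m["g1", "L1"], 50.0)  # 1000 of 2000 bp
  expect_true(all(m >= 0 & m <= 100))
})

test_that("quantile normalization matches the row-mean rule and makes
           columns permutations", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  set.seed(21)
  m2 <- matrix(rexp(60), 12, 5)
  qn2 <- quantile_normalize(m2)
  ref <- sort(qn2[, 1])
  for (j in 2:5) expect_equal(sort(qn2[, j]), ref)
})

test_that("hierarchical clustering splits well-separated planted groups", {
  set.seed(31)
  m <- rbind(matrix(rnorm(40, 0), 8, 5), matrix(rnorm(40, 8), 8, 5))
  rownames(m) <- paste0("g", 1:16)
  hc <- hierarchical_cluster(m, k = 2)
  expect_equal(hc$tree$method, "average")
  expect_equal(length(unique(hc$labels[1:8])), 1)
  expect_equal(length(unique(hc$labels[9:16])), 1)
  expect_false(hc$labels[1] == hc$labels[9])
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- paste0("g", 1:20)
  terms <- data.frame(term_id = "T1", gene_id = paste0("g", 1:5))
  query <- c("g1", "g2", "g3", "g10", "g11")  # overlap k = 3
  res <- term_enrichment(query, terms, universe)
  expect_equal(res$p_hyper, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$p_hyper, hyper_tail_exact(20, 5, 5, 3),
               tolerance = 1e-12)

  # k = 0 -> p = 1
  res0 <- term_enrichment(paste0("g", 10:14), terms, universe)
  expect_equal(res0$p_hyper, 1)

  # k = n = K is the most extreme outcome
  res_full <- term_enrichment(paste0("g", 1:5), terms, universe)
  expect_equal(res_full$p_hyper, 1 / choose(20, 5), tolerance = 1e-12)
  expect_lt(res_full$p_hyper, res$p_hyper)

  expect_error(term_enrichment("not_in_universe", terms, universe),
               "subset")
})

test_that("hypergeometric p matches enumeration over a small grid", {
  for (N in c(10, 15)) for (K in c(3, 6)) for (n in c(4, 7)) {
    for (k in max(0, n - (N - K)):min(K, n)) {
      universe <- paste0("g", 1:N)
      terms <- data.frame(term_id = "T", gene_id = universe[1:K])
      query <- c(universe[seq_len(k)],
                 universe[K + seq_len(n - k)])
      res <- term_enrichment(query, terms, universe)
      expect_equal(res$p_hyper, hyper_tail_exact(N, K, n, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("CDC comparison behaves at the null center and in the tail", {
  p <- (1:20) / 21
  expect_equal(cdc_compare(p, p)$p, 1)

  q <- (1:15) / 1000          # all smaller than any of the reference
  r <- 0.5 + (1:15) / 100
  out <- cdc_compare(q, r)
  expect_lt(out$p, 0.01)
  expect_equal(out$W, 0)      # minimal rank sum

  sets <- random_gene_sets(paste0("g", 1:100), 10, n_sets = 3, seed = 2)
  expect_equal(lengths(sets), rep(10L, 3))
  expect_identical(sets, random_gene_sets(paste0("g", 1:100), 10,
                                          n_sets = 3, seed = 2))
})
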