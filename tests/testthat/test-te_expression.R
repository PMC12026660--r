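test_that("TE location classes follow the distance and midpoint rules", {
  exons <- list(matrix(c(10000, 11000, 14000, 20000), 2, byrow = TRUE,
                       dimnames = list(NULL, c("start", "end"))))
  genes <- make_genes("g1", "chr1", "+", 10000, 20000, exons = exons)
  tes <- te_copies(
    c("intergenic6kb", "proximal4kb", "in_exon2", "in_intron"),
    "chr1",
    c(26100, 24000, 15000, 12000),
    c(26200, 24100, 15100, 12100),
    te_class = "SINE")
  loc <- classify_te_location(tes, genes, intergenic_min_bp = 5000)
  expect_equal(loc, c("intergenic", "proximal", "exonic", "intronic"))
})

test_that("TPM follows the per-kilobase rate rule and sums to one million", {
  counts <- matrix(c(10, 40), 2, 1,
                   dimnames = list(c("f1", "f2"), "s1"))
  x <- tpm(counts, lengths = c(1000, 2000))
  expect_equal(unname(x[, 1]), c(1e6 / 3, 2e6 / 3), tolerance = 1e-9)

  one <- tpm(matrix(5, 1, 1), lengths = 1500)
  expect_equal(unname(one[1, 1]), 1e6)

  cm <- simulate_counts(n_features = 300, n_planted = 20, seed = 71)
  x2 <- tpm(cm)
  expect_true(all(abs(colSums(x2) - 1e6) < 1e-6))

  z <- matrix(c(1, 0), 1, 2)
  expect_error(tpm(z, lengths = 100), "empty library")
})

test_that("expression filtering applies the CPM cutoff and group-size
           rules at their boundaries", {
  # equal 1e6 libraries make the CPM cutoff exactly 10 CPM = 10 counts
  n_feat <- 4
  counts <- matrix(0, n_feat, 6, dimnames = list(
    c("zero", "at_cutoff", "below", "few_samples"), NULL))
  groups <- rep(c("a", "b"), each = 3)       # smallest group size 3
  counts["at_cutoff", 1:3] <- 10             # exactly cutoff, exactly n*
  counts["below", 1:3] <- 9
  counts["below", 4:6] <- 2                  # total 33 but CPM below cutoff
  counts["few_samples", 1:2] <- 50           # only 2 samples reach cutoff
  # pad each column to a 1e6 library with a filler feature
  counts <- rbind(counts, filler_total = 1e6 - colSums(counts))
  keep <- filter_expressed(counts, groups, min_count = 10, min_total = 15)
  expect_true("at_cutoff" %in% keep)
  expect_false("zero" %in% keep)
  expect_false("below" %in% keep)
  expect_false("few_samples" %in% keep)
})

test_that("time-course model selects perfect fits and controls the null", {
  cm <- simulate_counts(n_features = 400, n_planted = 0, seed = 72)
  x <- tpm(cm)
  meta <- cm$sample_meta
  # plant an exactly linear-in-stage feature with zero residual
  t_num <- match(meta$stage, c("I", "II", "III")) - 1
  x[1, ] <- 2^(3 + t_num) - 1
  de <- timecourse_de(x, meta)
  expect_equal(de$R_squared[1], 1)
  expect_true(de$selected[1])
  expect_lte(mean(de$selected[-1]), 0.05)

  expect_error(timecourse_de(x, transform(meta, tissue = "dorsal")),
               "2 groups")
})

test_that("null p-values are uniform and the F-test matches lm/anova", {
  cm <- simulate_counts(n_features = 500, n_planted = 0, seed = 73)
  x <- tpm(cm)
  de <- timecourse_de(x, cm$sample_meta)
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)

  # independent route: lm + anova F against the intercept-only model
  meta <- cm$sample_meta
  t_num <- match(meta$stage, c("I", "II", "III")) - 1
  g <- as.numeric(factor(meta$tissue)) - 1
  for (i in c(1, 7, 42)) {
    y <- log2(x[i, ] + 1)
    full <- lm(y ~ t_num + I(t_num^2) + g + g:t_num + g:I(t_num^2))
    av <- anova(lm(y ~ 1), full)
    expect_equal(de$F_stat[i], av$F[2], tolerance = 1e-10)
    expect_equal(de$p[i], av$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(de$R_squared[i], summary(full)$r.squared,
                 tolerance = 1e-10)
  }
})

test_that("selection is monotone in alpha and the R2 threshold", {
  cm <- simulate_counts(n_features = 300, n_planted = 30, seed = 74)
  x <- tpm(cm)
  de1 <- timecourse_de(x, cm$sample_meta, alpha = 0.05, r2_min = 0.6)
  de2 <- timecourse_de(x, cm$sample_meta, alpha = 0.01, r2_min = 0.6)
  de3 <- timecourse_de(x, cm$sample_meta, alpha = 0.05, r2_min = 0.8)
  expect_true(all(de2$selected <= de1$selected))
  expect_true(all(de3$selected <= de1$selected))
})

test_that("profile clustering finds planted groups with
           silhouette-selected k", {
  set.seed(75)
  base <- rbind(c(1, 2, 3, 4, 5, 6),
                c(6, 5, 4, 3, 2, 1),
                c(1, 5, 1, 5, 1, 5))
  make_group <- function(profile, n)
    t(vapply(seq_len(n), function(i) profile + rnorm(6, 0, 0.05),
             numeric(6)))
  m2 <- rbind(make_group(base[1, ], 10), make_group(base[2, ], 10))
  rownames(m2) <- paste0("f", 1:20)
  cl2 <- cluster_profiles(m2, k_range = 2:6)
  expect_equal(cl2$k, 2L)
  truth <- rep(1:2, each = 10)
  expect_equal(length(unique(paste(cl2$cluster, truth))), 2)

  m3 <- rbind(make_group(base[1, ], 8), make_group(base[2, ], 8),
              make_group(base[3, ], 8))
  cl3 <- cluster_profiles(m3, k_range = 2:6)
  expect_equal(cl3$k, 3L)

  flat <- matrix(5, 10, 6)
  expect_true(cluster_profiles(flat)$degenerate)
})

test_that("TE-gene links report the nearest distal DEG and its
           correlation", {
  genes <- make_genes(c("gA", "gB"), "chr1", "+",
                      c(100000, 300000), c(110000, 310000),
                      annotation_label = c("DSG4", NA))
  tes <- te_copies("te1", "chr1", 120000, 120500, te_class = "LINE")
  samples <- paste0("s", 1:6)
  expr <- matrix(2^(1:6), 1, 6, dimnames = list("te1", samples))
  gene_expr <- rbind(gA = 2^(1:6), gB = 2^(6:1))
  colnames(gene_expr) <- samples
  links <- te_gene_links("te1", c("gA", "gB"), tes, genes, expr,
                         gene_expr)
  expect_equal(links$gene_id, "gA")
  expect_equal(links$annotation_label, "DSG4")
  expect_equal(links$distance_bp, 120000 - 110000)
  expect_gt(links$distance_bp, 5000)
  expect_equal(links$pearson_r, 1)

  # anti-correlated pair recovered with negative r
  links_b <- te_gene_links("te1", "gB", tes, genes, expr, gene_expr)
  expect_lt(links_b$pearson_r, 0)

  # genes within 5 kb are never linked
  near_gene <- make_genes("gC", "chr1", "+", 121000, 125000)
  expect_equal(nrow(te_gene_links("te1", "gC", tes, near_gene, expr,
                                  rbind(gC = gene_expr[1, ]))), 0)
})
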