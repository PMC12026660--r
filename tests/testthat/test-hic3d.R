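test_that("O/E normalization flattens per-diagonal structure", {
  # constant-per-diagonal matrix -> all unmasked entries become 1
  n <- 20
  d <- abs(outer(1:n, 1:n, "-"))
  m <- contact_matrix(100 / (1 + d))
  oe <- oe_normalize(m)
  expect_true(all(abs(oe$values - 1) < 1e-12))

  m2 <- contact_matrix(matrix(7, n, n))
  expect_true(all(abs(oe_normalize(m2)$values - 1) < 1e-12))

  # per-diagonal mean of O/E is 1 on unmasked entries (mass conservation)
  ms <- simulate_contact_matrix(50, rho = 0.3, tad_boundaries = c(20, 35),
                                tad_boost = 2, seed = 61)
  oe3 <- oe_normalize(ms)
  keep <- !attr(oe3, "masked")
  d50 <- abs(outer(1:50, 1:50, "-"))
  for (k in c(0, 3, 10)) {
    sel <- d50 == k & outer(keep, keep)
    expect_equal(mean(oe3$values[sel]), 1, tolerance = 1e-9)
  }
})

test_that("O/E keeps the plaid sign structure", {
  a <- rep(c(1, -1), each = 25)
  m <- simulate_contact_matrix(50, a, rho = 0.3, poisson_noise = FALSE)
  oe <- oe_normalize(m)$values
  same <- outer(a, a) > 0
  off <- row(oe) != col(oe)
  expect_gt(mean(oe[same & off]), mean(oe[!same & off]))
})

test_that("compartment calls recover the planted plaid and match the
           eigen oracle", {
  a <- rep(c(1, -1), each = 100)
  m <- simulate_contact_matrix(200, a, rho = 0.2, gamma = 1, seed = 62)
  gc <- 0.40 + 0.04 * (a > 0)
  tr <- compartments(m, gc)
  agree <- mean(tr$label[!tr$masked] ==
                  ifelse(a[!tr$masked] > 0, "A", "B"))
  expect_gte(agree, 0.95)
  expect_gte(tr$sign_anchor, 0)

  # independent full eigen-decomposition of the same correlation matrix
  oe <- oe_normalize(m)
  masked <- attr(oe, "masked")
  C <- cor(t(log2(oe$values + 0.01)[!masked, !masked]))
  ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
  p <- tr$pc1[!masked]
  cosine <- abs(sum(ev * p)) / sqrt(sum(ev^2) * sum(p^2))
  expect_gte(cosine, 0.999)
})

test_that("weak compartmentalization and masked bins are handled", {
  m <- simulate_contact_matrix(60, rho = 0, gamma = 1, seed = 63)
  a <- rep(c(1, -1), each = 30)
  tr <- compartments(m, gc = NULL)
  expect_lt(abs(cor(tr$pc1, a, use = "complete.obs")), 0.6)

  # a zero row is masked and labelled as such
  v <- simulate_contact_matrix(15, rho = 0, seed = 64)$values
  v[3, ] <- 0
  v[, 3] <- 0
  tr2 <- compartments(contact_matrix(v))
  expect_equal(tr2$label[3], "masked")
  expect_true(is.na(tr2$pc1[3]))

  expect_error(compartments(contact_matrix(matrix(0, 12, 12))),
               "unmasked bins")
})

test_that("TE content splits across compartments with a rank-sum test", {
  a <- rep(c(1, -1), each = 100)
  m <- simulate_contact_matrix(200, a, rho = 0.25, seed = 65)
  gc <- 0.40 + 0.04 * (a > 0)
  tr <- compartments(m, gc)
  # plant SINE fraction high in A bins
  sine <- ifelse(a > 0, 0.3, 0.1) + runif(200, 0, 0.02)
  res <- compartment_te_association(tr, sine)
  expect_gt(res$mean_A, res$mean_B)
  expect_lt(res$p, 0.01)

  one_label <- tr
  one_label$label <- rep("A", 200)
  expect_error(compartment_te_association(one_label, sine),
               "single compartment")
})

test_that("TAD boundaries are recovered on planted domains and absent on
           uniform matrices", {
  tb <- c(68, 135)
  m <- simulate_contact_matrix(200, rep(1, 200), rho = 0,
                               tad_boundaries = tb, tad_boost = 3,
                               seed = 66)
  td <- tad_separation(m)
  expect_equal(length(td$boundaries), 2)
  expect_true(all(abs(td$boundaries - (tb - 1)) <= 1))

  mu <- contact_matrix(matrix(50, 120, 120))
  expect_equal(length(tad_separation(mu)$boundaries), 0)

  # noiseless block-diagonal 2-TAD matrix: unique boundary at the interface
  v <- matrix(1, 60, 60)
  v[1:30, 1:30] <- 5
  v[31:60, 31:60] <- 5
  t2 <- tad_separation(contact_matrix(v))
  expect_equal(length(t2$boundaries), 1)
  expect_true(abs(t2$boundaries - 30) <= 1)
})

test_that("TAD boundary calls are invariant under global scaling", {
  m <- simulate_contact_matrix(150, rep(1, 150), rho = 0,
                               tad_boundaries = c(50, 100), tad_boost = 3,
                               seed = 67)
  t1 <- tad_separation(m)
  m2 <- contact_matrix(m$values * 37.5, resolution = m$resolution)
  t2 <- tad_separation(m2)
  expect_equal(t1$boundaries, t2$boundaries)
})

test_that("bin classification applies quantile and strict-majority rules", {
  line <- c(0.9, 0.1, 0.5, 0.2)
  sine <- c(0.1, 0.9, 0.5, 0.1)
  bc <- classify_bins(line, sine, quantile_cut = 0.75)
  expect_equal(bc$label[1], "LINE-rich")
  expect_equal(bc$label[2], "SINE-rich")
  expect_equal(bc$label[3], "neutral")   # exact tie
})

test_that("homotypic statistics follow the plaid sign structure and label
           swaps", {
  a <- rep(c(1, -1), each = 50)
  m <- simulate_contact_matrix(100, a, rho = 0.3, seed = 68)
  gc <- 0.4 + 0.04 * (a > 0)
  tr <- compartments(m, gc)
  # LINE-rich = B half, SINE-rich = A half
  bins <- classify_bins(ifelse(a < 0, 0.8, 0.1), ifelse(a > 0, 0.8, 0.1))
  hs <- homotypic_stats(tr$correlation, bins, masked = tr$masked)
  fp <- setNames(hs$fraction_positive, hs$pair_type)
  expect_gt(fp["LINE-LINE"], fp["LINE-SINE"])
  expect_gt(fp["SINE-SINE"], fp["LINE-SINE"])

  # swapping the labels swaps the homotypic rows
  bins_sw <- classify_bins(bins$sine_frac, bins$line_frac)
  hs_sw <- homotypic_stats(tr$correlation, bins_sw, masked = tr$masked)
  expect_equal(hs_sw$fraction_positive[hs_sw$pair_type == "LINE-LINE"],
               fp[["SINE-SINE"]])
  expect_equal(hs_sw$fraction_positive[hs_sw$pair_type == "SINE-SINE"],
               fp[["LINE-LINE"]])

  # all-positive matrix -> all fractions 1; absent class -> n_pairs 0
  ones <- matrix(1, 4, 4)
  b4 <- classify_bins(c(1, 1, 0, 0), c(0, 0, 1, 1))
  h4 <- homotypic_stats(ones, b4)
  expect_true(all(h4$fraction_positive == 1))
  b_no_sine <- classify_bins(c(1, 1, 1, 0.9), c(0, 0, 0, 0))
  h5 <- homotypic_stats(ones, b_no_sine)
  expect_equal(h5$n_pairs[h5$pair_type == "SINE-SINE"], 0L)
})

test_that("features assign to rich regions by majority bp or anchors", {
  bins <- classify_bins(c(0.9, 0.9, 0.1, 0.1), c(0.1, 0.1, 0.9, 0.9))
  res <- 1000
  # feature over bins 1-2 (LINE-rich)
  f1 <- data.frame(start = 0, end = 2000)
  expect_equal(feature_overlap(f1, bins, res)$assignment, "LINE-rich")
  # feature spanning both classes 75/25
  f2 <- data.frame(start = 1000, end = 4000)
  expect_equal(feature_overlap(f2, bins, res)$assignment, "SINE-rich")
  # exact tie -> mixed
  f3 <- data.frame(start = 1000, end = 3000)
  expect_equal(feature_overlap(f3, bins, res)$assignment, "mixed")
  # loop anchors both in SINE-rich bins
  l1 <- data.frame(start1 = 2100, end1 = 2500, start2 = 3100, end2 = 3600)
  expect_equal(feature_overlap(l1, bins, res)$assignment, "SINE-rich")
  # empty feature set
  expect_equal(sum(feature_overlap(f1[0, ], bins, res)$proportions), 0)
})
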