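# Compartment calling, TAD-separation boundaries, TE-rich bin
# classification and homotypic interaction statistics from binned
# contact matrices.

#' Observed/expected normalization of a contact matrix
#'
#' Each entry is divided by the mean of its diagonal (all entries at the
#' same |i - j|), computed over bins with a non-zero marginal. Masked
#' bins (zero marginal) are zeroed; diagonals with zero mean give 0.
#'
#' @param m A `"contact_matrix"`.
#' @return A `"contact_matrix"` of O/E values with attribute `"masked"`
#'   (logical per bin).
#' @export
oe_normalize <- function(m) {
  v <- m$values
  n <- nrow(v)
  masked <- rowSums(v) == 0
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  keep <- !masked
  dm <- vapply(0:(n - 1), function(k) {
    vals <- v[d == k & outer(keep, keep)]
    if (length(vals)) mean(vals) else 0
  }, 0)
  exp_mat <- matrix(dm[d + 1], n, n)
  oe <- ifelse(exp_mat > 0, v / exp_mat, 0)
  oe[masked, ] <- 0
  oe[, masked] <- 0
  out <- contact_matrix(oe, chrom = m$chrom, resolution = m$resolution)
  attr(out, "masked") <- masked
  out
}

.leading_eigenvector <- function(A, tol = 1e-10, max_iter = 10000) {
  n <- nrow(A)
  v <- rep(1, n) + seq_len(n) / n  # deterministic, not axis-aligned
  v <- v / sqrt(sum(v^2))
  lambda <- 0
  for (i in seq_len(max_iter)) {
    w <- A %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("degenerate matrix: rank 0")
    w <- as.numeric(w) / nw
    if (max(abs(w - v)) < tol || max(abs(w + v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  v
}

#' Call A/B compartments from a contact matrix
#'
#' Computes the O/E matrix, log-transforms it (`log2(O/E + pseudo)`, which
#' keeps sparse far-diagonal bins from dominating the correlation),
#' takes the Pearson correlation matrix of its rows over unmasked bins,
#' and extracts the leading eigenvector by deterministic power iteration
#' (tolerance 1e-10). The eigenvector sign is oriented so that its
#' correlation with per-bin GC is non-negative; bins with positive PC1
#' are labelled `A`, negative `B`, masked bins `masked`.
#'
#' @param m A `"contact_matrix"`.
#' @param gc Per-bin GC fractions (length `n_bins`) used as the sign
#'   anchor; `NULL` leaves the eigenvector sign as computed.
#' @param log_transform Correlate `log2(O/E + pseudo)` rather than raw
#'   O/E.
#' @param pseudo Pseudocount of the log transform.
#' @return List of class `"compartment_track"`: `pc1` (per-bin, `NA` for
#'   masked), `label` (`"A"`/`"B"`/`"masked"`), `sign_anchor`
#'   (correlation of PC1 with GC), `masked`, and `correlation` (the full
#'   bin-by-bin Pearson correlation matrix, `NA` on masked bins).
#' @export
compartments <- function(m, gc = NULL, log_transform = TRUE,
                         pseudo = 0.01) {
  oe <- oe_normalize(m)
  masked <- attr(oe, "masked")
  vals <- if (log_transform) log2(oe$values + pseudo) else oe$values
  # also mask bins with zero variance across unmasked columns
  sub <- vals[!masked, !masked, drop = FALSE]
  sds <- apply(sub, 1, sd)
  flat <- sds == 0
  if (any(flat)) {
    masked[which(!masked)[flat]] <- TRUE
    sub <- vals[!masked, !masked, drop = FALSE]
  }
  if (sum(!masked) < 10) stop("fewer than 10 unmasked bins")
  C <- cor(t(sub))
  pc <- .leading_eigenvector(C)
  pc1 <- rep(NA_real_, m$n_bins)
  pc1[!masked] <- pc
  anchor <- NA_real_
  if (!is.null(gc)) {
    anchor <- suppressWarnings(cor(pc1, gc, use = "complete.obs"))
    if (!is.na(anchor) && anchor < 0) {
      pc1 <- -pc1
      anchor <- -anchor
    }
  }
  label <- ifelse(is.na(pc1), "masked", ifelse(pc1 > 0, "A", "B"))
  Cfull <- matrix(NA_real_, m$n_bins, m$n_bins)
  Cfull[!masked, !masked] <- C
  structure(list(pc1 = pc1, label = label, sign_anchor = anchor,
                 masked = masked, correlation = Cfull),
            class = "compartment_track")
}

#' TE content in A vs B compartments
#'
#' Compares a per-bin TE measure (bp fraction) between A and B bins with
#' a two-sided Wilcoxon rank-sum test.
#'
#' @param track A `"compartment_track"`.
#' @param te_fraction Per-bin TE fraction (length `n_bins`).
#' @return List with `mean_A`, `mean_B`, `p` and per-label `n`.
#' @export
compartment_te_association <- function(track, te_fraction) {
  a <- te_fraction[track$label == "A"]
  b <- te_fraction[track$label == "B"]
  if (!length(a) || !length(b))
    stop("single compartment: both A and B bins required")
  wt <- suppressWarnings(wilcox.test(a, b))
  list(mean_A = mean(a), mean_B = mean(b), p = wt$p.value,
       n_A = length(a), n_B = length(b))
}

#' TAD-separation score and boundary calling
#'
#' For each bin `b` and depth `d` (in bins) the separation score is the
#' mean contact in the `d x d` square linking the `d` bins upstream of
#' the `b`/`b+1` interface to the `d` bins downstream. Scores are
#' z-transformed per depth and averaged across the depth range
#' (multi-scale score). A boundary is a local minimum of the multi-scale
#' score whose depth below the neighbouring local maxima is at least
#' `delta`, and whose inter-domain diamond values are significantly lower
#' than the flanking intra-domain values (one-sided Wilcoxon rank-sum,
#' Benjamini-Hochberg across candidates at `fdr`).
#'
#' Depths are given in bp and rounded up to at least one bin.
#'
#' @param m A `"contact_matrix"`.
#' @param min_depth_bp,max_depth_bp,step_bp Depth range of the diamonds.
#' @param delta Minimum score depth below neighbouring maxima.
#' @param fdr Benjamini-Hochberg threshold for the rank-sum filter.
#' @return List of class `"tad_boundaries"`: `boundaries` (bin indices,
#'   1-based, boundary between `b` and `b+1`), `score` (per-bin
#'   multi-scale score, `NA` near edges), `qvalues` (per boundary),
#'   `delta`.
#' @export
tad_separation <- function(m, min_depth_bp = 3 * m$resolution,
                           max_depth_bp = 8 * m$resolution,
                           step_bp = m$resolution,
                           delta = 0.01, fdr = 0.05) {
  v <- m$values
  n <- nrow(v)
  depths <- unique(pmax(1L, ceiling(seq(min_depth_bp, max_depth_bp,
                                        by = step_bp) / m$resolution)))
  score_by_d <- lapply(depths, function(d) {
    s <- rep(NA_real_, n)
    for (b in seq_len(n - 1)) {
      i0 <- b - d + 1L
      j1 <- b + d
      if (i0 < 1 || j1 > n) next
      s[b] <- mean(v[i0:b, (b + 1):j1])
    }
    mu <- mean(s, na.rm = TRUE)
    sdev <- sd(s, na.rm = TRUE)
    if (is.na(sdev) || sdev == 0) s[] <- ifelse(is.na(s), NA, 0)
    else s <- (s - mu) / sdev
    s
  })
  ms <- Reduce(`+`, score_by_d) / length(depths)
  valid <- which(!is.na(ms))
  boundaries <- integer()
  qvals <- numeric()
  if (length(valid) >= 3) {
    idx <- valid
    y <- ms[idx]
    is_min <- c(FALSE, y[-c(1, length(y))] < y[-c(length(y) - 1, length(y))] &
                  y[-c(1, 2)] >= y[-c(1, length(y))], FALSE)
    cand <- which(is_min)
    maxima <- which(c(FALSE,
                      y[-c(1, length(y))] > y[-c(length(y) - 1, length(y))] &
                        y[-c(1, 2)] <= y[-c(1, length(y))], FALSE))
    diamond <- function(b, d) {
      i0 <- b - d + 1L; j1 <- b + d
      if (i0 < 1 || j1 > n) {
        d <- min(b, n - b)
        i0 <- b - d + 1L; j1 <- b + d
      }
      as.numeric(v[i0:b, (b + 1):j1])
    }
    keep <- logical(length(cand))
    pvals <- numeric(length(cand))
    dmax <- max(depths)
    for (ci in seq_along(cand)) {
      k <- cand[ci]
      left <- maxima[maxima < k]
      right <- maxima[maxima > k]
      left_max <- if (length(left)) y[max(left)] else max(y[1:k])
      right_max <- if (length(right)) y[min(right)] else max(y[k:length(y)])
      if (min(left_max, right_max) - y[k] < delta) next
      # compare the boundary diamond against same-geometry diamonds at the
      # flanking score maxima: identical distance composition, so the
      # comparison is not confounded by distance decay
      ref_bins <- idx[c(if (length(left)) max(left),
                        if (length(right)) min(right))]
      if (!length(ref_bins)) next
      inter <- diamond(idx[k], dmax)
      intra <- unlist(lapply(ref_bins, diamond, d = dmax))
      pv <- suppressWarnings(
        wilcox.test(inter, intra, alternative = "less")$p.value)
      keep[ci] <- TRUE
      pvals[ci] <- pv
    }
    if (any(keep)) {
      q <- p.adjust(pvals[keep], method = "BH")
      sel <- q <= fdr
      boundaries <- idx[cand[keep][sel]]
      qvals <- q[sel]
    }
  }
  structure(list(boundaries = boundaries, score = ms, qvalues = qvals,
                 delta = delta, depths_bins = depths),
            class = "tad_boundaries")
}

#' Classify bins as LINE-rich, SINE-rich or neutral
#'
#' A bin is LINE-rich iff its LINE bp fraction reaches the genome-wide
#' class quantile (default upper quartile) and strictly exceeds its SINE
#' fraction; symmetrically for SINE-rich; everything else (including
#' exact ties) is neutral.
#'
#' @param line_frac,sine_frac Per-bin bp fractions.
#' @param quantile_cut Quantile defining "rich".
#' @return List of class `"bin_class_track"`: `label` per bin, plus the
#'   input fractions.
#' @export
classify_bins <- function(line_frac, sine_frac, quantile_cut = 0.75) {
  ql <- quantile(line_frac, quantile_cut)
  qs <- quantile(sine_frac, quantile_cut)
  label <- rep("neutral", length(line_frac))
  label[line_frac >= ql & line_frac > sine_frac] <- "LINE-rich"
  label[sine_frac >= qs & sine_frac > line_frac] <- "SINE-rich"
  structure(list(label = label, line_frac = line_frac,
                 sine_frac = sine_frac),
            class = "bin_class_track")
}

#' Homotypic interaction statistics
#'
#' Groups off-diagonal entries of a (correlation) matrix by the class
#' labels of the two bins and reports, per pair type, the number of
#' pairs, the fraction of positive entries and the mean entry.
#'
#' @param corr_matrix Symmetric numeric matrix (e.g. the Pearson
#'   correlation matrix of the O/E contacts).
#' @param bins A `"bin_class_track"`.
#' @param masked Optional logical vector of bins to exclude.
#' @return Data frame with rows `LINE-LINE`, `SINE-SINE`, `LINE-SINE`:
#'   `n_pairs`, `fraction_positive`, `mean_value`.
#' @export
homotypic_stats <- function(corr_matrix, bins, masked = NULL) {
  n <- nrow(corr_matrix)
  stopifnot(length(bins$label) == n)
  use <- if (is.null(masked)) rep(TRUE, n) else !masked
  lab <- bins$label
  idx <- which(upper.tri(corr_matrix), arr.ind = TRUE)
  ok <- use[idx[, 1]] & use[idx[, 2]]
  li <- lab[idx[ok, 1]]
  lj <- lab[idx[ok, 2]]
  vals_all <- corr_matrix[idx[ok, , drop = FALSE]]
  pick <- list(
    `LINE-LINE` = li == "LINE-rich" & lj == "LINE-rich",
    `SINE-SINE` = li == "SINE-rich" & lj == "SINE-rich",
    `LINE-SINE` = (li == "LINE-rich" & lj == "SINE-rich") |
                  (li == "SINE-rich" & lj == "LINE-rich"))
  out <- do.call(rbind, lapply(names(pick), function(pt) {
    vals <- vals_all[pick[[pt]]]
    data.frame(pair_type = pt, n_pairs = length(vals),
               fraction_positive = if (length(vals)) mean(vals > 0)
                                   else NA_real_,
               mean_value = if (length(vals)) mean(vals) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assign TADs or loops to LINE-rich vs SINE-rich bins
#'
#' Interval features (TADs) are assigned by majority bp over LINE-rich vs
#' SINE-rich bins ("mixed" on an exact tie, "neutral" when neither class
#' is touched). Anchor-pair features (loops, columns `start1`, `end1`,
#' `start2`, `end2`) are assigned by classifying each anchor the same way
#' and agreeing; disagreeing anchors give "mixed".
#'
#' @param features Data frame of intervals (`start`, `end`) or anchor
#'   pairs (`start1`, `end1`, `start2`, `end2`), bp coordinates on the
#'   matrix's chromosome.
#' @param bins A `"bin_class_track"`.
#' @param resolution Bin size in bp.
#' @return List with `assignment` (per feature) and `proportions` (share
#'   of features per category).
#' @export
feature_overlap <- function(features, bins, resolution) {
  n <- length(bins$label)
  bp_in_class <- function(s, e, cls) {
    b0 <- max(1, s %/% resolution + 1)
    b1 <- min(n, (e - 1) %/% resolution + 1)
    if (b1 < b0) return(0)
    bs <- b0:b1
    lo <- pmax(s, (bs - 1) * resolution)
    hi <- pmin(e, bs * resolution)
    sum((hi - lo)[bins$label[bs] == cls])
  }
  classify_iv <- function(s, e) {
    l <- bp_in_class(s, e, "LINE-rich")
    si <- bp_in_class(s, e, "SINE-rich")
    if (l == 0 && si == 0) "neutral"
    else if (l > si) "LINE-rich"
    else if (si > l) "SINE-rich"
    else "mixed"
  }
  if (!nrow(features)) {
    assignment <- character()
  } else if (all(c("start1", "end1", "start2", "end2") %in%
                 names(features))) {
    assignment <- vapply(seq_len(nrow(features)), function(i) {
      a1 <- classify_iv(features$start1[i], features$end1[i])
      a2 <- classify_iv(features$start2[i], features$end2[i])
      if (a1 == a2) a1 else "mixed"
    }, "")
  } else {
    assignment <- vapply(seq_len(nrow(features)), function(i)
      classify_iv(features$start[i], features$end[i]), "")
  }
  cats <- c("LINE-rich", "SINE-rich", "mixed", "neutral")
  props <- if (length(assignment))
    vapply(cats, function(ct) mean(assignment == ct), 0)
  else setNames(rep(0, 4), cats)
  list(assignment = assignment, proportions = props)
}
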