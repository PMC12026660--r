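# Windowed TE distribution statistics, Wald-Wolfowitz randomness testing,
# proximity distributions and dense-block detection.

#' Per-window TE statistics
#'
#' Tiles each chromosome with fixed windows and apportions every TE: its
#' bp goes to each overlapped window by intersection length, its count to
#' the window containing its midpoint. Summed window bp therefore equals
#' total TE bp exactly.
#'
#' @param tes TE copy table.
#' @param genome Genome index.
#' @param window_bp Window size (bp), default 250 kb.
#' @param classes TE classes to tabulate.
#' @return Data frame with `chrom`, `window_start`, `window_end` and, per
#'   class, `<class>_count`, `<class>_bp`, `<class>_frac` (fraction of the
#'   window covered).
#' @export
window_stats <- function(tes, genome, window_bp = 250000,
                         classes = c("LINE", "SINE")) {
  stopifnot(window_bp > 0)
  if (any(!tes$chrom %in% genome$chrom)) stop("TE on unknown chromosome")
  win <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = window_bp)
    data.frame(chrom = genome$chrom[i], window_start = starts,
               window_end = pmin(starts + window_bp, genome$length[i]),
               stringsAsFactors = FALSE)
  }))
  win_key <- paste(win$chrom, win$window_start %/% window_bp)
  for (cl in classes) {
    cnt <- numeric(nrow(win))
    bp <- numeric(nrow(win))
    sub <- tes[tes$te_class == cl, , drop = FALSE]
    if (nrow(sub)) {
      # counts by midpoint window
      mid <- floor((sub$start + sub$end) / 2)
      key <- paste(sub$chrom, mid %/% window_bp)
      tab <- table(key)
      cnt[match(names(tab), win_key)] <- as.numeric(tab)
      # bp by intersection: a TE spans windows floor(start/w)..floor((end-1)/w)
      w0 <- sub$start %/% window_bp
      w1 <- (sub$end - 1) %/% window_bp
      span <- lapply(seq_len(nrow(sub)), function(j) {
        ws <- seq(w0[j], w1[j])
        lo <- pmax(sub$start[j], ws * window_bp)
        hi <- pmin(sub$end[j], (ws + 1) * window_bp)
        cbind(ws, hi - lo, j)
      })
      span <- do.call(rbind, span)
      key2 <- paste(sub$chrom[span[, 3]], span[, 1])
      agg <- tapply(span[, 2], key2, sum)
      bp[match(names(agg), win_key)] <- as.numeric(agg)
    }
    win[[paste0(cl, "_count")]] <- cnt
    win[[paste0(cl, "_bp")]] <- bp
    win[[paste0(cl, "_frac")]] <- bp / (win$window_end - win$window_start)
  }
  win
}

#' Wald-Wolfowitz runs test
#'
#' Tests a two-symbol sequence for randomness of ordering. With `n1` and
#' `n2` symbols of each kind and `R` observed runs,
#' `mu_R = 2 n1 n2 / (n1 + n2) + 1` and
#' `sigma_R^2 = 2 n1 n2 (2 n1 n2 - n1 - n2) / ((n1+n2)^2 (n1+n2-1))`;
#' the two-sided p-value uses the normal approximation for
#' `z = (R - mu_R) / sigma_R`.
#'
#' @param x A vector (logical, character or numeric) taking exactly two
#'   distinct values.
#' @return A list with `R`, `n1`, `n2`, `mu_R`, `sigma_R`, `z`,
#'   `p_two_sided`.
#' @export
runs_test <- function(x) {
  x <- as.character(x)
  lev <- unique(x)
  if (length(lev) != 2)
    stop("runs test undefined: sequence must contain exactly two symbols")
  n1 <- sum(x == lev[1])
  n2 <- sum(x == lev[2])
  R <- 1L + sum(x[-1] != x[-length(x)])
  n <- n1 + n2
  mu_R <- 2 * n1 * n2 / n + 1
  sigma_R <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
  z <- (R - mu_R) / sigma_R
  list(R = R, n1 = n1, n2 = n2, mu_R = mu_R, sigma_R = sigma_R, z = z,
       p_two_sided = 2 * pnorm(-abs(z)))
}

#' Per-chromosome randomness test of window counts
#'
#' Binarises window counts at the chromosome median (count > median -> 1,
#' ties -> 0) and applies the runs test per chromosome. Chromosomes whose
#' binarisation is single-valued (e.g. all counts equal) are flagged
#' `degenerate` rather than tested.
#'
#' @param ws Output of [window_stats()].
#' @param te_class Class whose counts are tested.
#' @return Data frame with one row per chromosome: `chrom`, `n_windows`,
#'   `degenerate`, `R`, `z`, `p`.
#' @export
randomness_by_chromosome <- function(ws, te_class = "LINE") {
  col <- paste0(te_class, "_count")
  stopifnot(col %in% names(ws))
  out <- lapply(split(ws, ws$chrom), function(d) {
    if (nrow(d) < 2)
      return(data.frame(chrom = d$chrom[1], n_windows = nrow(d),
                        degenerate = TRUE, R = NA, z = NA, p = NA))
    b <- as.integer(d[[col]] > median(d[[col]]))
    if (length(unique(b)) < 2)
      return(data.frame(chrom = d$chrom[1], n_windows = nrow(d),
                        degenerate = TRUE, R = NA, z = NA, p = NA))
    rt <- runs_test(b)
    data.frame(chrom = d$chrom[1], n_windows = nrow(d), degenerate = FALSE,
               R = rt$R, z = rt$z, p = rt$p_two_sided)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Proximity distance distribution between consecutive same-class TEs
#'
#' Distance is `next start - current end` along each chromosome, clamped
#' at 0 for overlapping elements. Proportions are reported per chromosome
#' over half-open distance bins.
#'
#' @param tes TE copy table.
#' @param te_class Class to analyse.
#' @param breaks Bin edges in bp; a final `Inf` edge is appended.
#' @return Data frame: `chrom`, `bin` (label), `n`, `proportion` (summing
#'   to 1 per chromosome).
#' @export
proximity_distribution <- function(tes, te_class = "SINE",
                                   breaks = seq(0, 2000, by = 200)) {
  sub <- tes[tes$te_class == te_class, , drop = FALSE]
  edges <- c(breaks, Inf)
  labs <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  out <- lapply(split(sub, sub$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2) return(NULL)
    gap <- pmax(0, d$start[-1] - d$end[-nrow(d)])
    cut_i <- findInterval(gap, edges, rightmost.closed = FALSE)
    tab <- tabulate(cut_i, nbins = length(labs))
    data.frame(chrom = d$chrom[1], bin = labs, n = tab,
               proportion = tab / sum(tab), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect dense TE blocks
#'
#' A block is a maximal run of same-class elements along a chromosome in
#' which every consecutive gap (end-to-start, overlap = 0) is at most
#' `max_gap` and the run contains at least `min_elements` elements. Input
#' order is irrelevant; elements are sorted internally.
#'
#' @param tes TE copy table.
#' @param te_class Class to scan.
#' @param max_gap Maximum allowed gap between consecutive members (bp).
#' @param min_elements Minimum run length kept.
#' @return Data frame: `chrom`, `start`, `end`, `te_class`, `n_elements`.
#' @export
detect_blocks <- function(tes, te_class = "SINE", max_gap = 1000,
                          min_elements = 5) {
  sub <- tes[tes$te_class == te_class, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), te_class = character(),
                      n_elements = integer(), stringsAsFactors = FALSE)
  if (!nrow(sub)) return(empty)
  out <- lapply(split(sub, sub$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    if (nrow(d) == 1) {
      run_id <- 1L
    } else {
      gap <- pmax(0, d$start[-1] - d$end[-nrow(d)])
      run_id <- cumsum(c(1L, as.integer(gap > max_gap)))
    }
    keep <- tabulate(run_id)[run_id] >= min_elements
    if (!any(keep)) return(NULL)
    d <- d[keep, , drop = FALSE]
    run_id <- run_id[keep]
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, run_id, min),
               end = tapply(d$end, run_id, max),
               te_class = te_class,
               n_elements = as.integer(table(run_id)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Per-chromosome dispersion of window statistics
#'
#' Standard deviation (denominator n-1) of per-window counts and bp for
#' each class, one row per chromosome.
#'
#' @param ws Output of [window_stats()].
#' @param classes TE classes present in `ws`.
#' @return Data frame with `chrom` and `<class>_count_sd`, `<class>_bp_sd`.
#' @export
dispersion_summary <- function(ws, classes = c("LINE", "SINE")) {
  out <- lapply(split(ws, ws$chrom), function(d) {
    row <- data.frame(chrom = d$chrom[1], stringsAsFactors = FALSE)
    for (cl in classes) {
      row[[paste0(cl, "_count_sd")]] <- sd(d[[paste0(cl, "_count")]])
      row[[paste0(cl, "_bp_sd")]] <- sd(d[[paste0(cl, "_bp")]])
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-sample test of per-chromosome TE proportions against uniformity
#'
#' Tests whether per-chromosome TE content proportions are compatible with
#' a single genome-wide value via a one-sample t-test. `expected` is
#' normally the aggregate genome-wide proportion (total TE bp over total
#' genome bp), which differs from the unweighted chromosome mean when
#' chromosome lengths differ. Zero variance across chromosomes is
#' reported as `p = 1` with a `degenerate` flag.
#'
#' @param proportions Numeric vector of per-chromosome TE fractions.
#' @param expected Uniform value tested against; defaults to the
#'   unweighted mean of `proportions`.
#' @return List with `t_stat`, `p`, `expected`, `degenerate`.
#' @export
chromosome_proportion_test <- function(proportions,
                                       expected = mean(proportions)) {
  stopifnot(length(proportions) >= 2)
  if (sd(proportions) == 0)
    return(list(t_stat = 0, p = 1, expected = expected, degenerate = TRUE))
  tt <- t.test(proportions, mu = expected)
  list(t_stat = unname(tt$statistic), p = tt$p.value, expected = expected,
       degenerate = FALSE)
}
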