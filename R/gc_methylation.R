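# GC-content association and CpG-methylation aggregation statistics.

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` and other ambiguity codes are
#' excluded from the denominator.
#'
#' @param seq Character string or `DNAString`-like object.
#' @return Fraction in `[0, 1]` (`NaN` for an all-N sequence).
#' @export
gc_content <- function(seq) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  acgt <- sum(s %in% c("A", "C", "G", "T"))
  sum(s %in% c("G", "C")) / acgt
}

#' Per-window GC track of a genome
#'
#' @param genome List with `sequences` (`DNAStringSet`) and `index`.
#' @param window Window size in bp.
#' @return Data frame: `chrom`, `window_start`, `window_end`, `gc`.
#' @export
window_gc <- function(genome, window = 250000) {
  out <- lapply(names(genome$sequences), function(ch) {
    s <- genome$sequences[[ch]]
    len <- length(s)
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    v <- Biostrings::Views(s, start = starts + 1, end = ends)
    freq <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    data.frame(chrom = ch, window_start = starts, window_end = ends,
               gc = rowSums(freq[, c("G", "C"), drop = FALSE]) /
                 rowSums(freq),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.pearson_result <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = if (n >= 2 && sd(x) > 0 && sd(y) > 0) cor(x, y)
                else NA_real_,
                n = n, t_stat = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = n, t_stat = unname(ct$statistic),
       p = ct$p.value, degenerate = FALSE)
}

#' Windowed TE/GC association
#'
#' Per window: genome GC, TE-covered bp per class, and the GC of the
#' TE-covered bases themselves. The association statistic per class is
#' the Pearson correlation between window genome GC and TE bp, computed
#' over windows that carry any TE of that class.
#'
#' @param tes TE copy table.
#' @param genome Genome list (`sequences` + `index`).
#' @param window Window size in bp.
#' @param classes TE classes to analyse.
#' @return List with `track` (per-window data frame, including per-class
#'   `bp`, `te_gc` and `log10_ratio` of TE GC to window GC) and
#'   `association` (named list of Pearson results per class).
#' @export
te_gc_association <- function(tes, genome, window = 250000,
                              classes = c("LINE", "SINE")) {
  track <- window_gc(genome, window)
  ws <- window_stats(tes, genome$index, window_bp = window,
                     classes = classes)
  stopifnot(nrow(ws) == nrow(track))
  assoc <- list()
  for (cl in classes) {
    bp <- ws[[paste0(cl, "_bp")]]
    track[[paste0(cl, "_bp")]] <- bp
    te_gc <- rep(NA_real_, nrow(track))
    sub <- tes[tes$te_class == cl, , drop = FALSE]
    if (nrow(sub)) {
      for (i in which(bp > 0)) {
        ch <- track$chrom[i]
        lo <- track$window_start[i]; hi <- track$window_end[i]
        d <- sub[sub$chrom == ch & sub$end > lo & sub$start < hi, ,
                 drop = FALSE]
        if (!nrow(d)) next
        v <- Biostrings::Views(genome$sequences[[ch]],
                               start = pmax(d$start, lo) + 1,
                               end = pmin(d$end, hi))
        freq <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
        te_gc[i] <- sum(freq[, c("G", "C")]) / sum(freq)
      }
    }
    track[[paste0(cl, "_gc")]] <- te_gc
    track[[paste0(cl, "_log10_ratio")]] <-
      ifelse(te_gc > 0 & track$gc > 0, log10(te_gc / track$gc), NA_real_)
    with_te <- bp > 0
    if (!any(with_te)) stop("no data: no window carries a ", cl)
    assoc[[cl]] <- .pearson_result(track$gc[with_te], bp[with_te])
  }
  list(track = track, association = assoc)
}

#' Correlation between TE GC content and insertion age
#'
#' @param gc Numeric vector of per-copy GC fractions.
#' @param age_My Numeric vector of per-copy ages (My).
#' @return Pearson result list (`r`, `n`, `t_stat`, `p`, `degenerate`);
#'   degenerate when the correlation or its test is undefined (constant
#'   input, or fewer than 3 points).
#' @export
gc_vs_age <- function(gc, age_My) .pearson_result(gc, age_My)

#' Aggregate methylation sites over TE copies
#'
#' A site belongs to a copy iff `start <= pos < end` on the same
#' chromosome. Per-element summaries count every containing copy; the
#' class-level share of sites is deduplicated so a site inside two
#' overlapping same-class copies is counted once.
#'
#' @param tes TE copy table.
#' @param sites Methylation table (`chrom`, `pos`, `coverage`,
#'   `methyl_fraction`).
#' @param genes Optional gene model table; when given, per-class mean
#'   fractions are split by genomic context (within `near_gene_bp` of a
#'   gene vs distal).
#' @param near_gene_bp Distance defining "near gene".
#' @return List with `elements` (per-copy `copy_id`, `te_class`,
#'   `n_sites`, `mean_fraction`, `is_methylated`) and `classes`
#'   (per-class `n_sites` deduplicated, `site_share` of all sites,
#'   `element_share` with >= 1 site, `mean_fraction`, and when genes are
#'   supplied `mean_fraction_near_gene` / `mean_fraction_distal`).
#' @export
methylation_summary <- function(tes, sites, genes = NULL,
                                near_gene_bp = 5000) {
  te_gr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(tes$start + 1, tes$end))
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1,
                                                     sites$pos + 1))
  hits <- GenomicRanges::findOverlaps(site_gr, te_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n_sites <- tabulate(sh, nbins = nrow(tes))
  mean_fraction <- rep(NA_real_, nrow(tes))
  if (length(sh)) {
    agg <- tapply(sites$methyl_fraction[qh], sh, mean)
    mean_fraction[as.integer(names(agg))] <- as.numeric(agg)
  }
  elements <- data.frame(copy_id = tes$copy_id, te_class = tes$te_class,
                         n_sites = n_sites, mean_fraction = mean_fraction,
                         is_methylated = n_sites >= 1,
                         stringsAsFactors = FALSE)
  near <- NULL
  if (!is.null(genes)) {
    span <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(0, genes$tx_start - near_gene_bp) + 1,
                       genes$tx_end + near_gene_bp))
    near <- GenomicRanges::countOverlaps(te_gr, span) > 0
  }
  classes <- do.call(rbind, lapply(c("LINE", "SINE"), function(cl) {
    in_cl <- tes$te_class == cl
    cl_hits <- sh[in_cl[sh]]
    cl_sites <- unique(qh[in_cl[sh]])
    row <- data.frame(
      te_class = cl,
      n_sites = length(cl_sites),
      site_share = length(cl_sites) / nrow(sites),
      element_share = if (any(in_cl)) mean(elements$is_methylated[in_cl])
                      else NA_real_,
      mean_fraction = if (length(cl_sites))
        mean(sites$methyl_fraction[cl_sites]) else NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(near)) {
      row$mean_fraction_near_gene <-
        mean(elements$mean_fraction[in_cl & near], na.rm = TRUE)
      row$mean_fraction_distal <-
        mean(elements$mean_fraction[in_cl & !near], na.rm = TRUE)
    }
    row
  }))
  rownames(classes) <- NULL
  list(elements = elements, classes = classes)
}

#' Correlation between subfamily age and mean methylation
#'
#' @param age_My Per-subfamily mean insertion age (My).
#' @param mean_methylation Per-subfamily mean methylated fraction.
#' @return Pearson result list; errors with fewer than 2 subfamilies.
#' @export
methylation_vs_age <- function(age_My, mean_methylation) {
  if (length(age_My) < 2)
    stop("at least two subfamilies required")
  .pearson_result(age_My, mean_methylation)
}
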