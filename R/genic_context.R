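# Genic-context annotation of TE copies, enriched/specific gene sets,
# repeat-percentage matrices with quantile normalization, hypergeometric
# set enrichment and cumulative-distribution comparisons.

.gene_granges <- function(genes) {
  GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$tx_start + 1, genes$tx_end),
    strand = genes$strand, gene_id = genes$gene_id)
}

#' Annotate TE copies with their genic context
#'
#' Each TE is assigned by its midpoint to exactly one feature label with
#' priority Promoter > 5UTR > 3UTR > Exon > Intron > Downstream >
#' Intergenic. The promoter is the strand-aware window
#' `[TSS - promoter_flank, TSS + promoter_flank)`; Downstream extends
#' `downstream_flank` bp past the transcript end. UTRs require annotated
#' CDS; without CDS a genic midpoint falls to Exon/Intron.
#'
#' @param tes TE copy table.
#' @param genes Gene model table from [read_gff3_genes()] (or the same
#'   shape built in code).
#' @param promoter_flank,downstream_flank Flank sizes in bp.
#' @return Data frame: `copy_id`, `label`, `nearest_gene_id`,
#'   `distance_bp` (signed midpoint distance to the nearest transcript
#'   span; 0 when overlapping).
#' @export
annotate_te <- function(tes, genes, promoter_flank = 3000,
                        downstream_flank = 3000) {
  mid <- floor((tes$start + tes$end) / 2)
  labels <- rep("Intergenic", nrow(tes))
  nearest <- rep(NA_character_, nrow(tes))
  distance <- rep(NA_real_, nrow(tes))
  pri <- c(Promoter = 1, `5UTR` = 2, `3UTR` = 3, Exon = 4, Intron = 5,
           Downstream = 6, Intergenic = 7)
  for (i in seq_len(nrow(tes))) {
    g_idx <- which(genes$chrom == tes$chrom[i])
    if (!length(g_idx)) next
    m <- mid[i]
    best <- "Intergenic"
    # signed distance to nearest transcript span (negative = upstream of TSS
    # in genome coordinates' left direction is not meaningful; report
    # midpoint - nearest span edge, 0 on overlap)
    dists <- ifelse(m < genes$tx_start[g_idx], m - genes$tx_start[g_idx],
             ifelse(m >= genes$tx_end[g_idx], m - (genes$tx_end[g_idx] - 1),
                    0))
    j_near <- g_idx[which.min(abs(dists))]
    nearest[i] <- genes$gene_id[j_near]
    distance[i] <- dists[which.min(abs(dists))]
    for (j in g_idx) {
      plus <- genes$strand[j] != "-"
      tss <- if (plus) genes$tx_start[j] else genes$tx_end[j] - 1
      tes_end <- if (plus) genes$tx_end[j] else genes$tx_start[j]
      lab <- NULL
      if (m >= tss - promoter_flank && m < tss + promoter_flank) {
        lab <- "Promoter"
      } else if (m >= genes$tx_start[j] && m < genes$tx_end[j]) {
        ex <- genes$exons[[j]]
        in_exon <- nrow(ex) > 0 &&
          any(m >= ex[, "start"] & m < ex[, "end"])
        cds <- genes$cds[[j]]
        if (in_exon && nrow(cds) > 0) {
          cds_lo <- min(cds[, "start"]); cds_hi <- max(cds[, "end"])
          if (m < cds_lo) lab <- if (plus) "5UTR" else "3UTR"
          else if (m >= cds_hi) lab <- if (plus) "3UTR" else "5UTR"
          else lab <- "Exon"
        } else {
          lab <- if (in_exon) "Exon" else "Intron"
        }
      } else {
        down_lo <- if (plus) genes$tx_end[j] else genes$tx_start[j] -
          downstream_flank
        down_hi <- if (plus) genes$tx_end[j] + downstream_flank else
          genes$tx_start[j]
        if (m >= down_lo && m < down_hi) lab <- "Downstream"
      }
      if (!is.null(lab) && pri[lab] < pri[best]) best <- lab
    }
    labels[i] <- best
  }
  data.frame(copy_id = tes$copy_id, label = labels,
             nearest_gene_id = nearest, distance_bp = distance,
             stringsAsFactors = FALSE)
}

#' TE-enriched and TE-specific gene sets
#'
#' A gene is class-enriched when any TE of that class overlaps the flanked
#' transcript span `[tx_start - flank, tx_end + flank)`. Class-specific
#' genes are enriched for that class and for no other listed class.
#'
#' @param tes TE copy table.
#' @param genes Gene model table.
#' @param flank Flank size in bp (default 5 kb).
#' @param classes TE classes to consider.
#' @return Named list with `<class>_enriched` and `<class>_specific`
#'   character vectors of gene ids.
#' @export
enriched_genes <- function(tes, genes, flank = 5000,
                           classes = c("LINE", "SINE")) {
  span <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(0, genes$tx_start - flank) + 1,
                     genes$tx_end + flank))
  enriched <- lapply(classes, function(cl) {
    sub <- tes[tes$te_class == cl, , drop = FALSE]
    if (!nrow(sub)) return(character())
    gr <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$start + 1, sub$end))
    hits <- GenomicRanges::findOverlaps(span, gr)
    sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
  })
  names(enriched) <- classes
  out <- list()
  for (cl in classes) {
    others <- unlist(enriched[setdiff(classes, cl)])
    out[[paste0(cl, "_enriched")]] <- enriched[[cl]]
    out[[paste0(cl, "_specific")]] <- setdiff(enriched[[cl]], others)
  }
  out
}

#' Fraction of TEs near genes and of genes hit by TEs
#'
#' @param tes TE copy table.
#' @param genes Gene model table.
#' @param flank Genic flank in bp (default 3 kb).
#' @return List with `te_fraction` (TEs overlapping any flanked gene span)
#'   and `gene_fraction` (genes overlapped by any TE).
#' @export
genic_overlap_fraction <- function(tes, genes, flank = 3000) {
  if (!nrow(tes) || !nrow(genes))
    return(list(te_fraction = 0, gene_fraction = 0))
  span <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(0, genes$tx_start - flank) + 1,
                     genes$tx_end + flank))
  gr <- GenomicRanges::GRanges(tes$chrom,
                               IRanges::IRanges(tes$start + 1, tes$end))
  hits <- GenomicRanges::findOverlaps(gr, span)
  list(te_fraction = length(unique(S4Vectors::queryHits(hits))) / nrow(tes),
       gene_fraction = length(unique(S4Vectors::subjectHits(hits))) /
         nrow(genes))
}

#' Repeat-percentage matrix over flanked gene spans
#'
#' Entry (gene, family) is 100 times the fraction of the gene's flanked
#' span `[tx_start - flank, tx_end + flank)` covered by copies of that
#' family (same-family overlaps are merged before measuring coverage).
#'
#' @param tes TE copy table.
#' @param genes Gene model table.
#' @param flank Flank in bp added on both sides of each transcript.
#' @return Numeric matrix, genes x families, entries in `[0, 100]`.
#' @export
repeat_percent_matrix <- function(tes, genes, flank = 3000) {
  fams <- sort(unique(tes$family))
  span_start <- pmax(0, genes$tx_start - flank)
  span_end <- genes$tx_end + flank
  span <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(span_start + 1, span_end))
  m <- matrix(0, nrow(genes), length(fams),
              dimnames = list(genes$gene_id, fams))
  for (f in fams) {
    sub <- tes[tes$family == f, , drop = FALSE]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$start + 1, sub$end)))
    hits <- GenomicRanges::findOverlaps(span, gr)
    if (!length(hits)) next
    ov <- GenomicRanges::pintersect(span[S4Vectors::queryHits(hits)],
                                    gr[S4Vectors::subjectHits(hits)])
    cov <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(cov))
    m[idx, f] <- 100 * as.numeric(cov) / (span_end - span_start)[idx]
  }
  m
}

#' Quantile-normalize a matrix across columns
#'
#' Each column's sorted values are replaced by the across-column means of
#' the sorted columns; tied ranks receive the average of the values they
#' would have received. After normalization all columns are permutations
#' of one another.
#'
#' @param m Numeric matrix.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  out <- limma::normalizeQuantiles(as.matrix(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Average-linkage hierarchical clustering of a repeat matrix
#'
#' Euclidean distance between rows, `hclust` with the average method.
#'
#' @param m Numeric matrix (rows are clustered).
#' @param k Optional number of clusters to cut into.
#' @return List with `tree` (an `hclust`) and, when `k` is given,
#'   `labels` (named cluster assignment).
#' @export
hierarchical_cluster <- function(m, k = NULL) {
  tree <- hclust(dist(m, method = "euclidean"), method = "average")
  out <- list(tree = tree)
  if (!is.null(k)) out$labels <- cutree(tree, k = k)
  out
}

#' Hypergeometric term enrichment with BH adjustment
#'
#' For each term, the over-representation p-value is
#' `P(X >= k)` under `Hypergeometric(N, K, n)` where `N` is the universe
#' size, `K` the term size, `n` the query size and `k` the overlap.
#' Benjamini-Hochberg adjustment is applied across terms.
#'
#' @param query_genes Character vector of query gene ids (subset of
#'   `universe`).
#' @param term_membership Data frame with columns `term_id`, `gene_id`.
#' @param universe Character vector of all gene ids.
#' @param alpha Adjusted-p significance cutoff.
#' @return Data frame per term: `term_id`, `N`, `K`, `n`, `k`, `p_hyper`,
#'   `p_adjusted`, `significant`.
#' @export
term_enrichment <- function(query_genes, term_membership, universe,
                            alpha = 0.01) {
  if (!all(query_genes %in% universe))
    stop("query genes must be a subset of the universe")
  term_membership <- term_membership[
    term_membership$gene_id %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  n <- length(unique(query_genes))
  terms <- split(term_membership$gene_id, term_membership$term_id)
  res <- data.frame(
    term_id = names(terms),
    N = N,
    K = vapply(terms, function(g) length(unique(g)), 0L),
    n = n,
    k = vapply(terms, function(g)
      length(intersect(unique(g), query_genes)), 0L),
    stringsAsFactors = FALSE)
  res$p_hyper <- phyper(res$k - 1, res$K, N - res$K, n, lower.tail = FALSE)
  res$p_adjusted <- p.adjust(res$p_hyper, method = "BH")
  res$significant <- res$p_adjusted <= alpha
  rownames(res) <- NULL
  res[order(res$p_hyper), ]
}

#' Compare enrichment p-value distributions against random gene sets
#'
#' Two-sided Wilcoxon rank-sum test between the query p-values and the
#' pooled p-values of the random sets, the comparison behind a
#' cumulative-distribution-curve plot of enrichment p-values.
#'
#' @param pvals_query Numeric vector of query-set p-values.
#' @param pvals_random Numeric vector (or list of vectors) of random-set
#'   p-values, pooled.
#' @return List with `W` (rank-sum statistic) and `p`.
#' @export
cdc_compare <- function(pvals_query, pvals_random) {
  pooled <- unlist(pvals_random)
  wt <- suppressWarnings(wilcox.test(pvals_query, pooled,
                                     alternative = "two.sided"))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Draw size-matched random gene sets
#'
#' Sampling is without replacement within each set, seeded for
#' reproducibility; used as the null reference for [cdc_compare()].
#'
#' @param universe Character vector to sample from.
#' @param size Set size.
#' @param n_sets Number of sets.
#' @param seed Integer seed.
#' @return List of character vectors.
#' @export
random_gene_sets <- function(universe, size, n_sets = 10, seed = 1) {
  with_seed(seed, replicate(n_sets, sample(universe, size),
                            simplify = FALSE))
}
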