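# Post-quantification TE expression analytics: location classes, TPM,
# expression filtering, polynomial time-course differential selection,
# silhouette-guided profile clustering and TE-gene correlation links.

#' Classify TEs by genomic location
#'
#' Midpoint-based: `exonic` when the midpoint lies in an exon, `intronic`
#' when inside a gene body but outside exons, `intergenic` when the copy
#' is farther than `intergenic_min_bp` from every gene, and `proximal`
#' (excluded from the three analysis classes) when outside all genes but
#' within `intergenic_min_bp` of one.
#'
#' @param tes TE copy table.
#' @param genes Gene model table.
#' @param intergenic_min_bp Minimum distance from any gene for the
#'   intergenic class.
#' @return Character vector of labels, one per TE.
#' @export
classify_te_location <- function(tes, genes, intergenic_min_bp = 5000) {
  mid <- floor((tes$start + tes$end) / 2)
  vapply(seq_len(nrow(tes)), function(i) {
    g_idx <- which(genes$chrom == tes$chrom[i])
    if (!length(g_idx)) return("intergenic")
    m <- mid[i]
    inside <- g_idx[m >= genes$tx_start[g_idx] & m < genes$tx_end[g_idx]]
    if (length(inside)) {
      for (j in inside) {
        ex <- genes$exons[[j]]
        if (nrow(ex) && any(m >= ex[, "start"] & m < ex[, "end"]))
          return("exonic")
      }
      return("intronic")
    }
    # distance from the copy's span to the nearest gene span
    d <- pmax(0, pmax(genes$tx_start[g_idx] - tes$end[i],
                      tes$start[i] - genes$tx_end[g_idx]))
    if (min(d) > intergenic_min_bp) "intergenic" else "proximal"
  }, "")
}

#' Transcripts-per-million normalization
#'
#' `rate = count / (length / 1000); TPM = rate / sum(rate) * 1e6` per
#' sample; every column of the result sums to 1e6.
#'
#' @param cm A `"count_matrix"` (list with `counts` and
#'   `feature_lengths`), or a plain counts matrix with `lengths` given.
#' @param lengths Feature lengths in bp when `cm` is a plain matrix.
#' @return Matrix of TPM values, same shape as the counts.
#' @export
tpm <- function(cm, lengths = NULL) {
  if (inherits(cm, "count_matrix")) {
    counts <- cm$counts
    lengths <- cm$feature_lengths
  } else counts <- cm
  stopifnot(!is.null(lengths), length(lengths) == nrow(counts))
  if (any(colSums(counts) == 0)) stop("empty library: zero-count sample")
  rate <- counts / (lengths / 1000)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Filter features by expression level
#'
#' Mirrors the standard count-based expression filter: the CPM cutoff is
#' `min_count / median(lib_sizes) * 1e6`; a feature is kept iff its CPM
#' reaches the cutoff in at least `n*` samples, where `n*` is the size of
#' the smallest experimental group, and its total count across samples is
#' at least `min_total`.
#'
#' @param counts Features x samples count matrix.
#' @param groups Factor of sample group memberships.
#' @param min_count Count threshold defining the CPM cutoff.
#' @param min_total Minimum total count across all samples.
#' @return Character vector of kept feature ids (rownames), or indices
#'   when the matrix has no rownames.
#' @export
filter_expressed <- function(counts, groups, min_count = 10,
                             min_total = 15) {
  lib <- colSums(counts)
  cutoff <- min_count / median(lib) * 1e6
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  n_star <- min(table(groups))
  keep <- rowSums(cpm >= cutoff) >= n_star & rowSums(counts) >= min_total
  if (!is.null(rownames(counts))) rownames(counts)[keep] else which(keep)
}

#' Time-course differential expression selection
#'
#' Per feature, fits `y ~ 1 + t + t^2 + g + g:t + g:t^2` by least squares
#' on `log2(TPM + 1)`, with stages coded 0, 1, 2 and tissue as a 0/1
#' indicator, and tests the full model against the intercept-only model
#' with a global F-test. P-values are Benjamini-Hochberg adjusted across
#' features; a feature is selected iff `p_adjusted <= alpha` and
#' `R^2 >= r2_min`.
#'
#' @param expr Features x samples matrix of TPM values.
#' @param meta Sample metadata with `tissue` and `stage` columns matching
#'   the columns of `expr`.
#' @param alpha Adjusted-p cutoff.
#' @param r2_min Minimum R-squared.
#' @return Data frame per feature: `feature_id`, `F_stat`, `p`,
#'   `p_adjusted`, `R_squared`, `selected`.
#' @export
timecourse_de <- function(expr, meta, alpha = 0.05, r2_min = 0.6) {
  stopifnot(ncol(expr) == nrow(meta))
  t_num <- match(meta$stage, c("I", "II", "III")) - 1
  if (anyNA(t_num)) t_num <- as.numeric(factor(meta$stage)) - 1
  g <- as.numeric(factor(meta$tissue)) - 1
  if (length(unique(g)) < 2 || length(unique(t_num)) < 2)
    stop("design needs >= 2 groups and >= 2 time points")
  X <- cbind(1, t_num, t_num^2, g, g * t_num, g * t_num^2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design: aliased term in column ",
         paste(colnames(X)[qrX$rank + 1], collapse = ","))
  Y <- t(log2(expr + 1))          # samples x features
  fit <- qr.fitted(qrX, Y)
  rss <- colSums((Y - fit)^2)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  df1 <- ncol(X) - 1
  df2 <- nrow(X) - ncol(X)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  F_stat <- ((tss - rss) / df1) / (rss / df2)
  p <- pf(F_stat, df1, df2, lower.tail = FALSE)
  # a perfect fit (rss == 0) has infinite F and p = 0
  p[rss <= .Machine$double.eps * tss] <- 0
  p[tss == 0] <- 1                 # constant feature: nothing to explain
  padj <- p.adjust(p, method = "BH")
  data.frame(feature_id = rownames(expr) %||% seq_len(nrow(expr)),
             F_stat = F_stat, p = p, p_adjusted = padj, R_squared = r2,
             selected = padj <= alpha & r2 >= r2_min,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster expression profiles with silhouette-selected k
#'
#' Rows are standardized (mean 0, sd 1), distances are correlation
#' distances `1 - r`, the tree is average-linkage, and `k` is chosen to
#' maximize the mean silhouette width over `k_range`.
#'
#' @param expr Features x samples matrix (selected features).
#' @param k_range Candidate cluster counts.
#' @return List of class `"cluster_assignment"`: `cluster` (named
#'   vector), `k`, `silhouette` (mean width per scanned k), `degenerate`
#'   (`TRUE` when profiles are too uniform to cluster).
#' @export
cluster_profiles <- function(expr, k_range = 2:15) {
  sds <- apply(expr, 1, sd)
  if (all(sds == 0)) {
    return(structure(list(cluster = setNames(rep(1L, nrow(expr)),
                                             rownames(expr)),
                          k = 1L, silhouette = NA_real_, degenerate = TRUE),
                     class = "cluster_assignment"))
  }
  z <- t(scale(t(expr)))
  z[sds == 0, ] <- 0
  d <- as.dist(1 - cor(t(z)))
  d[is.na(d)] <- 2   # uncorrelatable pairs: maximal correlation distance
  tree <- hclust(d, method = "average")
  k_range <- k_range[k_range < nrow(expr)]
  sil <- vapply(k_range, function(k) {
    cl <- cutree(tree, k = k)
    if (length(unique(cl)) < 2) return(NA_real_)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, 0)
  best <- k_range[which.max(sil)]
  structure(list(cluster = cutree(tree, k = best), k = best,
                 silhouette = setNames(sil, k_range), degenerate = FALSE,
                 tree = tree),
            class = "cluster_assignment")
}

#' Link selected intergenic TEs to their nearest differentially
#' expressed gene
#'
#' For each selected TE, finds the nearest DEG on the same chromosome at
#' distance greater than `min_distance` and reports the Pearson
#' correlation of `log2(TPM + 1)` profiles across all samples.
#'
#' @param te_ids Selected TE ids (must be rows of `expr`).
#' @param deg_ids Differentially expressed gene ids (rows of
#'   `gene_expr`).
#' @param tes TE copy table covering `te_ids`.
#' @param genes Gene model table covering `deg_ids`.
#' @param expr TE expression matrix (TPM).
#' @param gene_expr Gene expression matrix (TPM), same columns as `expr`.
#' @param min_distance Minimum TE-gene distance in bp (default 5 kb).
#' @return Data frame: `te_id`, `gene_id`, `annotation_label`,
#'   `distance_bp`, `pearson_r`.
#' @export
te_gene_links <- function(te_ids, deg_ids, tes, genes, expr, gene_expr,
                          min_distance = 5000) {
  stopifnot(identical(colnames(expr), colnames(gene_expr)))
  degs <- genes[genes$gene_id %in% deg_ids, , drop = FALSE]
  rows <- lapply(te_ids, function(id) {
    te <- tes[tes$copy_id == id, ]
    if (!nrow(te)) return(NULL)
    g <- degs[degs$chrom == te$chrom, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    d <- pmax(0, pmax(g$tx_start - te$end, te$start - g$tx_end))
    g <- g[d > min_distance, , drop = FALSE]
    d <- d[d > min_distance]
    if (!nrow(g)) return(NULL)
    j <- which.min(d)
    r <- cor(log2(expr[id, ] + 1), log2(gene_expr[g$gene_id[j], ] + 1))
    data.frame(te_id = id, gene_id = g$gene_id[j],
               annotation_label = g$annotation_label[j],
               distance_bp = d[j], pearson_r = r,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(te_id = character(), gene_id = character(),
                      annotation_label = character(),
                      distance_bp = numeric(), pearson_r = numeric(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
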