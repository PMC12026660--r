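# Majority-rule consensus, Kimura two-parameter divergence, insertion-age
# dating, divergence landscapes and the putatively-active classifier.

#' Age model parameters for divergence dating
#'
#' @param mu Substitution rate per site per year (default: the average
#'   mammalian genome rate, 2.2e-9).
#' @param active_age_cutoff_My Age below which a copy counts as young.
#' @param active_min_copies Copy-number threshold (strictly exceeded) for
#'   a subfamily to be called putatively active.
#' @return List of class `"age_model"`.
#' @export
age_model <- function(mu = 2.2e-9, active_age_cutoff_My = 15,
                      active_min_copies = 10) {
  stopifnot(mu > 0)
  structure(list(mu = mu, active_age_cutoff_My = active_age_cutoff_My,
                 active_min_copies = active_min_copies),
            class = "age_model")
}

#' Majority-rule column consensus of aligned copies
#'
#' Per alignment column, the most frequent non-gap base wins; columns
#' whose gap fraction exceeds 0.5 are dropped; ties break by fixed base
#' order A < C < G < T.
#'
#' @param aligned Character vector of >= 2 equal-length aligned sequences
#'   over `A/C/G/T/-/N`.
#' @return Consensus sequence as a character string.
#' @export
majority_consensus <- function(aligned) {
  stopifnot(length(aligned) >= 2)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1) stop("aligned sequences must share length")
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  keep_base <- c("A", "C", "G", "T")
  cols <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (mean(col == "-") > 0.5) return(NA_character_)
    counts <- table(factor(col[col %in% keep_base], levels = keep_base))
    if (sum(counts) == 0) return(NA_character_)
    keep_base[which.max(counts)]  # which.max takes first tie: A<C<G<T order
  }, "")
  paste(cols[!is.na(cols)], collapse = "")
}

#' Kimura two-parameter divergence of an aligned pair
#'
#' Over comparable columns (both bases in `A/C/G/T`), the transition
#' fraction `P` and transversion fraction `Q` give
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`. When `1 - 2P - Q <= 0`
#' or `1 - 2Q <= 0` the distance is saturated and `K` is `NA` with
#' `saturated = TRUE`. Optionally, alignment columns where the consensus
#' has a CpG dinucleotide (both positions) are excluded before counting.
#'
#' @param copy_seq,cons_seq Equal-length aligned sequences
#'   (copy and consensus) over `A/C/G/T/-/N`.
#' @param exclude_cpg Drop both positions of every consensus CpG.
#' @return List with `P`, `Q`, `K`, `n_sites`, `saturated`.
#' @export
k2p <- function(copy_seq, cons_seq, exclude_cpg = FALSE) {
  a <- strsplit(toupper(copy_seq), "")[[1]]
  b <- strsplit(toupper(cons_seq), "")[[1]]
  if (length(a) != length(b)) stop("aligned pair must share length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (exclude_cpg) {
    cpg <- which(b[-length(b)] == "C" & b[-1] == "G")
    if (length(cpg)) ok[c(cpg, cpg + 1L)] <- FALSE
  }
  n <- sum(ok)
  if (n == 0) stop("no comparable columns")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(P = P, Q = Q, K = NA_real_, n_sites = n, saturated = TRUE))
  }
  K <- -0.5 * log(w1 * sqrt(w2))
  list(P = P, Q = Q, K = K, n_sites = n, saturated = FALSE)
}

#' Convert divergence to insertion age
#'
#' `T = K / mu` years: the consensus is treated as the ancestral active
#' element, and divergence accrues along the copy's lineage.
#'
#' @param K Substitutions per site (scalar or vector).
#' @param model An [age_model()].
#' @return Age in years.
#' @export
age_from_divergence <- function(K, model = age_model()) {
  K / model$mu
}

#' Divergence landscape: genome bp per family per divergence bin
#'
#' Element lengths are summed into half-open percent-divergence bins
#' `[0,5), [5,10), ...`. Saturated or missing divergences are excluded
#' and their total bp reported separately.
#'
#' @param tes TE copy table with a `K` column (substitutions/site) or
#'   `divergence_pct` (percent; used as `K*100` when `K` is absent).
#' @param bin_width_pct Bin width in percent divergence.
#' @param max_pct Upper edge of the last bin.
#' @return List with `bins` (data frame `family`, `bin_lo`, `bin_hi`,
#'   `bp`) and `excluded_bp` (bp with saturated/missing divergence).
#' @export
divergence_landscape <- function(tes, bin_width_pct = 5, max_pct = 100) {
  pct <- if (!is.null(tes$K)) tes$K * 100 else tes$divergence_pct
  len <- tes$end - tes$start
  ok <- !is.na(pct)
  edges <- seq(0, max_pct, by = bin_width_pct)
  fams <- sort(unique(tes$family))
  grid <- expand.grid(family = fams, bin_lo = edges[-length(edges)],
                      stringsAsFactors = FALSE)
  grid$bin_hi <- grid$bin_lo + bin_width_pct
  grid$bp <- rep(0, nrow(grid))
  if (any(ok)) {
    bin_i <- findInterval(pct[ok], edges, rightmost.closed = FALSE)
    bin_i[bin_i > length(edges) - 1] <- length(edges) - 1
    key <- paste(tes$family[ok], edges[bin_i])
    agg <- tapply(len[ok], key, sum)
    gkey <- paste(grid$family, grid$bin_lo)
    grid$bp[match(names(agg), gkey)] <- as.numeric(agg)
  }
  list(bins = grid, excluded_bp = sum(len[!ok]))
}

#' Classify a subfamily as putatively active
#'
#' Active iff its youngest copy is younger than the cutoff (default
#' 15 My) and the subfamily has strictly more than `active_min_copies`
#' copies (default > 10).
#'
#' @param min_age_My Youngest copy age in the subfamily (My).
#' @param n_copies Number of copies in the subfamily.
#' @param model An [age_model()].
#' @return Logical.
#' @export
classify_putatively_active <- function(min_age_My, n_copies,
                                       model = age_model()) {
  (min_age_My < model$active_age_cutoff_My) &
    (n_copies > model$active_min_copies)
}
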