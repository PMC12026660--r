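# Shared fixtures and independent oracles, all built in code.

rm_out_fixture <- function(records = NULL) {
  header <- c(
    "   SW  perc perc perc  query     position in query           matching  repeat         position in repeat",
    "score  div. del. ins.  sequence  begin  end      (left)  repeat    class/family   begin  end    (left)   ID",
    "")
  if (is.null(records)) records <- c(
    "  463   1.3  0.6  1.7  chr1        101    200  (9800) +  L1MC5a     LINE/L1         100   200    (10)     1",
    "  239  29.4  1.9  1.0  chr1        501    622  (9378) C  MIR3       SINE/tRNA       (0)   143     22      2")
  path <- tempfile(fileext = ".out")
  writeLines(c(header, records), path)
  path
}

gff3_fixture <- function() {
  lines <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=g1;Name=DSG4",
    "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t200\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t401\t1000\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t100\t900\t.\t+\t.\tParent=t1",
    "chr2\tsrc\tgene\t2001\t3000\t.\t-\t.\tID=g2",
    "chr2\tsrc\tmRNA\t2001\t2500\t.\t-\t.\tID=t2a;Parent=g2",
    "chr2\tsrc\tmRNA\t2001\t3000\t.\t-\t.\tID=t2b;Parent=g2",
    "chr2\tsrc\texon\t2001\t2500\t.\t-\t.\tParent=t2a",
    "chr2\tsrc\texon\t2001\t3000\t.\t-\t.\tParent=t2b",
    "chr3\tsrc\tgene\t1\t500\t.\t+\t.\tID=g3",
    "chr3\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=t3;Parent=g3",
    "chr3\tsrc\texon\t1\t500\t.\t+\t.\tParent=t3")
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

# minimal gene-model table built in code (same shape as read_gff3_genes)
make_genes <- function(gene_id, chrom, strand, tx_start, tx_end,
                       exons = NULL, cds = NULL, annotation_label = NA) {
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tx_start = tx_start, tx_end = tx_end,
                   annotation_label = annotation_label,
                   stringsAsFactors = FALSE)
  empty <- matrix(numeric(), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  span <- lapply(seq_len(nrow(df)), function(i)
    matrix(c(df$tx_start[i], df$tx_end[i]), 1,
           dimnames = list(NULL, c("start", "end"))))
  df$exons <- if (is.null(exons)) span else exons
  df$cds <- if (is.null(cds)) replicate(nrow(df), empty, simplify = FALSE)
            else cds
  class(df) <- c("gene_models", "data.frame")
  df
}

# O(n^2) brute-force block oracle: every window (i, j) of the sorted
# per-chromosome elements is checked for all-gaps-ok (via a prefix count
# of oversized gaps, so the check is exact, not a re-derivation of the
# run construction) plus maximality on both sides
brute_force_blocks <- function(tes, te_class, max_gap, min_elements) {
  sub <- tes[tes$te_class == te_class, , drop = FALSE]
  out <- NULL
  for (ch in unique(sub$chrom)) {
    d <- sub[sub$chrom == ch, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    n <- nrow(d)
    exceed <- if (n > 1) pmax(0, d$start[-1] - d$end[-n]) > max_gap
              else logical(0)
    C <- c(0, cumsum(exceed))  # C[t]: oversized gaps among the first t-1
    for (i in seq_len(n)) {
      for (j in i:n) {
        all_gaps_ok <- (C[j] - C[i]) == 0
        if (!all_gaps_ok) break
        left_open <- i == 1 || exceed[i - 1]
        right_open <- j == n || exceed[j]
        if (left_open && right_open && (j - i + 1) >= min_elements) {
          out <- rbind(out, data.frame(chrom = ch,
                                       start = min(d$start[i:j]),
                                       end = max(d$end[i:j]),
                                       n_elements = j - i + 1))
        }
      }
    }
  }
  if (is.null(out)) data.frame(chrom = character(), start = numeric(),
                               end = numeric(), n_elements = integer())
  else out[order(out$chrom, out$start), , drop = FALSE]
}

random_te_instance <- function(n, seed, chrom = "chr1") {
  set.seed(seed)
  start <- sort(sample.int(50000, n))
  len <- sample(50:1500, n, replace = TRUE)
  te_copies(paste0("e", seq_len(n)), chrom, start, start + len,
            te_class = "SINE")
}

rand_string <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exact hypergeometric upper tail by combinatorial enumeration
hyper_tail_exact <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
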