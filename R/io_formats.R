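# Readers and writers for the external formats the pipeline consumes.
# Everything is converted to 0-based half-open coordinates on the way in.

#' Read a RepeatMasker .out annotation table
#'
#' Parses the standard 15-column RepeatMasker `.out` layout (3 header
#' lines). The 1-based inclusive query coordinates are converted to
#' 0-based half-open; the `class/family` column is split into a
#' coarse class (`LINE`, `SINE`, anything else -> `other`) and the family
#' below the slash; the per-copy substitution percentage is kept as
#' `divergence_pct`. Strand `C` (complement) is mapped to `-`.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A TE copy table (see [te_copies()]).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated .out file: expected 3 header lines")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    return(te_copies(character(), character(), numeric(), numeric())[0, ])
  }
  fields <- strsplit(trimws(body), "[ \t]+")
  n <- lengths(fields)
  bad <- which(n < 14)
  if (length(bad))
    stop(sprintf("malformed .out record at line %d: %d columns",
                 bad[1] + 3L, n[bad[1]]))
  f <- function(i) vapply(fields, `[[`, "", i)
  cls <- f(11)
  split_cf <- strsplit(cls, "/", fixed = TRUE)
  major <- toupper(vapply(split_cf, `[[`, "", 1))
  te_class <- ifelse(grepl("^LINE", major), "LINE",
              ifelse(grepl("^SINE", major), "SINE", "other"))
  family <- vapply(split_cf, function(x) if (length(x) > 1) x[2] else x[1], "")
  strand <- ifelse(f(9) == "C", "-", f(9))
  start1 <- as.numeric(f(6))
  end1 <- as.numeric(f(7))
  tes <- te_copies(
    copy_id = sprintf("%s_%d", te_class, seq_along(body)),
    chrom = f(5), start = start1 - 1, end = end1,
    strand = strand, te_class = te_class, family = family,
    consensus_id = f(10), divergence_pct = as.numeric(f(2)))
  tes
}

#' Read gene models from a GFF3 file
#'
#' Extracts one model per gene; when a gene has several mRNAs the longest
#' transcript wins. GFF3 1-based inclusive coordinates are converted to
#' 0-based half-open. Orphan exons (no resolvable parent) are skipped with
#' a warning.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @return A gene model table: columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `annotation_label`, plus list-columns `exons`
#'   and `cds` holding two-column (start, end) matrices.
#' @export
read_gff3_genes <- function(path) {
  raw <- read.table(path, sep = "\t", comment.char = "#", quote = "",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attr"))
  get_tag <- function(attr, tag) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)", tag, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  raw$ID <- get_tag(raw$attr, "ID")
  raw$Parent <- get_tag(raw$attr, "Parent")
  genes <- raw[raw$type == "gene", ]
  mrnas <- raw[raw$type == "mRNA", ]
  exons <- raw[raw$type == "exon", ]
  cdss <- raw[raw$type == "CDS", ]
  # resolve exon/CDS parents up to the gene: parent may be an mRNA or a gene
  tx2gene <- setNames(mrnas$Parent, mrnas$ID)
  resolve <- function(parent) {
    out <- ifelse(parent %in% genes$ID, parent, unname(tx2gene[parent]))
    out
  }
  exons$gene <- resolve(exons$Parent)
  cdss$gene <- resolve(cdss$Parent)
  orphan <- is.na(exons$gene)
  if (any(orphan)) {
    warning(sum(orphan), " orphan exon(s) skipped")
    exons <- exons[!orphan, ]
  }
  cdss <- cdss[!is.na(cdss$gene), ]

  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- g$ID
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == gid, ]
    if (nrow(tx) > 1) {
      keep_tx <- tx$ID[which.max(tx$end - tx$start)]
      ex <- exons[exons$Parent == keep_tx, ]
      cd <- cdss[cdss$Parent == keep_tx, ]
    } else {
      ex <- exons[exons$gene == gid, ]
      cd <- cdss[cdss$gene == gid, ]
    }
    iv <- function(df) {
      if (!nrow(df)) return(matrix(numeric(), ncol = 2,
                                   dimnames = list(NULL, c("start", "end"))))
      m <- cbind(start = df$start - 1, end = df$end)
      m[order(m[, 1]), , drop = FALSE]
    }
    list(gene_id = gid, chrom = g$chrom, strand = g$strand,
         tx_start = g$start - 1, tx_end = g$end,
         annotation_label = get_tag(g$attr, "Name"),
         exons = iv(ex), cds = iv(cd))
  })
  df <- data.frame(
    gene_id = vapply(out, `[[`, "", "gene_id"),
    chrom = vapply(out, `[[`, "", "chrom"),
    strand = vapply(out, `[[`, "", "strand"),
    tx_start = vapply(out, `[[`, 0, "tx_start"),
    tx_end = vapply(out, `[[`, 0, "tx_end"),
    annotation_label = vapply(out, `[[`, "", "annotation_label"),
    stringsAsFactors = FALSE)
  df$exons <- lapply(out, `[[`, "exons")
  df$cds <- lapply(out, `[[`, "cds")
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Construct a contact matrix object
#'
#' @param values Symmetric non-negative numeric matrix of binned contacts.
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @return An object of class `"contact_matrix"`.
#' @export
contact_matrix <- function(values, chrom = "chr1", resolution = 100000) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (max(abs(values - t(values))) > 1e-9 * max(1, max(abs(values))))
    stop("contact matrix not symmetric within tolerance")
  if (any(values < 0)) stop("contact values must be non-negative")
  structure(list(chrom = chrom, resolution = resolution,
                 n_bins = nrow(values), values = values),
            class = "contact_matrix")
}

#' Read a binned contact matrix from text
#'
#' Two dialects are supported: `"dense"` (a whitespace-separated n x n
#' table) and `"triplet"` (COO text with columns `bin_i bin_j value`,
#' 0-based bin indices, mirrored across the diagonal on read).
#'
#' @param path File path.
#' @param resolution Bin size in bp.
#' @param dialect `"dense"` or `"triplet"`.
#' @param chrom Chromosome name to attach.
#' @param chrom_length Optional chromosome length; when given, the number
#'   of bins must equal `ceiling(chrom_length / resolution)`.
#' @return A `"contact_matrix"`.
#' @export
read_contact_matrix <- function(path, resolution, dialect = c("dense", "triplet"),
                                chrom = "chr1", chrom_length = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "dense") {
    m <- as.matrix(read.table(path))
    dimnames(m) <- NULL
  } else {
    tr <- read.table(path, col.names = c("i", "j", "value"))
    n <- max(tr$i, tr$j) + 1L
    if (!is.null(chrom_length)) n <- max(n, ceiling(chrom_length / resolution))
    m <- matrix(0, n, n)
    m[cbind(tr$i + 1L, tr$j + 1L)] <- tr$value
    m[cbind(tr$j + 1L, tr$i + 1L)] <- tr$value
  }
  if (!is.null(chrom_length)) {
    n_req <- ceiling(chrom_length / resolution)
    if (nrow(m) != n_req)
      stop(sprintf("expected %d bins for a %d bp chromosome at %d bp resolution, got %d",
                   n_req, chrom_length, resolution, nrow(m)))
  }
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

#' Write a contact matrix as triplet text
#'
#' Upper triangle (including diagonal) only; mirrored on re-read.
#'
#' @param m A `"contact_matrix"`.
#' @param path Output path.
#' @export
write_contact_matrix <- function(m, path) {
  idx <- which(upper.tri(m$values, diag = TRUE) & m$values != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   value = m$values[idx])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-CpG methylation table
#'
#' Four whitespace-separated columns: chrom, 0-based position, read
#' coverage, methylated-read fraction in `[0, 1]`.
#'
#' @param path File path.
#' @return A `data.frame` with columns `chrom`, `pos`, `coverage`,
#'   `methyl_fraction`.
#' @export
read_methylation_table <- function(path) {
  df <- read.table(path, col.names = c("chrom", "pos", "coverage",
                                       "methyl_fraction"),
                   stringsAsFactors = FALSE)
  if (any(df$methyl_fraction < 0 | df$methyl_fraction > 1))
    stop("methyl_fraction outside [0, 1]")
  if (any(df$coverage < 0)) stop("coverage must be >= 0")
  df
}

#' Write a methylation table
#' @param sites Methylation site table.
#' @param path Output path.
#' @export
write_methylation_table <- function(sites, path) {
  write.table(sites[, c("chrom", "pos", "coverage", "methyl_fraction")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file
#' @param path File path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to FASTA
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates pass through untouched.
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `copy_id`/`name` and `strand`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  name <- if (!is.null(intervals$copy_id)) intervals$copy_id
          else if (!is.null(intervals$name)) intervals$name
          else "."
  df <- data.frame(intervals$chrom, format(intervals$start, scientific = FALSE,
                                           trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   name)
  if (!is.null(intervals$strand))
    df <- cbind(df, score = 0, strand = intervals$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path File path.
#' @return Data frame with `chrom`, `start`, `end` and, when present,
#'   `name` and `strand`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  df
}
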