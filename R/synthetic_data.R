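# Synthetic-data generators with known ground truth. Each generator
# emulates one input class of the pipeline: genome sequence with a GC
# landscape, TE copies of known age and placement bias, plaid + TAD
# contact matrices, age-dependent CpG methylation, and negative-binomial
# tissue-by-stage count matrices.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a genome with a prescribed GC landscape
#'
#' Bases are drawn i.i.d. within each window so that the expected window
#' GC equals the target; realised window GC differs from the target only
#' by binomial sampling error.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param gc_profile Either a single target GC fraction in (0,1) applied
#'   everywhere, or a named list with one numeric vector per chromosome
#'   (recycled over windows).
#' @param window Window size in bp over which targets apply.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return A list with `sequences` (a `DNAStringSet`) and `index`
#'   (a genome index, see [genome_index()]).
#' @export
simulate_genome <- function(chrom_lengths, gc_profile = 0.42,
                            window = 10000, seed = 1) {
  with_seed(seed, {
    if (is.null(names(chrom_lengths)))
      names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
    seqs <- lapply(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      n_win <- ceiling(len / window)
      targets <- if (is.list(gc_profile)) gc_profile[[ch]] else gc_profile
      targets <- rep_len(targets, n_win)
      if (any(targets <= 0 | targets >= 1))
        stop("target GC must lie strictly in (0, 1)")
      win_len <- diff(c(seq(0, len - 1, by = window), len))
      gc_site <- rep(targets, win_len)
      is_gc <- runif(len) < gc_site
      base <- character(len)
      base[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
      base[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
      paste(base, collapse = "")
    })
    sequences <- Biostrings::DNAStringSet(setNames(unlist(seqs),
                                                   names(chrom_lengths)))
    list(sequences = sequences,
         index = genome_index(names(chrom_lengths),
                              unname(chrom_lengths)))
  })
}

#' Generate a random consensus sequence with a target GC content
#'
#' TE families have characteristic base composition (LINEs are AT-rich,
#' SINEs closer to or above the genome average), and planted copies carry
#' their consensus composition into the regions they occupy; generating
#' the consensus at the family's GC keeps that effect in the simulation.
#'
#' @param length Sequence length in bp.
#' @param gc Target GC fraction.
#' @param seed Integer seed or `NULL`.
#' @return Character string over A/C/G/T.
#' @export
random_consensus <- function(length, gc = 0.42, seed = NULL) {
  with_seed(seed, {
    is_gc <- runif(length) < gc
    base <- character(length)
    base[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
    base[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
    paste(base, collapse = "")
  })
}

.transition <- c(A = "G", G = "A", C = "T", T = "C")
.transversions <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Mutate a consensus sequence under a Kimura-style substitution process
#'
#' Each site receives a Poisson(`target_K`) number of substitution events;
#' each event is a transition with probability `kappa / (kappa + 2)` and
#' each of the two transversions with probability `1 / (kappa + 2)`.
#' Multiple hits at a site are allowed, so the Kimura two-parameter
#' estimator's multiple-hit correction is genuinely exercised: the
#' expected K2P estimate of the output against the consensus is
#' approximately `target_K`.
#'
#' @param consensus Character string over A/C/G/T.
#' @param target_K Expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param seed Integer seed or `NULL`.
#' @return Mutated copy as a character string.
#' @export
mutate_consensus <- function(consensus, target_K, kappa = 2, seed = NULL) {
  stopifnot(target_K >= 0, kappa >= 0)
  with_seed(seed, {
    bases <- strsplit(toupper(consensus), "")[[1]]
    if (!all(bases %in% c("A", "C", "G", "T")))
      stop("consensus must be over A/C/G/T")
    n_events <- rpois(length(bases), target_K)
    p_ts <- kappa / (kappa + 2)
    for (i in which(n_events > 0)) {
      b <- bases[i]
      for (k in seq_len(n_events[i])) {
        b <- if (runif(1) < p_ts) .transition[[b]]
             else sample(.transversions[[b]], 1)
      }
      bases[i] <- b
    }
    paste(bases, collapse = "")
  })
}

#' Plant TE families of known age into a simulated genome
#'
#' Copies of each family consensus are mutated to
#' `target_K = age_My * 1e6 * mu` and written into the genome at
#' non-overlapping positions. Placement is GC-biased through a softmax
#' over window GC: window weight is proportional to
#' `exp(gc_bias_sign * beta * standardized window GC)`, so `+1` prefers
#' GC-rich windows and `-1` AT-rich ones. Planted copies overwrite the
#' underlying sequence, keeping all coordinates stable.
#'
#' @param genome A list as returned by [simulate_genome()].
#' @param family_specs List of specs, each a list with `name`, `consensus`
#'   (character), `n_copies`, `age_My`, `gc_bias_sign` (+1/-1/0),
#'   `te_class` (`"LINE"`/`"SINE"`), and optionally `kappa` (default 2).
#' @param mu Substitution rate per site per year.
#' @param window Window size used for the GC placement bias.
#' @param beta Softmax inverse temperature of the placement bias.
#' @param seed Integer seed.
#' @return A list with `genome` (modified, same shape as input) and
#'   `tes` — a ground-truth TE copy table with extra columns `age_My` and
#'   `target_K`.
#' @export
plant_te_landscape <- function(genome, family_specs, mu = 2.2e-9,
                               window = 10000, beta = 3, seed = 1) {
  with_seed(seed, {
    seqs <- genome$sequences
    used <- lapply(names(seqs), function(ch) IRanges::IRanges())
    names(used) <- names(seqs)
    rows <- list()
    copy_counter <- 0L
    for (spec in family_specs) {
      if (spec$n_copies == 0) next
      kappa <- if (is.null(spec$kappa)) 2 else spec$kappa
      target_K <- spec$age_My * 1e6 * mu
      cons_len <- nchar(spec$consensus)
      # window GC weights per chromosome, concatenated
      win_tab <- do.call(rbind, lapply(names(seqs), function(ch) {
        len <- length(seqs[[ch]])
        starts <- seq(0, len - 1, by = window)
        ends <- pmin(starts + window, len)
        keep <- (ends - starts) >= cons_len + 2
        data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                   stringsAsFactors = FALSE)
      }))
      if (!nrow(win_tab)) stop("genome too small for requested copies")
      gc <- vapply(seq_len(nrow(win_tab)), function(i) {
        v <- Biostrings::subseq(seqs[[win_tab$chrom[i]]],
                                win_tab$start[i] + 1, win_tab$end[i])
        sum(Biostrings::letterFrequency(v, c("G", "C"))) / length(v)
      }, 0)
      z <- if (sd(gc) > 0) (gc - mean(gc)) / sd(gc) else rep(0, length(gc))
      w <- exp(spec$gc_bias_sign * beta * z)
      w <- w / sum(w)
      placed <- 0L
      attempts <- 0L
      while (placed < spec$n_copies) {
        attempts <- attempts + 1L
        if (attempts > 50L * spec$n_copies)
          stop("genome too small for requested copies")
        wi <- sample.int(nrow(win_tab), 1, prob = w)
        ch <- win_tab$chrom[wi]
        lo <- win_tab$start[wi]
        hi <- win_tab$end[wi] - cons_len
        if (hi <= lo) next
        s0 <- lo + sample.int(hi - lo, 1) - 1L  # 0-based start
        cand <- IRanges::IRanges(s0 + 1, s0 + cons_len)
        if (length(IRanges::findOverlaps(cand, used[[ch]]))) next
        used[[ch]] <- c(used[[ch]], cand)
        copy <- mutate_consensus(spec$consensus, target_K, kappa)
        Biostrings::subseq(seqs[[ch]], s0 + 1, s0 + cons_len) <-
          Biostrings::DNAString(copy)
        copy_counter <- copy_counter + 1L
        placed <- placed + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          copy_id = sprintf("%s_%06d", spec$name, copy_counter),
          chrom = ch, start = s0, end = s0 + cons_len,
          strand = "+", te_class = spec$te_class, family = spec$name,
          consensus_id = spec$name, divergence_pct = NA_real_,
          age_My = spec$age_My, target_K = target_K,
          stringsAsFactors = FALSE)
      }
    }
    tes <- if (length(rows)) do.call(rbind, rows)
           else te_copies(character(), character(), numeric(), numeric())[0, ]
    validate_te_copies(tes, genome$index)
    class(tes) <- c("te_copies", "data.frame")
    list(genome = list(sequences = seqs, index = genome$index), tes = tes)
  })
}

#' Simulate a plaid compartment + block-TAD contact matrix
#'
#' Expected contacts follow a power-law distance decay modulated by a
#' plaid checkerboard and a within-TAD boost:
#' `mean_scale * (1+|i-j|)^(-gamma) * (1 + rho * a_i * a_j) *
#'  tad_boost^(same TAD)`, optionally Poisson-sampled and symmetrised.
#'
#' @param n_bins Number of bins.
#' @param compartments Vector of +1/-1 compartment signs per bin
#'   (default: two equal halves).
#' @param rho Plaid strength in `[0, 1)`.
#' @param gamma Distance-decay exponent (> 0).
#' @param tad_boundaries Bin indices (1-based, interior) where a new TAD
#'   starts; empty for no TADs.
#' @param tad_boost Within-TAD contact multiplier (>= 1).
#' @param mean_scale Expected contact at distance 0 before modulation.
#' @param poisson_noise Sample Poisson counts (`TRUE`) or return the
#'   noiseless expectation (`FALSE`).
#' @param resolution,chrom Metadata attached to the result.
#' @param seed Integer seed.
#' @return A `"contact_matrix"` with attribute `"compartments"` carrying
#'   the planted signs and `"tad_boundaries"` the planted boundaries.
#' @export
simulate_contact_matrix <- function(n_bins = 200,
                                    compartments = NULL,
                                    rho = 0.2, gamma = 1,
                                    tad_boundaries = integer(),
                                    tad_boost = 1,
                                    mean_scale = 100,
                                    poisson_noise = TRUE,
                                    resolution = 100000, chrom = "chr1",
                                    seed = 1) {
  if (rho >= 1 || rho < 0) stop("rho must lie in [0, 1)")
  stopifnot(gamma > 0, tad_boost >= 1)
  if (is.null(compartments))
    compartments <- rep(c(1, -1), each = ceiling(n_bins / 2))[1:n_bins]
  stopifnot(length(compartments) == n_bins,
            all(compartments %in% c(-1, 1)))
  if (length(tad_boundaries) &&
      (is.unsorted(tad_boundaries) ||
       any(tad_boundaries <= 1 | tad_boundaries > n_bins)))
    stop("tad_boundaries must be sorted interior bin indices")
  with_seed(seed, {
    d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
    expected <- mean_scale * (1 + d)^(-gamma) *
      (1 + rho * outer(compartments, compartments))
    if (length(tad_boundaries)) {
      tad_id <- findInterval(seq_len(n_bins), c(1, tad_boundaries))
      same <- outer(tad_id, tad_id, "==")
      expected <- expected * tad_boost^same
    }
    if (poisson_noise) {
      up <- upper.tri(expected, diag = TRUE)
      vals <- matrix(0, n_bins, n_bins)
      vals[up] <- rpois(sum(up), expected[up])
      vals <- vals + t(vals) - diag(diag(vals))
    } else {
      vals <- expected
    }
    m <- contact_matrix(vals, chrom = chrom, resolution = resolution)
    attr(m, "compartments") <- compartments
    attr(m, "tad_boundaries") <- tad_boundaries
    m
  })
}

#' Simulate CpG methylation with an age-dependent TE signal
#'
#' CpG sites inside TEs get methylated fraction
#' `clamp(base_level - age_slope * age_My + N(0, noise_sd), 0, 1)`;
#' background sites are drawn from a two-component mixture to mimic the
#' bimodal genome-wide methylation distribution.
#'
#' @param tes Ground-truth TE table with an `age_My` column.
#' @param genome_index Genome index for background site placement.
#' @param sites_per_kb Expected CpG sites per kb of TE sequence.
#' @param base_level Methylation level of an age-0 TE.
#' @param age_slope Decrease in methylated fraction per My of age.
#' @param noise_sd Gaussian noise on the TE fractions.
#' @param n_background Number of background (non-TE) CpG sites.
#' @param bg_means,bg_weights Means and weights of the background mixture.
#' @param bg_sd Component standard deviation of the background mixture.
#' @param mean_coverage Mean read coverage (Poisson, floored at 1).
#' @param seed Integer seed.
#' @return A methylation site table (`chrom`, `pos`, `coverage`,
#'   `methyl_fraction`).
#' @export
simulate_methylation <- function(tes, genome_index,
                                 sites_per_kb = 10,
                                 base_level = 0.85, age_slope = 0.01,
                                 noise_sd = 0.05,
                                 n_background = 1000,
                                 bg_means = c(0.1, 0.9),
                                 bg_weights = c(0.5, 0.5),
                                 bg_sd = 0.05,
                                 mean_coverage = 20, seed = 1) {
  with_seed(seed, {
    clamp <- function(x) pmin(1, pmax(0, x))
    te_rows <- lapply(seq_len(nrow(tes)), function(i) {
      len <- tes$end[i] - tes$start[i]
      n <- rpois(1, sites_per_kb * len / 1000)
      if (n == 0) return(NULL)
      pos <- tes$start[i] + sort(sample.int(len, min(n, len)) - 1L)
      frac <- clamp(base_level - age_slope * tes$age_My[i] +
                      rnorm(length(pos), 0, noise_sd))
      data.frame(chrom = tes$chrom[i], pos = pos,
                 coverage = pmax(1, rpois(length(pos), mean_coverage)),
                 methyl_fraction = frac, stringsAsFactors = FALSE)
    })
    bg_rows <- NULL
    if (n_background > 0) {
      ch_idx <- sample.int(nrow(genome_index), n_background, replace = TRUE,
                           prob = genome_index$length)
      comp <- sample.int(length(bg_means), n_background, replace = TRUE,
                         prob = bg_weights)
      bg_rows <- data.frame(
        chrom = genome_index$chrom[ch_idx],
        pos = floor(runif(n_background) * genome_index$length[ch_idx]),
        coverage = pmax(1, rpois(n_background, mean_coverage)),
        methyl_fraction = clamp(rnorm(n_background, bg_means[comp], bg_sd)),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(te_rows, list(bg_rows)))
    out <- out[order(out$chrom, out$pos), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a tissue-by-stage negative-binomial count matrix
#'
#' The design is tissue (dorsal/abdominal) x stage (I/II/III) x replicate.
#' Null features have a flat expected expression. Planted features follow
#' a degree-2 stage polynomial shared by both tissues (a developmental
#' trend of log2 amplitude `stage_amp`, with a shape drawn per feature
#' from rising / falling / mid-peak) plus a tissue-by-stage interaction:
#' a log2 effect applied in the dorsal tissue with stage weights
#' `effect_profile` (default: stage I only) — exactly the structure the
#' degree-2 polynomial time-course model is built to detect.
#'
#' @param n_features Total number of features.
#' @param n_planted Number of features carrying the planted effect
#'   (the first `n_planted` feature indices).
#' @param effect_log2 Planted tissue-interaction log2 fold change
#'   (2-fold = 1).
#' @param effect_profile Stage weights of the planted tissue effect,
#'   length 3.
#' @param stage_amp Log2 amplitude of the planted stage trend (shared by
#'   both tissues).
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param n_reps Replicates per tissue/stage cell.
#' @param lib_size Target library scale.
#' @param seed Integer seed.
#' @return A list of class `"count_matrix"` with `counts` (features x
#'   samples), `feature_lengths`, `sample_meta` (tissue, stage, replicate)
#'   and `planted` (feature ids carrying the effect).
#' @export
simulate_counts <- function(n_features = 2100, n_planted = 100,
                            effect_log2 = 1,
                            effect_profile = c(1, 0, 0),
                            stage_amp = 2,
                            nb_dispersion = 0.1, n_reps = 3,
                            lib_size = 5e6, seed = 1) {
  stopifnot(n_planted <= n_features, length(effect_profile) == 3)
  with_seed(seed, {
    meta <- expand.grid(replicate = seq_len(n_reps),
                        stage = c("I", "II", "III"),
                        tissue = c("dorsal", "abdominal"),
                        stringsAsFactors = FALSE)[, c("tissue", "stage",
                                                      "replicate")]
    meta$sample_id <- sprintf("%s_%s_r%d", meta$tissue, meta$stage,
                              meta$replicate)
    n_samples <- nrow(meta)
    base_log2 <- runif(n_features, 3, 9)
    stage_num <- match(meta$stage, c("I", "II", "III"))
    is_dorsal <- as.numeric(meta$tissue == "dorsal")
    log2_mu <- matrix(base_log2, n_features, n_samples)
    if (n_planted > 0) {
      # degree-2 stage trends, normalized to log2 amplitude stage_amp
      shapes <- rbind(rising = c(0, 0.5, 1), falling = c(1, 0.5, 0),
                      peak = c(0, 1, 0))
      shape_i <- sample.int(nrow(shapes), n_planted, replace = TRUE)
      trend <- stage_amp * shapes[shape_i, , drop = FALSE]
      eff <- trend[, stage_num, drop = FALSE] +
        outer(rep(effect_log2, n_planted),
              is_dorsal * effect_profile[stage_num])
      log2_mu[seq_len(n_planted), ] <- log2_mu[seq_len(n_planted), ] + eff
    }
    mu <- 2^log2_mu
    # scale so each column's expected total is lib_size
    mu <- sweep(mu, 2, lib_size / colSums(mu), "*")
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = if (nb_dispersion > 0) 1 / nb_dispersion
                                    else 1e8),
                     n_features, n_samples)
    feature_ids <- sprintf("TE_%05d", seq_len(n_features))
    dimnames(counts) <- list(feature_ids, meta$sample_id)
    structure(list(counts = counts,
                   feature_lengths = setNames(
                     round(runif(n_features, 200, 5000)), feature_ids),
                   sample_meta = meta,
                   planted = feature_ids[seq_len(n_planted)]),
              class = "count_matrix")
  })
}
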