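#' Configuration for the synthetic promoter-capture study generator
#'
#' Bundles and validates every tunable of the synthetic-data generator.  The
#' generator emulates the inputs of a promoter-capture proximity-ligation
#' study: a small multi-chromosome genome partitioned into fixed-size bins,
#' H3K4me3/CTCF/ATAC peak sets (CTCF peaks carry one oriented motif hit
#' each), a gene annotation whose TSSs fall inside H3K4me3 peaks, chromatin
#' state segmentations, distance-decaying zero-truncated Poisson contact
#' counts with covariate biases and planted enriched bin pairs, pairs-style
#' read tables with known QC composition, and a multi-sample H3K27ac /
#' expression panel with planted monotone enhancer-gene links.
#'
#' @param n_chroms number of chromosomes (`chr1`, `chr2`, ...).
#' @param chrom_length length of every chromosome in bp; must be a multiple
#'   of `bin_size` and at least 2 Mb (twice the maximum interaction distance,
#'   so the full 20 kb-1 Mb range fits).
#' @param bin_size genomic bin width in bp (default 10,000, the working
#'   resolution of the pipeline).
#' @param n_promoter_bins number of bins that receive an H3K4me3 peak (and a
#'   gene TSS inside that peak).
#' @param peak_width_range bp interval for simulated peak widths.
#' @param depth expected total read-pair count per sample; contact
#'   expectations are thinned to this total before truncation.
#' @param distance_decay_exponent power-law decay exponent `alpha`: the
#'   expected contact rate scales as `distance^-alpha`.
#' @param covariate_effect_sizes named vector of log-linear effects for the
#'   pair covariates (effective fragment size `eff`, GC content `gc`,
#'   mappability `mapp`, ChIP enrichment `chip`).
#' @param planted_fraction fraction of candidate bin pairs whose expected
#'   count is multiplied by `planted_fold` (the planted true interactions).
#' @param planted_fold fold enrichment of planted pairs; must be `>= 1`.
#' @param n_samples number of samples in the H3K27ac/expression panel
#'   (default 22, matching the cross-sample correlation design).
#' @param link_noise_sd standard deviation of the Gaussian noise on the
#'   latent (log) scale linking gene expression to enhancer activity;
#'   0 gives perfectly monotone planted links (Spearman rho = 1), the
#'   default 0.72 gives a population Spearman rho of about 0.8 under the
#'   bivariate-normal rank correlation identity
#'   \eqn{\rho_S = (6/\pi)\,\mathrm{asin}(r/2)} with
#'   \eqn{r = 1/\sqrt{1+\sigma^2}}.
#' @param n_planted_links number of enhancer-gene links planted in the panel.
#' @param n_ctcf_peaks,n_atac_peaks sizes of the CTCF and accessible-
#'   chromatin peak sets.
#' @param n_states number of chromatin states in the segmentation.
#' @param enhancer_state label of the state treated as "distal enhancer".
#' @param enhancer_state_bias probability that a segment inside a planted
#'   non-promoter anchor bin is assigned the enhancer state (0 = unbiased).
#' @param min_dist,max_dist 1D genomic distance range of candidate bin
#'   pairs in bp.
#' @param seed integer seed; identical configuration and seed give
#'   bit-identical outputs.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 1e7, bin_size = 10000,
                       n_promoter_bins = 150, peak_width_range = c(500, 2000),
                       depth = 2e5, distance_decay_exponent = 1,
                       covariate_effect_sizes = c(eff = 0.5, gc = 0.3,
                                                  mapp = 0.4, chip = 0.8),
                       planted_fraction = 0.01, planted_fold = 4,
                       n_samples = 22, link_noise_sd = 0.72,
                       n_planted_links = 50,
                       n_ctcf_peaks = 400, n_atac_peaks = 600,
                       n_states = 15, enhancer_state = "St7",
                       enhancer_state_bias = 0,
                       min_dist = 20000, max_dist = 1e6, seed = 1) {
  cfg <- as.list(environment())
  if (chrom_length %% bin_size != 0)
    stop("bin_size must divide chrom_length")
  if (chrom_length < 2 * max_dist)
    stop("chrom_length must be at least 2 x the maximum interaction distance (",
         2 * max_dist, " bp) to host the full distance range")
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must lie in [0, 1]")
  if (planted_fold < 1) stop("planted_fold must be >= 1")
  if (depth <= 0) stop("depth must be positive")
  if (length(peak_width_range) != 2 || diff(peak_width_range) < 0)
    stop("peak_width_range must be an increasing bp interval")
  stopifnot(all(c("eff", "gc", "mapp", "chip") %in%
                  names(covariate_effect_sizes)))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration:\n")
  cat(sprintf("  genome: %d x %s bp, %d-bp bins\n", x$n_chroms,
              format(x$chrom_length, big.mark = ","), x$bin_size))
  cat(sprintf("  promoter bins: %d, depth: %s, decay alpha: %g\n",
              x$n_promoter_bins, format(x$depth, big.mark = ","),
              x$distance_decay_exponent))
  cat(sprintf("  planted pairs: %.1f%% at fold %g; panel: %d samples, %d links\n",
              100 * x$planted_fraction, x$planted_fold, x$n_samples,
              x$n_planted_links))
  invisible(x)
}

#' Simulate a genome with bins, peak sets, genes and chromatin states
#'
#' Generates the static genomic inputs of the pipeline: fixed-size bins with
#' bin-level covariates (effective fragment size, GC content, mappability,
#' ChIP enrichment; pair covariates downstream are the mean of the two
#' bins), H3K4me3 peaks placed wholly inside exactly `n_promoter_bins`
#' distinct bins, one gene TSS inside each H3K4me3 peak, CTCF peaks each
#' carrying exactly one motif hit with a recorded strand, ATAC peaks, and a
#' chromatin-state segmentation tiling every chromosome without gaps or
#' overlaps.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @param enhancer_bins optional `data.frame(chrom, start)` of bins near
#'   which the state segmentation is enriched for the enhancer state (see
#'   [simulate_chromatin_states()]).
#' @return a list with `chrom_sizes`, `bins` (with covariate columns
#'   `eff, gc, mapp, chip` and a `promoter` flag), `h3k4me3`, `genes`
#'   (`gene_id, chrom, tss, strand`), `ctcf_peaks`, `ctcf_motifs`
#'   (`peak_id, start, strand, score`), `atac` (the cCRE universe), `states`
#'   and `truth$planted_orientations` (named strand per CTCF peak).
#' @export
simulate_genome_and_peaks <- function(cfg, seed = cfg$seed,
                                      enhancer_bins = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$chrom_length < 2 * cfg$max_dist)
    stop("chrom_length cannot host the full distance range")
  set.seed(seed)
  bs <- cfg$bin_size
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                 paste0("chr", seq_len(cfg$n_chroms)))
  nb <- cfg$chrom_length / bs
  bins <- data.frame(
    chrom = rep(names(chrom_sizes), each = nb),
    start = rep(bs * (seq_len(nb) - 1), cfg$n_chroms))
  bins$end <- bins$start + bs
  n <- nrow(bins)
  if (cfg$n_promoter_bins > n)
    stop("n_promoter_bins exceeds the number of bins")
  prom_idx <- sort(sample.int(n, cfg$n_promoter_bins))
  bins$promoter <- seq_len(n) %in% prom_idx
  bins$eff <- stats::runif(n, 0.5, 1)
  bins$gc <- 0.3 + 0.4 * stats::rbeta(n, 5, 5)
  bins$mapp <- stats::rbeta(n, 8, 2)
  # ChIP enrichment on the log scale (short-read density score), higher at
  # promoter bins; enters the contact expectation linearly
  bins$chip <- stats::rnorm(n, mean = ifelse(bins$promoter, 1, 0), sd = 0.5)

  rpeak <- function(k, inside_bins = NULL, prefix = "peak") {
    if (k == 0)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), name = character(),
                        score = numeric(), strand = character()))
    w <- round(stats::runif(k, cfg$peak_width_range[1],
                            min(cfg$peak_width_range[2], bs - 1)))
    if (is.null(inside_bins)) {
      chrom <- sample(names(chrom_sizes), k, replace = TRUE)
      start <- floor(stats::runif(k, 0, cfg$chrom_length - w))
    } else {
      chrom <- inside_bins$chrom
      start <- inside_bins$start + floor(stats::runif(k, 0, bs - w))
    }
    data.frame(chrom = chrom, start = start, end = start + w,
               name = sprintf("%s_%05d", prefix, seq_len(k)),
               score = round(stats::runif(k, 10, 1000), 2), strand = ".")
  }

  h3k4me3 <- rpeak(cfg$n_promoter_bins, bins[prom_idx, ], "h3k4me3")
  genes <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(nrow(h3k4me3))),
    chrom = h3k4me3$chrom,
    tss = h3k4me3$start +
      floor(stats::runif(nrow(h3k4me3), 0, h3k4me3$end - h3k4me3$start)),
    strand = sample(c("+", "-"), nrow(h3k4me3), replace = TRUE))

  ctcf_peaks <- rpeak(cfg$n_ctcf_peaks, prefix = "ctcf")
  ctcf_motifs <- data.frame(
    peak_id = ctcf_peaks$name,
    start = ctcf_peaks$start +
      floor(stats::runif(nrow(ctcf_peaks), 0,
                         pmax(ctcf_peaks$end - ctcf_peaks$start - 19, 1))),
    strand = sample(c("+", "-"), nrow(ctcf_peaks), replace = TRUE),
    score = round(stats::runif(nrow(ctcf_peaks), 5, 25), 3))

  atac <- rpeak(cfg$n_atac_peaks, prefix = "atac")

  states <- simulate_chromatin_states(cfg, chrom_sizes,
                                      enhancer_bins = enhancer_bins)

  list(cfg = cfg, chrom_sizes = chrom_sizes, bins = bins, h3k4me3 = h3k4me3,
       genes = genes, ctcf_peaks = ctcf_peaks, ctcf_motifs = ctcf_motifs,
       atac = atac, states = states,
       truth = list(planted_orientations =
                      stats::setNames(ctcf_motifs$strand, ctcf_motifs$peak_id)))
}

#' Simulate a chromatin-state segmentation
#'
#' Tiles each chromosome with contiguous, non-overlapping segments (lengths
#' are multiples of 200 bp, geometric with mean 1 kb) labeled with one of
#' `cfg$n_states` integer-coded states.  When `enhancer_bins` is supplied
#' and `cfg$enhancer_state_bias > 0`, segments whose midpoint falls in one
#' of those bins receive the enhancer state with that probability, giving
#' the state-enrichment analyses a positive control.
#'
#' @inheritParams simulate_genome_and_peaks
#' @param chrom_sizes named vector of chromosome lengths.
#' @return `data.frame(chrom, start, end, state)` tiling every chromosome.
#' @export
simulate_chromatin_states <- function(cfg, chrom_sizes, enhancer_bins = NULL,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- paste0("St", seq_len(cfg$n_states))
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    n_guess <- ceiling(L / 600)
    len <- 200 * (1 + stats::rgeom(n_guess, 0.2))
    while (sum(len) < L)
      len <- c(len, 200 * (1 + stats::rgeom(n_guess, 0.2)))
    ends <- pmin(cumsum(len), L)
    k <- which(ends >= L)[1]
    ends <- ends[seq_len(k)]
    starts <- c(0, ends[-k])
    st <- sample(labels, k, replace = TRUE)
    if (!is.null(enhancer_bins) && cfg$enhancer_state_bias > 0) {
      eb <- enhancer_bins[enhancer_bins$chrom == ch, , drop = FALSE]
      if (nrow(eb)) {
        mid_bin <- cfg$bin_size * .bin_index(floor((starts + ends) / 2),
                                             cfg$bin_size)
        hit <- mid_bin %in% eb$start
        flip <- hit & stats::runif(k) < cfg$enhancer_state_bias
        st[flip] <- cfg$enhancer_state
      }
    }
    data.frame(chrom = ch, start = starts, end = ends, state = st)
  })
  do.call(rbind, out)
}

#' Simulate bin-pair contact counts with planted enriched pairs
#'
#' Enumerates all candidate AND/XOR bin pairs within the configured distance
#' range, builds the log-linear expectation
#' \deqn{\mu_{ij} \propto \exp(\beta^\top c_{ij})\, d_{ij}^{-\alpha}}
#' from the pair covariates (mean of the two bins) and the power-law
#' distance decay, thins expectations so the genome-wide expected total
#' equals `cfg$depth`, multiplies a random `planted_fraction` of pairs by
#' `planted_fold`, draws Poisson counts and emits the pairs with at least
#' one read.  Conditional on emission the counts are exactly
#' zero-truncated Poisson with the same rates, which is the caller's model.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [simulate_genome_and_peaks()].
#' @param sets which set labels to keep in the candidate universe.
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @return a list with `pairs` (emitted bin pairs: `chrom, start1, start2,
#'   count, distance, set, prom1, prom2`, covariates, the true rate
#'   `mu_true`, `planted` flag and `pair_id`), `truth` (all planted pairs
#'   with fold and whether they were emitted), and `n_candidates`.
#' @export
simulate_contacts <- function(cfg, genome, sets = c("AND", "XOR"),
                              seed = cfg$seed + 1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$planted_fold < 1) stop("planted_fold must be >= 1")
  set.seed(seed)
  bs <- cfg$bin_size
  offs <- seq.int(ceiling(cfg$min_dist / bs), floor(cfg$max_dist / bs))
  prom_keys <- .promoter_bin_keys(genome$h3k4me3, bs)

  per_chrom <- lapply(names(genome$chrom_sizes), function(ch) {
    b <- genome$bins[genome$bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    nb <- nrow(b)
    o <- rep(offs, pmax(nb - offs, 0))
    i1 <- sequence(pmax(nb - offs, 0))
    i2 <- i1 + o
    data.frame(chrom = ch, start1 = b$start[i1], start2 = b$start[i2],
               distance = o * bs,
               eff = (b$eff[i1] + b$eff[i2]) / 2,
               gc = (b$gc[i1] + b$gc[i2]) / 2,
               mapp = (b$mapp[i1] + b$mapp[i2]) / 2,
               chip = (b$chip[i1] + b$chip[i2]) / 2,
               prom1 = .chrom_key(ch, b$start[i1]) %in% prom_keys,
               prom2 = .chrom_key(ch, b$start[i2]) %in% prom_keys)
  })
  cand <- do.call(rbind, per_chrom)
  cand$set <- ifelse(cand$prom1 & cand$prom2, "AND",
                     ifelse(cand$prom1 | cand$prom2, "XOR", "NOT"))
  cand <- cand[cand$set %in% sets, , drop = FALSE]
  n <- nrow(cand)
  truth <- data.frame(pair_id = character(), chrom = character(),
                      start1 = numeric(), start2 = numeric(),
                      fold = numeric(), emitted = logical())
  if (n == 0)
    return(list(pairs = cbind(cand, count = integer(0)), truth = truth,
                n_candidates = 0L))

  b <- cfg$covariate_effect_sizes
  nu <- exp(b[["eff"]] * cand$eff + b[["gc"]] * cand$gc +
              b[["mapp"]] * cand$mapp + b[["chip"]] * cand$chip) *
    cand$distance^(-cfg$distance_decay_exponent)
  mu <- nu * (cfg$depth / sum(nu))
  n_planted <- round(cfg$planted_fraction * n)
  planted_idx <- if (n_planted > 0) sample.int(n, n_planted) else integer(0)
  mu[planted_idx] <- mu[planted_idx] * cfg$planted_fold
  cand$mu_true <- mu
  cand$planted <- seq_len(n) %in% planted_idx
  cand$count <- stats::rpois(n, mu)
  cand$pair_id <- .bin_key(cand$chrom, cand$start1, cand$start2)

  emitted <- cand[cand$count >= 1, , drop = FALSE]
  rownames(emitted) <- NULL
  if (n_planted > 0) {
    pl <- cand[planted_idx, , drop = FALSE]
    truth <- data.frame(pair_id = pl$pair_id, chrom = pl$chrom,
                        start1 = pl$start1, start2 = pl$start2,
                        fold = cfg$planted_fold, emitted = pl$count >= 1)
    truth <- truth[order(truth$pair_id), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(pairs = emitted, truth = truth, n_candidates = n)
}

#' Simulate a multi-sample H3K27ac / expression panel with planted links
#'
#' Generates an element-by-sample H3K27ac count matrix and a gene-by-sample
#' FPKM matrix.  Unlinked elements and genes vary independently across
#' samples.  For each planted link the element follows a latent cross-sample
#' activity profile, and the gene's FPKM is a strictly monotone function of
#' the element's *normalized* H3K27ac values (normal scores) plus Gaussian
#' noise with `cfg$link_noise_sd` on the log scale -- so at noise 0 the
#' downstream Spearman correlation is exactly 1, and the default noise gives
#' a population rank correlation near 0.8.  Columns carry sample-specific
#' library-size factors and per-column monotone scale distortions, which the
#' total-count + quantile normalization in [h3k27ac_matrix()] is designed to
#' remove.
#'
#' @param cfg a [sim_config()]; `cfg$n_samples` must be at least 3 (Spearman
#'   correlation is not usefully defined below that), and at least 5 for
#'   meaningful inference.
#' @param ccres `data.frame` with a `ccre_id` column (the element universe,
#'   e.g. the ATAC peaks with `name` as id).
#' @param genes `data.frame` with a `gene_id` column.
#' @param links optional `data.frame(ccre_id, gene_id)` of planted links;
#'   at most one link per gene is kept.
#' @param seed RNG seed (defaults to `cfg$seed + 2`).
#' @return list with `samples`, raw `h3k27ac` counts, `h3k27ac_norm`
#'   (total-count scaled + quantile normalized), `fpkm` and `truth` (the
#'   planted links).
#' @export
simulate_expression_panel <- function(cfg, ccres, genes, links = NULL,
                                      seed = cfg$seed + 2) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  if (n < 3)
    stop("n_samples must be >= 3: Spearman correlation is undefined usefully")
  set.seed(seed)
  ids <- if ("ccre_id" %in% names(ccres)) ccres$ccre_id else ccres$name
  gid <- genes$gene_id
  samples <- sprintf("s%02d", seq_len(n))
  if (!is.null(links) && nrow(links)) {
    stopifnot(all(links$ccre_id %in% ids), all(links$gene_id %in% gid))
    links <- links[!duplicated(links$gene_id), , drop = FALSE]
  } else {
    links <- data.frame(ccre_id = character(), gene_id = character())
  }

  E <- length(ids)
  base <- stats::rnorm(E, 5, 0.7)
  logval <- matrix(base + stats::rnorm(E * n, 0, 0.5), E, n)
  li <- match(links$ccre_id, ids)
  if (length(li)) {
    act <- matrix(stats::rnorm(length(li) * n), length(li), n)
    logval[li, ] <- base[li] + act
  }
  libsize <- stats::rlnorm(n, 0, 0.2)
  raw <- round(exp(sweep(logval, 2, log(libsize), "+")))
  dimnames(raw) <- list(ids, samples)
  norm <- normalize_panel(raw)

  G <- length(gid)
  fpkm <- matrix(exp(stats::rnorm(G, 2, 1) + stats::rnorm(G * n, 0, 1)), G, n,
                 dimnames = list(gid, samples))
  for (k in seq_len(nrow(links))) {
    v <- norm[links$ccre_id[k], ]
    u <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
    fpkm[links$gene_id[k], ] <-
      exp(1 + u + cfg$link_noise_sd * stats::rnorm(n))
  }
  list(samples = samples, h3k27ac = raw, h3k27ac_norm = norm, fpkm = fpkm,
       truth = links)
}

#' Simulate a pairs-style read table with known QC composition
#'
#' Draws read pairs whose inter-chromosomal, short-cis (<= 1,000 bp,
#' opposite strands) and long-cis fractions are fixed by multinomial
#' sampling, so the downstream QC metrics have known expected values:
#' `trans_ratio` equals `frac_inter` up to binomial error, all short-cis
#' pairs are "valid" in the FRiP sense, and a `frac_in_peak` share of them
#' is placed inside H3K4me3 peaks.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [simulate_genome_and_peaks()].
#' @param n_reads number of read pairs (defaults to `cfg$depth`).
#' @param frac_inter fraction of inter-chromosomal pairs.
#' @param frac_short_cis fraction of intra-chromosomal pairs at <= 1,000 bp.
#' @param frac_in_peak fraction of short-cis pairs whose first end lies in
#'   an H3K4me3 peak.
#' @param seed RNG seed (defaults to `cfg$seed + 3`).
#' @return `data.frame(chrom1, pos1, strand1, chrom2, pos2, strand2)`.
#' @export
simulate_read_pairs <- function(cfg, genome, n_reads = cfg$depth,
                                frac_inter = 0.1, frac_short_cis = 0.3,
                                frac_in_peak = 0.5, seed = cfg$seed + 3) {
  stopifnot(inherits(cfg, "sim_config"))
  if (frac_inter < 0 || frac_short_cis < 0 || frac_in_peak < 0 ||
      frac_in_peak > 1)
    stop("fractions must be non-negative (frac_in_peak in [0, 1])")
  if (frac_inter + frac_short_cis > 1)
    stop("frac_inter + frac_short_cis must not exceed 1")
  if (frac_inter > 0 && cfg$n_chroms < 2)
    stop("inter-chromosomal reads need at least two chromosomes")
  set.seed(seed)
  L <- cfg$chrom_length
  chroms <- names(genome$chrom_sizes)
  n_reads <- as.integer(n_reads)
  if (n_reads == 0)
    return(data.frame(chrom1 = character(), pos1 = numeric(),
                      strand1 = character(), chrom2 = character(),
                      pos2 = numeric(), strand2 = character()))
  cnt <- drop(stats::rmultinom(1, n_reads,
                               c(frac_inter, frac_short_cis,
                                 1 - frac_inter - frac_short_cis)))
  parts <- list()
  if (cnt[1] > 0) {  # inter-chromosomal
    k <- cnt[1]
    c1 <- sample(chroms, k, replace = TRUE)
    shift <- sample(length(chroms) - 1, k, replace = TRUE)
    c2 <- chroms[(match(c1, chroms) + shift - 1) %% length(chroms) + 1]
    parts$inter <- data.frame(
      chrom1 = c1, pos1 = floor(stats::runif(k, 0, L)),
      strand1 = sample(c("+", "-"), k, TRUE),
      chrom2 = c2, pos2 = floor(stats::runif(k, 0, L)),
      strand2 = sample(c("+", "-"), k, TRUE))
  }
  if (cnt[2] > 0) {  # short cis, valid (opposite strands, <= 1 kb)
    k <- cnt[2]
    in_peak <- stats::runif(k) < frac_in_peak
    pos1 <- floor(stats::runif(k, 0, L - 1001))
    ch <- sample(chroms, k, replace = TRUE)
    if (any(in_peak) && nrow(genome$h3k4me3)) {
      pk <- genome$h3k4me3[sample.int(nrow(genome$h3k4me3), sum(in_peak),
                                      replace = TRUE), ]
      ch[in_peak] <- pk$chrom
      pos1[in_peak] <- pk$start +
        floor(stats::runif(sum(in_peak), 0, pk$end - pk$start))
    }
    d <- sample(0:1000, k, replace = TRUE)
    s1 <- sample(c("+", "-"), k, TRUE)
    parts$short <- data.frame(
      chrom1 = ch, pos1 = pos1, strand1 = s1,
      chrom2 = ch, pos2 = pmin(pos1 + d, L - 1),
      strand2 = ifelse(s1 == "+", "-", "+"))
  }
  if (cnt[3] > 0) {  # long cis (> 1 kb)
    k <- cnt[3]
    d <- round(10^stats::runif(k, log10(1001), log10(min(1e6, L / 2))))
    pos1 <- floor(stats::runif(k, 0, L - d - 1))
    ch <- sample(chroms, k, replace = TRUE)
    parts$long <- data.frame(
      chrom1 = ch, pos1 = pos1, strand1 = sample(c("+", "-"), k, TRUE),
      chrom2 = ch, pos2 = pos1 + d, strand2 = sample(c("+", "-"), k, TRUE))
  }
  out <- do.call(rbind, parts)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study with planted ground truth
#'
#' Runs the whole generator: genome and peaks, contact counts with planted
#' enriched pairs, a read-pair table for QC, a chromatin-state segmentation
#' enriched for the enhancer state at planted non-promoter anchors (when
#' `cfg$enhancer_state_bias > 0`), and an H3K27ac/expression panel with
#' planted enhancer-gene links drawn from cCREs lying in non-promoter bins
#' of XOR pairs.  The returned `truth` component is the acceptance oracle
#' for every downstream stage.
#'
#' @param cfg a [sim_config()].
#' @return a list with `cfg`, `genome`, `contacts`, `reads`, `panel` and
#'   `truth` (`planted_pairs`, `planted_links`, `planted_orientations`).
#' @export
simulate_study <- function(cfg) {
  genome <- simulate_genome_and_peaks(cfg)
  contacts <- simulate_contacts(cfg, genome)
  if (cfg$enhancer_state_bias > 0 && nrow(contacts$truth)) {
    tr <- contacts$truth
    xor <- contacts$pairs[match(tr$pair_id, contacts$pairs$pair_id), ]
    xor <- xor[!is.na(xor$chrom) & xor$set == "XOR", , drop = FALSE]
    eb <- data.frame(
      chrom = xor$chrom,
      start = ifelse(xor$prom1, xor$start2, xor$start1))
    genome$states <- simulate_chromatin_states(cfg, genome$chrom_sizes,
                                               enhancer_bins = unique(eb),
                                               seed = cfg$seed + 4)
  }
  reads <- simulate_read_pairs(cfg, genome)

  # candidate links: ATAC peaks in non-promoter bins of emitted XOR pairs,
  # paired with the gene whose marked TSS sits in the promoter bin; pairs
  # planted as enriched come first so the links survive interaction calling
  xor <- contacts$pairs[contacts$pairs$set == "XOR", , drop = FALSE]
  xor <- xor[order(!xor$planted), , drop = FALSE]
  links <- data.frame(ccre_id = character(), gene_id = character())
  if (nrow(xor)) {
    bs <- cfg$bin_size
    nonprom <- data.frame(chrom = xor$chrom,
                          start = ifelse(xor$prom1, xor$start2, xor$start1),
                          prom = ifelse(xor$prom1, xor$start1, xor$start2))
    atac_bins <- .peak_bin_starts(genome$atac, bs)
    atac_key <- .chrom_key(genome$atac$chrom,
                           bs * .bin_index(floor((genome$atac$start +
                                                    genome$atac$end) / 2), bs))
    gene_key <- .chrom_key(genome$genes$chrom,
                           bs * .bin_index(genome$genes$tss, bs))
    m_ccre <- match(.chrom_key(nonprom$chrom, nonprom$start), atac_key)
    m_gene <- match(.chrom_key(nonprom$chrom, nonprom$prom), gene_key)
    ok <- !is.na(m_ccre) & !is.na(m_gene)
    cand <- unique(data.frame(ccre_id = genome$atac$name[m_ccre[ok]],
                              gene_id = genome$genes$gene_id[m_gene[ok]]))
    cand <- cand[!duplicated(cand$gene_id), , drop = FALSE]
    if (nrow(cand)) {
      # planted-pair candidates lead the ordering; take the first n
      links <- utils::head(cand, cfg$n_planted_links)
      rownames(links) <- NULL
    }
  }
  panel <- simulate_expression_panel(cfg, data.frame(ccre_id = genome$atac$name),
                                     genome$genes, links = links)
  list(cfg = cfg, genome = genome, contacts = contacts, reads = reads,
       panel = panel,
       truth = list(planted_pairs = contacts$truth,
                    planted_links = links,
                    planted_orientations = genome$truth$planted_orientations))
}
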