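#' Build interacting cCRE-gene pairs from P2N interactions
#'
#' For every called promoter-to-nonpromoter (XOR-set) interaction, pairs
#' each accessible-chromatin peak (cCRE) overlapping the non-anchor bin
#' with each gene whose H3K4me3-marked TSS (a TSS lying inside an H3K4me3
#' peak) falls in the promoter anchor bin.  Pairs are deduplicated at the
#' (cCRE, gene) level across interactions; AND-set (P2P) interactions
#' contribute nothing.
#'
#' @param interactions called interaction `data.frame` with `chrom, start1,
#'   start2, class, prom1, prom2` (only `P2N` rows are used).
#' @param atac_peaks accessible-peak `data.frame(chrom, start, end, name)`.
#' @param genes `data.frame(gene_id, chrom, tss, strand)`.
#' @param h3k4me3_peaks peak `data.frame` defining marked TSSs.
#' @param bin_size bin width in bp.
#' @return `data.frame(ccre_id, gene_id, chrom, ccre_center, tss,
#'   distance)`, one row per unique pair; `distance` is cCRE center to TSS.
#' @export
build_interacting_pairs <- function(interactions, atac_peaks, genes,
                                    h3k4me3_peaks, bin_size = 10000) {
  x <- interactions[interactions$class == "P2N", , drop = FALSE]
  if (!nrow(x))
    return(data.frame(ccre_id = character(), gene_id = character(),
                      chrom = character(), ccre_center = numeric(),
                      tss = numeric(), distance = numeric()))
  marked <- .pos_in_intervals(genes$chrom, genes$tss, h3k4me3_peaks)
  g <- genes[marked, , drop = FALSE]
  g$bin_key <- .chrom_key(g$chrom, bin_size * .bin_index(g$tss, bin_size))

  pb <- .peak_bin_starts_with_id(atac_peaks, bin_size)
  pb$key <- .chrom_key(pb$chrom, pb$start)

  prom_start <- ifelse(x$prom1, x$start1, x$start2)
  dist_start <- ifelse(x$prom1, x$start2, x$start1)
  pkey <- .chrom_key(x$chrom, prom_start)
  dkey <- .chrom_key(x$chrom, dist_start)

  out <- lapply(seq_len(nrow(x)), function(i) {
    gi <- which(g$bin_key == pkey[i])
    ci <- pb$peak_row[pb$key == dkey[i]]
    if (!length(gi) || !length(ci)) return(NULL)
    grid <- expand.grid(c = ci, g = gi)
    pk <- atac_peaks[grid$c, , drop = FALSE]
    data.frame(ccre_id = pk$name, gene_id = g$gene_id[grid$g],
               chrom = x$chrom[i],
               ccre_center = floor((pk$start + pk$end) / 2),
               tss = g$tss[grid$g])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(ccre_id = character(), gene_id = character(),
                      chrom = character(), ccre_center = numeric(),
                      tss = numeric(), distance = numeric()))
  out <- out[!duplicated(out[, c("ccre_id", "gene_id")]), , drop = FALSE]
  out$distance <- abs(out$ccre_center - out$tss)
  rownames(out) <- NULL
  out
}

#' Total-count scaling followed by quantile normalization
#'
#' Columns are first scaled to a common library size (the mean column
#' total), then quantile-normalized: each column's values are replaced by
#' the mean-of-sorted-columns reference at their within-column rank (ties
#' broken by first occurrence).  After normalization every column holds
#' exactly the same sorted value multiset, and columns that are monotone
#' transforms of a common reference become identical.
#'
#' @param mat numeric matrix, elements x samples; no column may sum to 0.
#' @return normalized matrix of the same dimensions and dimnames.
#' @export
normalize_panel <- function(mat) {
  totals <- colSums(mat)
  if (any(totals <= 0)) stop("sample with zero total counts")
  scaled <- sweep(mat, 2, totals / mean(totals), "/")
  sorted <- apply(scaled, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(scaled, 2, function(col)
    ref[rank(col, ties.method = "first")])
  dimnames(out) <- dimnames(mat)
  out
}

#' H3K27ac sample panel for interacting cCREs
#'
#' Builds the cCRE-by-sample H3K27ac matrix used for enhancer-gene
#' correlation: raw counts are the reads whose position falls within
#' `halfwidth` bp of each cCRE center (a 2-kb window by default), columns
#' are scaled to a common library size and quantile-normalized with
#' [normalize_panel()].  A precomputed count matrix can be supplied
#' instead of per-sample reads.
#'
#' @param ccres `data.frame(ccre_id, chrom, ccre_center)` (one row per
#'   unique cCRE; duplicated ids are collapsed).
#' @param reads named list (one per sample) of read `data.frame(chrom,
#'   pos)`; ignored when `counts` is given.
#' @param counts optional precomputed raw count matrix (cCREs x samples).
#' @param halfwidth half-window in bp around the cCRE center.
#' @return list with `raw` and `norm` matrices (rownames = `ccre_id`).
#' @export
h3k27ac_matrix <- function(ccres, reads = NULL, counts = NULL,
                           halfwidth = 1000) {
  u <- ccres[!duplicated(ccres$ccre_id), , drop = FALSE]
  if (is.null(counts)) {
    stopifnot(!is.null(reads))
    counts <- vapply(reads, function(r) {
      win <- GenomicRanges::GRanges(
        u$chrom, IRanges::IRanges(pmax(u$ccre_center - halfwidth, 0) + 1,
                                  u$ccre_center + halfwidth))
      q <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos + 1,
                                                            width = 1))
      GenomicRanges::countOverlaps(win, q)
    }, numeric(nrow(u)))
    rownames(counts) <- u$ccre_id
  } else {
    counts <- counts[u$ccre_id, , drop = FALSE]
  }
  list(raw = counts, norm = normalize_panel(counts))
}

#' Spearman correlation with a t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2`
#' degrees of freedom.  Constant vectors give `rho = NA`.
#'
#' @param x,y numeric vectors of equal length (`n >= 3`).
#' @return named vector `c(rho, p)`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Call cEnhancer-gene pairs by cross-sample correlation
#'
#' For every interacting cCRE-gene pair, computes the Spearman correlation
#' between the cCRE's normalized H3K27ac vector and the gene's FPKM vector
#' across samples, adjusts the two-sided p-values with Benjamini-Hochberg
#' over all tested pairs, and flags as cEnhancer-gene pairs those with a
#' positive correlation and `q < fdr`.  Pairs with a constant vector on
#' either side are excluded with a message (`rho = NA`).
#'
#' @param pairs output of [build_interacting_pairs()].
#' @param panel normalized H3K27ac matrix (cCREs x samples; e.g.
#'   `h3k27ac_matrix(...)$norm`).
#' @param fpkm expression matrix (genes x samples), same sample order.
#' @param fdr FDR threshold for the cEnhancer flag (default 0.05).
#' @return `pairs` with added `scc, p, q, is_cEnhancer` columns.
#' @export
link_ccre_genes <- function(pairs, panel, fpkm, fdr = 0.05) {
  stopifnot(ncol(panel) == ncol(fpkm))
  if (ncol(panel) < 5)
    stop("need at least 5 samples for meaningful correlation calling")
  res <- t(vapply(seq_len(nrow(pairs)), function(i)
    spearman_test(panel[pairs$ccre_id[i], ], fpkm[pairs$gene_id[i], ]),
    c(rho = 0, p = 0)))
  pairs$scc <- res[, "rho"]
  pairs$p <- res[, "p"]
  if (anyNA(pairs$scc))
    message("link_ccre_genes: ", sum(is.na(pairs$scc)),
            " pairs with constant vectors excluded (rho = NA)")
  pairs$q <- NA_real_
  ok <- !is.na(pairs$p)
  pairs$q[ok] <- stats::p.adjust(pairs$p[ok], method = "BH")
  pairs$is_cEnhancer <- !is.na(pairs$q) & pairs$scc > 0 & pairs$q < fdr
  pairs
}

#' Closest-promoter assignment of cCREs, for comparison with interactions
#'
#' Assigns every cCRE to its nearest protein-coding TSS (genes with
#' alternative TSSs are represented by the TSS with the highest H3K27ac
#' signal), keeps assignments between `min_dist` and `max_dist` to match
#' the distance range of interacting pairs, computes the same Spearman
#' correlations, and summarizes them in distance bins.
#'
#' @param ccres `data.frame(ccre_id, chrom, ccre_center)`.
#' @param tss_table `data.frame(gene_id, chrom, tss)`, possibly several
#'   rows per gene, with a `tss_signal` column (H3K27ac at the TSS) used to
#'   pick one TSS per gene.
#' @param panel,fpkm as in [link_ccre_genes()].
#' @param min_dist,max_dist assignment distance range in bp.
#' @param bin_width width of the distance-summary bins in bp.
#' @return list with `pairs` (`ccre_id, gene_id, distance, scc, p`) and
#'   `by_distance` (mean correlation per distance bin).  cCREs with no TSS
#'   within `max_dist` are unassigned (dropped).
#' @export
closest_promoter_comparison <- function(ccres, tss_table, panel, fpkm,
                                        min_dist = 20000, max_dist = 1e6,
                                        bin_width = 200000) {
  sig <- tss_table$tss_signal
  if (is.null(sig)) sig <- rep(0, nrow(tss_table))
  ts <- tss_table[order(tss_table$gene_id, -sig), , drop = FALSE]
  ts <- ts[!duplicated(ts$gene_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(ccres)), function(i) {
    cand <- ts[ts$chrom == ccres$chrom[i], , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    d <- abs(cand$tss - ccres$ccre_center[i])
    j <- which.min(d)
    if (d[j] > max_dist) return(NULL)  # no TSS within range: unassigned
    data.frame(ccre_id = ccres$ccre_id[i], gene_id = cand$gene_id[j],
               distance = d[j])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(list(pairs = data.frame(), by_distance = data.frame()))
  out <- out[out$distance >= min_dist & out$distance <= max_dist, ,
             drop = FALSE]
  res <- t(vapply(seq_len(nrow(out)), function(i)
    spearman_test(panel[out$ccre_id[i], ], fpkm[out$gene_id[i], ]),
    c(rho = 0, p = 0)))
  out$scc <- res[, "rho"]
  out$p <- res[, "p"]
  rownames(out) <- NULL
  bins <- pmin(floor(out$distance / bin_width), floor(max_dist / bin_width))
  by_dist <- do.call(rbind, lapply(split(out, bins), function(d)
    data.frame(dist_lo = min(floor(d$distance / bin_width)) * bin_width,
               n = nrow(d), mean_scc = mean(d$scc, na.rm = TRUE))))
  rownames(by_dist) <- NULL
  list(pairs = out, by_distance = by_dist)
}

#' Signal-matched control cCREs for cEnhancers
#'
#' Divides the H3K27ac signal distribution of all cCREs into `n_bins`
#' equal-frequency bins and, within each bin, samples (without replacement)
#' as many non-cEnhancer cCREs as there are cEnhancers in that bin --
#' preserving the per-bin histogram exactly.  Bins with too few candidates
#' contribute what they have; the shortfall is reported with a warning,
#' never silently backfilled.
#'
#' @param cenhancer_ids character vector of cEnhancer cCRE ids.
#' @param signal named numeric vector of H3K27ac signal for *all* cCREs
#'   (names are cCRE ids; must include the cEnhancers).
#' @param n_bins number of equal-frequency bins (default 100).
#' @param seed RNG seed.
#' @return character vector of control cCRE ids.
#' @export
sample_matched_controls <- function(cenhancer_ids, signal, n_bins = 100,
                                    seed = 1) {
  stopifnot(all(cenhancer_ids %in% names(signal)))
  set.seed(seed)
  N <- length(signal)
  bin <- ceiling(n_bins * rank(signal, ties.method = "first") / N)
  is_ce <- names(signal) %in% cenhancer_ids
  out <- character(0)
  shortfall <- 0L
  for (b in sort(unique(bin[is_ce]))) {
    k <- sum(is_ce & bin == b)
    cand <- names(signal)[!is_ce & bin == b]
    if (length(cand) < k) {
      shortfall <- shortfall + (k - length(cand))
      out <- c(out, cand)
    } else {
      out <- c(out, sample(cand, k))
    }
  }
  if (shortfall > 0)
    warning("matched-control shortfall of ", shortfall,
            " cCREs in bins with too few candidates")
  out
}

#' k-means clustering of enhancer signal profiles
#'
#' Euclidean k-means (multiple restarts, seeded) on a matrix of (typically
#' log2-transformed) H3K27ac profiles; clusters are relabeled in decreasing
#' order of mean signal so the labels are stable across runs.
#'
#' @param mat numeric matrix, elements x samples (e.g.
#'   `log2(counts + 1)`).
#' @param k number of clusters (`2 <= k <= nrow(mat)`).
#' @param seed RNG seed.
#' @param nstart random restarts passed to [stats::kmeans()].
#' @return list with `cluster` (named integer labels, 1 = highest mean
#'   signal) and `centers` (per-cluster mean profiles).
#' @export
kmeans_profiles <- function(mat, k, seed = 1, nstart = 25) {
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(mat)) stop("k cannot exceed the number of rows")
  set.seed(seed)
  if (k == nrow(mat)) {
    # degenerate but well-defined: every row is its own cluster
    km <- list(cluster = seq_len(k), centers = mat, tot.withinss = 0)
  } else {
    km <- stats::kmeans(mat, centers = k, nstart = nstart)
  }
  ord <- order(rowMeans(km$centers), decreasing = TRUE)
  relab <- match(km$cluster, ord)
  names(relab) <- rownames(mat)
  list(cluster = relab, centers = km$centers[ord, , drop = FALSE],
       withinss = km$tot.withinss)
}

#' In vivo validation rates against tested reporter elements
#'
#' For each element set, counts the elements overlapping (>= 1 bp) at
#' least one positive and at least one negative tested reporter element
#' (e.g. VISTA enhancer assays), and reports both the validation rate
#' `n_pos / (n_pos + n_neg)` and the positive:negative ratio.  All set
#' pairs are compared with a 2x2 chi-square test (no continuity
#' correction).
#'
#' @param element_sets named list of element `data.frame`s
#'   (`chrom, start, end`).
#' @param vista `data.frame(chrom, start, end, label)` with labels
#'   `"positive"`/`"negative"`.
#' @return list with `rates` (`set, n_pos, n_neg, rate, ratio`; `NA` when
#'   an element set overlaps no tested element) and `tests` (pairwise
#'   chi-square p-values).
#' @export
vista_validation_rate <- function(element_sets, vista) {
  pos <- .gr(vista[vista$label == "positive", , drop = FALSE])
  neg <- .gr(vista[vista$label == "negative", , drop = FALSE])
  rates <- do.call(rbind, lapply(names(element_sets), function(nm) {
    gr <- .gr(element_sets[[nm]])
    # disjoint chromosome sets are a legitimate "no overlap", not a warning
    n_pos <- sum(suppressWarnings(IRanges::overlapsAny(gr, pos)))
    n_neg <- sum(suppressWarnings(IRanges::overlapsAny(gr, neg)))
    data.frame(set = nm, n_pos = n_pos, n_neg = n_neg,
               rate = if (n_pos + n_neg > 0) n_pos / (n_pos + n_neg)
                      else NA_real_,
               ratio = if (n_neg > 0) n_pos / n_neg else NA_real_)
  }))
  nm <- names(element_sets)
  tests <- NULL
  if (length(nm) > 1) {
    cmb <- utils::combn(nm, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- rates[rates$set == cmb[1, i], ]
      b <- rates[rates$set == cmb[2, i], ]
      p <- if (a$n_pos + a$n_neg == 0 || b$n_pos + b$n_neg == 0) NA_real_
      else suppressWarnings(stats::chisq.test(
        matrix(c(a$n_pos, a$n_neg, b$n_pos, b$n_neg), 2),
        correct = FALSE))$p.value
      data.frame(set1 = cmb[1, i], set2 = cmb[2, i], p = p)
    }))
  }
  list(rates = rates, tests = tests)
}

#' Mean per-base conservation score of elements
#'
#' Averages a scored-interval conservation track (bedGraph-style) over
#' every base of each element; bases not covered by the track score 0.
#'
#' @param elements `data.frame(chrom, start, end)`; zero-length elements
#'   are an error.
#' @param track `data.frame(chrom, start, end, score)` of non-overlapping
#'   scored intervals.
#' @return numeric vector of per-element means, in input order.
#' @export
mean_conservation <- function(elements, track) {
  if (any(elements$end <= elements$start))
    stop("elements must have positive length")
  egr <- .gr(elements)
  tgr <- .gr(track)
  hits <- GenomicRanges::findOverlaps(egr, tgr)
  ov <- IRanges::pintersect(egr[S4Vectors::queryHits(hits)],
                            tgr[S4Vectors::subjectHits(hits)])
  contrib <- GenomicRanges::width(ov) *
    track$score[S4Vectors::subjectHits(hits)]
  tot <- rep(0, nrow(elements))
  agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  tot[as.integer(names(agg))] <- agg
  tot / (elements$end - elements$start)
}

#' Random size-matched control regions
#'
#' Places each element at a uniformly random position on a random
#' chromosome (weighted by length), keeping its width -- the shuffled
#' control used for conservation comparisons.
#'
#' @param elements `data.frame(chrom, start, end)`.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param seed RNG seed.
#' @return `data.frame(chrom, start, end)` of the same widths.
#' @export
shuffle_elements <- function(elements, chrom_sizes, seed = 1) {
  set.seed(seed)
  w <- elements$end - elements$start
  ch <- sample(names(chrom_sizes), nrow(elements), replace = TRUE,
               prob = chrom_sizes / sum(chrom_sizes))
  start <- floor(stats::runif(nrow(elements), 0, chrom_sizes[ch] - w))
  data.frame(chrom = ch, start = start, end = start + w)
}
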