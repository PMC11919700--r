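#' Bin intra-chromosomal read pairs into fixed-size bin pairs
#'
#' Assigns each intra-chromosomal read pair to the pair of fixed-size
#' genomic bins containing its two ends (0-based positions; bin index is
#' `floor(pos / bin_size)`), in canonical order `start1 <= start2`, and
#' tallies counts.  Inter-chromosomal pairs are excluded; reads on
#' chromosomes absent from `chrom_sizes` are skipped with a message.
#'
#' @param read_pairs `data.frame` with columns `chrom1, pos1, chrom2, pos2`
#'   (strand columns are ignored here).
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 10,000).
#' @return `data.frame(chrom, start1, start2, count, distance)` with one
#'   row per occupied bin pair; the counts sum to the number of binned
#'   intra-chromosomal read pairs.
#' @export
bin_read_pairs <- function(read_pairs, chrom_sizes, bin_size = 10000) {
  known <- read_pairs$chrom1 %in% names(chrom_sizes) &
    read_pairs$chrom2 %in% names(chrom_sizes)
  if (any(!known))
    message("bin_read_pairs: skipped ", sum(!known),
            " read pairs on unknown chromosomes")
  rp <- read_pairs[known, , drop = FALSE]
  in_bounds <- rp$pos1 >= 0 & rp$pos2 >= 0 &
    rp$pos1 < chrom_sizes[rp$chrom1] & rp$pos2 < chrom_sizes[rp$chrom2]
  if (any(!in_bounds)) stop("read positions outside chromosome bounds")
  rp <- rp[rp$chrom1 == rp$chrom2, , drop = FALSE]
  if (!nrow(rp))
    return(data.frame(chrom = character(), start1 = numeric(),
                      start2 = numeric(), count = integer(),
                      distance = numeric()))
  s1 <- bin_size * .bin_index(pmin(rp$pos1, rp$pos2), bin_size)
  s2 <- bin_size * .bin_index(pmax(rp$pos1, rp$pos2), bin_size)
  key <- .bin_key(rp$chrom1, s1, s2)
  tab <- rowsum(rep(1L, length(key)), key)
  parts <- strsplit(rownames(tab), "[:-]")
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    start1 = as.numeric(vapply(parts, `[`, "", 2)),
                    start2 = as.numeric(vapply(parts, `[`, "", 3)),
                    count = as.integer(tab[, 1]))
  out <- out[order(out$chrom, out$start1, out$start2), , drop = FALSE]
  out$distance <- out$start2 - out$start1
  rownames(out) <- NULL
  out
}

#' Label bin pairs as AND / XOR / NOT against H3K4me3 peaks
#'
#' A bin "contains a promoter" when at least 1 bp of an H3K4me3 peak
#' overlaps it (coordinates 0-based half-open, so a peak whose end equals
#' the bin start does not overlap).  Pairs where both, exactly one, or
#' neither bin contains a peak are labeled `AND`, `XOR` and `NOT`
#' respectively; `prom1`/`prom2` record which end is the promoter end.
#'
#' @param bin_pairs `data.frame` with `chrom, start1, start2`.
#' @param h3k4me3_peaks peak `data.frame` with `chrom, start, end`.
#' @param bin_size bin width in bp.
#' @return `bin_pairs` with added/overwritten `prom1, prom2, set` columns.
#' @export
classify_bin_sets <- function(bin_pairs, h3k4me3_peaks, bin_size = 10000) {
  keys <- .promoter_bin_keys(h3k4me3_peaks, bin_size)
  bin_pairs$prom1 <- .chrom_key(bin_pairs$chrom, bin_pairs$start1) %in% keys
  bin_pairs$prom2 <- .chrom_key(bin_pairs$chrom, bin_pairs$start2) %in% keys
  bin_pairs$set <- ifelse(bin_pairs$prom1 & bin_pairs$prom2, "AND",
                          ifelse(bin_pairs$prom1 | bin_pairs$prom2,
                                 "XOR", "NOT"))
  bin_pairs
}

#' Library quality-control metrics for a pairs-style read table
#'
#' Computes the three headline QC metrics of promoter-capture
#' proximity-ligation libraries from deduplicated, uniquely mapped read
#' pairs (alternative and mitochondrial contigs are dropped first):
#' * `trans_ratio` -- inter-chromosomal pairs / all pairs (pass `< 0.40`);
#' * `long_cis_ratio` -- intra-chromosomal pairs spanning more than
#'   1,000 bp / all intra-chromosomal pairs (pass `> 0.50`);
#' * `frip` -- among "valid" short-range pairs (opposite strands,
#'   intra-chromosomal, span `<= 1,000` bp), the fraction with at least one
#'   end in an H3K4me3 peak (pass `> 0.075`).
#'
#' @param read_pairs `data.frame(chrom1, pos1, strand1, chrom2, pos2,
#'   strand2)`.
#' @param h3k4me3_peaks peak `data.frame`.
#' @param exclude_chroms contigs removed before any metric is computed.
#' @param thresholds pass thresholds for the three metrics.
#' @return list of class `"qc_report"` with the three proportions, the
#'   per-metric pass flags and the denominators; a zero denominator is an
#'   error naming the metric.
#' @export
qc_metrics <- function(read_pairs, h3k4me3_peaks,
                       exclude_chroms = c("chrM"),
                       thresholds = c(trans_ratio = 0.40,
                                      long_cis_ratio = 0.50, frip = 0.075)) {
  keep <- !(read_pairs$chrom1 %in% exclude_chroms) &
    !(read_pairs$chrom2 %in% exclude_chroms) &
    !grepl("_alt$|_random$", read_pairs$chrom1) &
    !grepl("_alt$|_random$", read_pairs$chrom2)
  rp <- read_pairs[keep, , drop = FALSE]
  n <- nrow(rp)
  if (n == 0) stop("trans_ratio: no read pairs after contig filtering")
  intra <- rp$chrom1 == rp$chrom2
  trans_ratio <- sum(!intra) / n
  n_intra <- sum(intra)
  if (n_intra == 0) stop("long_cis_ratio: no intra-chromosomal read pairs")
  span <- abs(rp$pos2 - rp$pos1)
  long_cis_ratio <- sum(intra & span > 1000) / n_intra

  valid <- intra & span <= 1000 & rp$strand1 != rp$strand2
  if (sum(valid) == 0) stop("frip: no valid short-range read pairs")
  v <- rp[valid, , drop = FALSE]
  in_peak <- .pos_in_intervals(v$chrom1, v$pos1, h3k4me3_peaks) |
    .pos_in_intervals(v$chrom2, v$pos2, h3k4me3_peaks)
  frip <- sum(in_peak) / sum(valid)

  structure(list(
    trans_ratio = trans_ratio, long_cis_ratio = long_cis_ratio, frip = frip,
    pass = c(trans_ratio = trans_ratio < thresholds[["trans_ratio"]],
             long_cis_ratio = long_cis_ratio > thresholds[["long_cis_ratio"]],
             frip = frip > thresholds[["frip"]]),
    n_pairs = n, n_intra = n_intra, n_valid_short = sum(valid)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("PLAC-seq library QC\n")
  cat(sprintf("  trans_ratio    = %.4f (%s)\n", x$trans_ratio,
              ifelse(x$pass[["trans_ratio"]], "pass", "FAIL")))
  cat(sprintf("  long_cis_ratio = %.4f (%s)\n", x$long_cis_ratio,
              ifelse(x$pass[["long_cis_ratio"]], "pass", "FAIL")))
  cat(sprintf("  FRiP           = %.4f (%s)\n", x$frip,
              ifelse(x$pass[["frip"]], "pass", "FAIL")))
  cat(sprintf("  n = %d pairs, %d intra, %d valid short-range\n",
              x$n_pairs, x$n_intra, x$n_valid_short))
  invisible(x)
}

# is position pos on chrom inside any [start, end) interval?
.pos_in_intervals <- function(chrom, pos, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, width = 1))
  IRanges::overlapsAny(q, .gr(intervals))
}

#' Merge two replicate bin-pair tables by summing counts
#'
#' Counts of bin pairs present in either replicate are summed; set labels
#' and covariates must agree on the shared universe (the bin universes must
#' be compatible: a pair occurring in both replicates with conflicting
#' labels is an error).
#'
#' @param rep1,rep2 bin-pair `data.frame`s with `chrom, start1, start2,
#'   count` and optionally `set` plus covariate columns.
#' @return merged bin-pair `data.frame`; the total count equals the sum of
#'   the replicate totals.
#' @export
merge_replicates <- function(rep1, rep2) {
  k1 <- .bin_key(rep1$chrom, rep1$start1, rep1$start2)
  k2 <- .bin_key(rep2$chrom, rep2$start1, rep2$start2)
  if (anyDuplicated(k1) || anyDuplicated(k2))
    stop("replicate tables must have one row per bin pair")
  if ("set" %in% names(rep1) && "set" %in% names(rep2)) {
    shared <- intersect(k1, k2)
    if (!identical(rep1$set[match(shared, k1)], rep2$set[match(shared, k2)]))
      stop("mismatched bin universes: set labels disagree on shared pairs")
  }
  all_keys <- union(k1, k2)
  base <- rep1[match(all_keys, k1), , drop = FALSE]
  miss <- is.na(base$chrom)
  if (any(miss)) {
    fill <- rep2[match(all_keys[miss], k2), , drop = FALSE]
    common <- intersect(names(base), names(fill))
    base[miss, common] <- fill[, common]
  }
  c1 <- rep1$count[match(all_keys, k1)]; c1[is.na(c1)] <- 0L
  c2 <- rep2$count[match(all_keys, k2)]; c2[is.na(c2)] <- 0L
  base$count <- as.integer(c1 + c2)
  base <- base[order(base$chrom, base$start1, base$start2), , drop = FALSE]
  rownames(base) <- NULL
  base
}

#' Downsample AND/XOR read counts to a common per-chromosome depth
#'
#' For every chromosome, finds the minimum total AND+XOR count across the
#' supplied samples and downsamples the others to that total by sampling
#' individual read pairs without replacement (hypergeometric thinning of
#' bin-pair counts).  The minimal sample is left untouched on that
#' chromosome.  A chromosome where some sample has zero reads is reduced to
#' zero everywhere, with a warning.
#'
#' @param samples named list of bin-pair `data.frame`s (with `chrom,
#'   start1, start2, count, set`); only AND/XOR rows are balanced, other
#'   rows are dropped.
#' @param seed RNG seed.
#' @return list of bin-pair tables with per-chromosome AND+XOR totals equal
#'   across samples (rows whose count falls to zero are removed).
#' @export
downsample_balanced <- function(samples, seed = 1) {
  if (length(samples) < 2) stop("need at least two samples to balance")
  set.seed(seed)
  samples <- lapply(samples, function(s)
    s[s$set %in% c("AND", "XOR"), , drop = FALSE])
  chroms <- sort(unique(unlist(lapply(samples, function(s) s$chrom))))
  totals <- vapply(samples, function(s)
    vapply(chroms, function(ch) sum(s$count[s$chrom == ch]), 0), numeric(length(chroms)))
  totals <- matrix(totals, nrow = length(chroms),
                   dimnames = list(chroms, names(samples)))
  target <- apply(totals, 1, min)
  if (any(target == 0 & apply(totals, 1, max) > 0))
    warning("a sample has zero AND/XOR reads on some chromosome; ",
            "all samples downsampled to zero there")
  out <- lapply(samples, function(s) {
    for (ch in chroms) {
      idx <- which(s$chrom == ch)
      tot <- sum(s$count[idx])
      tgt <- target[[ch]]
      if (tot <= tgt) next
      # sample tgt individual read pairs without replacement
      reads <- rep.int(idx, s$count[idx])
      kept <- reads[sort(sample.int(length(reads), tgt))]
      newc <- tabulate(match(kept, idx), nbins = length(idx))
      s$count[idx] <- newc
    }
    s <- s[s$count >= 1, , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  out
}

#' Relabel bin pairs against the union of peak sets from all samples
#'
#' Merges the H3K4me3 peak sets of all samples into one interval union and
#' recomputes the AND/XOR/NOT labels against it.  Because the union can
#' only add promoter bins, each sample's AND and XOR universes are
#' supersets of the sample-specific ones; this makes bin pairs testable in
#' every sample for valid cross-sample comparisons.
#'
#' @param bin_pairs bin-pair `data.frame`.
#' @param peak_sets list of peak `data.frame`s (one per sample) or a single
#'   peak `data.frame`.
#' @param bin_size bin width in bp.
#' @return relabeled bin pairs (same rows, new `prom1, prom2, set`).
#' @export
union_peak_relabel <- function(bin_pairs, peak_sets, bin_size = 10000) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  if (!length(peak_sets)) stop("need at least one peak set")
  all_peaks <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  merged <- GenomicRanges::reduce(.gr(all_peaks))
  union_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                         start = GenomicRanges::start(merged) - 1,
                         end = GenomicRanges::end(merged))
  classify_bin_sets(bin_pairs, union_df, bin_size = bin_size)
}
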