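#' Assign one motif orientation to each CTCF peak
#'
#' Each peak with at least one motif hit receives the strand of its single
#' highest-scoring hit; peaks without hits are dropped from orientation
#' analyses.  Score ties are broken deterministically by (higher score,
#' then leftmost motif start, then `+` strand), so the assignment is
#' invariant to the input order of the hits.
#'
#' @param peaks CTCF peak `data.frame` with `chrom, start, end, name`.
#' @param motif_hits `data.frame(peak_id, start, strand, score)`; hits must
#'   reference existing peaks.
#' @return the subset of `peaks` with motifs, with added `strand` (the
#'   assigned orientation), `motif_score` and `motif_start` columns.
#' @export
assign_peak_orientation <- function(peaks, motif_hits) {
  stopifnot(all(motif_hits$peak_id %in% peaks$name))
  h <- motif_hits
  h <- h[order(h$peak_id, -h$score, h$start,
               match(h$strand, c("+", "-"))), , drop = FALSE]
  top <- h[!duplicated(h$peak_id), , drop = FALSE]
  out <- peaks[match(top$peak_id, peaks$name), , drop = FALSE]
  out$strand <- top$strand
  out$motif_score <- top$score
  out$motif_start <- top$start
  rownames(out) <- NULL
  out
}

#' Classify the CTCF orientation state of genomic bins (anchors)
#'
#' Oriented CTCF peaks are assigned to bins by >= 1 bp overlap (a peak may
#' touch two bins).  A bin is `forward` or `reverse` when all of its peaks
#' share that strand, `dual` when both strands are present, and `none` when
#' it holds no oriented peak.
#'
#' @param bins `data.frame(chrom, start)` of bins to annotate (starts are
#'   multiples of `bin_size`); a `promoter` logical column, if present, is
#'   carried through as `has_promoter`.
#' @param oriented_peaks output of [assign_peak_orientation()].
#' @param bin_size bin width in bp.
#' @return `data.frame(chrom, start, ctcf_peaks, orientation,
#'   has_promoter)`; `orientation` is `none` iff `ctcf_peaks` is 0.
#' @export
classify_anchor_orientation <- function(bins, oriented_peaks,
                                        bin_size = 10000) {
  pb <- .peak_bin_starts_with_id(oriented_peaks, bin_size)
  key <- .chrom_key(bins$chrom, bins$start)
  ann <- data.frame(chrom = bins$chrom, start = bins$start,
                    ctcf_peaks = 0L, orientation = "none",
                    has_promoter = if ("promoter" %in% names(bins))
                      bins$promoter else NA)
  if (nrow(pb)) {
    pb$strand <- oriented_peaks$strand[pb$peak_row]
    pk <- .chrom_key(pb$chrom, pb$start)
    n_fwd <- tapply(pb$strand == "+", pk, sum)
    n_rev <- tapply(pb$strand == "-", pk, sum)
    m <- match(key, names(n_fwd))
    nf <- ifelse(is.na(m), 0, n_fwd[m])
    nr <- ifelse(is.na(m), 0, n_rev[m])
    ann$ctcf_peaks <- as.integer(nf + nr)
    ann$orientation <- ifelse(nf + nr == 0, "none",
                              ifelse(nf > 0 & nr > 0, "dual",
                                     ifelse(nf > 0, "forward", "reverse")))
  }
  ann
}

# bins overlapped by each peak, keeping the peak row index
.peak_bin_starts_with_id <- function(peaks, bin_size) {
  peaks <- peaks[peaks$end > peaks$start, , drop = FALSE]
  if (!nrow(peaks))
    return(data.frame(chrom = character(), start = numeric(),
                      peak_row = integer()))
  first <- .bin_index(peaks$start, bin_size)
  last <- .bin_index(peaks$end - 1, bin_size)
  n <- last - first + 1
  data.frame(chrom = rep(peaks$chrom, n),
             start = bin_size * unlist(mapply(seq, first, last,
                                              SIMPLIFY = FALSE),
                                       use.names = FALSE),
             peak_row = rep(seq_len(nrow(peaks)), n))
}

#' Classify interactions by CTCF binding on their two ends
#'
#' P2P interactions are classified as CTCF-bound on `both`, `one-sided` or
#' `neither` end; P2N interactions as `both`, `P-side only`, `N-side only`
#' or `neither` (the P side being the promoter anchor).  An anchor counts
#' as bound when its orientation is not `none`.
#'
#' @param interactions `data.frame(chrom, start1, start2, class, prom1,
#'   prom2)` (class `P2P`/`P2N`, see [map_interactions()]).
#' @param annotations output of [classify_anchor_orientation()] covering
#'   every anchor.
#' @return list with `interactions` (input plus `ctcf_class`) and
#'   `proportions` (per class, summing to 1 within P2P and within P2N).
#' @export
interaction_ctcf_class <- function(interactions, annotations) {
  akey <- .chrom_key(annotations$chrom, annotations$start)
  bound <- annotations$orientation != "none"
  b1 <- bound[match(.chrom_key(interactions$chrom, interactions$start1), akey)]
  b2 <- bound[match(.chrom_key(interactions$chrom, interactions$start2), akey)]
  if (anyNA(b1) || anyNA(b2)) stop("every anchor must be annotated")
  x <- interactions
  pside <- ifelse(x$prom1, b1, b2)
  nside <- ifelse(x$prom1, b2, b1)
  x$ctcf_class <- ifelse(
    x$class == "P2P",
    ifelse(b1 & b2, "both", ifelse(b1 | b2, "one-sided", "neither")),
    ifelse(pside & nside, "both",
           ifelse(pside, "P-side only",
                  ifelse(nside, "N-side only", "neither"))))
  props <- lapply(split(x$ctcf_class, x$class), function(cl)
    table(cl) / length(cl))
  list(interactions = x, proportions = props)
}

#' Convergence of CTCF motif orientations at interaction anchors
#'
#' Restricts to interactions whose two anchors both have an unambiguous
#' orientation (a single peak, or several peaks all in the same direction:
#' `forward` or `reverse`, never `dual`/`none`), orders the anchors by
#' genomic coordinate, and classifies the pair as `convergent`
#' (left `+`, right `-`), `divergent` (left `-`, right `+`) or `tandem`
#' (same strand).  A chi-square goodness-of-fit test compares the counts
#' with the random-orientation null proportions 1/4, 1/4, 1/2.
#'
#' @param interactions interaction `data.frame` (`chrom, start1, start2`).
#' @param annotations output of [classify_anchor_orientation()].
#' @param min_n minimum eligible interactions for the test (default 5; the
#'   test is skipped below it and `p` is `NA`).
#' @return list with `counts` (convergent, divergent, tandem), the
#'   convergent fraction, `chisq` statistic, `p`, and `n`.
#' @export
convergence_enrichment <- function(interactions, annotations, min_n = 5) {
  akey <- .chrom_key(annotations$chrom, annotations$start)
  o1 <- annotations$orientation[
    match(.chrom_key(interactions$chrom, interactions$start1), akey)]
  o2 <- annotations$orientation[
    match(.chrom_key(interactions$chrom, interactions$start2), akey)]
  ok <- o1 %in% c("forward", "reverse") & o2 %in% c("forward", "reverse")
  l <- o1[ok]; r <- o2[ok]  # start1 < start2: left anchor is o1
  combo <- ifelse(l == "forward" & r == "reverse", "convergent",
                  ifelse(l == "reverse" & r == "forward", "divergent",
                         "tandem"))
  counts <- c(convergent = sum(combo == "convergent"),
              divergent = sum(combo == "divergent"),
              tandem = sum(combo == "tandem"))
  n <- sum(ok)
  if (n < min_n) {
    message("convergence_enrichment: fewer than ", min_n,
            " eligible interactions; test skipped")
    return(list(counts = counts, convergent_fraction = NA_real_,
                chisq = NA_real_, p = NA_real_, n = n))
  }
  tt <- suppressWarnings(
    stats::chisq.test(counts, p = c(1 / 4, 1 / 4, 1 / 2)))
  list(counts = counts, convergent_fraction = counts[["convergent"]] / n,
       chisq = unname(tt$statistic), p = tt$p.value, n = n)
}

#' Upstream/downstream partner bias of CTCF-bound promoters
#'
#' For P2N interactions whose promoter anchor is CTCF-bound in `forward`,
#' `reverse` or `dual` orientation, counts how many distal partners lie
#' upstream versus downstream of the promoter bin, and tests independence
#' of orientation and partner direction with a chi-square test (no Yates
#' correction).  Orientation rows with no interactions are dropped with a
#' warning.
#'
#' @param interactions P2N interaction `data.frame` with `chrom, start1,
#'   start2, prom1, prom2`.
#' @param annotations output of [classify_anchor_orientation()].
#' @return list with the orientation-by-direction contingency `table`,
#'   `chisq`, `p`.
#' @export
promoter_direction_bias <- function(interactions, annotations) {
  akey <- .chrom_key(annotations$chrom, annotations$start)
  x <- interactions[xor(interactions$prom1, interactions$prom2), ,
                    drop = FALSE]
  prom <- ifelse(x$prom1, x$start1, x$start2)
  part <- ifelse(x$prom1, x$start2, x$start1)
  orient <- annotations$orientation[match(.chrom_key(x$chrom, prom), akey)]
  keep <- orient %in% c("forward", "reverse", "dual")
  direction <- ifelse(part > prom, "downstream", "upstream")[keep]
  orient <- factor(orient[keep], levels = c("forward", "reverse", "dual"))
  tab <- table(orientation = orient,
               direction = factor(direction,
                                  levels = c("upstream", "downstream")))
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("dropping empty orientation rows: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  if (nrow(tab) < 2 || any(colSums(tab) == 0))
    return(list(table = tab, chisq = NA_real_, p = NA_real_))
  tt <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, chisq = unname(tt$statistic), p = tt$p.value)
}
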