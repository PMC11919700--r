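#' Distance-matched control bins for promoter-interacting regions
#'
#' For every promoter-to-nonpromoter (P2N) interaction, the promoter-distal
#' bin at distance `d` from the promoter bin is paired with the bin
#' equidistant on the *other side* of the promoter bin (`promoter - d` when
#' the partner sits at `promoter + d`).  Pairs whose reflected control
#' would fall outside the chromosome are dropped on both sides so the
#' foreground and control sets stay matched one-to-one.
#'
#' @param interactions P2N interaction `data.frame` with `chrom, start1,
#'   start2, prom1, prom2` (exactly one promoter end per row).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size bin width in bp.
#' @param dedupe_fg count a promoter-interacting bin once even when it
#'   interacts with several promoters (default `TRUE`); with `FALSE` every
#'   interaction contributes a row.
#' @return `data.frame(chrom, fg_start, ctrl_start)` with `|fg| = |ctrl|`
#'   by construction.
#' @export
distance_matched_controls <- function(interactions, chrom_sizes,
                                      bin_size = 10000, dedupe_fg = TRUE) {
  x <- interactions
  one_prom <- xor(x$prom1, x$prom2)
  x <- x[one_prom, , drop = FALSE]
  prom <- ifelse(x$prom1, x$start1, x$start2)
  fg <- ifelse(x$prom1, x$start2, x$start1)
  ctrl <- 2 * prom - fg
  ok <- ctrl >= 0 & ctrl <= chrom_sizes[x$chrom] - bin_size
  out <- data.frame(chrom = x$chrom[ok], fg_start = fg[ok],
                    ctrl_start = ctrl[ok])
  out <- unique(out)
  if (dedupe_fg)
    out <- out[!duplicated(out[, c("chrom", "fg_start")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peak-midpoint enrichment of foreground over control bins
#'
#' A region scores as a hit when it contains the midpoint
#' `floor((start + end) / 2)` of at least one peak; the enrichment fold is
#' the ratio of hit proportions, foreground over control.  When the control
#' proportion is zero the fold is undefined and reported as `NA` (such
#' categories are excluded from cross-sample testing, with a message).
#'
#' @param matched output of [distance_matched_controls()] (or any
#'   `data.frame` with `chrom, fg_start, ctrl_start`).
#' @param peaks one peak `data.frame` or a named list of peak sets
#'   (e.g. ATAC, histone marks, CTCF), each with `chrom, start, end`.
#' @param bin_size bin width in bp.
#' @return `data.frame(category, fg_prop, ctrl_prop, fold, n_regions)`.
#' @export
peak_midpoint_enrichment <- function(matched, peaks, bin_size = 10000) {
  if (is.data.frame(peaks)) peaks <- list(peaks = peaks)
  hit <- function(starts, chrom, mids) {
    if (!nrow(mids)) return(rep(FALSE, length(starts)))
    key <- .chrom_key(mids$chrom, bin_size * .bin_index(mids$mid, bin_size))
    .chrom_key(chrom, starts) %in% key
  }
  out <- lapply(names(peaks), function(cat) {
    p <- peaks[[cat]]
    mids <- data.frame(chrom = p$chrom, mid = floor((p$start + p$end) / 2))
    fg_prop <- mean(hit(matched$fg_start, matched$chrom, mids))
    ctrl_prop <- mean(hit(matched$ctrl_start, matched$chrom, mids))
    fold <- if (ctrl_prop > 0) fg_prop / ctrl_prop else NA_real_
    if (is.na(fold))
      message("peak_midpoint_enrichment: control proportion is 0 for '",
              cat, "'; fold reported as NA")
    data.frame(category = cat, fg_prop = fg_prop, ctrl_prop = ctrl_prop,
               fold = fold, n_regions = nrow(matched))
  })
  do.call(rbind, out)
}

#' Base-pair overlap enrichment of chromatin states
#'
#' For every chromatin state, the enrichment fold is the number of base
#' pairs of the foreground bins overlapping the state divided by the base
#' pairs of the control bins overlapping it.  States absent from both sets
#' are omitted; states absent from the control only give `NA` folds.
#'
#' @param matched output of [distance_matched_controls()].
#' @param states segmentation `data.frame(chrom, start, end, state)` with
#'   non-overlapping segments.
#' @param bin_size bin width in bp.
#' @return `data.frame(state, fg_bp, ctrl_bp, fold)`.
#' @export
state_bp_enrichment <- function(matched, states, bin_size = 10000) {
  bp_by_state <- function(starts, chrom) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts + 1, starts + bin_size)))
    vapply(split(states, states$state), function(seg) {
      sum(GenomicRanges::width(GenomicRanges::intersect(
        gr, GenomicRanges::reduce(.gr(seg)))))
    }, 0)
  }
  fg <- bp_by_state(matched$fg_start, matched$chrom)
  ctrl <- bp_by_state(matched$ctrl_start, matched$chrom)
  keep <- fg > 0 | ctrl > 0
  out <- data.frame(state = names(fg)[keep], fg_bp = fg[keep],
                    ctrl_bp = ctrl[keep],
                    fold = ifelse(ctrl[keep] > 0, fg[keep] / ctrl[keep],
                                  NA_real_))
  rownames(out) <- NULL
  out
}

#' Cross-sample test of enrichment folds against 1
#'
#' For each category (peak set or chromatin state), tests whether the
#' per-sample enrichment folds differ from 1 with a two-tailed one-sample
#' t-test (null mean 1), then adjusts across categories with
#' Benjamini-Hochberg.  Categories with fewer than 3 finite folds are
#' skipped with a warning; zero-variance folds give an undefined statistic
#' and are reported with `p = NA` and excluded from the adjustment rather
#' than fabricating significance.
#'
#' @param folds long `data.frame(category, sample, fold)` or a matrix with
#'   categories as rows and samples as columns.
#' @return `data.frame(category, n, mean_fold, t, p, q)`.
#' @export
cross_sample_test <- function(folds) {
  if (is.matrix(folds)) {
    folds <- data.frame(
      category = rep(rownames(folds), times = ncol(folds)),
      sample = rep(colnames(folds) %||% as.character(seq_len(ncol(folds))),
                   each = nrow(folds)),
      fold = as.vector(folds))
  }
  out <- lapply(split(folds, folds$category), function(d) {
    f <- d$fold[is.finite(d$fold)]
    if (length(f) < 3) {
      warning("category '", d$category[1],
              "' has fewer than 3 finite folds; skipped")
      return(NULL)
    }
    if (stats::sd(f) == 0) {
      tt <- list(statistic = if (f[1] == 1) 0 else NA_real_,
                 p.value = if (f[1] == 1) 1 else NA_real_)
    } else {
      tt <- stats::t.test(f, mu = 1)
    }
    data.frame(category = d$category[1], n = length(f), mean_fold = mean(f),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(out)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  rownames(out) <- NULL
  out
}
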