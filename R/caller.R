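#' Expected counts and normalized contact frequencies for bin pairs
#'
#' Evaluates a fitted [ztp_glm()] bias model on a bin-pair table, adding the
#' expected (parent Poisson) count `mu` and the normalized contact frequency
#' `ncf = count / mu` -- the observed-over-expected ratio after adjusting
#' for the systematic biases.  Covariates outside the training range are
#' allowed and reported via a message (see [predict.ztp_glm()]).
#'
#' @param model a fitted [ztp_glm()] (fitted on pairs of the same set label).
#' @param bin_pairs bin-pair `data.frame` with a `count` column and the
#'   model covariates.
#' @return `bin_pairs` with added `mu` and `ncf` columns.
#' @export
expected_and_ncf <- function(model, bin_pairs) {
  bin_pairs$mu <- predict(model, bin_pairs, type = "response")
  bin_pairs$ncf <- bin_pairs$count / bin_pairs$mu
  bin_pairs
}

#' Call significant interactions from scored bin pairs
#'
#' Takes bin pairs that already carry p-values and normalized contact
#' frequencies, restricts to the tested universe (autosomal, within the 1D
#' distance range -- the distance filter is applied *before* multiple
#' testing), computes Benjamini-Hochberg q-values pooled across
#' chromosomes within each set label, and calls the pairs with
#' `q < fdr` and `ncf >= min_ncf`.  AND-set calls are promoter-to-promoter
#' (`P2P`), XOR-set calls promoter-to-nonpromoter (`P2N`).
#'
#' @param scored bin-pair `data.frame` with `chrom, start1, start2, count,
#'   distance, p, ncf` and optionally `set`.
#' @param fdr FDR threshold (default 0.01).
#' @param min_ncf minimum normalized contact frequency (default 2).
#' @param min_dist,max_dist tested 1D distance range in bp.
#' @param autosomes_only drop sex/mitochondrial chromosomes before testing.
#' @param sex_chroms chromosome names treated as non-autosomal.
#' @return list of class `"interaction_calls"` with `tested` (all pairs
#'   entering multiple testing, with `q`, `called` and `class` columns) and
#'   `called` (the significant subset, sorted by `chrom, start1, start2`).
#'   Empty input gives empty output, not an error.
#' @export
call_interactions <- function(scored, fdr = 0.01, min_ncf = 2,
                              min_dist = 20000, max_dist = 1e6,
                              autosomes_only = TRUE,
                              sex_chroms = c("chrX", "chrY", "chrM")) {
  keep <- scored$distance >= min_dist & scored$distance <= max_dist
  if (autosomes_only) keep <- keep & .is_autosome(scored$chrom, sex_chroms)
  tested <- scored[keep, , drop = FALSE]
  if (!"set" %in% names(tested)) tested$set <- "XOR"
  if (nrow(tested)) {
    tested$q <- NA_real_
    for (s in unique(tested$set)) {
      i <- tested$set == s
      tested$q[i] <- stats::p.adjust(tested$p[i], method = "BH")
    }
    tested$called <- tested$q < fdr & tested$ncf >= min_ncf
  } else {
    tested$q <- numeric(0)
    tested$called <- logical(0)
  }
  tested$class <- ifelse(tested$set == "AND", "P2P",
                         ifelse(tested$set == "XOR", "P2N", NA))
  tested <- tested[order(tested$chrom, tested$start1, tested$start2), ,
                   drop = FALSE]
  rownames(tested) <- NULL
  called <- tested[which(tested$called), , drop = FALSE]
  rownames(called) <- NULL
  structure(list(tested = tested, called = called,
                 fdr = fdr, min_ncf = min_ncf,
                 dist_range = c(min_dist, max_dist)),
            class = "interaction_calls")
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat("Interaction calls (FDR <", x$fdr, ", NCF >=", x$min_ncf, ",",
      paste(format(x$dist_range, big.mark = ",", scientific = FALSE),
            collapse = "-"), "bp)\n")
  cat("  tested:", nrow(x$tested), "bin pairs\n")
  if (nrow(x$called)) {
    tab <- table(x$called$class)
    cat("  called:", nrow(x$called), "(",
        paste(names(tab), tab, collapse = ", "), ")\n")
  } else cat("  called: 0\n")
  invisible(x)
}

#' Fit the bias model and call interactions end to end
#'
#' The full calling pipeline for one sample: for each set label (`AND`,
#' `XOR`) separately, fits the zero-truncated Poisson regression
#' [ztp_glm()] of counts on the bias covariates over the tested universe
#' (counts >= 1, autosomal, within the distance range), computes expected
#' counts, normalized contact frequencies and upper-tail p-values
#' [ztp_pvalue()], and applies [call_interactions()].
#'
#' @param bin_pairs labeled bin-pair `data.frame` (see
#'   [classify_bin_sets()]) with `count`, `distance` and the covariate
#'   columns used by `formula`.
#' @param formula bias-model formula; the default adjusts for effective
#'   fragment size, GC content, mappability, ChIP enrichment and log10
#'   genomic distance.
#' @param fdr,min_ncf,min_dist,max_dist,autosomes_only,sex_chroms see
#'   [call_interactions()].
#' @param min_n minimum pairs per set-label fit.
#' @return an `"interaction_calls"` object (see [call_interactions()]) with
#'   an extra `models` component holding the per-set [ztp_glm()] fits.
#' @export
map_interactions <- function(bin_pairs,
                             formula = count ~ eff + gc + mapp + chip +
                               log10(distance),
                             fdr = 0.01, min_ncf = 2,
                             min_dist = 20000, max_dist = 1e6,
                             autosomes_only = TRUE,
                             sex_chroms = c("chrX", "chrY", "chrM"),
                             min_n = 500L) {
  keep <- bin_pairs$count >= 1 &
    bin_pairs$distance >= min_dist & bin_pairs$distance <= max_dist &
    bin_pairs$set %in% c("AND", "XOR")
  if (autosomes_only) keep <- keep & .is_autosome(bin_pairs$chrom, sex_chroms)
  universe <- bin_pairs[keep, , drop = FALSE]
  models <- list()
  scored <- list()
  for (s in intersect(c("AND", "XOR"), unique(universe$set))) {
    sub <- universe[universe$set == s, , drop = FALSE]
    fit <- ztp_glm(formula, sub, min_n = min_n)
    sub <- expected_and_ncf(fit, sub)
    sub$p <- ztp_pvalue(sub$count, sub$mu)
    models[[s]] <- fit
    scored[[s]] <- sub
  }
  scored <- do.call(rbind, scored)
  calls <- call_interactions(scored, fdr = fdr, min_ncf = min_ncf,
                             min_dist = min_dist, max_dist = max_dist,
                             autosomes_only = autosomes_only,
                             sex_chroms = sex_chroms)
  calls$models <- models
  calls
}
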