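#' Read and write the plain-text formats used by the pipeline
#'
#' Thin wrappers around [utils::read.table()]/[utils::write.table()] for the
#' formats the pipeline exchanges: BED6 peak files (0-based, half-open),
#' pairs-style read tables (`chrom1, pos1, strand1, chrom2, pos2, strand2`,
#' tab-separated with a header), bin-pair tables, BEDPE interaction files and
#' numeric matrices with row and column names.
#'
#' @param path file path.
#' @param x object to write (see the individual functions).
#' @return `read_bed` a `data.frame` with columns `chrom, start, end` and,
#'   when present, `name, score, strand`; `read_pairs_file` /
#'   `read_table_tsv` a `data.frame`; `read_matrix_tsv` a numeric matrix.
#' @name promloop_io
NULL

#' @rdname promloop_io
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(df))]
  df
}

#' @rdname promloop_io
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname promloop_io
#' @export
read_pairs_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
}

#' @rdname promloop_io
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname promloop_io
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
}

#' @rdname promloop_io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, quote = "")
  as.matrix(df)
}

#' @rdname promloop_io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called interactions as BEDPE
#'
#' Emits one row per interaction with the two 10-kb anchors, a name, a score
#' of `-log10(q)`, `.` strands, and extra columns `count, expected, ncf, p,
#' q, class`.
#'
#' @param calls a `data.frame` of called interactions (see [map_interactions()]).
#' @param path output file.
#' @param bin_size anchor width in bp.
#' @return the path, invisibly.
#' @export
write_bedpe <- function(calls, path, bin_size = 10000) {
  df <- data.frame(
    chrom1 = calls$chrom, start1 = calls$start1, end1 = calls$start1 + bin_size,
    chrom2 = calls$chrom, start2 = calls$start2, end2 = calls$start2 + bin_size,
    name = .bin_key(calls$chrom, calls$start1, calls$start2),
    score = round(-log10(pmax(calls$q, 1e-300)), 4),
    strand1 = ".", strand2 = ".",
    count = calls$count, expected = signif(calls$mu, 6),
    ncf = signif(calls$ncf, 6), p = signif(calls$p, 6),
    q = signif(calls$q, 6), class = calls$class)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
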