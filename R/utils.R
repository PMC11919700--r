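# Internal helpers shared across modules.  Genomic coordinates are 0-based,
# half-open (BED convention) in every data.frame the package handles;
# conversion to the 1-based closed convention of IRanges happens only inside
# these helpers.

.bin_index <- function(pos, bin_size) floor(pos / bin_size)

.bin_key <- function(chrom, start1, start2) {
  paste0(chrom, ":", format(start1, scientific = FALSE, trim = TRUE),
         "-", format(start2, scientific = FALSE, trim = TRUE))
}

# data.frame with chrom/start/end (0-based half-open) -> GRanges
.gr <- function(df, start = "start", end = "end") {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df[[start]] + 1, df[[end]]))
}

# bins (0-based starts) overlapped by >= 1 bp of each peak
.peak_bin_starts <- function(peaks, bin_size) {
  peaks <- peaks[peaks$end > peaks$start, , drop = FALSE]
  if (!nrow(peaks))
    return(data.frame(chrom = character(), start = numeric()))
  first <- .bin_index(peaks$start, bin_size)
  last <- .bin_index(peaks$end - 1, bin_size)
  n <- last - first + 1
  out <- data.frame(
    chrom = rep(peaks$chrom, n),
    start = bin_size * unlist(mapply(seq, first, last, SIMPLIFY = FALSE),
                              use.names = FALSE))
  unique(out)
}

# set of "chrom:start" keys for bins containing >= 1 bp of a peak
.promoter_bin_keys <- function(peaks, bin_size) {
  pb <- .peak_bin_starts(peaks, bin_size)
  unique(paste0(pb$chrom, ":", format(pb$start, scientific = FALSE, trim = TRUE)))
}

.chrom_key <- function(chrom, start) {
  paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE))
}

# chromosomes treated as non-autosomal (dropped before QC / calling)
.is_autosome <- function(chrom, exclude = c("chrX", "chrY", "chrM")) {
  !(chrom %in% exclude) & !grepl("_alt$|_random$", chrom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
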