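# CTCF motif orientation: peak assignment, anchor classes, convergence and
# promoter direction bias.

mk_peaks <- function(starts, chrom = "chr1", width = 400,
                     prefix = "p") {
  data.frame(chrom = chrom, start = starts, end = starts + width,
             name = sprintf("%s%03d", prefix, seq_along(starts)))
}

test_that("each peak takes the strand of its highest-scoring motif", {
  pk <- mk_peaks(c(1000, 5000, 9000))
  hits <- data.frame(peak_id = c("p001", "p001", "p002"),
                     start = c(1100, 1200, 5100),
                     strand = c("+", "-", "-"),
                     score = c(12.1, 9.8, 7))
  o <- assign_peak_orientation(pk, hits)
  expect_equal(o$strand[o$name == "p001"], "+")   # 12.1 beats 9.8
  expect_equal(o$strand[o$name == "p002"], "-")
  expect_false("p003" %in% o$name)                # no motif: dropped
  # tie on score: leftmost start wins, then + strand; order-invariant
  tie <- data.frame(peak_id = "p001", start = c(1200, 1100),
                    strand = c("-", "+"), score = c(10, 10))
  expect_equal(assign_peak_orientation(pk, tie)$strand[1], "+")
  tie2 <- data.frame(peak_id = "p001", start = c(1100, 1100),
                     strand = c("-", "+"), score = c(10, 10))
  expect_equal(assign_peak_orientation(pk, tie2)$strand[1], "+")
  expect_identical(assign_peak_orientation(pk, tie),
                   assign_peak_orientation(pk, tie[2:1, ]))
  # hits must reference existing peaks
  expect_error(assign_peak_orientation(pk[2:3, ], hits))
})

test_that("anchor orientation is forward/reverse/dual/none by peak content", {
  pk <- mk_peaks(c(1000, 3000, 12000, 21000, 23000))
  pk$strand <- c("+", "+", "-", "+", "-")
  bins <- data.frame(chrom = "chr1", start = c(0, 10000, 20000, 30000))
  ann <- classify_anchor_orientation(bins, pk)
  expect_equal(ann$orientation, c("forward", "reverse", "dual", "none"))
  expect_equal(ann$ctcf_peaks, c(2L, 1L, 2L, 0L))
  expect_true(all((ann$orientation == "none") == (ann$ctcf_peaks == 0)))
  # a peak spanning a bin boundary annotates both bins
  pk2 <- mk_peaks(9800); pk2$strand <- "+"
  ann2 <- classify_anchor_orientation(bins, pk2)
  expect_equal(ann2$orientation[1:2], c("forward", "forward"))
})

test_that("interaction CTCF classes match a brute-force tally", {
  set.seed(6)
  bins <- data.frame(chrom = "chr1", start = seq(0, 9e5, 1e4))
  ori <- sample(c("forward", "reverse", "dual", "none"), nrow(bins), TRUE)
  ann <- data.frame(chrom = bins$chrom, start = bins$start,
                    ctcf_peaks = ifelse(ori == "none", 0L, 1L),
                    orientation = ori, has_promoter = NA)
  n <- 60
  x <- data.frame(chrom = "chr1",
                  start1 = 1e4 * sample(0:40, n, TRUE))
  x$start2 <- x$start1 + 1e4 * sample(5:40, n, TRUE)
  x$prom1 <- rep(c(TRUE, FALSE), n / 2)
  x$prom2 <- !x$prom1 | rep(c(FALSE, TRUE, FALSE), length.out = n)
  x$class <- ifelse(x$prom1 & x$prom2, "P2P", "P2N")
  res <- interaction_ctcf_class(x, ann)
  # brute-force re-tally
  b <- function(s) ori[match(s, bins$start)] != "none"
  for (i in seq_len(n)) {
    b1 <- b(x$start1[i]); b2 <- b(x$start2[i])
    expected <- if (x$class[i] == "P2P") {
      if (b1 && b2) "both" else if (b1 || b2) "one-sided" else "neither"
    } else {
      ps <- if (x$prom1[i]) b1 else b2
      ns <- if (x$prom1[i]) b2 else b1
      if (ps && ns) "both" else if (ps) "P-side only"
      else if (ns) "N-side only" else "neither"
    }
    expect_equal(res$interactions$ctcf_class[i], expected)
  }
  for (cl in names(res$proportions))
    expect_equal(sum(res$proportions[[cl]]), 1)
})

test_that("convergence classes follow the genome-ordered definition", {
  ann <- data.frame(chrom = "chr1", start = c(0, 1e5, 2e5, 3e5),
                    ctcf_peaks = c(1L, 1L, 1L, 0L),
                    orientation = c("forward", "reverse", "dual", "none"),
                    has_promoter = NA)
  x <- data.frame(chrom = "chr1",
                  start1 = c(0, 1e5, 0, 0),
                  start2 = c(1e5, 2e5, 2e5, 3e5))
  res <- convergence_enrichment(x, ann, min_n = 1)
  # (+,-) convergent; dual and none anchors are ineligible
  expect_equal(unname(res$counts["convergent"]), 1L)
  expect_equal(res$n, 1L)
  # divergent: left reverse, right forward
  x2 <- data.frame(chrom = "chr1", start1 = 1e5, start2 = 4e5)
  ann2 <- rbind(ann, data.frame(chrom = "chr1", start = 4e5, ctcf_peaks = 1L,
                                orientation = "forward", has_promoter = NA))
  res2 <- convergence_enrichment(x2, ann2, min_n = 1)
  expect_equal(unname(res2$counts["divergent"]), 1L)
  # below min_n the test is skipped
  expect_message(r0 <- convergence_enrichment(x, ann), "skipped")
  expect_true(is.na(r0$p))
})

test_that("planted convergence is detected and the null is calibrated", {
  plant <- function(frac_conv, n, seed) {
    set.seed(seed)
    starts <- 2e4 * (seq_len(2 * n) - 1)
    left <- starts[seq(1, 2 * n, 2)]
    right <- starts[seq(2, 2 * n, 2)]
    conv <- runif(n) < frac_conv
    ls <- ifelse(conv, "forward", sample(c("forward", "reverse"), n, TRUE))
    rs <- ifelse(conv, "reverse",
                 ifelse(ls == "forward", "forward",
                        sample(c("forward", "reverse"), n, TRUE)))
    ann <- data.frame(chrom = "chr1", start = c(left, right),
                      ctcf_peaks = 1L, orientation = c(ls, rs),
                      has_promoter = NA)
    x <- data.frame(chrom = "chr1", start1 = left, start2 = right)
    convergence_enrichment(x, ann)
  }
  res <- plant(0.7, 500, 9)
  expect_gt(res$convergent_fraction, 0.5)
  expect_lt(res$p, 0.01)
  # uniform random strands: convergent fraction ~ 1/4 within 3 s.e.
  set.seed(10)
  n <- 2000
  starts <- 2e4 * (seq_len(2 * n) - 1)
  ann <- data.frame(chrom = "chr1", start = starts, ctcf_peaks = 1L,
                    orientation = sample(c("forward", "reverse"), 2 * n, TRUE),
                    has_promoter = NA)
  x <- data.frame(chrom = "chr1", start1 = starts[seq(1, 2 * n, 2)],
                  start2 = starts[seq(2, 2 * n, 2)])
  res0 <- convergence_enrichment(x, ann)
  expect_lt(abs(res0$convergent_fraction - 0.25),
            3 * sqrt(0.25 * 0.75 / n))
})

test_that("forward promoters planted downstream show the direction bias", {
  set.seed(14)
  n <- 400
  prom <- 2e6 * seq_len(n)   # well separated: one promoter bin each
  ori <- sample(c("forward", "reverse", "dual"), n, TRUE,
                prob = c(0.4, 0.4, 0.2))
  # forward promoters interact 80% downstream, reverse 80% upstream,
  # dual symmetric
  down <- ifelse(ori == "forward", runif(n) < 0.8,
                 ifelse(ori == "reverse", runif(n) < 0.2, runif(n) < 0.5))
  d <- 2e4 * sample(2:40, n, TRUE)
  part <- ifelse(down, prom + d, prom - d)
  ann <- unique(data.frame(chrom = "chr1", start = c(prom, part)))
  ann$ctcf_peaks <- 1L
  ann$orientation <- "none"
  ann$orientation[match(prom, ann$start)] <- ori
  ann$has_promoter <- NA
  x <- data.frame(chrom = "chr1", start1 = pmin(prom, part),
                  start2 = pmax(prom, part),
                  prom1 = prom < part, prom2 = prom > part)
  res <- promoter_direction_bias(x, ann)
  expect_lt(res$p, 0.01)
  expect_equal(rownames(res$table), c("forward", "reverse", "dual"))
  tab <- res$table
  expect_gt(tab["forward", "downstream"], tab["forward", "upstream"])
  expect_gt(tab["reverse", "upstream"], tab["reverse", "downstream"])
})

test_that("direction-bias p-values are calibrated under symmetry", {
  # symmetric partners: chi-square p roughly uniform; check the rejection
  # rate at 5% over replicates
  rej <- vapply(1:300, function(s) {
    set.seed(1000 + s)
    n <- 120
    prom <- 2e6 + 2e4 * sample(0:80, n, TRUE)
    ori <- sample(c("forward", "reverse"), n, TRUE)
    down <- runif(n) < 0.5
    d <- 2e4 * sample(2:40, n, TRUE)
    part <- ifelse(down, prom + d, prom - d)
    ann <- unique(data.frame(chrom = "chr1", start = c(prom, part)))
    ann$ctcf_peaks <- 1L; ann$orientation <- "none"; ann$has_promoter <- NA
    ann$orientation[match(prom, ann$start)] <- ori
    x <- data.frame(chrom = "chr1", start1 = pmin(prom, part),
                    start2 = pmax(prom, part),
                    prom1 = prom < part, prom2 = prom > part)
    suppressWarnings(promoter_direction_bias(x, ann)$p) < 0.05
  }, NA)
  expect_lt(mean(rej), 0.10)
  expect_gt(mean(rej), 0.005)
})

test_that("orientation analytics agree on a full synthetic study", {
  cfg <- tiny_cfg()
  st <- simulate_study(cfg)
  g <- st$genome
  oriented <- assign_peak_orientation(g$ctcf_peaks, g$ctcf_motifs)
  # with one motif per peak, orientation equals the planted strand
  expect_equal(oriented$strand,
               unname(st$truth$planted_orientations[oriented$name]))
  ann <- classify_anchor_orientation(g$bins, oriented)
  xorp <- st$contacts$pairs[st$contacts$pairs$set == "XOR", ]
  calls <- map_interactions(xorp)
  cc <- interaction_ctcf_class(calls$called, ann)
  expect_equal(sum(cc$proportions$P2N), 1)
})
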