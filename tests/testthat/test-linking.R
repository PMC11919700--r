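# Enhancer-gene linking: pair construction, normalization, correlation
# calling, closest-promoter comparison, matched controls, clustering,
# validation rates and conservation.

test_that("interacting pairs are built from XOR anchors only", {
  x <- data.frame(chrom = "chr1",
                  start1 = c(100000, 100000, 500000),
                  start2 = c(400000, 600000, 900000),
                  class = c("P2N", "P2N", "P2P"),
                  prom1 = c(TRUE, TRUE, TRUE), prom2 = c(FALSE, FALSE, TRUE))
  h3k <- data.frame(chrom = "chr1", start = 104000, end = 106000)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(105000, 101000), strand = "+")
  atac <- data.frame(chrom = "chr1", start = c(401000, 405000, 601000),
                     end = c(401600, 405600, 601600),
                     name = c("cc1", "cc2", "cc3"))
  pairs <- build_interacting_pairs(x, atac, genes, h3k)
  # anchor bin holds the marked TSS of gA only (gB's TSS is unmarked);
  # partner bins hold 2 and 1 ATAC peaks -> 3 pairs, all with gA
  expect_equal(nrow(pairs), 3)
  expect_true(all(pairs$gene_id == "gA"))
  expect_setequal(pairs$ccre_id, c("cc1", "cc2", "cc3"))
  expect_equal(pairs$distance,
               abs(pairs$ccre_center - 105000))
  # anchor bin without an annotated marked TSS contributes nothing
  x2 <- x[1, ]; x2$start1 <- 2e6; x2$start2 <- 2.4e6
  expect_equal(nrow(build_interacting_pairs(x2, atac, genes, h3k)), 0)
  # duplicated (ccre, gene) combinations collapse to one pair
  xdup <- rbind(x[1, ], x[1, ])
  expect_equal(nrow(build_interacting_pairs(xdup, atac, genes, h3k)), 2)
})

test_that("quantile normalization matches the brute-force oracle exactly", {
  set.seed(3)
  m <- matrix(rpois(15, 40) + 1, 5, 3)
  expect_equal(normalize_panel(m), oracle_quantile_norm(m))
  # identical columns: normalization is the identity (up to scaling)
  mi <- matrix(rep(c(1, 5, 9, 2, 7), 3), 5, 3)
  expect_equal(normalize_panel(mi), mi)
  # columns that are monotone transforms of one reference become identical
  base <- c(2, 9, 4, 30, 11)
  mm <- cbind(base, base^2, exp(base / 10))
  nm <- normalize_panel(mm)
  expect_equal(nm[, 1], nm[, 2], ignore_attr = TRUE)
  expect_equal(nm[, 1], nm[, 3], ignore_attr = TRUE)
  # every column holds exactly the same sorted multiset
  set.seed(4)
  big <- matrix(rpois(600, 20), 60, 10)
  nb <- normalize_panel(big)
  for (j in 2:10) expect_identical(sort(nb[, 1]), sort(nb[, j]))
  expect_error(normalize_panel(cbind(c(0, 0), c(1, 2))), "zero total")
})

test_that("quantile normalization agrees with the limma reference", {
  set.seed(5)
  m <- matrix(rlnorm(200, 3, 1), 40, 5)
  m <- sweep(m, 2, colSums(m) / mean(colSums(m)), "/")  # equal totals
  ours <- normalize_panel(m)
  ref <- limma::normalizeQuantiles(m, ties = FALSE)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("window counting and panel assembly work from reads", {
  ccres <- data.frame(ccre_id = c("a", "b"), chrom = "chr1",
                      ccre_center = c(5000, 50000))
  reads <- list(
    s1 = data.frame(chrom = "chr1", pos = c(4200, 5800, 49100, 51200, 80000)),
    s2 = data.frame(chrom = "chr1", pos = c(4000, 6001, 49000)))
  hm <- h3k27ac_matrix(ccres, reads = reads)
  # window is center +/- 1 kb, half-open: [4000, 6000) catches 4200 and
  # 5800 for "a"; [49000, 51000) catches 49100 but not 51200 for "b"
  expect_equal(unname(hm$raw[, "s1"]), c(2, 1))
  expect_equal(unname(hm$raw[, "s2"]), c(1, 1))   # 6001 outside, 4000 inside
  expect_equal(dim(hm$norm), dim(hm$raw))
})

test_that("spearman statistics match stats::cor.test and exact permutation", {
  expect_equal(unname(spearman_test(1:3, c(10, 20, 30))["rho"]), 1)
  expect_equal(unname(spearman_test(1:4, c(9, 7, 5, 3))["rho"]), -1)
  expect_true(is.na(spearman_test(rep(2, 5), 1:5)["rho"]))
  set.seed(8)
  x <- rnorm(15); y <- 0.5 * x + rnorm(15)
  st <- spearman_test(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(unname(st["rho"]), unname(ct$estimate))
  # t approximation against the exact permutation distribution at n = 7
  set.seed(9)
  for (rep in 1:3) {
    x7 <- rnorm(7); y7 <- rnorm(7)
    pe <- oracle_spearman_perm_p(x7, y7)
    pt_ <- spearman_test(x7, y7)["p"]
    expect_lt(abs(pt_ - pe), 0.12)
  }
})

test_that("planted links are recovered and decoys controlled", {
  sens <- c(); fdps <- c()
  for (s in 1:5) {
    cfg <- tiny_cfg(seed = 200 + s, n_samples = 22, link_noise_sd = 0.72)
    ccres <- data.frame(ccre_id = sprintf("c%03d", 1:300))
    genes <- data.frame(gene_id = sprintf("g%03d", 1:300))
    links <- data.frame(ccre_id = sprintf("c%03d", 1:30),
                        gene_id = sprintf("g%03d", 1:30))
    pan <- simulate_expression_panel(cfg, ccres, genes, links)
    pairs <- data.frame(ccre_id = ccres$ccre_id, gene_id = genes$gene_id)
    res <- link_ccre_genes(pairs, pan$h3k27ac_norm, pan$fpkm)
    planted <- paste(res$ccre_id, res$gene_id) %in%
      paste(links$ccre_id, links$gene_id)
    sens <- c(sens, mean(res$is_cEnhancer[planted]))
    ncalls <- sum(res$is_cEnhancer)
    fdps <- c(fdps, if (ncalls) sum(res$is_cEnhancer & !planted) / ncalls
              else 0)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdps), 0.05)
})

test_that("anti-correlated and constant pairs are never cEnhancers", {
  panel <- rbind(a = c(1, 2, 3, 4, 5, 6), b = rep(2, 6))
  fpkm <- rbind(gA = c(60, 50, 40, 30, 20, 10), gB = 1:6)
  pairs <- data.frame(ccre_id = c("a", "b"), gene_id = c("gA", "gB"))
  expect_message(res <- link_ccre_genes(pairs, panel, fpkm), "constant")
  expect_equal(res$scc[1], -1)
  expect_false(res$is_cEnhancer[1])
  expect_true(is.na(res$scc[2]))
  expect_false(res$is_cEnhancer[2])
})

test_that("closest-promoter assignment follows distance and TSS rules", {
  ccres <- data.frame(ccre_id = c("near", "mid", "far"), chrom = "chr1",
                      ccre_center = c(110000, 530000, 5e6))
  tss <- data.frame(gene_id = c("g1", "g1", "g2"), chrom = "chr1",
                    tss = c(100000, 560000, 500000),
                    tss_signal = c(5, 50, 10))
  panel <- matrix(rnorm(18), 3, 6, dimnames = list(c("near", "mid", "far"),
                                                   NULL))
  fpkm <- matrix(rnorm(12), 2, 6, dimnames = list(c("g1", "g2"), NULL))
  res <- closest_promoter_comparison(ccres, tss, panel, fpkm)
  # "near" is 10 kb from g1's top TSS (560000? no: distances use the
  # highest-signal TSS per gene): g1 -> 560000, g2 -> 500000.
  # near: min distance 390000 (g2); mid: 30000 (g1/g2 -> g1 at 30000);
  # far: beyond 1 Mb from every TSS -> unassigned
  expect_false("far" %in% res$pairs$ccre_id)
  expect_equal(res$pairs$gene_id[res$pairs$ccre_id == "mid"], "g1")
  expect_equal(res$pairs$distance[res$pairs$ccre_id == "mid"], 30000)
  # a cCRE 10 kb from the nearest TSS is excluded by the range filter
  cc2 <- data.frame(ccre_id = "near", chrom = "chr1", ccre_center = 550000)
  res2 <- closest_promoter_comparison(cc2, tss, panel["near", , drop = FALSE],
                                      fpkm)
  expect_equal(nrow(res2$pairs), 0)
})

test_that("interacting pairs out-correlate closest-promoter pairs when
          true targets skip the nearest gene", {
  cfg <- tiny_cfg(seed = 77, n_samples = 22, link_noise_sd = 0.5)
  ccres <- data.frame(ccre_id = sprintf("c%02d", 1:40), chrom = "chr1",
                      ccre_center = 1e6 + 5e4 * (1:40))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40))
  # true target is the second-nearest promoter: TSS grid offset so the
  # nearest gene is a decoy
  links <- data.frame(ccre_id = ccres$ccre_id, gene_id = genes$gene_id)
  pan <- simulate_expression_panel(cfg, ccres, genes, links)
  pairs <- data.frame(ccre_id = ccres$ccre_id, gene_id = genes$gene_id)
  res_int <- link_ccre_genes(pairs, pan$h3k27ac_norm, pan$fpkm)
  # closest-promoter rule pairs each cCRE with a decoy gene: the TSS
  # 20 kb away (the nearest in range) carries an unrelated gene label
  decoy <- genes$gene_id[(seq_len(40) + 16) %% 40 + 1]
  tss <- data.frame(gene_id = decoy, chrom = "chr1",
                    tss = 1e6 + 5e4 * (1:40) + 20000, tss_signal = 1)
  res_cp <- closest_promoter_comparison(ccres, tss, pan$h3k27ac_norm,
                                        pan$fpkm)
  expect_equal(res_cp$pairs$distance, rep(20000, 40))
  expect_gt(mean(res_int$scc), mean(res_cp$pairs$scc) + 0.2)
})

test_that("matched controls reproduce the per-bin histogram exactly", {
  set.seed(21)
  sig <- setNames(rlnorm(2000, 3, 1), sprintf("c%04d", 1:2000))
  ce <- sample(names(sig), 200)
  ctrl <- sample_matched_controls(ce, sig, n_bins = 100, seed = 5)
  expect_equal(length(ctrl), 200)
  expect_false(any(ctrl %in% ce))
  N <- length(sig)
  bin <- ceiling(100 * rank(sig, ties.method = "first") / N)
  expect_equal(table(bin[names(sig) %in% ce]),
               table(bin[names(sig) %in% ctrl]))
  # determinism and distribution match (KS) across seeds
  expect_identical(ctrl, sample_matched_controls(ce, sig, seed = 5))
  ks_ok <- vapply(1:10, function(s) {
    ct <- sample_matched_controls(ce, sig, seed = s)
    suppressWarnings(ks.test(sig[ce], sig[ct])$p.value) > 0.05
  }, NA)
  expect_gte(sum(ks_ok), 9)
  # shortfall: more cEnhancers than candidates in a bin
  sig2 <- setNames(c(1:10), sprintf("x%02d", 1:10))
  expect_warning(sample_matched_controls(sprintf("x%02d", 1:8), sig2,
                                         n_bins = 2, seed = 1), "shortfall")
})

test_that("k-means profiling recovers planted clusters", {
  set.seed(33)
  hi <- matrix(rnorm(150, 8, 0.3), 30, 5)
  lo <- matrix(rnorm(100, 1, 0.3), 20, 5)
  m <- rbind(hi, lo)
  rownames(m) <- sprintf("e%02d", 1:50)
  km <- kmeans_profiles(m, k = 2, seed = 2)
  truth <- rep(1:2, c(30, 20))
  expect_equal(oracle_ari(km$cluster, truth), 1)
  # relabeling: cluster 1 has the highest mean signal
  expect_gt(mean(km$centers[1, ]), mean(km$centers[2, ]))
  # duplicate rows land in the same cluster
  md <- rbind(m, e51 = m[1, ])
  km2 <- kmeans_profiles(md, k = 2, seed = 2)
  expect_equal(unname(km2$cluster["e51"]), unname(km2$cluster["e01"]))
  # k = rows: each distinct row its own cluster
  ms <- matrix(c(0, 10, 20, 1, 11, 21), 3, 2)
  rownames(ms) <- c("r1", "r2", "r3")
  km3 <- kmeans_profiles(ms, k = 3, seed = 1)
  expect_equal(sort(unname(km3$cluster)), 1:3)
  expect_error(kmeans_profiles(ms, k = 4), "exceed")
  expect_error(kmeans_profiles(ms, k = 1), "at least 2")
})

test_that("validation rates and their chi-square comparisons are exact", {
  vista <- data.frame(chrom = "chr1",
                      start = c(seq(0, 7e4, 1e4), seq(2e5, 2.1e5, 1e4)),
                      end = c(seq(0, 7e4, 1e4), seq(2e5, 2.1e5, 1e4)) + 5000,
                      label = c(rep("positive", 8), rep("negative", 2)))
  # elements overlapping 6 positive and 2 negative records
  els <- data.frame(chrom = "chr1",
                    start = c(seq(0, 5e4, 1e4), 2e5, 2.1e5),
                    end = c(seq(0, 5e4, 1e4), 2e5, 2.1e5) + 1000)
  res <- vista_validation_rate(list(mine = els, same = els), vista)
  expect_equal(res$rates$n_pos, c(6, 6))
  expect_equal(res$rates$n_neg, c(2, 2))
  expect_equal(res$rates$rate, c(0.75, 0.75))
  expect_equal(res$rates$ratio, c(3, 3))
  expect_equal(res$tests$p, 1)                      # identical sets
  # a set overlapping nothing takes the NA path
  far <- data.frame(chrom = "chr2", start = 1, end = 100)
  res2 <- vista_validation_rate(list(a = els, none = far), vista)
  expect_true(is.na(res2$rates$rate[2]))
  expect_true(is.na(res2$tests$p))
})

test_that("mean conservation equals the per-base brute-force expansion", {
  track <- data.frame(chrom = "chr1", start = c(100, 300, 1000),
                      end = c(200, 500, 1500),
                      score = c(0.8, 0.5, 1.0))
  # fully inside a scored interval
  expect_equal(mean_conservation(
    data.frame(chrom = "chr1", start = 120, end = 180), track), 0.8)
  # half covered at 1.0, half uncovered
  expect_equal(mean_conservation(
    data.frame(chrom = "chr1", start = 750, end = 1250), track), 0.5)
  expect_error(mean_conservation(
    data.frame(chrom = "chr1", start = 5, end = 5), track), "length")
  # random fixture against explicit per-base expansion
  set.seed(55)
  tr <- data.frame(chrom = "chr1", start = seq(0, 9000, 1000))
  tr$end <- tr$start + sample(200:900, 10)
  tr$score <- round(runif(10), 3)
  els <- data.frame(chrom = "chr1", start = sample(0:9000, 20))
  els$end <- els$start + sample(100:800, 20)
  got <- mean_conservation(els, tr)
  base_score <- rep(0, 10000)
  for (i in seq_len(nrow(tr)))
    base_score[(tr$start[i] + 1):tr$end[i]] <- tr$score[i]
  want <- vapply(seq_len(nrow(els)), function(i)
    mean(base_score[(els$start[i] + 1):els$end[i]]), 0)
  expect_equal(got, want)
})

test_that("shuffled controls preserve widths and stay in bounds", {
  els <- data.frame(chrom = "chr1", start = c(0, 100), end = c(500, 900))
  cs <- c(chr1 = 1e5, chr2 = 2e5)
  sh <- shuffle_elements(els, cs, seed = 3)
  expect_equal(sh$end - sh$start, els$end - els$start)
  expect_true(all(sh$start >= 0 & sh$end <= cs[sh$chrom]))
  expect_identical(sh, shuffle_elements(els, cs, seed = 3))
})
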