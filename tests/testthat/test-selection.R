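test_that("gene-wise (n, x) matches a brute-force scan", {
  track <- data.frame(chrom = "chr1", pos = c(150L, 250L), score = c(-3.2, 1.0))
  iv <- data.frame(gene = "gA", chrom = "chr1", start = 100L, end = 300L,
                   strand = "+")
  out <- gene_max_score(track, iv)
  expect_equal(out$n, 2L)
  expect_equal(out$x, 3.2)

  empty <- data.frame(gene = "gB", chrom = "chr1", start = 5000L, end = 5400L,
                      strand = "+")
  out2 <- gene_max_score(track, empty)
  expect_equal(out2$n, 0L)
  expect_true(is.na(out2$x))

  # 7 SNPs across 3 genes vs a by-hand scan
  track7 <- data.frame(chrom = "chr1",
                       pos = c(120L, 180L, 290L, 1100L, 1400L, 5100L, 5395L),
                       score = c(0.5, -2.1, 1.7, 4.4, -0.2, -1.1, 0.9))
  genes <- toy_genes()
  out3 <- gene_max_score(track7, genes)
  expect_equal(out3$n, c(3L, 2L, 2L))
  expect_equal(out3$x, c(2.1, 4.4, 1.1))
})

test_that("locus mode uses the flank window around the lead SNP", {
  track <- data.frame(chrom = "chr1", pos = c(1000L, 90000L, 250000L),
                      score = c(2, 3, 5))
  iv <- data.frame(gene = "gA", chrom = "chr1", start = 100L, end = 300L,
                   strand = "+", lead_pos = 1000L)
  out <- gene_max_score(track, iv, mode = "locus", flank_bp = 100000L)
  expect_equal(out$n, 2L)   # 1000 and 90000; 250000 outside
  expect_equal(out$x, 3)
})

test_that("max-iHS p-value follows 1 - Phi(x)^n with exact anchors", {
  expect_equal(max_ihs_pvalue(0, 1), 0.5)
  expect_equal(max_ihs_pvalue(qnorm(0.95), 1), 0.05)
  expect_equal(max_ihs_pvalue(2, 1), 1 - pnorm(2))
  # log-space route stays finite and correct at large n
  expect_equal(max_ihs_pvalue(3, 1000), 1 - pnorm(3)^1000, tolerance = 1e-12)
  expect_gt(max_ihs_pvalue(5, 1e6), 0)
  expect_error(max_ihs_pvalue(Inf, 1), "non-finite")
  expect_error(max_ihs_pvalue(1, 0), "positive")
})

test_that("p(x|n) is decreasing in x and increasing in n", {
  xs <- seq(0.5, 4, by = 0.5)
  for (n in c(1L, 10L, 100L)) {
    expect_true(all(diff(max_ihs_pvalue(xs, n)) < 0))
  }
  for (x in c(1, 2, 3)) {
    expect_true(all(diff(max_ihs_pvalue(x, c(1L, 10L, 100L, 1000L))) > 0))
  }
  # folded variant is uniformly stricter (larger p for the same x)
  expect_true(all(max_ihs_pvalue(xs, 10, folded = TRUE) >=
                  max_ihs_pvalue(xs, 10)))
})

test_that("BH flagging matches hand arithmetic and skips n = 0 genes", {
  stats <- data.frame(gene = paste0("g", 1:10),
                      n = c(0L, rep(5L, 9)),
                      x = c(NA, 4.5, rep(1, 8)))
  expect_message(out <- flag_significant(stats, alpha = 0.01), "excluded")
  g <- out$genes
  expect_true(is.na(g$p[1]))
  # hand BH over the 9 tested genes
  raw <- max_ihs_pvalue(g$x[-1], g$n[-1])
  expect_equal(g$p_adj[-1], p.adjust(raw, "BH"))
  expect_true(g$flag[2])             # x = 4.5 over 5 SNPs is tiny
  expect_false(any(g$flag[-c(1, 2)]))

  all1 <- data.frame(gene = paste0("g", 1:5), n = 1L, x = rep(-10, 5))
  expect_false(any(flag_significant(all1)$genes$flag))
})

test_that("hard cutoffs are strict at their boundaries", {
  stats <- data.frame(gene = c("a", "b", "c"), n = c(3L, 3L, 0L),
                      x = c(4.0, 4.1, NA))
  expect_message(f <- flag_hard_cutoff(stats), "without SNPs")
  expect_equal(unname(f), c(FALSE, TRUE, FALSE))

  drc <- data.frame(gene = c("a", "b"), n = 2L, x = c(0.0025, 0.003))
  fd <- flag_drc(drc)
  expect_equal(unname(fd), c(FALSE, TRUE))
})

test_that("combined LOEUF/iHS flag uses strict LOEUF < 0.6", {
  stats <- data.frame(gene = paste0("g", 1:10), n = 10L,
                      x = c(rep(5, 5), rep(0.5, 5)))
  loeuf <- setNames(c(0.5, 0.6, 0.7, 0.5, NA, 0.5, 0.6, 0.1, 0.2, 0.9),
                    stats$gene)
  expect_message(out <- combined_selection_flags(stats, loeuf), "without LOEUF")
  g <- out$genes
  # adj p tiny for the first five genes; LOEUF gates the flag
  expect_true(g$flag[1])                   # 0.5 < 0.6 and significant
  expect_false(g$flag[2])                  # 0.6 exactly -> excluded
  expect_false(g$flag[3])
  expect_true(is.na(g$flag[5]))            # missing LOEUF
  expect_false(any(g$flag[6:10], na.rm = TRUE))  # not significant
})

test_that("length-matched draws reproduce the stated degenerate p", {
  set.seed(60)
  genes <- paste0("g", 1:100)
  lengths <- setNames(seq(1000, 100000, length.out = 100), genes)
  flags <- setNames(rep(FALSE, 100), genes)
  target <- sample(genes, 20)
  flags[target] <- TRUE                     # all flags inside the target
  out <- length_matched_enrichment(flags, target, genes, lengths,
                                   n_draws = 99, seed = 1)
  expect_equal(out$observed, 1)
  expect_equal(out$p, 1 / 100)
})

test_that("every draw preserves the target's length-bin histogram", {
  # flags = indicator of the top length bin; if draws match the target's
  # bin histogram exactly, every null proportion equals the observed one
  set.seed(63)
  genes <- paste0("g", 1:100)
  lengths <- setNames(seq(1000, 100000, length.out = 100), genes)
  br <- quantile(lengths, probs = seq(0, 1, length.out = 6))
  bin <- cut(lengths, breaks = br, include.lowest = TRUE, labels = FALSE)
  flags <- setNames(bin == 5L, genes)
  target <- c(sample(genes[bin == 5L], 8), sample(genes[bin == 2L], 12))
  out <- length_matched_enrichment(flags, target, genes, lengths,
                                   n_draws = 50, n_bins = 5L, seed = 4)
  expect_equal(out$observed, 8 / 20)
  expect_true(all(out$null == out$observed))
  expect_equal(out$p, 1)
})

test_that("length matching removes a pure length artifact", {
  set.seed(61)
  genes <- paste0("g", 1:300)
  lengths <- setNames(exp(rnorm(300, 9, 1)), genes)
  flags <- setNames(lengths >= quantile(lengths, 0.8), genes)  # by length only
  target <- names(sort(lengths, decreasing = TRUE))[1:30]      # longest genes
  out <- length_matched_enrichment(flags, target, genes, lengths,
                                   n_draws = 200, seed = 2)
  expect_gt(out$p, 0.05)
})

test_that("a random target yields a central empirical p", {
  set.seed(62)
  genes <- paste0("g", 1:200)
  lengths <- setNames(runif(200, 1e3, 1e5), genes)
  flags <- setNames(runif(200) < 0.2, genes)
  ps <- vapply(1:7, function(s) {
    set.seed(s + 100)
    target <- sample(genes, 40)
    length_matched_enrichment(flags, target, genes, lengths,
                              n_draws = 200, seed = s)$p
  }, numeric(1))
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
})
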