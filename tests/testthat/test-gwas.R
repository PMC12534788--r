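mk_stats <- function(variant, chrom, pos, z, trait = "t1", se = 0.1) {
  data.frame(trait = trait, variant = variant, chrom = chrom, pos = pos,
             beta = z * se, se = se, p = 2 * pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

test_that("trait filter is strict at the z threshold and deduplicates", {
  man <- data.frame(trait = c("a", "b"), z_h2 = c(2.33, 2.32),
                    trait_type = "continuous", h2 = c(0.1, 0.1))
  out <- filter_traits(man)
  expect_equal(out$trait, "a")

  dup <- data.frame(trait = c("x__v1", "x__v2", "y__v1"),
                    z_h2 = c(3.0, 4.0, 5.0), trait_type = "continuous",
                    h2 = c(0.1, 0.3, 0.2))
  out2 <- filter_traits(dup)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$h2[startsWith(out2$trait, "x")], 0.3)  # max h2 entry kept

  low <- data.frame(trait = "a", z_h2 = 1.0, trait_type = "continuous", h2 = 0.1)
  expect_error(filter_traits(low), "no traits")
})

test_that("greedy clumping keeps one lead per window and splits chromosomes", {
  s <- mk_stats(c("rs1", "rs2"), "chr1", c(100000L, 110000L), c(8, 7))
  out <- clump_lead_snps(s, p_threshold = 5e-8, window_bp = 250000L)
  expect_equal(out$variant, "rs1")   # smaller p wins

  s2 <- mk_stats(c("rs1", "rs2"), c("chr1", "chr2"), c(100000L, 100000L), c(8, 7))
  expect_equal(nrow(clump_lead_snps(s2)), 2L)

  none <- mk_stats("rs1", "chr1", 100L, 1)
  expect_equal(nrow(clump_lead_snps(none)), 0L)
})

test_that("clumping matches an exhaustive greedy hand trace on 5 SNPs", {
  # positions 1e5, 2e5, 4.6e5, 5e5, 9e5; |z| chosen so p order is rs3 < rs1 < rs5 < rs2 < rs4
  s <- mk_stats(paste0("rs", 1:5), "chr1",
                c(100000L, 200000L, 460000L, 500000L, 900000L),
                c(7.0, 6.0, 7.5, 5.8, 6.5))
  out <- clump_lead_snps(s, p_threshold = 1e-8, window_bp = 250000L)
  # trace: rs3 lead, removes rs2 (260kb? no: |460-200|=260 > 250 stays) and rs4;
  # then rs1 lead removes rs2 (100kb); then rs5 lead.
  expect_equal(out$variant, c("rs3", "rs1", "rs5"))
})

test_that("clumping is idempotent on its own lead set", {
  set.seed(5)
  s <- mk_stats(sprintf("rs%03d", 1:200), "chr1",
                sort(sample.int(5e6, 200)), rnorm(200, 0, 3))
  leads <- clump_lead_snps(s, p_threshold = 0.05, window_bp = 100000L)
  again <- clump_lead_snps(leads, p_threshold = 0.05, window_bp = 100000L)
  expect_equal(again$variant, leads$variant)
})

test_that("closest gene: inside = 0, ties break lexicographically", {
  genes <- toy_genes()
  inside <- data.frame(chrom = "chr1", pos = 150L)
  out <- closest_gene(inside, genes)
  expect_equal(out$gene, "geneA")
  expect_equal(out$distance, 0)

  # geneA ends at 300, geneB starts at 1000; pos 650 equidistant (350/350)
  tie <- data.frame(chrom = "chr1", pos = 650L)
  out2 <- closest_gene(tie, genes)
  expect_equal(out2$distance, 350)
  expect_equal(out2$gene, "geneA")   # lexicographic tie rule

  # brute force over all genes for an off-center SNP
  snp <- data.frame(chrom = "chr1", pos = 4000L)
  d <- pmin(abs(4000 - genes$start), abs(4000 - genes$end))
  expect_equal(closest_gene(snp, genes)$gene, genes$gene[which.min(d)])
  expect_message(closest_gene(data.frame(chrom = "chrX", pos = 1L), genes),
                 "unassigned")
})

test_that("window gene retrieval matches brute-force overlap", {
  genes <- data.frame(
    gene = paste0("g", 1:6), chrom = "chr1",
    start = c(0L, 5000L, 20000L, 120000L, 199999L, 400000L),
    end = c(1000L, 6000L, 30000L, 130000L, 210000L, 401000L), strand = "+"
  )
  lead <- data.frame(chrom = "chr1", pos = 100000L)
  hit <- window_genes(lead, genes, flank_bp = 100000L)[[1]]
  # brute force: 1-based gene span [start+1, end] vs [pos-flank, pos+flank]
  manual <- genes$gene[(genes$start + 1) <= 200000 & genes$end >= 0]
  expect_setequal(hit, manual)
  expect_true("g5" %in% hit)    # overlap at a single bp (200000)
  expect_false("g6" %in% hit)   # just outside
})

test_that("reconstituted r_p handles exact, negated and simulated correlation", {
  set.seed(9)
  z <- rnorm(200)
  a <- mk_stats(sprintf("rs%03d", 1:200), "chr1", 1:200, z)
  expect_equal(reconstituted_rp(a, a)$r_p, 1)
  b <- a; b$beta <- -b$beta
  expect_equal(reconstituted_rp(a, b)$r_p, -1)

  # Monte-Carlo oracle: bivariate normal with rho = 0.6, 10k variants
  set.seed(10)
  n <- 10000
  z1 <- rnorm(n); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  sa <- mk_stats(sprintf("v%05d", 1:n), "chr1", 1:n, z1)
  sb <- mk_stats(sprintf("v%05d", 1:n), "chr1", 1:n, z2, trait = "t2")
  est <- reconstituted_rp(sa, sb)
  expect_lt(abs(est$r_p - 0.6), 0.05)
  # symmetry
  expect_equal(est$r_p, reconstituted_rp(sb, sa)$r_p)
})

test_that("too few shared null variants yields NA with the pair logged", {
  a <- mk_stats(paste0("rs", 1:10), "chr1", 1:10, rnorm(10))
  expect_message(est <- reconstituted_rp(a, a, min_shared = 50L), "NA")
  expect_true(is.na(est$r_p))
})

test_that("trait clustering recovers planted blocks and splits unrelated traits", {
  tr <- paste0("t", 1:4)
  d <- matrix(0.9, 4, 4, dimnames = list(tr, tr)); diag(d) <- 0
  d[1:2, 1:2] <- 0.1; d[3:4, 3:4] <- 0.1; diag(d) <- 0
  cl <- cluster_traits(d, cut_height = 0.5)
  expect_equal(cl[["t1"]], cl[["t2"]])
  expect_equal(cl[["t3"]], cl[["t4"]])
  expect_false(cl[["t1"]] == cl[["t3"]])

  # r_p = 1 pair joins at any positive cut
  d2 <- matrix(c(0, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(cluster_traits(d2, cut_height = 0.01)), c(1L, 1L))

  # all-distance-1: every trait its own cluster at cut 0.5
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3])); diag(d3) <- 0
  expect_equal(length(unique(cluster_traits(d3, cut_height = 0.5))), 3L)

  d_bad <- d3; d_bad[1, 2] <- 0.2
  expect_error(cluster_traits(d_bad), "symmetric")
})

test_that("block dendrogram cut is exact on 8 traits (exhaustive check)", {
  tr <- paste0("t", 1:8)
  blocks <- rep(1:2, each = 4)
  d <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.1, 0.9))
  diag(d) <- 0; dimnames(d) <- list(tr, tr)
  cl <- cluster_traits(d, cut_height = 0.5)
  expect_equal(adjusted_rand_index(cl, blocks), 1)
})

test_that("gene-cluster matrix counts clusters, not traits", {
  clusters <- c(t1 = 1L, t2 = 1L, t3 = 1L, t4 = 2L)
  hits <- data.frame(trait = c("t1", "t2", "t3"), gene = "g1")
  m <- gene_cluster_matrix(hits, clusters)
  expect_equal(unname(rowSums(m)["g1"]), 1L)   # 3 traits, one cluster

  hits2 <- data.frame(trait = c("t1", "t4"), gene = "g1")
  m2 <- gene_cluster_matrix(hits2, clusters)
  expect_equal(unname(rowSums(m2)["g1"]), 2L)

  m3 <- gene_cluster_matrix(hits[0, ], clusters)
  expect_equal(nrow(m3), 0L)
})

test_that("merging two traits of one cluster never raises a gene's degree", {
  set.seed(12)
  traits <- paste0("t", 1:6)
  hits <- data.frame(trait = sample(traits, 30, replace = TRUE),
                     gene = sample(paste0("g", 1:8), 30, replace = TRUE))
  fine <- setNames(1:6, traits)                 # every trait its own cluster
  merged <- fine; merged[["t2"]] <- merged[["t1"]]  # merge t2 into t1
  d_fine <- rowSums(gene_cluster_matrix(hits, fine))
  d_merge <- rowSums(gene_cluster_matrix(hits, merged))
  expect_true(all(d_merge[names(d_fine)] <= d_fine))
})
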