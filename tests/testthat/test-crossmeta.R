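test_that("subset search maximizes the standardized combined statistic", {
  # 3 traits, z = (3, 3, -1), equal weights: the positive pair beats the
  # sign-flipped triple: 6/sqrt(2) = 4.243 > 7/sqrt(3) = 4.041
  w <- c(1, 1, 1)
  null <- subset_null_sample(w, n_null = 2000, prefilter_p = 0.999)
  res <- subset_meta(c(3, 3, -1), null)
  expect_identical(sort(res$best_subset), c(1L, 2L))
  expect_equal(res$subset_z, 6 / sqrt(2), tolerance = 1e-12)
  # single retained trait
  null1 <- subset_null_sample(c(1, 1, 1), n_null = 2000, prefilter_p = 0.1)
  res1 <- subset_meta(c(6, 0.1, -0.2), null1)
  expect_identical(res1$best_subset, 1L)
  expect_equal(res1$subset_z, 6)
  expect_equal(res1$n_sig_traits, 1L)
  # no trait passes the prefilter
  expect_null(subset_meta(c(0.1, 0.2, -0.3), null1))
})

test_that("chosen subset matches exhaustive sign/subset enumeration", {
  set.seed(30)
  for (rep in 1:30) {
    k <- sample(2:6, 1)
    w <- runif(k, 0.5, 2)
    z <- rnorm(k, sd = 2)
    null <- subset_null_sample(w, n_null = 1000, prefilter_p = 0.999)
    res <- subset_meta(z, null, max_traits = 12L)
    orc <- oracle_best_subset(z, w)
    expect_equal(res$subset_z, orc$stat, tolerance = 1e-10)
    expect_identical(sort(res$best_subset), sort(orc$subset))
  }
})

test_that("meta p-value is multiplicity-adjusted yet above the raw tail", {
  set.seed(31)
  w <- rep(1, 4)
  null <- subset_null_sample(w, n_null = 5e4, prefilter_p = 0.1)
  for (rep in 1:20) {
    z <- rnorm(4, sd = 1.8)
    res <- subset_meta(z, null)
    if (is.null(res)) next
    expect_gte(res$p_meta, 2 * pnorm(-res$subset_z) - 1e-12)
    expect_lte(res$p_meta, 1)
  }
  # strong signal reaches genome-wide depth through the tail extrapolation
  res_big <- subset_meta(c(9, 8.5, 0, 0), null)
  expect_lt(res_big$p_meta, 5e-8)
})

test_that("null meta p-values are uniform (conditional on entering the search)", {
  set.seed(32)
  w <- rep(1, 5)
  null <- subset_null_sample(w, n_null = 5e4, prefilter_p = 0.1)
  pvals <- c()
  for (i in 1:4000) {
    res <- subset_meta(rnorm(5), null)
    if (!is.null(res)) pvals <- c(pvals, res$p_meta)
  }
  expect_gt(length(pvals), 1000)
  # p-values are discrete at the Monte-Carlo resolution; ties are expected
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clumping follows PLINK greedy semantics", {
  cfg <- tiny_config(seed = 70, n_chromosomes = 1, blocks_per_chrom = 2,
                     snps_per_block = 10, n_genes = 2, gene_snps = 4,
                     ld_decay = 0.8)
  ld <- simulate_ld(cfg)
  r2f <- function(a, b) pleioscan:::ld_r2(a, b, ld)
  # one significant SNP, no neighbours below p2
  meta1 <- data.frame(snp_id = c("S00001", "S00005"), chrom = 1L,
                      pos = c(1L, 8001L), p_meta = c(1e-10, 0.5))
  cl1 <- clump(meta1, ld)
  expect_equal(nrow(cl1), 1)
  expect_identical(cl1$members, "S00001")
  # two linked SNPs: single clump indexed by the smaller p
  meta2 <- data.frame(snp_id = c("S00002", "S00003"), chrom = 1L,
                      pos = c(2001L, 4001L), p_meta = c(1e-9, 1e-10))
  cl2 <- clump(meta2, ld)
  expect_equal(nrow(cl2), 1)
  expect_identical(cl2$index_snp, "S00003")
  expect_identical(cl2$members, "S00002,S00003")
  # randomized regions against the independent greedy oracle
  set.seed(71)
  all_snps <- unlist(lapply(ld$blocks, function(b) b$snp_ids))
  pos_of <- unlist(lapply(ld$blocks, function(b) b$pos))
  for (rep in 1:100) {
    n <- 12
    pick <- sort(sample(seq_along(all_snps), n))
    meta <- data.frame(snp_id = all_snps[pick], chrom = 1L,
                       pos = pos_of[pick],
                       p_meta = 10^runif(n, -12, -3))
    got <- clump(meta, ld, kb = 50)
    orc <- oracle_clump(meta, r2f, p1 = 5e-8, p2 = 1e-5, r2 = 0.1, kb = 50)
    expect_equal(nrow(got), length(orc))
    for (i in seq_along(orc)) {
      expect_identical(got$index_snp[i], orc[[i]]$index)
      expect_identical(got$members[i], paste(orc[[i]]$members, collapse = ","))
    }
    # indexes mutually unlinked; members satisfy the joining predicate
    if (nrow(got) >= 2) {
      for (i in 1:(nrow(got) - 1)) for (j in (i + 1):nrow(got)) {
        linked <- r2f(got$index_snp[i], got$index_snp[j]) >= 0.1 &&
          abs(got$pos[i] - got$pos[j]) <= 50 * 1000
        expect_false(linked)
      }
    }
  }
})

test_that("locus merging applies the window and decision cascade", {
  base <- data.frame(index_snp = c("A", "B"), chrom = 1L,
                     pos = c(1e6, 1.600001e6 + 1), p_meta = c(1e-9, 1e-12),
                     genes = "", n_traits = 2L, start = c(9e5, 1.59e6),
                     end = c(1.1e6, 1.7e6), members = c("A", "B"),
                     traits = c("D1,D2", "D2,D3"), stringsAsFactors = FALSE)
  # 600,001 bp apart: unchanged
  expect_equal(nrow(merge_loci(base)), 2)
  # ratio >= 10 forces the smaller p
  m2 <- base
  m2$pos <- c(1e6, 1.3e6)
  out2 <- merge_loci(m2)
  expect_equal(nrow(out2), 1)
  expect_identical(out2$index_snp, "B")
  expect_identical(out2$traits, "D1,D2,D3")
  expect_equal(out2$start, 9e5)
  expect_equal(out2$end, 1.7e6)
  # comparable p (ratio < 10): the in-gene SNP wins despite larger p
  m3 <- base
  m3$pos <- c(1e6, 1.3e6)
  m3$p_meta <- c(5e-10, 2e-10)
  m3$genes <- c("GX", "")
  out3 <- merge_loci(m3)
  expect_identical(out3$index_snp, "A")
  # same gene: smallest p wins even when comparable
  m4 <- m3
  m4$genes <- c("GX", "GX")
  expect_identical(merge_loci(m4)$index_snp, "B")
  # comparable, neither in a gene: larger trait count wins
  m5 <- base
  m5$pos <- c(1e6, 1.3e6)
  m5$p_meta <- c(5e-10, 2e-10)
  m5$n_traits <- c(4L, 2L)
  expect_identical(merge_loci(m5)$index_snp, "A")
})

test_that("locus merging matches an independent cascade re-implementation", {
  for (rep in 1:200) {
    df <- make_loci_df(n = sample(3:8, 1), seed = 9000 + rep)
    got <- merge_loci(df)
    orc <- oracle_merge(df)
    expect_identical(got$index_snp, orc$index_snp)
    expect_identical(got$pos, orc$pos)
    # idempotence and final spacing
    expect_identical(merge_loci(got)$index_snp, got$index_snp)
    if (nrow(got) >= 2) {
      expect_true(all(diff(got$pos) > 5e5))
    }
  }
})

test_that("gene assignment prefers containing gene, then nearest within bounds", {
  ann <- data.frame(
    gene_id = c("G1", "G2", "G3"), symbol = "s", chrom = 1L,
    tx_start = c(1e6, 1.02e6, 2e6), tx_end = c(1.1e6, 1.05e6, 2.1e6),
    coding = 1L)
  # index inside G1 and G2: smaller span wins
  loc <- list(chrom = 1L, pos = 1.03e6, start = 9e5, end = 2.2e6)
  expect_identical(assign_gene(loc, ann), "G2")
  # intergenic: gene ending 10 kb left beats gene starting 50 kb right
  loc2 <- list(chrom = 1L, pos = 1.11e6, start = 9e5, end = 2.2e6)
  expect_identical(assign_gene(loc2, ann), "G1")
  # no gene overlapping the locus bounds
  loc3 <- list(chrom = 1L, pos = 5e6, start = 4.9e6, end = 5.1e6)
  expect_true(is.na(assign_gene(loc3, ann)))
})

test_that("meta scan + clump + merge recover a planted locus end to end", {
  cfg <- tiny_config(
    seed = 72, n_chromosomes = 1, blocks_per_chrom = 5, snps_per_block = 20,
    n_genes = 5, gene_snps = 8, ld_decay = 0.7,
    planted_genes = data.frame(gene_id = "G003", diseases = "D1,D2",
                               lambda = 3))
  ld <- simulate_ld(cfg)
  sim <- simulate_sumstats(cfg, ld)
  set.seed(1)
  meta <- run_meta_scan(sim$stats, n_null = 2e4)
  clumps <- clump(meta, ld)
  loci <- merge_loci(loci_from_clumps(clumps, meta, sim_annotation(cfg)))
  ann <- sim_annotation(cfg)
  g <- ann[ann$gene_id == "G003", ]
  in_region <- loci$pos >= g$tx_start - 2e5 & loci$pos <= g$tx_end + 2e5
  expect_equal(sum(in_region), 1)
  expect_true(all(c("D1", "D2") %in% strsplit(loci$traits[in_region], ",")[[1]]))
  expect_identical(assign_gene(loci[in_region, ], ann), "G003")
})
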