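test_that("quadratic-form tails match closed-form chi-square cases", {
  expect_equal(qform_pvalue(5, c(1, 1))$p, exp(-5 / 2), tolerance = 1e-7)
  expect_equal(qform_pvalue(3.84, 1)$p,
               pchisq(3.84, df = 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(qform_pvalue(7, c(2, 2, 2))$p,
               pchisq(3.5, df = 3, lower.tail = FALSE), tolerance = 1e-7)
  # Monte-Carlo oracle for an uneven mixture
  lambda <- c(2, 1, 0.5)
  set.seed(10)
  draws <- colSums(lambda * matrix(rchisq(3 * 2e5, df = 1), nrow = 3))
  q <- 8
  expect_equal(qform_pvalue(q, lambda)$p, mean(draws > q), tolerance = 0.004)
  # Liu fallback approximates the inversion in the bulk
  expect_equal(pleioscan:::liu_tail(q, lambda), qform_pvalue(q, lambda)$p,
               tolerance = 0.05)
})

test_that("SKAT-O reduces to the single-SNP chi-square test", {
  expect_equal(skato_test(0, matrix(1, 1, 1))$p, 1)
  p <- skato_test(1.959964, matrix(1, 1, 1))$p
  expect_equal(p, 0.05, tolerance = 1e-6)
  # every rho gives the same answer for one SNP
  expect_equal(unname(skato_test(2.5, matrix(1, 1, 1))$p_rho),
               rep(pchisq(2.5^2, 1, lower.tail = FALSE), 8), tolerance = 1e-9)
})

test_that("SKAT component with independent SNPs is the chi-square sum", {
  p <- skato_test(c(1, 2), diag(2), rho_grid = 0)$p
  expect_equal(p, exp(-5 / 2), tolerance = 1e-7)
  # weighted version against a Monte-Carlo oracle
  w <- c(1, 2, 0.5)
  z <- c(1.2, -0.8, 2.1)
  q <- sum(w^2 * z^2)
  set.seed(11)
  draws <- colSums(w^2 * matrix(rchisq(3 * 2e5, df = 1), nrow = 3))
  expect_equal(skato_test(z, diag(3), w = w, rho_grid = 0)$p,
               mean(draws > q), tolerance = 0.005)
})

test_that("SKAT-O omnibus p is bracketed by min-p and Bonferroni over the grid", {
  set.seed(12)
  R <- 0.6^abs(outer(1:6, 1:6, "-"))
  ch <- chol(R)
  for (rep in 1:20) {
    z <- as.vector(t(ch) %*% rnorm(6))
    res <- skato_test(z, R)
    expect_gte(res$p, min(res$p_rho) - 1e-12)
    expect_lte(res$p, min(1, length(res$p_rho) * min(res$p_rho)) + 1e-12)
  }
})

test_that("SKAT-O and PCA are invariant to a global sign flip of z", {
  set.seed(13)
  R <- 0.5^abs(outer(1:5, 1:5, "-"))
  z <- as.vector(t(chol(R)) %*% rnorm(5))
  expect_equal(skato_test(z, R)$p, skato_test(-z, R)$p, tolerance = 1e-10)
  expect_equal(pca_test(z, R)$p, pca_test(-z, R)$p, tolerance = 1e-12)
})

test_that("SKAT-O null distribution is calibrated under LD", {
  set.seed(14)
  R <- 0.7^abs(outer(1:5, 1:5, "-"))
  ch <- chol(R)
  n <- 1500
  pv <- vapply(seq_len(n), function(i) {
    skato_test(as.vector(t(ch) %*% rnorm(5)), R)$p
  }, numeric(1))
  hits <- sum(pv < 0.05)
  ci <- qbinom(c(0.025, 0.975), n, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("PCA test follows the cumulative eigenvalue-share rule", {
  expect_equal(pca_test(c(0, 0), diag(2))$p, 1)
  # 2 SNPs, r = 0.9: eigenvalues (1.9, 0.1), first share 0.95 -> k = 1
  R <- matrix(c(1, 0.9, 0.9, 1), 2)
  z <- c(1.4, 0.6)
  res <- pca_test(R = R, z = z, var_explained = 0.85)
  expect_equal(res$k, 1)
  v1 <- c(1, 1) / sqrt(2)
  stat <- (sum(v1 * z))^2 / 1.9
  expect_equal(res$p, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-10)
  # eigenvalue shares (0.80, 0.133, 0.067): 0.80 < 0.85 <= 0.933 -> k = 2
  shares <- c(0.800, 0.133, 0.067)
  V <- qr.Q(qr(matrix(rnorm(9), 3)))
  M <- V %*% diag(3 * shares) %*% t(V)
  expect_equal(pca_test(c(0.5, 0.2, -0.3), M, var_explained = 0.85)$k, 2)
  expect_error(pca_test(c(1, 1), matrix(0, 2, 2)), "eigenvalues")
})

test_that("Cauchy combination matches its defining formula and properties", {
  expect_equal(acat_combine(c(0.5, 0.5, 0.5)), 0.5, tolerance = 1e-12)
  for (p in c(0.9, 0.5, 0.01, 1e-8)) {
    expect_equal(acat_combine(p), p, tolerance = 1e-9)
  }
  # high-precision evaluation of the stated formula for (0.01, 0.04)
  expected <- 0.5 - atan(mean(tan((0.5 - c(0.01, 0.04)) * pi))) / pi
  expect_equal(acat_combine(c(0.01, 0.04)), expected, tolerance = 1e-12)
  expect_equal(acat_combine(c(0.01, 0.04)), 0.01600759, tolerance = 1e-6)
  # permutation invariance and range
  set.seed(15)
  for (rep in 1:20) {
    ps <- runif(sample(2:6, 1))
    a <- acat_combine(ps)
    expect_equal(a, acat_combine(sample(ps)), tolerance = 1e-12)
    expect_gt(a, 0); expect_lt(a, 1)
  }
  expect_equal(acat_combine(c(1, 1)), 1, tolerance = 1e-9)
  expect_error(acat_combine(numeric(0)), "empty")
  expect_error(acat_combine(c(0.5, 0)), "0, 1")
})

test_that("gene threshold is the Bonferroni correction for 20,000 genes", {
  expect_identical(gene_significance_threshold(), 0.05 / 20000)
  expect_identical(gene_significance_threshold(0.01, 100), 1e-4)
})

test_that("gene scan requires two SNPs, codes significance strictly, finds planted genes", {
  cfg <- tiny_config(
    seed = 50, n_chromosomes = 1, blocks_per_chrom = 4, snps_per_block = 20,
    n_genes = 4, gene_snps = 6, ld_decay = 0.7,
    planted_genes = data.frame(gene_id = "G002", diseases = "D1,D2",
                               lambda = 3))
  ld <- simulate_ld(cfg)
  sim <- simulate_sumstats(cfg, ld)
  ann <- sim_annotation(cfg)
  # restrict one gene to a single SNP by shrinking its bounds
  ann1 <- ann
  ann1$tx_end[1] <- ann1$tx_start[1] + 1L
  st1 <- sim$stats$D1
  g1 <- ann[1, ]
  ann1$tx_start[1] <- st1$pos[st1$pos >= g1$tx_start & st1$pos <= g1$tx_end][1]
  ann1$tx_end[1] <- ann1$tx_start[1]
  scan <- run_gene_scan(sim$stats, ann1, ld)
  expect_false("G001" %in% scan$gene_id)
  expect_true(all(scan$n_snps >= 2))
  expect_true(all(scan$p_acat > 0 & scan$p_acat <= 1))
  # planted gene significant exactly in its planted diseases
  sig <- scan[scan$significant, ]
  expect_setequal(paste(sig$gene_id, sig$disease_id),
                  c("G002 D1", "G002 D2"))
})

test_that("non-coding genes are excluded from the scan", {
  cfg <- tiny_config(seed = 51, n_chromosomes = 1, blocks_per_chrom = 8,
                     snps_per_block = 20, n_genes = 8, gene_snps = 6,
                     ld_decay = 0.5)
  ld <- simulate_ld(cfg)
  sim <- simulate_sumstats(cfg, ld)
  ann <- sim_annotation(cfg)
  expect_true(any(ann$coding == 0L))
  scan <- run_gene_scan(sim$stats, ann, ld)
  expect_false(any(scan$gene_id %in% ann$gene_id[ann$coding == 0L]))
})

test_that("pleiotropic gene selection keeps genes with two or more diseases", {
  scan <- data.frame(
    gene_id = c("G1", "G1", "G2", "G3", "G3", "G3"),
    disease_id = c("A", "B", "A", "A", "B", "C"),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  out <- find_pleiotropic_genes(scan)
  expect_identical(names(out), c("G1", "G3"))
  expect_identical(out$G1, c("A", "B"))
  expect_identical(out$G3, c("A", "C"))
  # counting oracle on random maps
  set.seed(16)
  for (rep in 1:10) {
    n <- 40
    df <- data.frame(gene_id = sample(sprintf("G%02d", 1:10), n, replace = TRUE),
                     disease_id = sample(LETTERS[1:5], n, replace = TRUE),
                     significant = TRUE)
    out <- find_pleiotropic_genes(df)
    for (g in unique(df$gene_id)) {
      nd <- length(unique(df$disease_id[df$gene_id == g]))
      expect_identical(g %in% names(out), nd >= 2)
    }
  }
})

test_that("LD gene-cluster filter drops only unsupported members of clusters", {
  ann <- data.frame(gene_id = c("G1", "G2", "G3"), symbol = c("a", "b", "c"),
                    chrom = c(1L, 1L, 1L),
                    tx_start = c(1e6, 1.62e6, 5e6),
                    tx_end = c(1.1e6, 1.72e6, 5.1e6), coding = 1L)
  # G1-G2 gap is 520 kb -> separate clusters, both kept regardless of scores
  pleio <- list(G1 = c("A", "B"), G2 = c("A", "B"))
  ev0 <- data.frame(gene_id = character(0), disease_id = character(0),
                    score = numeric(0))
  expect_identical(filter_ld_gene_clusters(pleio, ann, ev0), pleio)
  # 2-gene cluster sharing {A, B}: scores (A: 0.5) vs (A: 0.1, B: 0.2)
  ann2 <- ann
  ann2$tx_start[2] <- 1.3e6   # gap 200 kb -> one cluster
  ev <- data.frame(gene_id = c("G1", "G2", "G2"),
                   disease_id = c("A", "A", "B"),
                   score = c(0.5, 0.1, 0.2))
  out <- filter_ld_gene_clusters(pleio, ann2, ev)
  expect_identical(names(out), "G1")
  # different disease patterns never cluster
  pleio2 <- list(G1 = c("A", "B"), G2 = c("A", "C"))
  expect_identical(filter_ld_gene_clusters(pleio2, ann2, ev),
                   pleio2[order(names(pleio2))])
  # singletons always pass
  expect_identical(filter_ld_gene_clusters(list(G3 = c("A", "B")), ann, ev0),
                   list(G3 = c("A", "B")))
})

test_that("cluster filter agrees with a brute-force rule application", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 8
    starts <- sort(sample(seq(1e6, 8e6, by = 1e5), n))
    ann <- data.frame(gene_id = sprintf("G%02d", 1:n), symbol = "s",
                      chrom = 1L, tx_start = starts, tx_end = starts + 5e4,
                      coding = 1L)
    pats <- list(c("A", "B"), c("A", "C"), c("B", "C"))
    pleio <- lapply(seq_len(n), function(i) pats[[sample(3, 1)]])
    names(pleio) <- ann$gene_id
    ev <- expand.grid(gene_id = ann$gene_id, disease_id = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
    ev$score <- runif(nrow(ev))
    out <- filter_ld_gene_clusters(pleio, ann, ev, window = 2e5, score_min = 0.3)
    # oracle: scan sorted genes, chain clusters, apply the rule directly
    keep <- character(0)
    cl <- list(1L)
    for (i in 2:n) {
      prev <- cl[[length(cl)]]
      last <- prev[length(prev)]
      same <- ann$tx_start[i] - ann$tx_end[last] <= 2e5 &&
        identical(pleio[[i]], pleio[[last]])
      if (same) cl[[length(cl)]] <- c(prev, i) else cl[[length(cl) + 1L]] <- i
    }
    for (members in cl) {
      if (length(members) == 1L) { keep <- c(keep, ann$gene_id[members]); next }
      shared <- Reduce(intersect, pleio[members])
      for (i in members) {
        sc <- vapply(shared, function(d) {
          hit <- ev$score[ev$gene_id == ann$gene_id[i] & ev$disease_id == d]
          if (length(hit)) hit[1] else 0
        }, numeric(1))
        if (any(sc >= 0.3)) keep <- c(keep, ann$gene_id[i])
      }
    }
    expect_setequal(names(out), keep)
  }
})
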