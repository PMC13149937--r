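#' Configuration for the synthetic multi-disease GWAS generator
#'
#' Builds and validates the configuration object that drives every synthetic
#' input of the pipeline: per-disease summary statistics, block-diagonal LD,
#' gene annotation, variant consequences, external-evidence scores, gene sets
#' and disease metadata. The defaults describe a desk-scale study of six
#' binary diseases over three autosomes, 3,000 SNPs in 60 LD blocks of 50
#' SNPs, one gene per block, four planted pleiotropic genes, a uniform
#' genetic-correlation background of 0.5, and an excluded high-LD region
#' mimicking the MHC.
#'
#' @param n_diseases number of diseases.
#' @param n_chromosomes,blocks_per_chrom,snps_per_block genome layout; blocks
#'   are independent (zero LD between blocks) and laid out 1.2 Mb apart so
#'   that clumping windows never span blocks. The default of 150 blocks of
#'   20 SNPs keeps the number of independent genome segments large enough
#'   for the block-level regression and jackknife estimates.
#' @param ld_decay first-order autoregressive LD parameter in `[0, 1)`:
#'   `cor(z_i, z_j) = ld_decay^|i-j|` within a block. Either a scalar (all
#'   blocks identical) or one value per block; the default spreads decays
#'   evenly over `[0.4, 0.9]` along each chromosome so that LD scores vary
#'   across the genome (LD-score regression needs that spread).
#' @param maf_range minor-allele-frequency range for common variants.
#' @param low_maf_fraction fraction of SNPs drawn with MAF below `1e-5`
#'   (these exercise the MAF filter and are removed by QC).
#' @param n_genes number of annotated genes, spread evenly over the blocks
#'   (at most one gene per block, placed as a centred contiguous run of
#'   `gene_snps` SNPs; the remaining SNPs are intergenic). Every seventh
#'   gene is flagged non-coding.
#' @param gene_snps SNPs per gene.
#' @param planted_genes data.frame with columns `gene_id`, `diseases`
#'   (comma-joined disease ids) and `lambda` (per-SNP noncentrality added to
#'   the z-score mean for the listed diseases). Planted genes must be coding.
#' @param sample_sizes data.frame with `disease_id`, `n_case`, `n_ctrl`.
#' @param rg_target disease-by-disease genetic-correlation matrix of the
#'   polygenic background (symmetric, unit diagonal, positive semidefinite).
#' @param overlap_corr cross-disease correlation of the non-genetic z-score
#'   noise (sample overlap). `NULL` means "equal to `rg_target`", which makes
#'   the marginal cross-disease z correlation match `rg_target` at null SNPs.
#' @param poly_sd per-SNP standard deviation of the polygenic effect
#'   component; 0 switches the polygenic background off (exact null).
#'   Polygenic effects are carried only by blocks without annotated genes,
#'   which keeps the gene-test null exact while leaving the genetic
#'   correlation estimable; the attenuation from inactive blocks cancels in
#'   the rg ratio. The default of 1 concentrates a realistic genome-wide
#'   polygenic signal onto the desk-scale SNP panel.
#' @param mhc_like_region `c(chrom, start, end)` of the excluded region; the
#'   default covers one full block on chromosome 2.
#' @param seed integer seed; the seed fully determines the bundle.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_diseases = 6,
                       n_chromosomes = 3,
                       blocks_per_chrom = 50,
                       snps_per_block = 20,
                       ld_decay = NULL,
                       maf_range = c(0.01, 0.5),
                       low_maf_fraction = 0.02,
                       n_genes = 60,
                       gene_snps = 8,
                       planted_genes = NULL,
                       sample_sizes = NULL,
                       rg_target = NULL,
                       overlap_corr = NULL,
                       poly_sd = 1,
                       mhc_like_region = NULL,
                       seed = 1L) {
  if (snps_per_block <= 0 || blocks_per_chrom <= 0 || n_chromosomes <= 0) {
    stop("invalid config: block/chromosome counts must be positive")
  }
  n_blocks_total <- n_chromosomes * blocks_per_chrom
  if (is.null(ld_decay)) {
    ld_decay <- rep(seq(0.4, 0.9, length.out = blocks_per_chrom), n_chromosomes)
  }
  if (!length(ld_decay) %in% c(1L, n_blocks_total)) {
    stop("invalid config: ld_decay must be scalar or one value per block")
  }
  if (any(ld_decay < 0) || any(ld_decay >= 1)) {
    stop("invalid config: ld_decay must be in [0, 1)")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("invalid config: maf_range must be an interval in (0, 0.5]")
  }
  diseases <- sprintf("D%d", seq_len(n_diseases))
  n_blocks <- n_chromosomes * blocks_per_chrom
  if (n_genes > n_blocks) stop("invalid config: at most one gene per LD block")
  if (gene_snps > snps_per_block) stop("invalid config: gene_snps exceeds block size")

  if (is.null(rg_target)) {
    rg_target <- matrix(0.5, n_diseases, n_diseases)
    diag(rg_target) <- 1
  }
  if (!isSymmetric(unname(rg_target)) || any(abs(diag(rg_target) - 1) > 1e-12)) {
    stop("invalid config: rg_target must be symmetric with unit diagonal")
  }
  if (min(eigen(rg_target, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("invalid config: rg_target must be positive semidefinite")
  }
  if (!is.null(overlap_corr)) {
    if (!isSymmetric(unname(overlap_corr)) ||
        min(eigen(overlap_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("invalid config: overlap_corr must be symmetric positive semidefinite")
    }
  }
  if (is.null(sample_sizes)) {
    n_case <- round(seq(4000, 20000, length.out = n_diseases))
    sample_sizes <- data.frame(disease_id = diseases, n_case = n_case,
                               n_ctrl = 100000 - n_case)
  }
  stopifnot(all(sample_sizes$disease_id == diseases))
  if (is.null(planted_genes)) {
    planted_genes <- default_planted(diseases, n_genes)
  }
  if (is.null(mhc_like_region)) {
    # one full block on chromosome 2 (the 10th block of that chromosome)
    start <- (10 - 1) * 1.2e6 + 1
    mhc_like_region <- c(2, start, start + 2e5)
  }
  cfg <- list(
    n_diseases = n_diseases, diseases = diseases,
    n_chromosomes = n_chromosomes, blocks_per_chrom = blocks_per_chrom,
    snps_per_block = snps_per_block, ld_decay = ld_decay,
    maf_range = maf_range, low_maf_fraction = low_maf_fraction,
    n_genes = n_genes, gene_snps = gene_snps,
    planted_genes = planted_genes, sample_sizes = sample_sizes,
    rg_target = rg_target, overlap_corr = overlap_corr,
    poly_sd = poly_sd, mhc_like_region = mhc_like_region,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  # planted subsets must be subsets of the disease list and name coding genes
  ann <- sim_annotation(cfg)
  for (i in seq_len(nrow(planted_genes))) {
    ds <- split_key(planted_genes$diseases[i])
    if (!all(ds %in% diseases)) stop("invalid config: planted disease subset unknown")
    row <- ann[ann$gene_id == planted_genes$gene_id[i], ]
    if (nrow(row) == 0L) stop("invalid config: planted gene not in annotation")
    if (row$coding != 1L) stop("invalid config: planted genes must be coding")
  }
  cfg
}

# Default planting: four pleiotropic genes on separate blocks/chromosomes,
# with per-SNP noncentrality 3 (single-SNP power >> 0.99 at 5e-8 once LD
# amplification across the 8-SNP run is accounted for).
default_planted <- function(diseases, n_genes) {
  idx <- list(c(1, 2), c(5, 6), c(2, 3, 4), c(1, 4))
  slots <- c(5, 12, 25, 45)
  keep <- which(slots <= n_genes &
                  vapply(idx, function(i) all(i <= length(diseases)), logical(1)))
  data.frame(gene_id = sprintf("G%03d", slots[keep]),
             diseases = vapply(idx[keep], function(i) set_key(diseases[i]),
                               character(1)),
             lambda = 3)
}

# Deterministic genome layout shared by all generator components: SNP ids,
# 1-based positions (2 kb spacing within a block, blocks 1.2 Mb apart).
sim_layout <- function(config) {
  n_blocks <- config$n_chromosomes * config$blocks_per_chrom
  block <- rep(seq_len(n_blocks), each = config$snps_per_block)
  chrom <- (block - 1L) %/% config$blocks_per_chrom + 1L
  block_in_chrom <- (block - 1L) %% config$blocks_per_chrom + 1L
  idx <- rep(seq_len(config$snps_per_block), times = n_blocks)
  pos <- (block_in_chrom - 1L) * 1.2e6 + 1 + (idx - 1L) * 2000
  data.frame(
    snp_id = sprintf("S%05d", seq_along(block)),
    chrom = chrom,
    pos = as.integer(pos),
    block_id = sprintf("B%03d", block),
    idx_in_block = idx,
    stringsAsFactors = FALSE
  )
}

#' Gene annotation of the synthetic genome
#'
#' Genes are spread evenly over the LD blocks (at most one per block), each
#' a centred contiguous run of `gene_snps` SNPs with transcription bounds
#' 500 bp beyond the outermost member SNPs; every seventh gene is
#' non-coding.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with `gene_id`, `symbol`, `chrom`, `tx_start`,
#'   `tx_end`, `coding`.
#' @export
sim_annotation <- function(config) {
  lay <- sim_layout(config)
  n_blocks <- config$n_chromosomes * config$blocks_per_chrom
  ratio <- n_blocks / config$n_genes
  offset <- (config$snps_per_block - config$gene_snps) %/% 2
  out <- lapply(seq_len(config$n_genes), function(g) {
    blk_idx <- floor((g - 0.5) * ratio) + 1
    blk <- lay[lay$block_id == sprintf("B%03d", blk_idx), ]
    run <- blk[seq(offset + 1L, offset + config$gene_snps), ]
    data.frame(gene_id = sprintf("G%03d", g),
               symbol = sprintf("SYM%03d", g),
               chrom = run$chrom[1],
               tx_start = min(run$pos) - 500L,
               tx_end = max(run$pos) + 500L,
               coding = if (g %% 7L == 0L) 0L else 1L)
  })
  do.call(rbind, out)
}

#' Simulate block-diagonal LD and per-SNP LD scores
#'
#' Each block has first-order autoregressive correlation
#' `R[i, j] = ld_decay^|i-j|`; the LD score of a SNP is the sum of squared
#' correlations with all SNPs of its block (blocks are independent).
#'
#' @param config a [sim_config()] object.
#' @return list with `blocks` (list of `list(block_id, chrom, snp_ids, pos,
#'   R)`) and `ldscores` (data.frame `snp_id`, `l2`).
#' @export
simulate_ld <- function(config) {
  if (config$snps_per_block <= 0) stop("invalid config: non-positive block size")
  lay <- sim_layout(config)
  p <- config$snps_per_block
  ids <- unique(lay$block_id)
  decay <- rep_len(config$ld_decay, length(ids))
  dist <- abs(outer(seq_len(p), seq_len(p), "-"))
  blocks <- vector("list", length(ids))
  l2 <- numeric(nrow(lay))
  for (k in seq_along(ids)) {
    rows <- lay[lay$block_id == ids[k], ]
    Rb <- decay[k]^dist
    dimnames(Rb) <- list(rows$snp_id, rows$snp_id)
    blocks[[k]] <- list(block_id = ids[k], chrom = rows$chrom[1],
                        snp_ids = rows$snp_id, pos = rows$pos, R = Rb)
    l2[match(rows$snp_id, lay$snp_id)] <- rowSums(Rb^2)
  }
  list(blocks = blocks, ldscores = data.frame(snp_id = lay$snp_id, l2 = l2))
}

#' Simulate per-disease GWAS summary statistics with planted causal genes
#'
#' Z-scores are generated directly at the summary level (no genotypes). For a
#' block with LD matrix `R`, the disease-`d` z vector is
#' `z_d = R (lambda_d + gamma_d) + eta_d`, where `lambda_d` is the planted
#' noncentrality (nonzero only inside planted genes whose disease subset
#' contains `d`), `gamma_d` is a polygenic effect with per-SNP standard
#' deviation `poly_sd` and cross-disease correlation `rg_target`, and `eta`
#' is multivariate-normal noise with LD structure `R` and cross-disease
#' correlation `overlap_corr`. Betas and standard errors are derived from the
#' allele frequency and the effective case/control sample size
#' (`4 / (1/n_case + 1/n_ctrl)`); p-values are two-sided normal tails.
#'
#' @param config a [sim_config()] object.
#' @param ld output of [simulate_ld()] for the same config.
#' @return list with `stats` (named list of per-disease data.frames with
#'   columns `snp_id, chrom, pos, a1, a2, eaf, beta, se, z, p, n_case,
#'   n_ctrl`) and `truth` (see Details).
#' @details `truth` is a list with `causal_gene_to_diseases` (named list
#'   mapping each planted gene to its disease subset) and `null_pair`
#'   (logical disease-by-disease matrix, `TRUE` where no planted gene is
#'   shared by the pair).
#' @export
simulate_sumstats <- function(config, ld) {
  lay <- sim_layout(config)
  if (length(ld$blocks) * config$snps_per_block != nrow(lay) ||
      any(vapply(ld$blocks, function(b) length(b$snp_ids), 1L) != config$snps_per_block)) {
    stop("dimension error: LD blocks do not match the configured SNP count")
  }
  set.seed(config$seed)
  D <- config$n_diseases
  n_snp <- nrow(lay)

  # minor allele frequencies, with a planted low-frequency tail
  maf <- stats::runif(n_snp, config$maf_range[1], config$maf_range[2])
  low <- stats::runif(n_snp) < config$low_maf_fraction
  maf[low] <- stats::runif(sum(low), 1e-7, 1e-5)
  flip <- stats::runif(n_snp) < 0.5
  eaf <- ifelse(flip, 1 - maf, maf)

  # planted noncentrality per disease
  ann <- sim_annotation(config)
  lambda <- matrix(0, n_snp, D, dimnames = list(lay$snp_id, config$diseases))
  for (i in seq_len(nrow(config$planted_genes))) {
    g <- config$planted_genes[i, ]
    row <- ann[ann$gene_id == g$gene_id, ]
    in_gene <- lay$chrom == row$chrom & lay$pos >= row$tx_start & lay$pos <= row$tx_end
    lambda[in_gene, split_key(g$diseases)] <- g$lambda
  }

  O <- config$overlap_corr %||% config$rg_target
  cholO <- chol(O + diag(1e-10, D))
  cholG <- chol(config$rg_target + diag(1e-10, D))

  # polygenic effects live on blocks without annotated genes, so the null of
  # the gene-level tests is exactly N(0, R); rg remains unbiased because the
  # attenuation cancels between genetic covariance and heritability slopes
  gene_block <- rep(FALSE, length(ld$blocks))
  for (i in seq_along(ld$blocks)) {
    b <- ld$blocks[[i]]
    gene_block[i] <- any(ann$chrom == b$chrom &
                           ann$tx_start <= max(b$pos) &
                           ann$tx_end >= min(b$pos))
  }

  z <- matrix(0, n_snp, D)
  for (i in seq_along(ld$blocks)) {
    b <- ld$blocks[[i]]
    jj <- match(b$snp_ids, lay$snp_id)
    p <- length(jj)
    cholR <- chol(b$R)
    gamma <- if (gene_block[i]) matrix(0, p, D) else
      config$poly_sd * (matrix(stats::rnorm(p * D), p, D) %*% cholG)
    eta <- t(cholR) %*% matrix(stats::rnorm(p * D), p, D) %*% cholO
    z[jj, ] <- b$R %*% (lambda[jj, , drop = FALSE] + gamma) + eta
  }

  stats_list <- lapply(seq_len(D), function(d) {
    ncase <- config$sample_sizes$n_case[d]
    nctrl <- config$sample_sizes$n_ctrl[d]
    se <- 1 / sqrt(effective_n(ncase, nctrl) * 2 * maf * (1 - maf))
    df <- data.frame(
      snp_id = lay$snp_id, chrom = lay$chrom, pos = lay$pos,
      a1 = "A", a2 = "G", eaf = eaf,
      beta = z[, d] * se, se = se, z = z[, d], p = z_to_p(z[, d]),
      n_case = ncase, n_ctrl = nctrl,
      stringsAsFactors = FALSE
    )
    round_trip_numeric(df)
  })
  names(stats_list) <- config$diseases

  planted <- config$planted_genes
  truth_map <- lapply(seq_len(nrow(planted)), function(i) split_key(planted$diseases[i]))
  names(truth_map) <- planted$gene_id
  null_pair <- matrix(TRUE, D, D, dimnames = list(config$diseases, config$diseases))
  for (ds in truth_map) {
    null_pair[ds, ds] <- FALSE
  }
  diag(null_pair) <- FALSE

  list(stats = stats_list,
       truth = list(causal_gene_to_diseases = truth_map, null_pair = null_pair))
}

# Snap numeric columns to their 17-significant-digit text representation so
# the in-memory table and the written/re-read table are bit-identical; z is
# re-derived from the snapped beta and se exactly as the reader does.
round_trip_numeric <- function(df) {
  for (cn in names(df)) {
    if (is.double(df[[cn]])) df[[cn]] <- as.numeric(sprintf("%.17g", df[[cn]]))
  }
  if (all(c("beta", "se", "z") %in% names(df))) df$z <- df$beta / df$se
  df
}

#' Variant-consequence table for the synthetic genome
#'
#' SNPs inside coding genes are assigned `stop_gained`, `missense`,
#' `synonymous` or `other` consequences at fixed rates (0.05 / 0.25 / 0.25 /
#' 0.45); SNPs in non-coding genes are `other`; intergenic SNPs are absent
#' from the table. The first SNP of every planted gene is forced to
#' `missense` so planted signals are visible to the coding-SNP route.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with `snp_id`, `gene_id`, `consequence`.
#' @export
sim_consequences <- function(config) {
  set.seed(config$seed + 101L)
  lay <- sim_layout(config)
  ann <- sim_annotation(config)
  out <- lapply(seq_len(nrow(ann)), function(i) {
    g <- ann[i, ]
    in_gene <- lay$chrom == g$chrom & lay$pos >= g$tx_start & lay$pos <= g$tx_end
    snps <- lay$snp_id[in_gene]
    if (g$coding == 1L) {
      cons <- sample(c("stop_gained", "missense", "synonymous", "other"),
                     length(snps), replace = TRUE,
                     prob = c(0.05, 0.25, 0.25, 0.45))
    } else {
      cons <- rep("other", length(snps))
    }
    data.frame(snp_id = snps, gene_id = g$gene_id, consequence = cons,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  for (gid in config$planted_genes$gene_id) {
    first <- which(out$gene_id == gid)[1]
    out$consequence[first] <- "missense"
  }
  out
}

#' External-evidence scores for gene-disease pairs
#'
#' Emulates an aggregated gene-disease association score in `[0, 1]`:
#' planted gene-disease pairs draw from `U(0.5, 1)`, all remaining pairs
#' from `U(0, 0.5)`.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with `gene_id`, `disease_id`, `score`.
#' @export
sim_evidence <- function(config) {
  set.seed(config$seed + 202L)
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  ev <- expand.grid(gene_id = genes, disease_id = config$diseases,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ev$score <- stats::runif(nrow(ev), 0, 0.5)
  for (i in seq_len(nrow(config$planted_genes))) {
    g <- config$planted_genes[i, ]
    hit <- ev$gene_id == g$gene_id & ev$disease_id %in% split_key(g$diseases)
    ev$score[hit] <- stats::runif(sum(hit), 0.5, 1)
  }
  ev$score <- as.numeric(sprintf("%.17g", ev$score))
  ev[order(ev$gene_id, ev$disease_id), ]
}

#' Synthetic gene sets in GMT structure
#'
#' Ten sets of ten genes; the first set contains all planted genes (an
#' enriched set for the hypergeometric test), the rest are random draws.
#'
#' @param config a [sim_config()] object.
#' @return named list of character vectors of gene ids.
#' @export
sim_gene_sets <- function(config) {
  set.seed(config$seed + 303L)
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  planted <- config$planted_genes$gene_id
  size <- min(10L, max(2L, config$n_genes %/% 3L))
  pad <- sample(setdiff(genes, planted),
                min(max(0, size - length(planted)),
                    config$n_genes - length(planted)))
  sets <- c(list(sort(unique(c(planted, pad)))),
            lapply(2:10, function(i) sort(sample(genes, size))))
  names(sets) <- sprintf("GS%02d", 1:10)
  sets
}

#' Disease metadata table
#'
#' @param config a [sim_config()] object.
#' @return data.frame with `disease_id`, `name`, `category`, `n_case`,
#'   `n_total`.
#' @export
sim_metadata <- function(config) {
  cats <- c("cardiometabolic", "digestive", "respiratory")
  data.frame(
    disease_id = config$diseases,
    name = sprintf("Synthetic disease %d", seq_len(config$n_diseases)),
    category = cats[(seq_len(config$n_diseases) - 1L) %% length(cats) + 1L],
    n_case = config$sample_sizes$n_case,
    n_total = config$sample_sizes$n_case + config$sample_sizes$n_ctrl,
    stringsAsFactors = FALSE
  )
}

#' Write the full synthetic input bundle to disk
#'
#' Deterministically (given the config seed) writes every external-interface
#' file consumed by the pipeline: per-disease SAIGE-like summary-statistic
#' TSVs, per-block LD matrices, LD scores, gene annotation, variant
#' consequences, evidence scores, gene sets (GMT), disease metadata, and the
#' planted ground truth.
#'
#' @param config a [sim_config()] object.
#' @param dir output directory (created if missing).
#' @return (invisibly) the directory path.
#' @export
write_fixture_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  ld <- simulate_ld(config)
  sim <- simulate_sumstats(config, ld)

  for (d in names(sim$stats)) {
    write_sumstats(sim$stats[[d]], file.path(dir, sprintf("sumstats_%s.tsv", d)))
  }
  for (b in ld$blocks) {
    write_ld_block(b, file.path(dir, sprintf("ld_block_%s.tsv", b$block_id)))
  }
  write_tsv17(ld_scores_frame(ld), file.path(dir, "ldscores.tsv"))
  ann <- sim_annotation(config)
  write_tsv17(data.frame(CHR = ann$chrom, TX_START = ann$tx_start,
                         TX_END = ann$tx_end, GENE_ID = ann$gene_id,
                         SYMBOL = ann$symbol, CODING = ann$coding),
              file.path(dir, "genes.tsv"))
  cons <- sim_consequences(config)
  write_tsv17(data.frame(SNPID = cons$snp_id, GENE_ID = cons$gene_id,
                         CONSEQUENCE = cons$consequence),
              file.path(dir, "consequences.tsv"))
  ev <- sim_evidence(config)
  write_tsv17(data.frame(GENE_ID = ev$gene_id, DISEASE_ID = ev$disease_id,
                         SCORE = ev$score),
              file.path(dir, "evidence.tsv"))
  write_gmt(sim_gene_sets(config), file.path(dir, "gene_sets.gmt"))
  md <- sim_metadata(config)
  write_tsv17(data.frame(DISEASE_ID = md$disease_id, NAME = md$name,
                         CATEGORY = md$category, N_case = md$n_case,
                         N_total = md$n_total),
              file.path(dir, "diseases.tsv"))
  truth <- sim$truth$causal_gene_to_diseases
  write_tsv17(data.frame(GENE_ID = names(truth),
                         DISEASES = vapply(truth, set_key, character(1))),
              file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

ld_scores_frame <- function(ld) {
  data.frame(SNPID = ld$ldscores$snp_id,
             L2 = as.numeric(sprintf("%.17g", ld$ldscores$l2)))
}
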