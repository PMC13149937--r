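#' Bonferroni gene-based significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_genes number of genes tested genome-wide (default 20000,
#'   the approximate number of protein-coding genes).
#' @return the per-gene significance threshold `alpha / n_genes`.
#' @export
gene_significance_threshold <- function(alpha = 0.05, n_genes = 20000) {
  alpha / n_genes
}

#' SKAT-O gene test from summary statistics
#'
#' Optimal unified variance-component/burden test on the z-score vector of a
#' gene. For each `rho` on the grid the statistic is
#' `Q_rho = (1 - rho) * sum(w_j^2 z_j^2) + rho * (sum(w_j z_j))^2`; its null
#' distribution under `z ~ N(0, R)` is a mixture of 1-df chi-squares whose
#' weights are the eigenvalues of the weighted LD kernel, evaluated by
#' numerical inversion of the characteristic function ([qform_pvalue()]).
#' The reported p-value is the minimum over the grid corrected by the
#' one-dimensional integration of the omnibus null (the Lee et al. SKAT-O
#' construction). Near-singular LD matrices are ridge-regularised on the
#' diagonal (`1e-6`, retried at `1e-4`).
#'
#' @param z z-score vector of the gene's SNPs.
#' @param R LD correlation matrix (symmetric, unit diagonal).
#' @param w per-SNP weights (default flat).
#' @param rho_grid grid of variance-component/burden mixing proportions.
#' @return list with `p` (omnibus p-value), `p_rho` (per-rho p-values) and
#'   `rho_grid`.
#' @export
skato_test <- function(z, R,
                       w = rep(1, length(z)),
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)) {
  m <- length(z)
  stopifnot(length(w) == m, nrow(R) == m, ncol(R) == m)
  if (length(rho_grid) == 0L) stop("empty rho grid")
  res <- tryCatch(skato_core(z, R, w, rho_grid, ridge = 1e-6),
                  error = function(e) NULL)
  if (is.null(res)) {
    res <- tryCatch(skato_core(z, R, w, rho_grid, ridge = 1e-4),
                    error = function(e) {
                      kappa <- tryCatch(kappa(R), error = function(e2) NA)
                      stop(sprintf(
                        "skato_test: LD matrix numerically singular (condition number %.3g)",
                        kappa), call. = FALSE)
                    })
  }
  res
}

skato_core <- function(z, R, w, rho_grid, ridge) {
  m <- length(z)
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) R <- R + diag(ridge, m)
  rho <- pmin(rho_grid, 0.999)

  u <- w * z
  Sigma <- outer(w, w) * R
  su <- sum(u)
  q_stat <- (1 - rho) * sum(u^2) + rho * su^2

  lam_list <- lapply(rho, function(r) {
    a <- sqrt(1 - r)
    b <- (sqrt(1 - r + m * r) - a) / m
    Ah <- diag(a, m) + matrix(b, m, m)
    K <- Ah %*% Sigma %*% Ah
    lam <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
    # near rho = 1 the kernel is almost rank one; eigenvalues carrying a
    # negligible share of the null mass only destabilise the inversion
    lam[lam > 2e-4 * max(lam)]
  })
  p_rho <- vapply(seq_along(rho), function(i)
    qform_pvalue(q_stat[i], lam_list[[i]])$p, numeric(1))
  names(p_rho) <- as.character(rho_grid)

  if (m == 1L || length(rho) == 1L) {
    return(list(p = min(p_rho), p_rho = p_rho, rho_grid = rho_grid))
  }

  T_min <- min(p_rho)
  q_rho <- vapply(seq_along(rho), function(i)
    liu_quantile(T_min, lam_list[[i]]), numeric(1))

  cvec <- as.vector(Sigma %*% rep(1, m))
  s <- sum(cvec)
  Sigma_t <- Sigma - outer(cvec, cvec) / s
  lam_k <- eigen((Sigma_t + t(Sigma_t)) / 2, symmetric = TRUE,
                 only.values = TRUE)$values
  lam_k <- lam_k[lam_k > 1e-12 * max(lam_k)]
  mu_q <- sum(lam_k)
  var_k <- 2 * sum(lam_k^2)
  var_zeta <- 4 * as.numeric(t(cvec) %*% Sigma_t %*% cvec) / s
  tau <- rho * s + (1 - rho) * sum(cvec^2) / s

  integrand <- function(x) {
    min1 <- apply(outer(-tau, x) + q_rho, 2, function(col) min(col / (1 - rho)))
    out <- numeric(length(x))
    pos <- min1 > 0
    if (any(pos)) {
      shrink <- sqrt(var_k) / sqrt(var_k + var_zeta)
      m_st <- (min1[pos] - mu_q) * shrink + mu_q
      out[pos] <- pmax(0, 1 - liu_tail(m_st, lam_k))
    }
    out * stats::dchisq(x, df = 1)
  }
  p_omni <- tryCatch(
    1 - stats::integrate(integrand, 0, 40, subdivisions = 400L,
                         abs.tol = 1e-10)$value,
    error = function(e) NA_real_)
  if (!is.finite(p_omni) || p_omni <= 0) p_omni <- T_min * length(rho)
  p_omni <- min(max(p_omni, T_min), T_min * length(rho), 1)
  list(p = p_omni, p_rho = p_rho, rho_grid = rho_grid)
}

#' Principal-component gene test from summary statistics
#'
#' Eigendecomposes the LD matrix, keeps the smallest number `k` of leading
#' components whose cumulative eigenvalue share reaches `var_explained`, and
#' tests `T = sum_i (v_i' z)^2 / lambda_i ~ chi^2_k` under the null.
#'
#' @param z z-score vector.
#' @param R LD correlation matrix.
#' @param var_explained minimum cumulative eigenvalue share (default 0.85).
#' @return list with `p`, `k` (components used) and `statistic`.
#' @export
pca_test <- function(z, R, var_explained = 0.85) {
  m <- length(z)
  stopifnot(nrow(R) == m, ncol(R) == m)
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(abs(eg$values), 1)
  if (all(eg$values < tol)) stop("pca_test: all eigenvalues below tolerance")
  share <- cumsum(eg$values) / sum(eg$values)
  k <- which(share >= var_explained)[1]
  k <- max(1L, min(k, sum(eg$values >= tol)))
  proj <- as.vector(t(eg$vectors[, seq_len(k), drop = FALSE]) %*% z)
  stat <- sum(proj^2 / eg$values[seq_len(k)])
  list(p = stats::pchisq(stat, df = k, lower.tail = FALSE), k = k,
       statistic = stat)
}

#' Cauchy combination (ACAT) of p-values
#'
#' Equal-weight Cauchy combination: `T = mean(tan((0.5 - p) * pi))`,
#' combined p `= 0.5 - atan(T) / pi`. Values of exactly 1 are clipped to
#' `1 - 1e-15`; very small inputs use the asymptotic `1 / (p * pi)` tangent
#' to avoid cancellation.
#'
#' @param p_list numeric vector of p-values in `(0, 1]`.
#' @return combined p-value in `(0, 1)`.
#' @export
acat_combine <- function(p_list) {
  p <- as.numeric(p_list)
  if (length(p) == 0L) stop("acat_combine: empty p-value list")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("acat_combine: p-values must lie in (0, 1]")
  }
  p[p == 1] <- 1 - 1e-15
  small <- p < 1e-16
  tanvec <- numeric(length(p))
  tanvec[small] <- 1 / (p[small] * pi)
  tanvec[!small] <- tan((0.5 - p[!small]) * pi)
  T_stat <- mean(tanvec)
  if (T_stat > 1e15) return(1 / (T_stat * pi))
  0.5 - atan(T_stat) / pi
}

# Assemble the (block-diagonal) LD matrix for a set of SNP ids; returns NULL
# if any SNP is absent from every block.
ld_matrix_for <- function(snp_ids, ld) {
  owner <- snp_block_index(ld)
  blk <- owner[snp_ids]
  if (anyNA(blk)) return(NULL)
  m <- length(snp_ids)
  R <- matrix(0, m, m, dimnames = list(snp_ids, snp_ids))
  for (b in unique(blk)) {
    ids <- snp_ids[blk == b]
    R[ids, ids] <- ld$blocks[[b]]$R[ids, ids]
  }
  diag(R) <- 1
  R
}

snp_block_index <- function(ld) {
  idx <- rep(seq_along(ld$blocks),
             vapply(ld$blocks, function(b) length(b$snp_ids), integer(1)))
  names(idx) <- unlist(lapply(ld$blocks, function(b) b$snp_ids))
  idx
}

#' Gene-based association scan across diseases
#'
#' For every protein-coding gene with at least two SNPs with available
#' summary statistics, runs SKAT-O and the principal-component test per
#' disease and combines the two p-values by the Cauchy combination. SNP
#' weights are `dbeta(MAF, a, b)` (flat for the default `(1, 1)`). Genes
#' whose SNPs are not covered by the LD blocks are skipped with a message.
#'
#' @param stats_list named list of QC-filtered summary-statistics tables.
#' @param annotation gene annotation data.frame ([read_annotation()]).
#' @param ld LD bundle ([simulate_ld()] / [read_ld_bundle()]).
#' @param weights_beta beta-distribution shape parameters for MAF weights.
#' @param var_explained PCA cumulative eigenvalue share.
#' @param rho_grid SKAT-O grid.
#' @param threshold gene-level significance threshold (strict `<`).
#' @return data.frame `gene_id, disease_id, n_snps, p_skato, p_pca, p_acat,
#'   significant`.
#' @export
run_gene_scan <- function(stats_list, annotation, ld,
                          weights_beta = c(1, 1),
                          var_explained = 0.85,
                          rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                          threshold = gene_significance_threshold()) {
  stopifnot(all(weights_beta > 0))
  coding <- annotation[annotation$coding == 1L, , drop = FALSE]
  rows <- list()
  for (d in names(stats_list)) {
    st <- stats_list[[d]]
    for (i in seq_len(nrow(coding))) {
      g <- coding[i, ]
      in_gene <- st$chrom == g$chrom & st$pos >= g$tx_start & st$pos <= g$tx_end
      snps <- st$snp_id[in_gene]
      if (length(snps) < 2L) next
      R <- ld_matrix_for(snps, ld)
      if (is.null(R)) {
        message(sprintf("gene scan: %s skipped for %s (SNPs missing from LD blocks)",
                        g$gene_id, d))
        next
      }
      z <- st$z[in_gene]
      w <- stats::dbeta(maf_of(st$eaf[in_gene]), weights_beta[1], weights_beta[2])
      p_sk <- skato_test(z, R, w, rho_grid)$p
      p_pc <- pca_test(z, R, var_explained)$p
      p_ac <- acat_combine(c(p_sk, p_pc))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, disease_id = d, n_snps = length(snps),
        p_skato = p_sk, p_pca = p_pc, p_acat = p_ac,
        significant = p_ac < threshold, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), disease_id = character(0),
                      n_snps = integer(0), p_skato = numeric(0),
                      p_pca = numeric(0), p_acat = numeric(0),
                      significant = logical(0)))
  }
  do.call(rbind, rows)
}

#' Genes significantly associated with at least two diseases
#'
#' @param scan gene-scan data.frame (rows with `significant = TRUE` are
#'   used; a data.frame without that column is taken as already-significant
#'   gene-disease pairs).
#' @param min_diseases minimum disease count (default 2).
#' @return named list mapping gene id to its sorted disease set, ordered by
#'   gene id.
#' @export
find_pleiotropic_genes <- function(scan, min_diseases = 2L) {
  if ("significant" %in% names(scan)) {
    scan <- scan[scan$significant, , drop = FALSE]
  }
  if (nrow(scan) == 0L) return(stats::setNames(list(), character(0)))
  sets <- tapply(scan$disease_id, scan$gene_id,
                 function(x) sort(unique(x)), simplify = FALSE)
  sets <- sets[vapply(sets, length, integer(1)) >= min_diseases]
  sets[order(names(sets))]
}

#' Evidence-based filter of LD gene clusters
#'
#' Pleiotropic genes closer than `window` (boundary-to-boundary) on one
#' chromosome with an identical disease-association pattern form a cluster,
#' within which individual causal genes cannot be prioritised from
#' association signals alone. Within each multi-gene cluster a member is
#' excluded when its external-evidence score is below `score_min` for every
#' disease shared by the whole cluster; singleton clusters pass unfiltered.
#' Missing evidence rows count as score 0.
#'
#' @param pleio_map named list gene -> disease set ([find_pleiotropic_genes()]).
#' @param annotation gene annotation data.frame.
#' @param evidence data.frame `gene_id, disease_id, score`.
#' @param window boundary-to-boundary clustering distance in bp (default 5e5).
#' @param score_min minimal evidence score (strict `<` excludes; default 0.3).
#' @return filtered map, same structure as `pleio_map`.
#' @export
filter_ld_gene_clusters <- function(pleio_map, annotation, evidence,
                                    window = 5e5, score_min = 0.3) {
  if (length(pleio_map) == 0L) return(pleio_map)
  ann <- annotation[match(names(pleio_map), annotation$gene_id), , drop = FALSE]
  ord <- order(ann$chrom, ann$tx_start, ann$gene_id)
  genes <- names(pleio_map)[ord]
  ann <- ann[ord, , drop = FALSE]
  pattern <- vapply(pleio_map[genes], set_key, character(1))

  cluster <- integer(length(genes))
  cid <- 0L
  for (i in seq_along(genes)) {
    new_cluster <- i == 1L ||
      ann$chrom[i] != ann$chrom[i - 1L] ||
      max(0, ann$tx_start[i] - ann$tx_end[i - 1L]) > window ||
      pattern[i] != pattern[i - 1L]
    if (new_cluster) cid <- cid + 1L
    cluster[i] <- cid
  }

  score_of <- function(gene, disease) {
    hit <- evidence$gene_id == gene & evidence$disease_id == disease
    if (any(hit)) evidence$score[hit][1] else 0
  }
  keep <- rep(TRUE, length(genes))
  for (cl in unique(cluster)) {
    members <- which(cluster == cl)
    if (length(members) < 2L) next
    shared <- Reduce(intersect, pleio_map[genes[members]])
    for (i in members) {
      scores <- vapply(shared, function(d) score_of(genes[i], d), numeric(1))
      if (all(scores < score_min)) keep[i] <- FALSE
    }
  }
  out <- pleio_map[genes[keep]]
  out[order(names(out))]
}
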