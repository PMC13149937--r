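#' Quality-control filter for summary statistics
#'
#' Retains autosomal SNPs with minor allele frequency strictly above
#' `maf_min` and position outside the excluded region (1-based inclusive
#' coordinates; by default an MHC-like high-LD region). Row order is
#' preserved and the operation is idempotent.
#'
#' @param stats summary-statistics data.frame (internal layout, see
#'   [read_sumstats()]).
#' @param maf_min strict lower MAF bound (default `1e-5`).
#' @param excluded_region `c(chrom, start, end)` or `NULL`.
#' @param max_autosome chromosomes above this are dropped (non-autosomal).
#' @return filtered data.frame (warns if empty).
#' @export
qc_filter <- function(stats, maf_min = 1e-5, excluded_region = NULL,
                      max_autosome = 22L) {
  keep <- maf_of(stats$eaf) > maf_min & stats$chrom >= 1L & stats$chrom <= max_autosome
  if (!is.null(excluded_region)) {
    in_region <- stats$chrom == excluded_region[1] &
      stats$pos >= excluded_region[2] & stats$pos <= excluded_region[3]
    keep <- keep & !in_region
  }
  out <- stats[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("qc_filter: no SNP passed the filters")
  out
}

#' Select diseases by minimum case count
#'
#' Keeps diseases with strictly more than `min_cases` cases, preserving
#' input order.
#'
#' @param metadata disease metadata data.frame with `disease_id`, `n_case`.
#' @param min_cases strict lower bound (default 1000).
#' @return character vector of disease ids.
#' @export
filter_diseases <- function(metadata, min_cases = 1000) {
  metadata$disease_id[metadata$n_case > min_cases]
}

#' Cross-trait LD-score regression genetic correlation
#'
#' Single-trait heritability scales are estimated as the slope of `z^2` on
#' the LD score (free intercept); the genetic covariance as the slope of
#' `z_a * z_b` on the LD score (free intercept, absorbing sample overlap).
#' Both regressions use the customary two-pass weighting: ordinary least
#' squares gives provisional slopes, and the second pass weights SNP `j` by
#' `1 / (l_j (1 + h2 l_j)^2)` (cross-trait: the product of the two traits'
#' variance factors), countering both LD-induced redundancy and the
#' heteroskedasticity of chi-square outcomes. The genetic correlation is
#' `rg = cov / sqrt(h2_a * h2_b)`; its standard error comes from a
#' delete-one block jackknife over contiguous SNP blocks and the p-value
#' from a two-sided normal approximation of `rg / se`.
#'
#' @param stats_a,stats_b summary-statistics data.frames for the two traits.
#' @param ldscores data.frame `snp_id, l2`.
#' @param n_blocks jackknife block count (default 20).
#' @param chisq_max SNPs with `z^2` above this in either trait are excluded
#'   from the regressions (the usual LD-score-regression guard against
#'   outlier loci dominating the slopes; default 80).
#' @return list `rg, se, p, h2_a, h2_b, n_snps, reason` (`reason` is `NA`
#'   on success, otherwise a code such as `"nonpositive_h2"`, with `rg`
#'   `NaN`).
#' @export
estimate_rg <- function(stats_a, stats_b, ldscores, n_blocks = 20L,
                        chisq_max = 80) {
  common <- intersect(intersect(stats_a$snp_id, stats_b$snp_id), ldscores$snp_id)
  if (length(common) < 200L) {
    stop("estimate_rg: fewer than 200 SNPs shared between traits and LD scores")
  }
  za <- stats_a$z[match(common, stats_a$snp_id)]
  zb <- stats_b$z[match(common, stats_b$snp_id)]
  l2 <- ldscores$l2[match(common, ldscores$snp_id)]
  ok <- za^2 <= chisq_max & zb^2 <= chisq_max
  za <- za[ok]; zb <- zb[ok]; l2 <- l2[ok]
  n <- length(za)

  point <- rg_from_slopes(za, zb, l2)
  if (!is.na(point$reason)) {
    return(list(rg = NaN, se = NA_real_, p = NA_real_, h2_a = point$h2_a,
                h2_b = point$h2_b, n_snps = n, reason = point$reason))
  }
  blk <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  loo <- vapply(seq_len(n_blocks), function(b) {
    keep <- blk != b
    rg_from_slopes(za[keep], zb[keep], l2[keep])$rg
  }, numeric(1))
  loo <- loo[is.finite(loo)]
  B <- length(loo)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  p <- if (se > 0) z_to_p(point$rg / se) else 0
  list(rg = point$rg, se = se, p = p, h2_a = point$h2_a, h2_b = point$h2_b,
       n_snps = n, reason = NA_character_)
}

# Two-pass weighted slopes of z^2 and cross products on LD scores; the rg
# point estimate. Pass 1 is OLS; pass 2 reweights by the implied variance
# of the outcomes.
rg_from_slopes <- function(za, zb, l2) {
  ols <- function(y) {
    x <- l2 - mean(l2)
    sum(x * (y - mean(y))) / sum(x^2)
  }
  wls <- function(y, wt) {
    w <- wt / sum(wt)
    xm <- sum(w * l2); ym <- sum(w * y)
    sum(w * (l2 - xm) * (y - ym)) / sum(w * (l2 - xm)^2)
  }
  s2a <- max(ols(za^2), 0)
  s2b <- max(ols(zb^2), 0)
  h2_a <- wls(za^2, 1 / (l2 * (1 + s2a * l2)^2))
  h2_b <- wls(zb^2, 1 / (l2 * (1 + s2b * l2)^2))
  cov_ab <- wls(za * zb, 1 / (l2 * (1 + s2a * l2) * (1 + s2b * l2)))
  if (!is.finite(h2_a) || !is.finite(h2_b) || h2_a <= 0 || h2_b <= 0) {
    return(list(rg = NaN, h2_a = h2_a, h2_b = h2_b, reason = "nonpositive_h2"))
  }
  list(rg = cov_ab / sqrt(h2_a * h2_b), h2_a = h2_a, h2_b = h2_b,
       reason = NA_character_)
}

#' Pairwise genetic correlations for a set of diseases
#'
#' @param stats_list named list of summary-statistics data.frames.
#' @param ldscores data.frame `snp_id, l2`.
#' @param n_blocks jackknife block count.
#' @return long-format data.frame `dis_a, dis_b, rg, se, p` (one row per
#'   unordered pair).
#' @export
rg_matrix <- function(stats_list, ldscores, n_blocks = 20L) {
  ids <- names(stats_list)
  pairs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    est <- estimate_rg(stats_list[[a]], stats_list[[b]], ldscores, n_blocks)
    data.frame(dis_a = a, dis_b = b, rg = est$rg, se = est$se, p = est$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Disease significance graph from pairwise genetic correlations
#'
#' An undirected simple graph with an edge wherever the genetic-correlation
#' p-value is at most `alpha` (inclusive). Edges carry `neglogp =
#' -log10(p)`.
#'
#' @param rg long-format data.frame from [rg_matrix()] (columns `dis_a,
#'   dis_b, p`).
#' @param alpha significance level (default 0.05).
#' @param diseases optional node set (defaults to all diseases in `rg`).
#' @return an `igraph` graph.
#' @export
build_graph <- function(rg, alpha = 0.05, diseases = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  diseases <- diseases %||% sort(unique(c(rg$dis_a, rg$dis_b)))
  sig <- rg[!is.na(rg$p) & rg$p <= alpha & rg$dis_a != rg$dis_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = sig$dis_a, to = sig$dis_b, neglogp = -log10(sig$p)),
    directed = FALSE,
    vertices = data.frame(name = diseases)
  )
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Maximum fully connected disease cluster (maximum clique)
#'
#' Exact maximum-clique search on the significance graph. Among maximum
#' cliques, ties are broken by (1) the larger sum over clique edges of
#' `-log10(p)` and then (2) lexicographically smallest sorted member list.
#'
#' @param graph an `igraph` graph from [build_graph()] (edge attribute
#'   `neglogp` used for tie-breaking when present).
#' @return list with `diseases` (sorted ids) and `fully_connected = TRUE`.
#' @export
max_fully_connected_cluster <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  cliques <- igraph::largest_cliques(graph)
  members <- lapply(cliques, function(cl) sort(igraph::V(graph)$name[cl]))
  if (length(members) > 1L) {
    has_w <- "neglogp" %in% igraph::edge_attr_names(graph)
    wsum <- vapply(members, function(m) {
      sub <- igraph::induced_subgraph(graph, m)
      if (has_w && igraph::ecount(sub) > 0) sum(igraph::E(sub)$neglogp) else 0
    }, numeric(1))
    members <- members[wsum == max(wsum)]
    keys <- vapply(members, paste, character(1), collapse = ",")
    members <- members[order(keys)]
  }
  list(diseases = members[[1]], fully_connected = TRUE)
}
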