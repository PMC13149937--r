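# Subset-based cross-trait meta-analysis with Monte-Carlo multiplicity
# adjustment, PLINK-1.9 clumping semantics, locus merging and gene
# assignment.

# Enumerate the best trait subset for one z vector. Traits enter with their
# absolute z (per-trait signs are flipped to allow opposite-direction
# subsets), so Z(S) = sum_{k in S} w_k |z_k| / sqrt(sum_{k in S} w_k^2).
best_subset_search <- function(z, w, retained) {
  k <- which(retained)
  best <- list(stat = -Inf, subset = integer(0))
  a <- w[k] * abs(z[k])
  b <- w[k]^2
  n <- length(k)
  for (mask in seq_len(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    stat <- sum(a[sel]) / sqrt(sum(b[sel]))
    if (stat > best$stat) best <- list(stat = stat, subset = k[sel])
  }
  best
}

# Max-over-subsets statistic for a matrix of null draws (rows = draws).
# Entries failing the prefilter contribute zero numerator, which never helps
# a subset, so the row maximum equals the maximum over passing-trait subsets.
null_max_stats <- function(Z, w, z_pre, chunk = 5000L) {
  K <- ncol(Z)
  masks <- seq_len(2^K - 1L)
  M <- t(vapply(masks, function(m) as.numeric(bitwAnd(m, 2^(seq_len(K) - 1L)) > 0L),
                numeric(K)))
  denom <- sqrt(as.vector(M %*% w^2))
  out <- numeric(nrow(Z))
  for (beg in seq(1L, nrow(Z), by = chunk)) {
    idx <- beg:min(beg + chunk - 1L, nrow(Z))
    A <- abs(Z[idx, , drop = FALSE])
    A[A <= z_pre] <- 0
    A <- sweep(A, 2, w, `*`)
    S <- A %*% t(M)
    S <- sweep(S, 2, denom, `/`)
    out[idx] <- do.call(pmax, as.data.frame(S))
  }
  out
}

#' Null reference sample for the subset meta-analysis statistic
#'
#' Draws the max-over-subsets statistic under the null (independent traits
#' by default, or a given correlation matrix), replicating the single-trait
#' prefilter. Draws in which no trait passes the prefilter are discarded, so
#' the sample is the conditional null of SNPs that enter the search. A
#' calibrated effective-number-of-tests extrapolation is attached for tail
#' p-values beyond the Monte-Carlo resolution.
#'
#' @param weights per-trait meta-analysis weights.
#' @param n_null number of null draws (default 1e5).
#' @param prefilter_p single-trait inclusion threshold (default 0.1).
#' @param corr optional trait correlation matrix of the null (identity when
#'   `NULL`).
#' @param tail_k exceedance count at which the tail extrapolation takes over.
#' @return object of class `subset_null` used by [subset_meta()].
#' @export
subset_null_sample <- function(weights, n_null = 1e5, prefilter_p = 0.1,
                               corr = NULL, tail_k = 50L) {
  K <- length(weights)
  z_pre <- stats::qnorm(1 - prefilter_p / 2)
  Z <- matrix(stats::rnorm(n_null * K), n_null, K)
  if (!is.null(corr)) Z <- Z %*% chol(corr)
  stats <- null_max_stats(Z, weights, z_pre)
  stats <- sort(stats[stats > 0])
  B <- length(stats)
  if (B < 20L) stop("subset_null_sample: too few conditional null draws")
  tail_k <- min(tail_k, B %/% 2L)
  q_tail <- stats[B - tail_k + 1L]
  n_eff <- max(1, (tail_k / B) / (2 * stats::pnorm(-q_tail)))
  structure(list(stats = stats, weights = weights, prefilter_p = prefilter_p,
                 n_eff = n_eff, tail_k = tail_k),
            class = "subset_null")
}

#' Subset-based cross-trait meta-analysis of one SNP
#'
#' Retains traits with single-trait two-sided p below `prefilter_p` (capped
#' at `max_traits`, keeping the smallest p-values), exhaustively searches all
#' nonempty subsets of retained traits for the maximal standardized combined
#' statistic `Z(S) = |sum s_k w_k z_k| / sqrt(sum w_k^2)` (per-trait signs
#' `s_k` allow opposite-direction effects), and converts the maximum to a
#' multiplicity-adjusted p-value against the Monte-Carlo null of
#' [subset_null_sample()]. In the extreme tail beyond the Monte-Carlo
#' resolution, a calibrated effective-number-of-tests normal-tail
#' extrapolation is used; the reported p never falls below the unadjusted
#' tail of the best subset.
#'
#' @param z per-trait z-scores of the SNP.
#' @param null a `subset_null` object (its weights and prefilter are used).
#' @param max_traits cap on retained traits (default 10).
#' @param sig_p single-trait threshold defining `n_sig_traits` (default 5e-8).
#' @return `NULL` when no trait passes the prefilter, else a list with
#'   `p_meta`, `best_subset` (indices), `subset_z`, `n_sig_traits`.
#' @export
subset_meta <- function(z, null, max_traits = 10L, sig_p = 5e-8) {
  w <- null$weights
  stopifnot(length(z) == length(w))
  z_pre <- stats::qnorm(1 - null$prefilter_p / 2)
  retained <- abs(z) > z_pre
  if (!any(retained)) return(NULL)
  if (sum(retained) > max_traits) {
    keep <- order(abs(z), decreasing = TRUE)[seq_len(max_traits)]
    message(sprintf("subset_meta: %d traits pass the prefilter, keeping the %d smallest p-values",
                    sum(retained), max_traits))
    retained <- seq_along(z) %in% keep & retained
  }
  best <- best_subset_search(z, w, retained)

  ns <- null$stats
  B <- length(ns)
  exc <- B - findInterval(best$stat, ns)
  p_mc <- (1 + exc) / (B + 1)
  p_raw <- 2 * stats::pnorm(-best$stat)
  p <- if (exc >= null$tail_k) p_mc else min(p_mc, null$n_eff * p_raw)
  p <- min(1, max(p, p_raw))

  list(p_meta = p,
       best_subset = best$subset,
       subset_z = best$stat,
       n_sig_traits = sum(z_to_p(z[best$subset]) < sig_p))
}

#' Genome-wide subset meta-analysis scan
#'
#' Runs [subset_meta()] for every SNP present in all disease tables, using
#' sqrt-effective-sample-size weights and a single shared null reference
#' sample (common random numbers across SNPs).
#'
#' @param stats_list named list of QC-filtered summary-statistics tables.
#' @param prefilter_p single-trait inclusion threshold (default 0.1).
#' @param n_null Monte-Carlo null size (default 1e5).
#' @param null_corr optional trait correlation of the null sampler.
#' @param max_traits cap on retained traits.
#' @param weights optional per-trait weights (default `sqrt` effective n).
#' @return data.frame `snp_id, chrom, pos, p_meta, subset, subset_z,
#'   n_sig_traits` (SNPs with no trait passing the prefilter are absent).
#' @export
run_meta_scan <- function(stats_list, prefilter_p = 0.1, n_null = 1e5,
                          null_corr = NULL, max_traits = 10L, weights = NULL) {
  ids <- Reduce(intersect, lapply(stats_list, function(s) s$snp_id))
  K <- length(stats_list)
  if (is.null(weights)) {
    weights <- vapply(stats_list, function(s)
      sqrt(effective_n(s$n_case[1], s$n_ctrl[1])), numeric(1))
  }
  weights <- weights / max(weights)
  null <- subset_null_sample(weights, n_null = n_null,
                             prefilter_p = prefilter_p, corr = null_corr)
  Z <- vapply(stats_list, function(s) s$z[match(ids, s$snp_id)],
              numeric(length(ids)))
  ref <- stats_list[[1]]
  pos <- ref$pos[match(ids, ref$snp_id)]
  chrom <- ref$chrom[match(ids, ref$snp_id)]
  traits <- names(stats_list)

  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    res <- subset_meta(Z[i, ], null, max_traits = max_traits)
    if (is.null(res)) next
    rows[[i]] <- data.frame(
      snp_id = ids[i], chrom = chrom[i], pos = pos[i],
      p_meta = res$p_meta, subset = set_key(traits[res$best_subset]),
      subset_z = res$subset_z, n_sig_traits = res$n_sig_traits,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(snp_id = character(0), chrom = integer(0),
                      pos = integer(0), p_meta = numeric(0),
                      subset = character(0), subset_z = numeric(0),
                      n_sig_traits = integer(0)))
  }
  do.call(rbind, rows)
}

# Squared LD correlation of two SNPs; zero when they sit in different blocks.
ld_r2 <- function(snp_a, snp_b, ld, owner = snp_block_index(ld)) {
  ba <- owner[snp_a]; bb <- owner[snp_b]
  if (is.na(ba) || is.na(bb) || ba != bb) return(0)
  ld$blocks[[ba]]$R[snp_a, snp_b]^2
}

#' Greedy clumping with PLINK-1.9 semantics
#'
#' Candidate index SNPs (`p < p1`) are processed in ascending p order; each
#' still-unassigned SNP with `p < p2`, within `kb` kilobases of the index on
#' the same chromosome and with LD `r^2 >= r2`, joins the index's clump.
#' Assigned SNPs can neither seed nor join later clumps.
#'
#' @param meta data.frame with `snp_id, chrom, pos, p_meta`.
#' @param ld LD bundle (blocks are independent, so cross-block `r^2` is 0).
#' @param p1 index significance threshold (default 5e-8).
#' @param p2 member significance threshold (default 1e-5).
#' @param r2 LD threshold (default 0.1).
#' @param kb distance window in kilobases (default 1000).
#' @return data.frame `index_snp, chrom, pos, p_meta, n_members, members`.
#' @export
clump <- function(meta, ld, p1 = 5e-8, p2 = 1e-5, r2 = 0.1, kb = 1000) {
  owner <- snp_block_index(ld)
  cand <- meta[meta$p_meta < p1, , drop = FALSE]
  cand <- cand[order(cand$p_meta, cand$chrom, cand$pos), , drop = FALSE]
  pool <- meta[meta$p_meta < p2, , drop = FALSE]
  assigned <- stats::setNames(rep(FALSE, nrow(pool)), pool$snp_id)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    idx <- cand[i, ]
    if (assigned[idx$snp_id]) next
    near <- !assigned & pool$chrom == idx$chrom &
      abs(pool$pos - idx$pos) <= kb * 1000
    members <- pool$snp_id[near]
    members <- members[vapply(members, function(s)
      ld_r2(idx$snp_id, s, ld, owner) >= r2, logical(1))]
    assigned[members] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      index_snp = idx$snp_id, chrom = idx$chrom, pos = idx$pos,
      p_meta = idx$p_meta, n_members = length(members),
      members = paste(sort(members), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(index_snp = character(0), chrom = integer(0),
                      pos = integer(0), p_meta = numeric(0),
                      n_members = integer(0), members = character(0)))
  }
  do.call(rbind, out)
}

#' Build locus records from clumps
#'
#' Locus bounds are the min/max positions of member SNPs; the locus trait
#' set is the union of best subsets over genome-wide significant members;
#' `genes` lists the genes whose transcription bounds contain the index SNP.
#'
#' @param clumps output of [clump()].
#' @param meta meta-scan data.frame (for member positions and subsets).
#' @param annotation gene annotation data.frame.
#' @param sig_p member significance for the trait union (default 5e-8).
#' @return data.frame `index_snp, chrom, pos, p_meta, n_traits, genes,
#'   start, end, members, traits`.
#' @export
loci_from_clumps <- function(clumps, meta, annotation, sig_p = 5e-8) {
  rows <- lapply(seq_len(nrow(clumps)), function(i) {
    cl <- clumps[i, ]
    members <- split_key(cl$members)
    mrows <- meta[meta$snp_id %in% members, , drop = FALSE]
    sig <- mrows[mrows$p_meta < sig_p, , drop = FALSE]
    traits <- sort(unique(unlist(lapply(sig$subset, split_key))))
    g <- annotation[annotation$chrom == cl$chrom &
                      annotation$tx_start <= cl$pos &
                      annotation$tx_end >= cl$pos, , drop = FALSE]
    irow <- meta[meta$snp_id == cl$index_snp, ]
    data.frame(index_snp = cl$index_snp, chrom = cl$chrom, pos = cl$pos,
               p_meta = cl$p_meta,
               n_traits = irow$n_sig_traits[1],
               genes = set_key(g$gene_id),
               start = min(mrows$pos), end = max(mrows$pos),
               members = cl$members, traits = set_key(traits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Decision cascade choosing the index SNP of a merged pair (rows a, b).
# Returns 1L or 2L.
merge_winner <- function(a, b) {
  ga <- split_key(a$genes); gb <- split_key(b$genes)
  smaller_p <- function() {
    if (a$p_meta < b$p_meta) 1L else if (b$p_meta < a$p_meta) 2L
    else if (a$pos <= b$pos) 1L else 2L
  }
  if (length(intersect(ga, gb)) > 0L) return(smaller_p())
  ratio <- max(a$p_meta, b$p_meta) / min(a$p_meta, b$p_meta)
  if (ratio >= 10) return(smaller_p())
  if (length(ga) > 0L && length(gb) == 0L) return(1L)
  if (length(gb) > 0L && length(ga) == 0L) return(2L)
  if (a$n_traits != b$n_traits) return(if (a$n_traits > b$n_traits) 1L else 2L)
  if (a$p_meta != b$p_meta) return(smaller_p())
  if (a$pos <= b$pos) 1L else 2L
}

#' Merge nearby index SNPs into final independent loci
#'
#' Index SNPs within `window` base pairs of each other (inclusive) on the
#' same chromosome are merged, leftmost pair first and re-scanned to
#' fixpoint. The merged locus takes the union of member SNPs and traits and
#' the enclosing bounds; its index SNP is chosen by a decision cascade:
#' same gene -> smaller p; p-values an order of magnitude apart (ratio >= 10)
#' -> smaller p; one inside a gene -> that one; more significant traits;
#' smaller p; smaller position.
#'
#' @param loci data.frame from [loci_from_clumps()].
#' @param window merge distance in bp (default 5e5, inclusive).
#' @return data.frame of final loci, sorted by chromosome and position, with
#'   pairwise index distance strictly above `window` per chromosome.
#' @export
merge_loci <- function(loci, window = 5e5) {
  if (nrow(loci) <= 1L) return(loci)
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(loci) - 1L)) {
      a <- loci[i, ]; b <- loci[i + 1L, ]
      if (a$chrom == b$chrom && b$pos - a$pos <= window) {
        win <- if (merge_winner(a, b) == 1L) a else b
        new <- win
        new$start <- min(a$start, b$start)
        new$end <- max(a$end, b$end)
        new$members <- set_key(c(split_key(a$members), split_key(b$members)))
        new$traits <- set_key(c(split_key(a$traits), split_key(b$traits)))
        loci <- rbind(loci[-c(i, i + 1L), , drop = FALSE], new)
        loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  rownames(loci) <- NULL
  loci
}

#' Assign a gene to a locus
#'
#' The gene containing the index SNP (smallest transcript span, then
#' lexicographic id, when several overlap); otherwise the gene with minimal
#' base-pair distance from the index SNP among genes overlapping the locus
#' bounds; `NA` when no gene overlaps the locus.
#'
#' @param locus one locus row (`chrom, pos, start, end`).
#' @param annotation gene annotation data.frame.
#' @return gene id or `NA_character_`.
#' @export
assign_gene <- function(locus, annotation) {
  ann <- annotation[annotation$chrom == locus$chrom, , drop = FALSE]
  inside <- ann[ann$tx_start <= locus$pos & ann$tx_end >= locus$pos, , drop = FALSE]
  if (nrow(inside) > 0L) {
    span <- inside$tx_end - inside$tx_start
    inside <- inside[order(span, inside$gene_id), , drop = FALSE]
    return(inside$gene_id[1])
  }
  overl <- ann[ann$tx_end >= locus$start & ann$tx_start <= locus$end, , drop = FALSE]
  if (nrow(overl) == 0L) return(NA_character_)
  dist <- pmax(0, overl$tx_start - locus$pos, locus$pos - overl$tx_end)
  overl <- overl[order(dist, overl$tx_end - overl$tx_start, overl$gene_id), ,
                 drop = FALSE]
  overl$gene_id[1]
}

#' Gene-disease map from final loci
#'
#' @param loci merged loci data.frame (after [merge_loci()]).
#' @param annotation gene annotation data.frame.
#' @return named list gene -> sorted disease set (loci without an assignable
#'   gene are dropped; disease sets of loci mapping to the same gene are
#'   unioned). Only genes whose locus trait set has at least two diseases
#'   are informative downstream.
#' @export
loci_gene_map <- function(loci, annotation) {
  out <- list()
  for (i in seq_len(nrow(loci))) {
    g <- assign_gene(loci[i, ], annotation)
    if (is.na(g)) next
    ds <- split_key(loci$traits[i])
    if (length(ds) == 0L) next
    out[[g]] <- sort(unique(c(out[[g]], ds)))
  }
  out[order(names(out))]
}
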