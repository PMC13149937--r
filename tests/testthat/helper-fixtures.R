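# Shared fixtures: tiny configs and independent oracles used across tests.

tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_diseases = 3, n_chromosomes = 2, blocks_per_chrom = 4,
    snps_per_block = 20, n_genes = 8, gene_snps = 6,
    ld_decay = 0.6, poly_sd = 0,
    planted_genes = data.frame(gene_id = character(0),
                               diseases = character(0),
                               lambda = numeric(0)),
    rg_target = diag(3),
    mhc_like_region = c(2, 2, 3),  # degenerate: between SNPs, excludes nothing
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Brute-force maximum clique by enumerating all vertex subsets (n <= 15).
oracle_max_clique_size <- function(adj) {
  n <- nrow(adj)
  best <- 1L
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(members) <= best) next
    ok <- TRUE
    for (i in members) {
      for (j in members) {
        if (i < j && !adj[i, j]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) best <- length(members)
  }
  best
}

# Literal PLINK-style greedy clumping, written independently of clump().
oracle_clump <- function(meta, r2_fun, p1, p2, r2, kb) {
  cand <- meta[meta$p_meta < p1, ]
  cand <- cand[order(cand$p_meta, cand$chrom, cand$pos), ]
  pool <- meta[meta$p_meta < p2, ]
  assigned <- character(0)
  res <- list()
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, ]
    if (x$snp_id %in% assigned) next
    mem <- character(0)
    for (j in seq_len(nrow(pool))) {
      y <- pool[j, ]
      if (y$snp_id %in% assigned) next
      if (y$chrom != x$chrom) next
      if (abs(y$pos - x$pos) > kb * 1000) next
      if (r2_fun(x$snp_id, y$snp_id) < r2) next
      mem <- c(mem, y$snp_id)
    }
    assigned <- c(assigned, mem)
    res[[length(res) + 1L]] <- list(index = x$snp_id, members = sort(mem))
  }
  res
}

# Independent re-implementation of the locus-merge cascade.
oracle_merge <- function(df, window = 5e5) {
  pick <- function(a, b) {
    ga <- strsplit(a$genes, ",")[[1]]; ga <- ga[nzchar(ga)]
    gb <- strsplit(b$genes, ",")[[1]]; gb <- gb[nzchar(gb)]
    byp <- function() {
      if (a$p_meta != b$p_meta) {
        if (a$p_meta < b$p_meta) "a" else "b"
      } else if (a$pos <= b$pos) "a" else "b"
    }
    if (length(intersect(ga, gb)) > 0) return(byp())
    if (max(a$p_meta, b$p_meta) / min(a$p_meta, b$p_meta) >= 10) return(byp())
    if (length(ga) > 0 && length(gb) == 0) return("a")
    if (length(gb) > 0 && length(ga) == 0) return("b")
    if (a$n_traits != b$n_traits) return(if (a$n_traits > b$n_traits) "a" else "b")
    byp()
  }
  df <- df[order(df$chrom, df$pos), ]
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(df) - 1L)) {
      a <- df[i, ]; b <- df[i + 1L, ]
      if (a$chrom == b$chrom && b$pos - a$pos <= window) {
        w <- if (pick(a, b) == "a") a else b
        w$start <- min(a$start, b$start); w$end <- max(a$end, b$end)
        df <- rbind(df[-c(i, i + 1L), ], w)
        df <- df[order(df$chrom, df$pos), ]
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  rownames(df) <- NULL
  df
}

# Exhaustive subset search over all subsets and all sign patterns.
oracle_best_subset <- function(z, w) {
  n <- length(z)
  best <- -Inf; best_set <- integer(0)
  for (mask in seq_len(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(sel))))
    for (r in seq_len(nrow(signs))) {
      stat <- abs(sum(signs[r, ] * w[sel] * z[sel])) / sqrt(sum(w[sel]^2))
      if (stat > best + 1e-12) { best <- stat; best_set <- sel }
    }
  }
  list(stat = best, subset = best_set)
}

make_loci_df <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample(1:5e6, n))
  data.frame(
    index_snp = sprintf("S%02d", seq_len(n)), chrom = 1L, pos = pos,
    p_meta = 10^-stats::runif(n, 8, 16),
    genes = ifelse(stats::runif(n) < 0.5, "",
                   sample(c("GA", "GB", "GC"), n, replace = TRUE)),
    n_traits = sample(2:5, n, replace = TRUE),
    start = pos - 1000L, end = pos + 1000L,
    members = sprintf("S%02d", seq_len(n)),
    traits = "D1,D2", stringsAsFactors = FALSE)
}
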