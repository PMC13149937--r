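#' Run the full pleiotropy-mapping pipeline on a synthetic study
#'
#' Simulates a study from `config` (or reads a previously written bundle),
#' applies the QC filters, estimates pairwise genetic correlations, extracts
#' the fully connected disease cluster, runs the three gene-discovery routes
#' restricted to the cluster, and integrates them into a pleiotropy table,
#' disease network, category classification and gene-set enrichment. Input
#' and output counts of every filtering step are logged with `message()`.
#'
#' @param config a [sim_config()] object.
#' @param maf_min MAF filter (strict; default 1e-5).
#' @param min_cases case-count filter (strict; default 1000).
#' @param rg_alpha edge significance for the disease graph (default 0.05).
#' @param gene_threshold gene-based significance threshold.
#' @param n_null Monte-Carlo null size of the subset meta-analysis.
#' @return list with every intermediate product: `stats, truth, metadata,
#'   cluster, rg, gene_scan, gba_map, snp_map, meta_scan, loci, meta_map,
#'   pleiotropy, network, span, enrichment, sharing`.
#' @export
run_pipeline <- function(config,
                         maf_min = 1e-5,
                         min_cases = 1000,
                         rg_alpha = 0.05,
                         gene_threshold = gene_significance_threshold(),
                         n_null = 1e5) {
  ld <- simulate_ld(config)
  sim <- simulate_sumstats(config, ld)
  metadata <- sim_metadata(config)
  annotation <- sim_annotation(config)
  consequences <- sim_consequences(config)
  evidence <- sim_evidence(config)
  gene_sets <- sim_gene_sets(config)

  keep <- filter_diseases(metadata, min_cases)
  message(sprintf("diseases: %d -> %d after case-count filter (> %d cases)",
                  nrow(metadata), length(keep), min_cases))
  stats <- lapply(sim$stats[keep], qc_filter, maf_min = maf_min,
                  excluded_region = config$mhc_like_region)
  message(sprintf("SNPs per disease: %d -> %d after QC",
                  nrow(sim$stats[[1]]), nrow(stats[[1]])))

  rg <- rg_matrix(stats, ld$ldscores)
  graph <- build_graph(rg, alpha = rg_alpha)
  cluster <- max_fully_connected_cluster(graph)
  message(sprintf("fully connected cluster: %d of %d diseases",
                  length(cluster$diseases), length(keep)))
  stats <- stats[cluster$diseases]

  scan <- run_gene_scan(stats, annotation, ld, threshold = gene_threshold)
  gba_raw <- find_pleiotropic_genes(scan)
  gba_map <- filter_ld_gene_clusters(gba_raw, annotation, evidence)
  message(sprintf("gene-based route: %d significant gene-disease pairs, %d pleiotropic genes (%d after cluster filter)",
                  sum(scan$significant), length(gba_raw), length(gba_map)))

  snp_sel <- select_pleiotropic_snps(stats)
  snp_map <- assign_coding_genes(snp_sel, consequences)
  message(sprintf("SNP route: %d pleiotropic SNPs, %d coding genes",
                  length(snp_sel), length(snp_map)))

  meta_scan <- run_meta_scan(stats, n_null = n_null)
  clumps <- clump(meta_scan, ld)
  loci <- if (nrow(clumps) > 0) merge_loci(loci_from_clumps(clumps, meta_scan, annotation))
          else clumps
  meta_map <- if (nrow(clumps) > 0) loci_gene_map(loci, annotation) else list()
  meta_map <- meta_map[vapply(meta_map, length, integer(1)) >= 2L]
  message(sprintf("locus route: %d SNPs in meta scan, %d clumps, %d final loci, %d genes",
                  nrow(meta_scan), nrow(clumps),
                  if (is.data.frame(loci)) nrow(loci) else 0, length(meta_map)))

  pleiotropy <- combine_methods(gba_map, snp_map, meta_map)
  network <- build_disease_network(pleiotropy, metadata)
  span <- if (nrow(pleiotropy) > 0) classify_category_span(pleiotropy, metadata)
          else NULL
  enrichment <- if (length(unique(pleiotropy$gene_id)) > 0) {
    enrich(unique(pleiotropy$gene_id), gene_sets, annotation$gene_id)
  } else NULL
  sharing <- if (nrow(pleiotropy) > 0) sharing_fraction(network, cluster$diseases)
             else 0
  message(sprintf("integrated: %d pleiotropic genes, %.0f%% of cluster diseases share a gene",
                  length(unique(pleiotropy$gene_id)), 100 * sharing))

  list(stats = stats, truth = sim$truth, metadata = metadata,
       annotation = annotation, cluster = cluster, rg = rg,
       gene_scan = scan, gba_map = gba_map, snp_map = snp_map,
       meta_scan = meta_scan, loci = loci, meta_map = meta_map,
       pleiotropy = pleiotropy, network = network, span = span,
       enrichment = enrichment, sharing = sharing)
}
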