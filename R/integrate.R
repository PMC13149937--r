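#' Combine the gene-disease maps of the three discovery routes
#'
#' Unions (gene, disease) pairs from the gene-based route (`GBA`), the
#' coding-SNP route (`SNP`) and the cross-trait meta-analysis route
#' (`META`), recording method provenance per pair. Genes whose unioned
#' disease set has fewer than `min_diseases` diseases are dropped.
#'
#' @param gba,snp,meta named lists mapping gene id to a disease set (any may
#'   be empty).
#' @param min_diseases minimum unioned disease count per gene (default 2).
#' @return data.frame `gene_id, disease_id, methods` (`methods` a
#'   `+`-joined subset of `GBA, SNP, META`), sorted by gene then disease,
#'   with attribute `n_diseases` (named integer vector per gene).
#' @export
combine_methods <- function(gba = list(), snp = list(), meta = list(),
                            min_diseases = 2L) {
  maps <- list(GBA = gba, SNP = snp, META = meta)
  rows <- list()
  for (m in names(maps)) {
    for (g in names(maps[[m]])) {
      for (d in maps[[m]][[g]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, disease_id = d, method = m, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(gene_id = character(0), disease_id = character(0),
                      methods = character(0))
    attr(out, "n_diseases") <- integer(0)
    return(out)
  }
  long <- do.call(rbind, rows)
  key <- paste(long$gene_id, long$disease_id, sep = "\r")
  methods <- tapply(long$method, key, function(x)
    paste(intersect(c("GBA", "SNP", "META"), x), collapse = "+"))
  parts <- strsplit(names(methods), "\r", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 1),
    disease_id = vapply(parts, `[`, character(1), 2),
    methods = as.vector(methods), stringsAsFactors = FALSE)
  counts <- table(out$gene_id)
  keep_genes <- names(counts)[counts >= min_diseases]
  out <- out[out$gene_id %in% keep_genes, , drop = FALSE]
  out <- out[order(out$gene_id, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  nd <- vapply(split(out$disease_id, out$gene_id), length, integer(1))
  attr(out, "n_diseases") <- nd
  out
}

#' Per-method gene and disease counts with overlaps
#'
#' Venn-style counts of genes (and of diseases touched) per discovery route,
#' mirroring an integrated-comparison diagram.
#'
#' @param gba,snp,meta named lists gene -> disease set.
#' @return list with `genes` and `diseases`, each a named integer vector
#'   over the seven non-empty method combinations.
#' @export
method_overlap <- function(gba = list(), snp = list(), meta = list()) {
  venn <- function(a, b, c) {
    combos <- c(GBA = 1, SNP = 2, META = 4)
    universe <- unique(c(a, b, c))
    code <- (universe %in% a) + 2 * (universe %in% b) + 4 * (universe %in% c)
    labels <- vapply(1:7, function(bit)
      paste(names(combos)[bitwAnd(bit, combos) > 0], collapse = "+"),
      character(1))
    stats::setNames(vapply(1:7, function(bit) sum(code == bit), integer(1)),
                    labels)
  }
  list(
    genes = venn(names(gba), names(snp), names(meta)),
    diseases = venn(unique(unlist(gba)), unique(unlist(snp)),
                    unique(unlist(meta)))
  )
}

#' Disease network connected by shared pleiotropic genes
#'
#' An undirected edge joins two diseases whenever at least one gene maps to
#' both; the edge weight is the shared-gene count. Diseases present in the
#' table but sharing no gene are reported as isolated.
#'
#' @param table pleiotropy table from [combine_methods()].
#' @param metadata disease metadata (for categories; missing diseases get
#'   category `"unknown"` with a message).
#' @return list with `edges` (data.frame `dis_a, dis_b, weight, genes`),
#'   `nodes` (data.frame `disease_id, category`) and `isolated` (character).
#' @export
build_disease_network <- function(table, metadata = NULL) {
  diseases <- sort(unique(table$disease_id))
  cat_of <- function(d) {
    if (!is.null(metadata) && d %in% metadata$disease_id) {
      metadata$category[metadata$disease_id == d][1]
    } else {
      message(sprintf("build_disease_network: no metadata for %s, category 'unknown'", d))
      "unknown"
    }
  }
  nodes <- data.frame(disease_id = diseases,
                      category = vapply(diseases, cat_of, character(1)),
                      stringsAsFactors = FALSE)
  genes_of <- split(table$gene_id, table$disease_id)
  edges <- list()
  if (length(diseases) >= 2L) {
    pairs <- utils::combn(diseases, 2)
    for (k in seq_len(ncol(pairs))) {
      shared <- sort(intersect(genes_of[[pairs[1, k]]], genes_of[[pairs[2, k]]]))
      if (length(shared) == 0L) next
      edges[[length(edges) + 1L]] <- data.frame(
        dis_a = pairs[1, k], dis_b = pairs[2, k], weight = length(shared),
        genes = paste(shared, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(dis_a = character(0), dis_b = character(0),
               weight = integer(0), genes = character(0))
  connected <- unique(c(edges$dis_a, edges$dis_b))
  list(edges = edges, nodes = nodes,
       isolated = setdiff(diseases, connected))
}

#' Export the disease network as an igraph object (and optionally GraphML)
#'
#' @param network output of [build_disease_network()].
#' @param graphml_path optional path for a GraphML export.
#' @return an `igraph` graph including isolated nodes.
#' @export
network_graph <- function(network, graphml_path = NULL) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("dis_a", "dis_b", "weight", "genes")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes$disease_id,
                          category = network$nodes$category))
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  g
}

#' Classify each pleiotropic gene as within- or cross-category
#'
#' @param table pleiotropy table from [combine_methods()].
#' @param metadata disease metadata with categories.
#' @return data.frame `gene_id, n_diseases, n_categories, span`
#'   (`span` is `"within"` when all of a gene's diseases share one
#'   category, else `"cross"`).
#' @export
classify_category_span <- function(table, metadata) {
  cat_map <- stats::setNames(metadata$category, metadata$disease_id)
  if (any(!table$disease_id %in% names(cat_map))) {
    stop("classify_category_span: disease without category metadata")
  }
  per_gene <- split(table$disease_id, table$gene_id)
  data.frame(
    gene_id = names(per_gene),
    n_diseases = vapply(per_gene, length, integer(1)),
    n_categories = vapply(per_gene, function(d)
      length(unique(cat_map[d])), integer(1)),
    span = vapply(per_gene, function(d)
      if (length(unique(cat_map[d])) == 1L) "within" else "cross", character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of diseases sharing at least one gene with another disease
#'
#' @param network output of [build_disease_network()].
#' @param all_diseases the full disease set of the analysis (e.g. the fully
#'   connected cluster); defaults to the network's own nodes.
#' @return proportion in `[0, 1]`.
#' @export
sharing_fraction <- function(network, all_diseases = NULL) {
  all_diseases <- all_diseases %||% network$nodes$disease_id
  connected <- unique(c(network$edges$dis_a, network$edges$dis_b))
  length(intersect(all_diseases, connected)) / length(all_diseases)
}

#' Hypergeometric gene-set enrichment with Benjamini-Hochberg correction
#'
#' One-sided hypergeometric upper tail (probability of the observed overlap
#' or more) per gene set, against an explicit background gene universe;
#' adjusted p-values by the Benjamini-Hochberg step-up procedure over all
#' tested sets.
#'
#' @param query character vector of query genes (must be non-empty; genes
#'   outside the background are dropped).
#' @param gene_sets named list of character vectors.
#' @param background character vector, the gene universe (set members
#'   outside it are ignored).
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.frame `set_id, overlap, set_size, query_size,
#'   background_size, p, p_adjusted, significant`.
#' @export
enrich <- function(query, gene_sets, background, alpha = 0.05) {
  if (length(query) == 0L) stop("enrich: empty query gene list")
  query <- intersect(unique(query), background)
  if (length(query) == 0L) stop("enrich: no query gene in the background")
  N <- length(unique(background))
  q <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1, length(set), N - length(set), q,
                       lower.tail = FALSE)
    data.frame(set_id = nm, overlap = k, set_size = length(set),
               query_size = q, background_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out[order(out$p_adjusted, out$p, out$set_id), ]
}
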