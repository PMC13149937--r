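#' SNPs genome-wide significant in at least two diseases
#'
#' @param stats_list named list of QC-filtered summary-statistics tables.
#' @param threshold genome-wide significance threshold, strict `<`
#'   (default 5e-8).
#' @param min_diseases minimum number of qualifying diseases (default 2).
#' @return named list mapping SNP id to the sorted set of diseases in which
#'   it is significant.
#' @export
select_pleiotropic_snps <- function(stats_list, threshold = 5e-8,
                                    min_diseases = 2L) {
  hits <- lapply(names(stats_list), function(d) {
    st <- stats_list[[d]]
    hit <- st$snp_id[st$p < threshold]
    data.frame(snp_id = hit, disease_id = rep(d, length(hit)),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) return(stats::setNames(list(), character(0)))
  sets <- tapply(hits$disease_id, hits$snp_id,
                 function(x) sort(unique(x)), simplify = FALSE)
  sets <- sets[vapply(sets, length, integer(1)) >= min_diseases]
  sets[order(names(sets))]
}

#' Map coding pleiotropic SNPs to genes
#'
#' A selected SNP annotated as `stop_gained`, `missense` or `synonymous` in
#' a gene passes its disease set to that gene; disease sets are unioned over
#' a gene's SNPs. Consequence `other` contributes nothing, and SNPs absent
#' from the consequence table are treated as non-coding (logged).
#'
#' @param snp_map named list SNP -> disease set ([select_pleiotropic_snps()]).
#' @param consequences data.frame `snp_id, gene_id, consequence`.
#' @param coding_classes consequence classes treated as gene-implicating.
#' @return named list gene -> sorted disease set, ordered by gene id, with a
#'   `provenance` attribute (data.frame `gene_id, snp_id, consequence`
#'   recording the supporting SNPs).
#' @export
assign_coding_genes <- function(snp_map,
                                consequences,
                                coding_classes = c("stop_gained", "missense",
                                                   "synonymous")) {
  genes <- list()
  prov <- list()
  missing <- setdiff(names(snp_map), consequences$snp_id)
  if (length(missing) > 0L) {
    message(sprintf("assign_coding_genes: %d selected SNP(s) absent from the consequence table, treated as non-coding",
                    length(missing)))
  }
  for (snp in names(snp_map)) {
    rows <- consequences[consequences$snp_id == snp &
                           consequences$consequence %in% coding_classes, ,
                         drop = FALSE]
    for (g in rows$gene_id) {
      genes[[g]] <- sort(unique(c(genes[[g]], snp_map[[snp]])))
      prov[[length(prov) + 1L]] <- data.frame(
        gene_id = g, snp_id = snp,
        consequence = rows$consequence[rows$gene_id == g][1],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(genes)) genes[order(names(genes))] else
    stats::setNames(list(), character(0))
  attr(out, "provenance") <- if (length(prov)) do.call(rbind, prov) else
    data.frame(gene_id = character(0), snp_id = character(0),
               consequence = character(0))
  out
}
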