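# Readers and writers for the external interchange formats. All numeric
# columns are written with 17 significant digits so values survive a
# write/read round trip exactly.

write_tsv17 <- function(df, path) {
  out <- df
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write per-disease summary statistics (SAIGE-like TSV)
#'
#' Columns on disk: `CHR, POS, SNPID, Allele1, Allele2, AF_Allele2, BETA,
#' SE, p.value, N_case, N_ctrl` (1-based positions). In memory the table
#' uses `snp_id, chrom, pos, a1, a2, eaf, beta, se, z, p, n_case, n_ctrl`
#' with `z = beta / se`.
#'
#' @param path file path.
#' @return data.frame in internal layout.
#' @export
read_sumstats <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  df <- data.frame(
    snp_id = x$SNPID, chrom = as.integer(x$CHR), pos = as.integer(x$POS),
    a1 = x$Allele1, a2 = x$Allele2, eaf = x$AF_Allele2,
    beta = x$BETA, se = x$SE, z = x$BETA / x$SE, p = x$p.value,
    n_case = x$N_case, n_ctrl = x$N_ctrl,
    stringsAsFactors = FALSE
  )
  df
}

#' @rdname read_sumstats
#' @param stats summary-statistics data.frame (internal layout).
#' @export
write_sumstats <- function(stats, path) {
  write_tsv17(data.frame(
    CHR = stats$chrom, POS = stats$pos, SNPID = stats$snp_id,
    Allele1 = stats$a1, Allele2 = stats$a2, AF_Allele2 = stats$eaf,
    BETA = stats$beta, SE = stats$se, p.value = stats$p,
    N_case = stats$n_case, N_ctrl = stats$n_ctrl
  ), path)
}

# An LD block file is a TSV whose first row is the SNP ids and whose
# remaining rows are the square correlation matrix.
write_ld_block <- function(block, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(block$snp_ids, collapse = "\t"), con)
  writeLines(apply(block$R, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
             con)
  invisible(path)
}

#' Read the LD blocks and LD scores of a fixture bundle
#'
#' @param dir bundle directory (as written by [write_fixture_bundle()]).
#' @return list with `blocks` and `ldscores` in the layout of
#'   [simulate_ld()]. Block chromosome/position metadata is recovered from
#'   any sumstats file present in the bundle.
#' @export
read_ld_bundle <- function(dir) {
  files <- sort(list.files(dir, pattern = "^ld_block_.*\\.tsv$", full.names = TRUE))
  ss_file <- list.files(dir, pattern = "^sumstats_.*\\.tsv$", full.names = TRUE)[1]
  snpmap <- NULL
  if (!is.na(ss_file)) {
    ss <- read_sumstats(ss_file)
    snpmap <- ss[, c("snp_id", "chrom", "pos")]
  }
  blocks <- lapply(files, function(f) {
    lines <- readLines(f)
    ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    R <- do.call(rbind, lapply(lines[-1], function(l)
      as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
    dimnames(R) <- list(ids, ids)
    chrom <- NA_integer_; pos <- rep(NA_integer_, length(ids))
    if (!is.null(snpmap)) {
      m <- match(ids, snpmap$snp_id)
      chrom <- snpmap$chrom[m[1]]
      pos <- snpmap$pos[m]
    }
    list(block_id = sub("^ld_block_(.*)\\.tsv$", "\\1", basename(f)),
         chrom = chrom, snp_ids = ids, pos = pos, R = R)
  })
  ls <- data.table::fread(file.path(dir, "ldscores.tsv"), sep = "\t",
                          data.table = FALSE)
  list(blocks = blocks, ldscores = data.frame(snp_id = ls$SNPID, l2 = ls$L2))
}

#' Read gene annotation (1-based inclusive transcription bounds)
#' @param path file path.
#' @return data.frame `gene_id, symbol, chrom, tx_start, tx_end, coding`.
#' @export
read_annotation <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  data.frame(gene_id = x$GENE_ID, symbol = x$SYMBOL, chrom = as.integer(x$CHR),
             tx_start = as.integer(x$TX_START), tx_end = as.integer(x$TX_END),
             coding = as.integer(x$CODING), stringsAsFactors = FALSE)
}

#' Read a variant-consequence table
#' @param path file path.
#' @return data.frame `snp_id, gene_id, consequence`.
#' @export
read_consequences <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  data.frame(snp_id = x$SNPID, gene_id = x$GENE_ID,
             consequence = x$CONSEQUENCE, stringsAsFactors = FALSE)
}

#' Read a gene-disease evidence-score table
#' @param path file path.
#' @return data.frame `gene_id, disease_id, score`.
#' @export
read_evidence <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  data.frame(gene_id = x$GENE_ID, disease_id = x$DISEASE_ID, score = x$SCORE,
             stringsAsFactors = FALSE)
}

#' Read disease metadata
#' @param path file path.
#' @return data.frame `disease_id, name, category, n_case, n_total`.
#' @export
read_metadata <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  data.frame(disease_id = x$DISEASE_ID, name = x$NAME, category = x$CATEGORY,
             n_case = x$N_case, n_total = x$N_total, stringsAsFactors = FALSE)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated: name, description, member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read every summary-statistics table of a bundle
#' @param dir bundle directory.
#' @return named list of data.frames keyed by disease id.
#' @export
read_sumstats_bundle <- function(dir) {
  files <- sort(list.files(dir, pattern = "^sumstats_.*\\.tsv$", full.names = TRUE))
  out <- lapply(files, read_sumstats)
  names(out) <- sub("^sumstats_(.*)\\.tsv$", "\\1", basename(files))
  out
}
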