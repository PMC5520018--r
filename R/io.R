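#' Write a genotype matrix as tab-separated text
#'
#' @param genotypes samples x SNPs matrix; NA written as `NA`.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix written by [write_genotypes_tsv()]
#' @param path input file.
#' @return integer matrix with sample ids as rownames.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- df[[1]]
  g
}

#' Write genotypes as a minimal VCF (GT field, 1-based positions)
#'
#' Coded-allele counts become unphased GT strings (0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1, NA -> ./.), with the risk allele as ALT.
#'
#' @param genotypes samples x SNPs matrix.
#' @param snps SNP table with snp_id, chr, pos, allele_risk, allele_other.
#' @param path output file.
#' @export
write_vcf <- function(genotypes, snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "FORMAT", rownames(genotypes)), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    writeLines(paste(c(snps$chr[j], snps$pos[j], snps$snp_id[j],
                       snps$allele_other[j], snps$allele_risk[j], ".", "PASS",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write aligned protein sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences))
    writeLines(c(paste0(">", nm), sequences[[nm]]), con)
  invisible(path)
}

#' Read a FASTA file of aligned sequences
#' @param path input file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1),
                 collapse = "")
  names(seqs) <- sub("^>", "", lines[hdr])
  seqs
}

#' Read a simple key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); values are parsed as
#' numeric vectors where possible (comma-separated), otherwise strings;
#' `#` comments and blank lines ignored.
#'
#' @param path input file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", perl = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Write a result table as TSV with a header comment block
#'
#' @param df data.frame.
#' @param path output file.
#' @param meta named character/numeric vector recorded as `# key: value`
#'   lines (e.g. thresholds and seed).
#' @export
write_result_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
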