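#' Parental SNP genotype matrix
#'
#' Container for biallelic SNP calls of a panel of (near-inbred) parents.
#' Calls are coded as alt-allele dosages: 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, `NA` = missing. Coordinates
#' are 1-based and inclusive (VCF convention).
#'
#' @param calls integer matrix, parents in rows (rownames = parent ids),
#'   SNPs in columns; values in \{0, 1, 2, NA\}.
#' @param snps data.frame with one row per SNP and columns `chrom`, `pos`,
#'   `ref`, `alt`. Positions must be strictly increasing within chromosome.
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   and `snps`.
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0L, 2L, 0L, 2L), 2, 2, dimnames = list(c("P1", "P2"), NULL)),
#'   data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G")
#' )
#' n_snps(g)
#' @export
geno_matrix <- function(calls, snps) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) stop("`calls` must have parent ids as rownames")
  if (anyDuplicated(rownames(calls))) stop("parent ids must be unique")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snps))) {
    stop("`snps` needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(snps) != ncol(calls)) stop("ncol(calls) must equal nrow(snps)")
  colnames(calls) <- NULL
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (any(snps$pos < 1L)) stop("positions are 1-based and must be >= 1")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  rownames(snps) <- NULL
  structure(list(calls = calls, snps = snps), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "geno_matrix: %d parents x %d SNPs on %d chromosome(s); %.1f%% missing\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$snps$chrom)),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @rdname geno_matrix
#' @param g a `geno_matrix`.
#' @export
n_snps <- function(g) ncol(g$calls)

#' @rdname geno_matrix
#' @export
n_parents <- function(g) nrow(g$calls)

#' @rdname geno_matrix
#' @export
parent_ids <- function(g) rownames(g$calls)

#' Minor-allele frequency per SNP
#'
#' Alt-allele frequency is computed over non-missing calls with a
#' heterozygote contributing one copy of each allele; the MAF is
#' `min(p, 1 - p)` and always lies in `[0, 0.5]`.
#'
#' @param g a [geno_matrix()].
#' @return Numeric vector of per-SNP MAF (NaN for fully missing SNPs).
#' @export
snp_maf <- function(g) {
  alt <- colSums(g$calls, na.rm = TRUE)
  n <- 2L * colSums(!is.na(g$calls))
  p <- alt / n
  pmin(p, 1 - p)
}

#' Read parental genotypes from VCF or TSV
#'
#' VCF parsing uses \pkg{vcfR}; only the GT field is used. Multi-allelic
#' records and non-SNP records (indels) are dropped with a message giving
#' the count. The TSV dialect has columns `chrom`, `pos`, `ref`, `alt`
#' followed by one column per parent with calls coded 0/1/2/NA.
#'
#' @param path file path.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & !is.na(fix$ALT)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " multi-allelic/non-SNP record(s) dropped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  snps <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  if (anyDuplicated(snps[, c("chrom", "pos")])) {
    stop("duplicated (chromosome, position) records in ", path)
  }
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  code[gt_clean %in% c("0/0")] <- 0L
  code[gt_clean %in% c("0/1", "1/0")] <- 1L
  code[gt_clean %in% c("1/1")] <- 2L
  ord <- order(snps$chrom, snps$pos)
  geno_matrix(t(code)[, ord, drop = FALSE], snps[ord, , drop = FALSE])
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("chrom", "pos", "ref", "alt")
  if (!all(meta %in% names(tab))) {
    stop("TSV must have columns chrom, pos, ref, alt followed by parent columns")
  }
  keep <- nchar(tab$ref) == 1L & nchar(tab$alt) == 1L & !grepl(",", tab$alt)
  dropped <- sum(!keep)
  if (dropped > 0) message(dropped, " multi-allelic/non-SNP record(s) dropped")
  tab <- tab[keep, , drop = FALSE]
  if (anyDuplicated(tab[, c("chrom", "pos")])) {
    stop("duplicated (chromosome, position) records in ", path)
  }
  parents <- setdiff(names(tab), meta)
  calls <- t(as.matrix(tab[, parents, drop = FALSE]))
  storage.mode(calls) <- "integer"
  rownames(calls) <- parents
  ord <- order(tab$chrom, tab$pos)
  geno_matrix(calls[, ord, drop = FALSE], tab[ord, meta])
}

#' Write parental genotypes to VCF or TSV
#'
#' The VCF writer emits plain-text VCF v4.2 with a GT-only FORMAT so the
#' file round-trips through [read_genotypes()].
#'
#' @param g a [geno_matrix()].
#' @param path output file path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- cbind(g$snps, as.data.frame(t(g$calls)))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gt_str <- matrix("./.", nrow(g$calls), ncol(g$calls))
  gt_str[!is.na(g$calls) & g$calls == 0L] <- "0/0"
  gt_str[!is.na(g$calls) & g$calls == 1L] <- "0/1"
  gt_str[!is.na(g$calls) & g$calls == 2L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gcaldb",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", parent_ids(g)), collapse = "\t")
  )
  body <- vapply(seq_len(n_snps(g)), function(j) {
    paste(c(g$snps$chrom[j], g$snps$pos[j], ".", g$snps$ref[j], g$snps$alt[j],
            ".", "PASS", ".", "GT", gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Impute missing genotype calls by the per-SNP mode
#'
#' Each missing call is replaced with the most frequent genotype code at
#' that SNP. Ties break toward homozygous reference, then heterozygous.
#' Non-missing calls are never changed, so the operation is idempotent.
#'
#' @param g a [geno_matrix()].
#' @return A [geno_matrix()] with no missing calls.
#' @export
impute_missing <- function(g) {
  calls <- g$calls
  for (j in seq_len(ncol(calls))) {
    miss <- is.na(calls[, j])
    if (!any(miss)) next
    obs <- calls[!miss, j]
    if (length(obs) == 0L) {
      stop(sprintf(
        "SNP %s:%d has no non-missing calls; cannot impute",
        g$snps$chrom[j], g$snps$pos[j]
      ))
    }
    cnt <- c(sum(obs == 0L), sum(obs == 1L), sum(obs == 2L))
    calls[miss, j] <- c(0L, 1L, 2L)[which.max(cnt)]
  }
  geno_matrix(calls, g$snps)
}

#' Filter SNPs on minor-allele frequency
#'
#' @param g a [geno_matrix()].
#' @param min_maf minimum MAF to retain a SNP (default 0.01, the threshold
#'   used for the rice panel this package was built around).
#' @return A [geno_matrix()] with the retained SNPs, original order kept.
#' @export
filter_maf <- function(g, min_maf = 0.01) {
  keep <- !is.na(snp_maf(g)) & snp_maf(g) >= min_maf
  geno_matrix(g$calls[, keep, drop = FALSE], g$snps[keep, , drop = FALSE])
}

#' Subset a genotype matrix by SNP index
#' @param g a [geno_matrix()].
#' @param idx integer vector of SNP (column) indices.
#' @return A [geno_matrix()].
#' @export
subset_snps <- function(g, idx) {
  geno_matrix(g$calls[, idx, drop = FALSE], g$snps[idx, , drop = FALSE])
}
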