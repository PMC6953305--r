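#' Collapse LD blocks into multi-allelic SNPLDB markers
#'
#' Every blocked SNP belongs to exactly one block marker whose alleles are
#' the haplotype strings over the member SNPs (reference/alternate
#' nucleotides, e.g. `"AGG"`); every unblocked SNP becomes a singleton
#' marker (id `S<chrom>_<pos>`) whose alleles are its genotype classes
#' (`"A"`, `"G"`, or `"A/G"` for residual heterozygotes). Block haplotype
#' classes observed in fewer than `rare_count_threshold` parents are
#' merged into class `"other"`. A parent heterozygous inside a block is
#' assigned the pure haplotype class matching the majority of its member
#' SNP calls (heterozygous member SNPs count half toward each allele);
#' ties go to `"other"`.
#'
#' @param g an imputed, MAF-filtered [geno_matrix()].
#' @param blocks block data.frame from [partition_blocks()] (may have zero
#'   rows, in which case every SNP becomes a singleton marker).
#' @param rare_count_threshold minimum carrier count for a block haplotype
#'   class to keep its own label (default 2).
#' @return A list of `snpldb_marker` objects, ordered by chromosome and
#'   position. Each has fields `id`, `type` (`"block"`/`"snp"`), `chrom`,
#'   `start_bp`, `end_bp`, `snp_idx`, `assign` (named character vector,
#'   one allele class per parent), `freqs`, `maf`, `gene_diversity`,
#'   `pic`.
#' @export
build_markers <- function(g, blocks, rare_count_threshold = 2L) {
  if (any(is.na(g$calls))) stop("genotypes must be imputed before marker construction")
  parents <- parent_ids(g)
  in_block <- rep(FALSE, n_snps(g))
  markers <- list()
  if (!is.null(blocks) && nrow(blocks) > 0) {
    for (r in seq_len(nrow(blocks))) {
      idx <- blocks$first[r]:blocks$last[r]
      in_block[idx] <- TRUE
      ref <- g$snps$ref[idx]
      alt <- g$snps$alt[idx]
      calls <- g$calls[, idx, drop = FALSE]
      het_free <- rowSums(calls == 1L) == 0L
      hap_of <- function(p) {
        paste(ifelse(calls[p, ] == 0L, ref, alt), collapse = "")
      }
      assign <- rep(NA_character_, length(parents))
      names(assign) <- parents
      assign[het_free] <- vapply(which(het_free), hap_of, character(1))
      pure <- unique(assign[het_free])
      if (any(!het_free)) {
        pure_mat <- do.call(rbind, strsplit(pure, ""))
        for (p in which(!het_free)) {
          if (length(pure) == 0L) {
            assign[p] <- "other"
            next
          }
          score <- vapply(seq_along(pure), function(h) {
            hom_match <- sum(calls[p, ] == 0L & pure_mat[h, ] == ref) +
              sum(calls[p, ] == 2L & pure_mat[h, ] == alt)
            hom_match + 0.5 * sum(calls[p, ] == 1L)
          }, numeric(1))
          top <- which(score == max(score))
          assign[p] <- if (length(top) == 1L) pure[top] else "other"
        }
      }
      cnt <- table(assign)
      rare <- names(cnt)[cnt < rare_count_threshold & names(cnt) != "other"]
      assign[assign %in% rare] <- "other"
      markers[[length(markers) + 1L]] <- new_marker(
        id = blocks$id[r], type = "block", chrom = blocks$chrom[r],
        start_bp = blocks$start_bp[r], end_bp = blocks$end_bp[r],
        snp_idx = idx, assign = assign
      )
    }
  }
  for (j in which(!in_block)) {
    ref <- g$snps$ref[j]
    alt <- g$snps$alt[j]
    cls <- c(ref, paste0(ref, "/", alt), alt)[g$calls[, j] + 1L]
    names(cls) <- parents
    markers[[length(markers) + 1L]] <- new_marker(
      id = sprintf("S%s_%d", g$snps$chrom[j], g$snps$pos[j]), type = "snp",
      chrom = g$snps$chrom[j], start_bp = g$snps$pos[j],
      end_bp = g$snps$pos[j], snp_idx = j, assign = cls
    )
  }
  ord <- order(vapply(markers, `[[`, "", "chrom"),
               vapply(markers, `[[`, 0, "start_bp"))
  markers[ord]
}

new_marker <- function(id, type, chrom, start_bp, end_bp, snp_idx, assign) {
  m <- structure(
    list(id = id, type = type, chrom = chrom, start_bp = start_bp,
         end_bp = end_bp, snp_idx = snp_idx, assign = assign),
    class = "snpldb_marker"
  )
  st <- marker_stats(m)
  m$freqs <- attr(st, "freqs")
  m$maf <- st[["maf"]]
  m$gene_diversity <- st[["gene_diversity"]]
  m$pic <- st[["pic"]]
  m
}

#' @export
print.snpldb_marker <- function(x, ...) {
  cat(sprintf("%s (%s, %d SNP%s): %d allele class(es), MAF %.3f, PIC %.3f\n",
              x$id, x$type, length(x$snp_idx),
              if (length(x$snp_idx) > 1) "s" else "",
              length(x$freqs), x$maf, x$pic))
  invisible(x)
}

#' Multi-allelic marker summary statistics
#'
#' With allele-class frequencies `p_i` (one class per parent):
#' gene diversity `= 1 - sum(p_i^2)`, polymorphism information content
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, and
#' `MAF = 1 - max(p_i)` (frequency mass outside the major allele).
#'
#' @param m a `snpldb_marker`.
#' @return Named numeric vector (maf, gene_diversity, pic) with the allele
#'   frequency table attached as attribute `"freqs"`.
#' @export
marker_stats <- function(m) {
  tab <- table(m$assign)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  sq <- p^2
  gd <- 1 - sum(sq)
  cross <- (sum(sq)^2 - sum(sq^2)) / 2   # sum_{i<j} p_i^2 p_j^2
  pic <- gd - 2 * cross
  out <- c(maf = 1 - max(p), gene_diversity = gd, pic = pic)
  attr(out, "freqs") <- p
  out
}

#' Tabulate a marker list
#'
#' @param markers list from [build_markers()].
#' @return data.frame: id, type, chrom, start_bp, end_bp, n_snps,
#'   n_alleles, alleles (comma-separated), freqs (comma-separated), maf,
#'   gene_diversity, pic.
#' @export
markers_table <- function(markers) {
  data.frame(
    id = vapply(markers, `[[`, "", "id"),
    type = vapply(markers, `[[`, "", "type"),
    chrom = vapply(markers, `[[`, "", "chrom"),
    start_bp = vapply(markers, `[[`, 0, "start_bp"),
    end_bp = vapply(markers, `[[`, 0, "end_bp"),
    n_snps = vapply(markers, function(m) length(m$snp_idx), 0L),
    n_alleles = vapply(markers, function(m) length(m$freqs), 0L),
    alleles = vapply(markers, function(m) paste(names(m$freqs), collapse = ","), ""),
    freqs = vapply(markers, function(m) paste(signif(m$freqs, 4), collapse = ","), ""),
    maf = vapply(markers, `[[`, 0, "maf"),
    gene_diversity = vapply(markers, `[[`, 0, "gene_diversity"),
    pic = vapply(markers, `[[`, 0, "pic"),
    stringsAsFactors = FALSE
  )
}

#' Write markers as TSV
#' @param markers list from [build_markers()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers_table(markers), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
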