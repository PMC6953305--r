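#' Two-locus haplotype frequencies from unphased genotypes
#'
#' Counts the four gametes AB, Ab, aB, ab (A/B = reference alleles at the
#' two loci) over all parents with non-missing calls at both SNPs. Parents
#' with at most one heterozygous call contribute two fully determined
#' haplotypes; double heterozygotes are resolved by EM over the two
#' possible phases (initialized at linkage equilibrium, tolerance 1e-6,
#' at most 100 iterations). Near-inbred panels contain almost no double
#' heterozygotes, so the EM step is usually a no-op.
#'
#' @param g a [geno_matrix()].
#' @param i,j SNP column indices.
#' @return A list: `freqs` (numeric, named AB/Ab/aB/ab, sums to 1) and
#'   `n` (number of gametes counted).
#' @export
two_locus_haplotype_freqs <- function(g, i, j) {
  g1 <- g$calls[, i]
  g2 <- g$calls[, j]
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 2) stop("need at least 2 parents with calls at both loci")
  # reference-allele dosages
  a1 <- 2L - g1
  a2 <- 2L - g2
  n_hap <- 2L * length(g1)
  # determined contributions (at most one het)
  det <- !(g1 == 1L & g2 == 1L)
  cnt <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  if (any(det)) {
    for (k in which(det)) {
      h1 <- c(rep("A", a1[k]), rep("a", 2L - a1[k]))
      h2 <- c(rep("B", a2[k]), rep("b", 2L - a2[k]))
      if (g1[k] == 1L) {           # het at locus 1 only: pair each copy
        cnt[paste0("A", h2[1])] <- cnt[paste0("A", h2[1])] + 1
        cnt[paste0("a", h2[2])] <- cnt[paste0("a", h2[2])] + 1
      } else if (g2[k] == 1L) {
        cnt[paste0(h1[1], "B")] <- cnt[paste0(h1[1], "B")] + 1
        cnt[paste0(h1[2], "b")] <- cnt[paste0(h1[2], "b")] + 1
      } else {
        cnt[paste0(h1[1], h2[1])] <- cnt[paste0(h1[1], h2[1])] + 2
      }
    }
  }
  n_dh <- sum(!det)
  if (n_dh == 0L) {
    return(list(freqs = cnt / n_hap, n = n_hap))
  }
  # EM over phase of double heterozygotes
  pA <- mean(a1) / 2
  pB <- mean(a2) / 2
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  for (iter in seq_len(100L)) {
    cis <- p["AB"] * p["ab"]
    trans <- p["Ab"] * p["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    e <- cnt
    e["AB"] <- e["AB"] + n_dh * w
    e["ab"] <- e["ab"] + n_dh * w
    e["Ab"] <- e["Ab"] + n_dh * (1 - w)
    e["aB"] <- e["aB"] + n_dh * (1 - w)
    p_new <- e / n_hap
    if (max(abs(p_new - p)) < 1e-6) {
      p <- p_new
      break
    }
    p <- p_new
  }
  list(freqs = p, n = n_hap)
}

#' D' and its likelihood-based confidence interval
#'
#' Computes `D = p_AB - p_A p_B` and `D' = |D| / Dmax` with
#' `Dmax = min(p_A p_b, p_a p_B)` for `D > 0` and
#' `min(p_A p_B, p_a p_b)` otherwise. The confidence interval follows the
#' Gabriel/Haploview convention: the multinomial likelihood of the
#' estimated haplotype counts is evaluated on a grid of D' values over
#' `[0, 1]`, normalized, and the bounds are the grid points one step
#' outside the 5th and 95th percentiles of that distribution.
#'
#' A pair is classified `strong_ld` when `ci_low >= 0.70` and
#' `ci_high >= 0.98`, `strong_recomb` when `ci_high < 0.90`; pairs in
#' either class are "informative" for block partitioning. Monomorphic
#' pairs are uninformative and carry no CI.
#'
#' @param freqs haplotype frequencies (AB, Ab, aB, ab), as from
#'   [two_locus_haplotype_freqs()].
#' @param n_haplotypes number of gametes behind `freqs` (>= 4).
#' @param grid_points number of grid points for the likelihood (default
#'   101, i.e. steps of 0.01).
#' @param ci_strong_low,ci_strong_high,ci_recomb Gabriel thresholds.
#' @return An object of class `pair_ld`: list with `dprime`, `ci_low`,
#'   `ci_high`, `informative`, `strong_ld`, `strong_recomb`.
#' @export
dprime_ci <- function(freqs, n_haplotypes, grid_points = 101L,
                      ci_strong_low = 0.70, ci_strong_high = 0.98,
                      ci_recomb = 0.90) {
  if (n_haplotypes < 4) stop("need at least 4 haplotypes")
  p <- freqs / sum(freqs)
  pA <- p[1] + p[2]
  pB <- p[1] + p[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(structure(
      list(dprime = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           informative = FALSE, strong_ld = FALSE, strong_recomb = FALSE),
      class = "pair_ld"
    ))
  }
  D <- p[1] - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (D == 0) 0 else abs(D) / dmax
  dprime <- min(dprime, 1)
  sgn <- if (D >= 0) 1 else -1

  grid <- seq(0, 1, length.out = grid_points)
  counts <- p * n_haplotypes
  ll <- vapply(grid, function(d) {
    Dd <- sgn * d * dmax
    h <- c(pA * pB + Dd, pA * (1 - pB) - Dd, (1 - pA) * pB - Dd,
           (1 - pA) * (1 - pB) + Dd)
    h <- pmax(h, 1e-12)
    sum(counts * log(h))
  }, numeric(1))
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  i_low <- which(cum > 0.05)[1]
  ci_low <- grid[max(i_low - 1L, 1L)]
  rev_cum <- rev(cumsum(rev(lik))) / sum(lik)
  i_high <- max(which(rev_cum > 0.05))
  ci_high <- grid[min(i_high + 1L, grid_points)]

  strong_ld <- ci_low >= ci_strong_low && ci_high >= ci_strong_high
  strong_recomb <- ci_high < ci_recomb
  structure(
    list(dprime = unname(dprime), ci_low = unname(ci_low),
         ci_high = unname(ci_high),
         informative = strong_ld || strong_recomb,
         strong_ld = strong_ld, strong_recomb = strong_recomb),
    class = "pair_ld"
  )
}

#' @export
print.pair_ld <- function(x, ...) {
  cat(sprintf("D' = %.3f, CI [%.2f, %.2f], %s\n", x$dprime, x$ci_low,
              x$ci_high,
              if (x$strong_ld) "strong LD"
              else if (x$strong_recomb) "strong recombination"
              else "uninformative"))
  invisible(x)
}

pair_ld_snps <- function(g, i, j, ...) {
  hf <- two_locus_haplotype_freqs(g, i, j)
  dprime_ci(hf$freqs, hf$n, ...)
}

#' Partition SNPs into LD blocks (confidence-interval method)
#'
#' Gabriel-style rules: a candidate interval of >= 2 SNPs is a block iff
#' its outermost pair is in strong LD, at least `min_strong_frac` of its
#' informative pairs are in strong LD, and its bp span does not exceed
#' `max_distance_bp`. Overlapping candidates are resolved greedily,
#' largest bp span first, ties by leftmost start. Inputs should be
#' MAF-filtered and imputed.
#'
#' @param g a [geno_matrix()].
#' @param max_distance_bp maximum block span (default 200 kb).
#' @param min_strong_frac minimum fraction of informative pairs in strong
#'   LD (default 0.95).
#' @param ... passed to [dprime_ci()] (thresholds, grid resolution).
#' @return data.frame of blocks: chrom, start_bp, end_bp, first (column
#'   index of first SNP), last, n_snps, id. Zero rows when no block is
#'   found.
#' @export
partition_blocks <- function(g, max_distance_bp = 200000L,
                             min_strong_frac = 0.95, ...) {
  out <- NULL
  for (ch in unique(g$snps$chrom)) {
    idx <- which(g$snps$chrom == ch)
    if (length(idx) < 2) next
    pos <- g$snps$pos[idx]
    k <- length(idx)
    strong <- matrix(FALSE, k, k)
    info <- matrix(FALSE, k, k)
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (pos[b] - pos[a] > max_distance_bp) next
        pl <- pair_ld_snps(g, idx[a], idx[b], ...)
        strong[a, b] <- isTRUE(pl$strong_ld)
        info[a, b] <- isTRUE(pl$informative)
      }
    }
    cand <- NULL
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (pos[b] - pos[a] > max_distance_bp) next
        if (!strong[a, b]) next
        sub_s <- strong[a:b, a:b]
        sub_i <- info[a:b, a:b]
        ni <- sum(sub_i[upper.tri(sub_i)])
        ns <- sum(sub_s[upper.tri(sub_s)])
        if (ni == 0 || ns / ni < min_strong_frac) next
        cand <- rbind(cand, data.frame(first = a, last = b,
                                       span = pos[b] - pos[a]))
      }
    }
    if (is.null(cand)) next
    cand <- cand[order(-cand$span, cand$first), , drop = FALSE]
    taken <- rep(FALSE, k)
    for (r in seq_len(nrow(cand))) {
      rng <- cand$first[r]:cand$last[r]
      if (any(taken[rng])) next
      taken[rng] <- TRUE
      out <- rbind(out, data.frame(
        chrom = ch, start_bp = pos[cand$first[r]], end_bp = pos[cand$last[r]],
        first = idx[cand$first[r]], last = idx[cand$last[r]],
        n_snps = cand$last[r] - cand$first[r] + 1L,
        stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), first = integer(), last = integer(),
                      n_snps = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out$id <- block_id(out$chrom, out$start_bp, out$end_bp)
  out
}

#' Block identifiers
#'
#' Blocks are named `<chrom>_BLOCK_<start>_<end>`; [parse_block_id()]
#' recovers the coordinates.
#'
#' @param chrom,start_bp,end_bp block coordinates (1-based inclusive).
#' @return Character vector of ids.
#' @export
block_id <- function(chrom, start_bp, end_bp) {
  if (length(chrom) == 0) return(character())
  sprintf("%s_BLOCK_%d_%d", chrom, start_bp, end_bp)
}

#' @rdname block_id
#' @param id block id string(s).
#' @export
parse_block_id <- function(id) {
  m <- regmatches(id, regexec("^(.+)_BLOCK_([0-9]+)_([0-9]+)$", id))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("not a block id: ", paste(id[bad], collapse = ", "))
  data.frame(
    chrom = vapply(m, `[`, "", 2),
    start_bp = as.integer(vapply(m, `[`, "", 3)),
    end_bp = as.integer(vapply(m, `[`, "", 4)),
    stringsAsFactors = FALSE
  )
}

#' Write block definitions as BED
#'
#' Converts internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param blocks data.frame from [partition_blocks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(blocks$chrom, blocks$start_bp - 1L, blocks$end_bp,
                    blocks$id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
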