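# Small in-code fixtures and independent oracles used across test files.

# genotype matrix from a plain call matrix (parents x snps)
make_geno <- function(calls, chrom = "1", pos = NULL, ref = "A", alt = "G") {
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("P%02d", seq_len(nrow(calls)))
  }
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000L
  geno_matrix(calls, data.frame(
    chrom = rep_len(chrom, ncol(calls)), pos = pos,
    ref = rep_len(ref, ncol(calls)), alt = rep_len(alt, ncol(calls)),
    stringsAsFactors = FALSE
  ))
}

# panel of hom parents realizing given two-locus haplotype counts (no hets)
make_two_locus_panel <- function(n_AB, n_Ab, n_aB, n_ab) {
  calls <- rbind(
    matrix(rep(c(0L, 0L), n_AB), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 2L), n_Ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 0L), n_aB), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 2L), n_ab), ncol = 2, byrow = TRUE)
  )
  make_geno(calls)
}

# random small panel with planted block structure plus recombination noise
random_panel <- function(seed, max_snps = 12) {
  set.seed(seed)
  k <- sample(4:max_snps, 1)
  n <- sample(20:40, 1)
  pos <- cumsum(sample(c(500L, 2000L, 50000L, 250000L), k, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)))
  # segment SNPs into runs sharing haplotypes
  seg <- cumsum(stats::runif(k) < 0.35)
  calls <- matrix(0L, n, k)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    nh <- sample(2:3, 1)
    pat <- matrix(sample(0:1, nh * length(idx), replace = TRUE),
                  nh, length(idx))
    hap <- sample(nh, n, replace = TRUE)
    calls[, idx] <- 2L * pat[hap, , drop = FALSE]
  }
  # sprinkle recombination-like flips
  flip <- matrix(stats::runif(n * k) < 0.05, n, k)
  calls[flip] <- 2L - calls[flip]
  make_geno(calls, pos = pos)
}

# brute-force reference for partition_blocks: enumerate every interval,
# apply the Gabriel rules directly, resolve overlaps largest-span-first
oracle_partition <- function(g, max_distance_bp = 200000L,
                             min_strong_frac = 0.95) {
  res <- NULL
  for (ch in unique(g$snps$chrom)) {
    idx <- which(g$snps$chrom == ch)
    k <- length(idx)
    if (k < 2) next
    pos <- g$snps$pos[idx]
    cand <- NULL
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (pos[b] - pos[a] > max_distance_bp) next
        n_strong <- 0
        n_info <- 0
        for (x in a:(b - 1)) {
          for (y in (x + 1):b) {
            pl <- gcaldb:::pair_ld_snps(g, idx[x], idx[y])
            if (pl$informative) n_info <- n_info + 1
            if (pl$strong_ld) n_strong <- n_strong + 1
          }
        }
        outer <- gcaldb:::pair_ld_snps(g, idx[a], idx[b])
        if (!outer$strong_ld) next
        if (n_info == 0 || n_strong / n_info < min_strong_frac) next
        cand <- rbind(cand, data.frame(a = a, b = b, span = pos[b] - pos[a]))
      }
    }
    if (is.null(cand)) next
    cand <- cand[order(-cand$span, cand$a), , drop = FALSE]
    used <- rep(FALSE, k)
    for (r in seq_len(nrow(cand))) {
      rng <- cand$a[r]:cand$b[r]
      if (any(used[rng])) next
      used[rng] <- TRUE
      res <- rbind(res, data.frame(chrom = ch, start_bp = pos[cand$a[r]],
                                   end_bp = pos[cand$b[r]],
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(res)) {
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), stringsAsFactors = FALSE))
  }
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# all-pairs LSD letter grouping: maximal cliques of the non-significance
# graph on means sorted descending (cliques are intervals in sorted order)
oracle_letters <- function(means, mse, df_error, n_per_mean, alpha = 0.01) {
  lsd <- qt(1 - alpha / 2, df_error) * sqrt(2 * mse / n_per_mean)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  nonsig <- outer(m, m, function(x, y) abs(x - y) <= lsd + 1e-12)
  cliques <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (all(nonsig[i:j, i:j])) {
        # maximal: cannot extend left or right
        left_ok <- i == 1 || !all(nonsig[(i - 1):j, (i - 1):j])
        right_ok <- j == k || !all(nonsig[i:(j + 1), i:(j + 1)])
        if (left_ok && right_ok) cliques[[length(cliques) + 1]] <- c(i, j)
      }
    }
  }
  cliques <- unique(cliques)
  cliques <- cliques[order(vapply(cliques, `[`, 0, 1))]
  lab <- character(k)
  for (ci in seq_along(cliques)) {
    rng <- cliques[[ci]][1]:cliques[[ci]][2]
    lab[rng] <- paste0(lab[rng], letters[ci])
  }
  out <- character(k)
  out[ord] <- lab
  names(out) <- names(means)
  out
}

# explicit sums-of-squares one-way ANOVA for cross-checking associate()
oracle_oneway <- function(values, classes) {
  cl <- factor(classes)
  grand <- mean(values)
  ssb <- sum(tapply(values, cl, function(x) length(x) * (mean(x) - grand)^2))
  sst <- sum((values - grand)^2)
  ssw <- sst - ssb
  dfb <- nlevels(cl) - 1
  dfw <- length(values) - nlevels(cl)
  f <- (ssb / dfb) / (ssw / dfw)
  list(ss_between = ssb, ss_total = sst, f = f,
       p = pf(f, dfb, dfw, lower.tail = FALSE), r2 = ssb / sst)
}

# standard 14-parent simulation setup used by recovery tests
recovery_blocks <- function() {
  list(
    block_spec("1", 100000, 3, 5000, c(0.5, 0.5)),
    block_spec("1", 400000, 3, 5000, c(0.6, 0.4)),
    block_spec("1", 900000, 1, 1, c(0.5, 0.5)),
    block_spec("2", 150000, 3, 6000, c(0.5, 0.5)),
    block_spec("2", 600000, 1, 1, c(0.6, 0.4)),
    block_spec("2", 800000, 1, 1, c(0.7, 0.3))
  )
}
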