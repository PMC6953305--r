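#' Specify one LD block for the parental-panel simulator
#'
#' A block is a run of tightly linked SNPs carried as whole haplotypes.
#' Haplotype allele patterns are assigned so that every haplotype is
#' distinct: haplotype h gets the bits of h - 1 (over ceil(log2(n))
#' bits) tiled across the member SNPs, which for 2-3 haplotypes keeps
#' every SNP pair in complete LD (at most three of the four gametes
#' present).
#'
#' @param chrom chromosome label.
#' @param start_bp 1-based position of the first SNP.
#' @param n_snps number of member SNPs (>= 1; 1 gives a singleton SNP).
#' @param spacing_bp distance between adjacent member SNPs.
#' @param hap_freqs haplotype frequency vector (>= 2 haplotypes, sums to 1).
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(chrom, start_bp, n_snps, spacing_bp, hap_freqs) {
  stopifnot(n_snps >= 1, spacing_bp >= 1, start_bp >= 1)
  if (length(hap_freqs) < 2) stop("need at least 2 haplotypes")
  if (abs(sum(hap_freqs) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  if (any(hap_freqs < 0)) stop("haplotype frequencies must be non-negative")
  structure(
    list(chrom = as.character(chrom), start_bp = as.integer(start_bp),
         n_snps = as.integer(n_snps), spacing_bp = as.integer(spacing_bp),
         hap_freqs = hap_freqs),
    class = "block_spec"
  )
}

block_span <- function(b) {
  c(b$start_bp, b$start_bp + (b$n_snps - 1L) * b$spacing_bp)
}

# distinct binary allele patterns, one row per haplotype
hap_patterns <- function(n_hap, n_snps) {
  nbits <- max(1L, ceiling(log2(n_hap)))
  pat <- matrix(0L, n_hap, n_snps)
  for (h in seq_len(n_hap)) {
    bits <- as.integer(intToBits(h - 1L))[seq_len(nbits)]
    pat[h, ] <- bits[((seq_len(n_snps) - 1L) %% nbits) + 1L]
  }
  pat
}

#' Simulate an inbred parental panel organized in LD blocks
#'
#' Each parent draws one haplotype per block from the block's haplotype
#' frequencies and is homozygous for it, except that a `het_rate` fraction
#' of calls is switched to heterozygous and a `missing_rate` fraction is
#' set missing (emulating residual heterozygosity and missing GBS calls).
#'
#' @param blocks list of [block_spec()]; blocks on the same chromosome must
#'   not overlap.
#' @param n_parents number of parents.
#' @param het_rate,missing_rate per-call probabilities in `[0, 1]`.
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @return A [geno_matrix()] with parents named `P01`, `P02`, ...
#' @export
simulate_parents <- function(blocks, n_parents, het_rate = 0.02,
                             missing_rate = 0.05, seed = 1L) {
  stopifnot(het_rate >= 0, het_rate <= 1, missing_rate >= 0, missing_rate <= 1)
  for (b in blocks) if (!inherits(b, "block_spec")) stop("blocks must be block_spec objects")
  by_chrom <- split(blocks, vapply(blocks, `[[`, "", "chrom"))
  for (bs in by_chrom) {
    if (length(bs) < 2) next
    spans <- t(vapply(bs, block_span, numeric(2)))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (any(spans[-1, 1] <= spans[-nrow(spans), 2])) {
      stop("overlapping block coordinates on chromosome ", bs[[1]]$chrom)
    }
  }
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_parents))
  calls_list <- vector("list", length(blocks))
  snps_list <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    pat <- hap_patterns(length(b$hap_freqs), b$n_snps)
    hap <- sample.int(length(b$hap_freqs), n_parents, replace = TRUE,
                      prob = b$hap_freqs)
    calls_list[[k]] <- 2L * pat[hap, , drop = FALSE]
    snps_list[[k]] <- data.frame(
      chrom = b$chrom,
      pos = b$start_bp + (seq_len(b$n_snps) - 1L) * b$spacing_bp,
      ref = "A", alt = "G", stringsAsFactors = FALSE
    )
  }
  calls <- do.call(cbind, calls_list)
  snps <- do.call(rbind, snps_list)
  rownames(calls) <- ids
  if (het_rate > 0) {
    flip <- matrix(stats::runif(length(calls)) < het_rate, nrow(calls))
    calls[flip] <- 1L
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < missing_rate, nrow(calls))
    calls[drop] <- NA_integer_
  }
  ord <- order(snps$chrom, snps$pos)
  g <- geno_matrix(calls[, ord, drop = FALSE], snps[ord, , drop = FALSE])
  # the drawn (noise-free) genotypes: QTL ground truth for simulate_ncii
  true_calls <- do.call(cbind, calls_list)
  rownames(true_calls) <- ids
  g$true_calls <- true_calls[, ord, drop = FALSE]
  g
}

#' Specify a simulated GCA QTL
#'
#' A QTL sits on a set of SNP columns of the parental genotype matrix (a
#' block or one SNP) and shifts a parent's true GCA by the effect mapped
#' to the parent's haplotype at those columns. The haplotype key is the
#' concatenated genotype codes, e.g. `"222"` for a parent homozygous
#' alternate at a 3-SNP block; haplotypes without an entry get effect 0.
#'
#' @param trait trait label.
#' @param snp_idx integer vector of SNP column indices.
#' @param allele_effects named numeric vector: haplotype key to GCA shift
#'   (trait units); at least one effect must be nonzero and all finite.
#' @param direction `"higher_better"` or `"lower_better"` (bookkeeping for
#'   downstream superior-allele checks).
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(trait, snp_idx, allele_effects,
                     direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (is.null(names(allele_effects)) || any(names(allele_effects) == "")) {
    stop("`allele_effects` must be named by haplotype key")
  }
  if (!any(allele_effects != 0)) stop("at least one allele effect must be nonzero")
  if (any(!is.finite(allele_effects))) stop("allele effects must be finite")
  structure(
    list(trait = trait, snp_idx = as.integer(snp_idx),
         allele_effects = allele_effects, direction = direction),
    class = "qtl_spec"
  )
}

#' Configuration for the NCII phenotype simulator
#'
#' @param n_females,n_males numbers of female (CMS) and male (restorer)
#'   parents taken, in order, from the genotype matrix.
#' @param n_reps replicates per cross (default 3, a randomized complete
#'   block design with three replications).
#' @param mu named per-trait grand means (or a single number).
#' @param sca_sd standard deviation of cross-specific (SCA) deviations.
#' @param error_sd standard deviation of replicate error.
#' @param seed integer seed.
#' @param groups optional named list partitioning the design into
#'   independent NCII sets, each element `list(females =, males =)` with
#'   parent ids; defaults to one group named `"all"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_females, n_males, n_reps = 3L, mu = 50,
                       sca_sd = 0.5, error_sd = 1, seed = 1L, groups = NULL) {
  stopifnot(n_females >= 2, n_males >= 2, n_reps >= 1,
            sca_sd >= 0, error_sd >= 0)
  structure(
    list(n_females = as.integer(n_females), n_males = as.integer(n_males),
         n_reps = as.integer(n_reps), mu = mu, sca_sd = sca_sd,
         error_sd = error_sd, seed = as.integer(seed), groups = groups),
    class = "sim_config"
  )
}

#' Simulate NCII cross phenotypes with known GCA ground truth
#'
#' Each replicate value is composed as
#' `mu + g_female + g_male + s_cross + e`, where a parent's true GCA `g`
#' is the sum of its QTL allele effects, centered to mean zero within each
#' (group, parent class); `s` is an i.i.d. normal SCA deviation per cross
#' and trait, and `e` i.i.d. normal replicate error.
#'
#' @param parents a [geno_matrix()]; the first `n_females` parents are the
#'   females, the next `n_males` the males (or as listed in `cfg$groups`).
#' @param qtls list of [qtl_spec()] (may be empty).
#' @param cfg a [sim_config()].
#' @return A list with `traits` (long data.frame: female, male, replicate,
#'   trait, value), `truth` (data.frame: parent, class, group, trait,
#'   effect) and `design` (a [mating_design()]).
#' @export
simulate_ncii <- function(parents, qtls, cfg) {
  stopifnot(inherits(parents, "geno_matrix"), inherits(cfg, "sim_config"))
  ids <- parent_ids(parents)
  for (q in qtls) {
    if (any(q$snp_idx > n_snps(parents))) {
      stop("QTL references SNP index absent from the genotype matrix")
    }
  }
  if (is.null(cfg$groups)) {
    if (cfg$n_females + cfg$n_males > length(ids)) {
      stop("not enough parents for the requested design")
    }
    groups <- list(all = list(females = ids[seq_len(cfg$n_females)],
                              males = ids[cfg$n_females + seq_len(cfg$n_males)]))
  } else {
    groups <- cfg$groups
  }
  traits <- unique(vapply(qtls, `[[`, "", "trait"))
  if (length(traits) == 0) traits <- "trait1"
  mu <- cfg$mu
  if (is.null(names(mu))) mu <- stats::setNames(rep_len(mu, length(traits)), traits)

  set.seed(cfg$seed)
  # QTL genotype = the parent's true constitution where the simulator
  # recorded it (call-level het/missing noise must not alter biology)
  qtl_calls <- if (!is.null(parents$true_calls)) parents$true_calls else parents$calls
  raw_effect <- function(parent, trait) {
    tot <- 0
    for (q in qtls) {
      if (q$trait != trait) next
      key <- paste(qtl_calls[parent, q$snp_idx], collapse = "")
      e <- q$allele_effects[key]
      if (!is.na(e)) tot <- tot + unname(e)
    }
    tot
  }

  truth <- NULL
  tt <- NULL
  for (gname in names(groups)) {
    fem <- groups[[gname]]$females
    mal <- groups[[gname]]$males
    stopifnot(all(c(fem, mal) %in% ids))
    for (tr in traits) {
      gf <- vapply(fem, raw_effect, numeric(1), trait = tr)
      gm <- vapply(mal, raw_effect, numeric(1), trait = tr)
      gf <- gf - mean(gf)
      gm <- gm - mean(gm)
      truth <- rbind(
        truth,
        data.frame(parent = c(fem, mal),
                   class = rep(c("female", "male"), c(length(fem), length(mal))),
                   group = gname, trait = tr, effect = c(gf, gm),
                   stringsAsFactors = FALSE)
      )
      cross <- expand.grid(female = fem, male = mal,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      sca <- stats::rnorm(nrow(cross), 0, cfg$sca_sd)
      base <- mu[[tr]] + gf[cross$female] + gm[cross$male] + sca
      for (r in seq_len(cfg$n_reps)) {
        tt <- rbind(
          tt,
          data.frame(female = cross$female, male = cross$male, replicate = r,
                     trait = tr,
                     value = base + stats::rnorm(nrow(cross), 0, cfg$error_sd),
                     stringsAsFactors = FALSE)
        )
      }
    }
  }
  rownames(tt) <- rownames(truth) <- NULL
  design <- mating_design(groups)
  list(traits = tt, truth = truth, design = design)
}

#' Write simulator outputs to disk
#'
#' @param sim result of [simulate_ncii()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "gca_truth.csv"), row.names = FALSE)
  invisible(dir)
}
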