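#' Example LD-block layout for simulation experiments
#'
#' A compact two-chromosome panel: three multi-SNP blocks plus three
#' singleton SNPs, all with common haplotype frequencies — enough structure
#' to exercise block partitioning, marker construction, and association in
#' a 14-parent NCII experiment.
#'
#' @return List of [block_spec()].
#' @export
example_blocks <- function() {
  list(
    block_spec("1", 100000, 3, 5000, c(0.5, 0.5)),
    block_spec("1", 400000, 3, 5000, c(0.6, 0.4)),
    block_spec("1", 900000, 1, 1, c(0.5, 0.5)),
    block_spec("2", 150000, 3, 6000, c(0.5, 0.5)),
    block_spec("2", 600000, 1, 1, c(0.6, 0.4)),
    block_spec("2", 800000, 1, 1, c(0.7, 0.3))
  )
}

derive_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 100000L) * 10000L + as.integer(offset)
}

#' Power of the pipeline to recover a planted GCA QTL
#'
#' Monte Carlo experiment: a 14-parent (8 female x 6 male) NCII panel is
#' simulated with one QTL on the first LD block shifting GCA by
#' `effect` (default 3 trait units, i.e. 3 x the replicate error SD), the
#' full pipeline is run (impute, MAF filter, block partition, marker
#' construction, GCA fit, association scan), and a replicate counts as a
#' recovery when the top-ranked marker for the trait overlaps the QTL
#' block and passes alpha = 0.001.
#'
#' @param n_sim number of simulation replicates (default 200).
#' @param seed integer seed; each replicate derives its own sub-seed.
#' @param effect QTL allele effect in trait units.
#' @param error_sd replicate error SD.
#' @param sca_sd SCA deviation SD.
#' @param n_reps replicates per cross.
#' @return Recovery rate in `[0, 1]`.
#' @export
qtl_recovery_rate <- function(n_sim = 200, seed = 1, effect = 3,
                              error_sd = 1, sca_sd = 0.5, n_reps = 3) {
  blocks <- example_blocks()
  qtl_span <- c(blocks[[1]]$start_bp,
                blocks[[1]]$start_bp + (blocks[[1]]$n_snps - 1L) * blocks[[1]]$spacing_bp)
  qtl_chrom <- blocks[[1]]$chrom
  hits <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    sd_s <- derive_seed(seed, s)
    parents <- simulate_parents(blocks, 14, seed = sd_s)
    qtl <- qtl_spec("BRR", 1:3, stats::setNames(effect, "222"))
    sim <- simulate_ncii(parents, list(qtl),
                         sim_config(8, 6, n_reps = n_reps, sca_sd = sca_sd,
                                    error_sd = error_sd, seed = sd_s))
    fit <- fit_gca(sim$traits, sim$design, letters = FALSE)
    gi <- filter_maf(impute_missing(parents), 0.01)
    markers <- build_markers(gi, partition_blocks(gi))
    scan <- scan_markers(fit, markers, alpha_policy())
    tab <- scan$table[scan$table$trait == "BRR", ]
    if (nrow(tab) == 0) next
    top_id <- tab$marker[which.min(tab$p_value)]
    m <- markers[[which(vapply(markers, `[[`, "", "id") == top_id)]]
    covers <- m$chrom == qtl_chrom && m$start_bp <= qtl_span[2] &&
      m$end_bp >= qtl_span[1]
    hits[s] <- covers && min(tab$p_value) <= 0.001
  }
  mean(hits)
}

#' Empirical type-I error of the association scan under the null
#'
#' Simulates a 33-parent panel (two NCII sets, 8 x 6 and 13 x 6) with no
#' QTLs, estimates GCA from the noise-only phenotypes, scans `n_markers`
#' independent singleton markers, and returns the fraction of tests with
#' `P < alpha`, pooled over `n_sim` independent simulations.
#'
#' @param n_markers markers per simulation (default 1000).
#' @param n_sim independent simulations pooled (default 10).
#' @param seed integer seed.
#' @param alpha nominal level checked (default 0.01).
#' @return Pooled rejection fraction.
#' @export
null_type1_rate <- function(n_markers = 1000, n_sim = 10, seed = 1,
                            alpha = 0.01) {
  blocks <- lapply(seq_len(n_markers), function(k) {
    block_spec("1", k * 10000L, 1, 1, c(0.6, 0.4))
  })
  n_rej <- 0
  n_tests <- 0
  for (s in seq_len(n_sim)) {
    sd_s <- derive_seed(seed, 5000L + s)
    parents <- simulate_parents(blocks, 33, seed = sd_s)
    ids <- parent_ids(parents)
    groups <- list(
      set1 = list(females = ids[1:8], males = ids[9:14]),
      set2 = list(females = ids[15:27], males = ids[28:33])
    )
    sim <- simulate_ncii(parents, list(),
                         sim_config(8, 6, seed = sd_s, groups = groups))
    fit <- fit_gca(sim$traits, sim$design, letters = FALSE)
    gi <- filter_maf(impute_missing(parents), 0.01)
    markers <- build_markers(gi, NULL)
    scan <- scan_markers(fit, markers, alpha_policy())
    n_rej <- n_rej + sum(scan$table$p_value < alpha)
    n_tests <- n_tests + nrow(scan$table)
  }
  n_rej / n_tests
}

#' Zero-noise GCA recovery error
#'
#' Simulates a noise-free NCII experiment with a planted QTL and returns
#' the largest absolute deviation between estimated and true GCA effects
#' (machine precision when the estimator is exact on balanced data).
#'
#' @param seed integer seed.
#' @return Maximum absolute deviation.
#' @export
gca_zero_noise_error <- function(seed = 1) {
  parents <- simulate_parents(example_blocks(), 14, het_rate = 0,
                              missing_rate = 0, seed = derive_seed(seed, 99L))
  sim <- simulate_ncii(parents, list(qtl_spec("BRR", 1:3, c("222" = 3))),
                       sim_config(8, 6, sca_sd = 0, error_sd = 0,
                                  seed = derive_seed(seed, 99L)))
  fit <- fit_gca(sim$traits, sim$design, letters = FALSE)
  m <- merge(fit, sim$truth, by = c("parent", "class", "group", "trait"))
  max(abs(m$effect.x - m$effect.y))
}
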