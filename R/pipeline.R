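#' Packaged transcriptions of the published result tables
#'
#' Plain-text transcriptions of the study's three result tables ship under
#' `inst/extdata`: the 39 significant trait-SNPLDB associations
#' (trait, marker id, chromosome, P, R^2 in percent), the per-locus
#' homozygous/heterozygous group means with printed increments, and the
#' 33-parent x 9-trait superior-allele tally.
#'
#' @param which `"associations"`, `"increments"` or `"tally"`.
#' @return data.frame.
#' @export
paper_fixture <- function(which = c("associations", "increments", "tally")) {
  which <- match.arg(which)
  file <- c(associations = "table_significant_snpldbs.csv",
            increments = "table_group_increments.csv",
            tally = "table_superior_allele_tally.csv")[[which]]
  path <- system.file("extdata", file, package = "gcaldb", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Recompute summary statistics over the packaged result tables
#'
#' Independent arithmetic checks of the packaged transcriptions: row and
#' per-chromosome counts and R^2 summaries of the association table,
#' increments recomputed from the printed group means, and row/column sums
#' of the superior-allele tally.
#'
#' @return A list: `n_significant`, `per_chromosome` (named counts),
#'   `r2_overall` (mean/min/max), `r2_by_trait` (data.frame),
#'   `increments` (data.frame with recomputed_pct and printed_pct),
#'   `tally_col_sums`, `tally_row_sums`.
#' @export
verify_fixtures <- function() {
  t3 <- paper_fixture("associations")
  t4 <- paper_fixture("increments")
  t5 <- paper_fixture("tally")

  per_chrom <- table(t3$chromosome)
  r2_by_trait <- do.call(rbind, lapply(split(t3, t3$trait), function(x) {
    data.frame(trait = x$trait[1], n = nrow(x), mean_r2 = mean(x$r2_pct),
               min_r2 = min(x$r2_pct), max_r2 = max(x$r2_pct))
  }))
  rownames(r2_by_trait) <- NULL

  has_means <- !is.na(t4$mean_homozygous) & !is.na(t4$mean_heterozygous)
  inc <- t4[has_means, c("trait", "snpldb", "position_bp",
                         "mean_homozygous", "mean_heterozygous",
                         "increment_pct")]
  names(inc)[names(inc) == "increment_pct"] <- "printed_pct"
  inc$recomputed_pct <- increment_pct(inc$mean_homozygous,
                                      inc$mean_heterozygous)
  inc$consistent <- !is.na(inc$printed_pct) &
    abs(round(inc$recomputed_pct, 2) - inc$printed_pct) < 0.005
  rownames(inc) <- NULL

  traits <- setdiff(names(t5), c("parent", "subspecies", "class"))
  tmat <- as.matrix(t5[, traits])
  rownames(tmat) <- t5$parent

  list(
    n_significant = nrow(t3),
    per_chromosome = per_chrom,
    r2_overall = c(mean = mean(t3$r2_pct), min = min(t3$r2_pct),
                   max = max(t3$r2_pct)),
    r2_by_trait = r2_by_trait,
    increments = inc,
    tally_col_sums = colSums(tmat),
    tally_row_sums = rowSums(tmat)
  )
}

#' Pipeline configuration
#'
#' Bundles every tunable setting of the end-to-end analysis. Defaults are
#' the study settings: MAF threshold 0.01, maximum block span 200 kb,
#' Gabriel CI thresholds 0.70/0.98 (strong LD) and 0.90 (recombination),
#' association alpha 0.001 with CAS and AC at 0.01, LSD letters at
#' alpha 0.01.
#'
#' @param min_maf MAF filter threshold.
#' @param max_distance_bp maximum LD-block span in bp.
#' @param ci_strong_low,ci_strong_high,ci_recomb Gabriel CI thresholds.
#' @param min_strong_frac minimum strong-LD fraction among informative
#'   pairs.
#' @param rare_count_threshold rare-haplotype merge threshold.
#' @param policy an [alpha_policy()].
#' @param dirs a [trait_directions()] registry.
#' @param lsd_alpha LSD letter-grouping level.
#' @param per_group scan per group instead of pooled?
#' @param seed integer seed for any simulation step.
#' @return An object of class `run_config` (a list).
#' @export
run_config <- function(min_maf = 0.01, max_distance_bp = 200000L,
                       ci_strong_low = 0.70, ci_strong_high = 0.98,
                       ci_recomb = 0.90, min_strong_frac = 0.95,
                       rare_count_threshold = 2L, policy = alpha_policy(),
                       dirs = trait_directions(), lsd_alpha = 0.01,
                       per_group = FALSE, seed = 1L) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, max_distance_bp >= 1)
  structure(
    list(min_maf = min_maf, max_distance_bp = max_distance_bp,
         ci_strong_low = ci_strong_low, ci_strong_high = ci_strong_high,
         ci_recomb = ci_recomb, min_strong_frac = min_strong_frac,
         rare_count_threshold = rare_count_threshold, policy = policy,
         dirs = dirs, lsd_alpha = lsd_alpha, per_group = per_group,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full GCA-SNPLDB association pipeline
#'
#' Genotypes -> imputation -> MAF filter -> LD blocks -> SNPLDB markers ->
#' GCA estimation -> association scan -> superior-allele tally and cross
#' ranking. Deterministic given inputs and config. When `out_dir` is
#' given, every stage's output is written (VCF/TSV/BED/CSV) together with
#' a `manifest.yaml` of the settings used.
#'
#' @param genotypes a [geno_matrix()] (or a path readable by
#'   [read_genotypes()]).
#' @param traits long trait table (female, male, replicate, trait, value)
#'   or a CSV path.
#' @param design a [mating_design()].
#' @param cfg a [run_config()].
#' @param out_dir optional output directory.
#' @return A list: `genotypes` (filtered/imputed), `blocks`, `markers`,
#'   `gca`, `anova`, `scan`, `carriers`, `tally`, `cross_ranking`.
#' @export
run_pipeline <- function(genotypes, traits, design, cfg = run_config(),
                         out_dir = NULL) {
  if (is.character(genotypes)) {
    if (!file.exists(genotypes)) stop("genotype file not found: ", genotypes)
    genotypes <- read_genotypes(genotypes)
  }
  if (is.character(traits)) {
    if (!file.exists(traits)) stop("trait file not found: ", traits)
    traits <- utils::read.csv(traits, stringsAsFactors = FALSE)
  }
  stage_log("genio", "%d parents, %d SNPs", n_parents(genotypes),
            n_snps(genotypes))
  g <- impute_missing(genotypes)
  g <- filter_maf(g, cfg$min_maf)
  stage_log("genio", "%d SNPs after MAF >= %g filter", n_snps(g), cfg$min_maf)

  blocks <- partition_blocks(
    g, max_distance_bp = cfg$max_distance_bp,
    min_strong_frac = cfg$min_strong_frac,
    ci_strong_low = cfg$ci_strong_low, ci_strong_high = cfg$ci_strong_high,
    ci_recomb = cfg$ci_recomb
  )
  stage_log("ldblock", "%d block(s)", nrow(blocks))
  markers <- build_markers(g, blocks,
                           rare_count_threshold = cfg$rare_count_threshold)
  stage_log("markers", "%d SNPLDB marker(s)", length(markers))

  gca <- fit_gca(traits, design, alpha = cfg$lsd_alpha)
  av <- anova_gca(traits, design)
  stage_log("gca", "%d parent x trait effects", nrow(gca))

  scan <- scan_markers(gca, markers, policy = cfg$policy,
                       per_group = cfg$per_group)
  stage_log("assoc", "%d tests, %d significant", nrow(scan$table),
            nrow(scan$significant))

  carriers <- NULL
  tally <- NULL
  ranking <- NULL
  if (nrow(scan$significant) > 0) {
    carriers <- superior_carriers(scan, markers, cfg$dirs)
    tally <- tally_superior(carriers)
    females <- unlist(lapply(design$groups, `[[`, "females"))
    males <- unlist(lapply(design$groups, `[[`, "males"))
    ranking <- rank_crosses(carriers, females, males)
  }

  res <- list(genotypes = g, blocks = blocks, markers = markers, gca = gca,
              anova = av, scan = scan, carriers = carriers, tally = tally,
              cross_ranking = ranking)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genotypes(g, file.path(out_dir, "genotypes.vcf"), "vcf")
    write_blocks_bed(blocks, file.path(out_dir, "blocks.bed"))
    write_markers(markers, file.path(out_dir, "markers.tsv"))
    write_gca(gca, file.path(out_dir, "gca.csv"))
    utils::write.csv(av, file.path(out_dir, "anova.csv"), row.names = FALSE)
    write_assoc(scan, file.path(out_dir, "assoc_significant.csv"), TRUE)
    write_assoc(scan, file.path(out_dir, "assoc_full.csv"), FALSE)
    if (!is.null(tally)) {
      write_tally(tally, file.path(out_dir, "tally.csv"))
      utils::write.csv(ranking, file.path(out_dir, "cross_ranking.csv"),
                       row.names = FALSE)
    }
    manifest <- cfg
    manifest$policy <- list(default_alpha = cfg$policy$default_alpha,
                            overrides = as.list(cfg$policy$overrides))
    manifest$dirs <- stats::setNames(as.list(cfg$dirs$polarity), cfg$dirs$trait)
    yaml::write_yaml(lapply(unclass(manifest), function(x)
      if (is.data.frame(x)) as.list(x) else x),
      file.path(out_dir, "manifest.yaml"))
  }
  res
}
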