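#' Per-trait significance policy
#'
#' The scan uses a fixed per-trait alpha with no multiple-testing
#' correction (a deliberate, documented choice for this single-factor
#' design). The default mirrors the rice study settings: 0.001 for all
#' traits except chalky area size (CAS) and amylose content (AC) at 0.01.
#'
#' @param default_alpha alpha applied to traits without an override.
#' @param overrides named numeric vector of per-trait alphas.
#' @return An object of class `alpha_policy`.
#' @export
alpha_policy <- function(default_alpha = 0.001,
                         overrides = c(CAS = 0.01, AC = 0.01)) {
  stopifnot(default_alpha > 0, default_alpha < 1,
            all(overrides > 0), all(overrides < 1))
  structure(list(default_alpha = default_alpha, overrides = overrides),
            class = "alpha_policy")
}

policy_alpha <- function(policy, trait) {
  if (!is.null(policy$overrides) && trait %in% names(policy$overrides)) {
    unname(policy$overrides[[trait]])
  } else {
    policy$default_alpha
  }
}

#' Single-factor ANOVA association of values with marker alleles
#'
#' One-way ANOVA of per-parent response values (GCA effects) across the
#' allele classes of one marker: `F = MS_between / MS_within`, P from the
#' F distribution, `R^2 = SS_between / SS_total`. Classes with fewer than
#' `min_group_size` parents are dropped before testing. With fewer than
#' two usable classes the result is flagged untestable rather than raising
#' an error; with zero within-class variance but distinct class means the
#' P-value is the smallest representable positive double and the result is
#' flagged.
#'
#' @param values named numeric vector, one response value per parent.
#' @param marker a `snpldb_marker` (from [build_markers()]).
#' @param min_group_size smallest allele-class size used (default 2, so a
#'   within-class variance exists).
#' @return An object of class `assoc_result`: list with `marker_id`,
#'   `chrom`, `start_bp`, `f_stat`, `p_value`, `r_squared`,
#'   `group_means`, `group_sizes`, `df_between`, `df_within`, `n_used`,
#'   `testable`, `flag`.
#' @export
associate <- function(values, marker, min_group_size = 2L) {
  cls <- marker$assign[names(values)]
  ok <- !is.na(values) & !is.na(cls)
  v <- values[ok]
  cl <- cls[ok]
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_group_size]
  use <- cl %in% keep
  v <- v[use]
  cl <- factor(cl[use])
  res <- list(marker_id = marker$id, chrom = marker$chrom,
              start_bp = marker$start_bp,
              f_stat = NA_real_, p_value = NA_real_, r_squared = NA_real_,
              group_means = NULL, group_sizes = NULL,
              df_between = NA_integer_, df_within = NA_integer_,
              n_used = length(v), testable = FALSE, flag = NA_character_)
  class(res) <- "assoc_result"
  if (nlevels(cl) < 2L) {
    res$flag <- "untestable: fewer than 2 allele classes"
    return(res)
  }
  n <- length(v)
  k <- nlevels(cl)
  gmean <- c(tapply(v, cl, mean))
  gn <- c(tapply(v, cl, length))
  grand <- mean(v)
  ss_between <- sum(gn * (gmean - grand)^2)
  ss_total <- sum((v - grand)^2)
  ss_within <- ss_total - ss_between
  res$group_means <- gmean
  res$group_sizes <- gn
  res$df_between <- k - 1L
  res$df_within <- n - k
  res$testable <- TRUE
  if (ss_total <= 0) {                       # all values identical
    res$f_stat <- 0
    res$p_value <- 1
    res$r_squared <- 0
    return(res)
  }
  res$r_squared <- ss_between / ss_total
  if (ss_within <= .Machine$double.eps * ss_total && ss_between > 0) {
    res$f_stat <- Inf
    res$p_value <- .Machine$double.xmin
    res$flag <- "zero within-class variance"
    return(res)
  }
  res$f_stat <- (ss_between / res$df_between) / (ss_within / res$df_within)
  res$p_value <- stats::pf(res$f_stat, res$df_between, res$df_within,
                           lower.tail = FALSE)
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  if (!x$testable) {
    cat(sprintf("%s: %s\n", x$marker_id, x$flag))
  } else {
    cat(sprintf("%s: F(%d, %d) = %.3g, P = %.3g, R2 = %.1f%%\n",
                x$marker_id, x$df_between, x$df_within, x$f_stat,
                x$p_value, 100 * x$r_squared))
  }
  invisible(x)
}

#' Scan markers for association with GCA effects
#'
#' Runs [associate()] for every (trait, marker) pair. The response per
#' trait is the parents' GCA effect values pooled across groups and parent
#' classes (set `per_group = TRUE` to scan each group separately).
#'
#' @param gca a `gca_table` from [fit_gca()] (or any data.frame with
#'   parent, trait, effect and, if `per_group`, group).
#' @param markers list from [build_markers()].
#' @param policy an [alpha_policy()].
#' @param min_group_size passed to [associate()].
#' @param per_group scan within each group separately? (default FALSE:
#'   pooled, the canonical mode).
#' @return An object of class `assoc_scan`: list with `table` (data.frame
#'   of all testable results: trait, marker, chrom, start_bp, f_stat,
#'   p_value, r_squared, r2_pct, alpha, significant), `significant`
#'   (subset, sorted by trait, chromosome, position), and `results`
#'   (named list of `assoc_result`, keys `"<trait>|<marker id>"`).
#' @export
scan_markers <- function(gca, markers, policy = alpha_policy(),
                         min_group_size = 2L, per_group = FALSE) {
  gca <- as.data.frame(gca)
  slices <- if (per_group) split(gca, gca$group) else list(pooled = gca)
  rows <- list()
  results <- list()
  for (sl_name in names(slices)) {
    sl <- slices[[sl_name]]
    for (tr in unique(sl$trait)) {
      sub <- sl[sl$trait == tr, ]
      values <- stats::setNames(sub$effect, sub$parent)
      for (m in markers) {
        r <- associate(values, m, min_group_size = min_group_size)
        key <- paste0(tr, "|", m$id)
        if (per_group) key <- paste0(sl_name, "|", key)
        results[[key]] <- r
        if (!r$testable) next
        alpha <- policy_alpha(policy, tr)
        rows[[length(rows) + 1L]] <- data.frame(
          group = sl_name, trait = tr, marker = m$id, chrom = m$chrom,
          start_bp = m$start_bp, f_stat = r$f_stat, p_value = r$p_value,
          r_squared = r$r_squared, r2_pct = round(100 * r$r_squared, 1),
          alpha = alpha, significant = r$p_value <= alpha,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), trait = character(), marker = character(),
               chrom = character(), start_bp = integer(), f_stat = numeric(),
               p_value = numeric(), r_squared = numeric(), r2_pct = numeric(),
               alpha = numeric(), significant = logical())
  tab <- tab[order(tab$trait, tab$chrom, tab$start_bp), , drop = FALSE]
  rownames(tab) <- NULL
  sig <- tab[tab$significant, , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(table = tab, significant = sig, results = results,
                 policy = policy),
            class = "assoc_scan")
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("assoc_scan: %d tests, %d significant\n",
              nrow(x$table), nrow(x$significant)))
  invisible(x)
}

#' Write an association table to CSV
#'
#' Columns mirror the published significant-locus table: trait, SNPLDB id,
#' chromosome, P-value and R-squared in percent (1 decimal).
#'
#' @param scan an `assoc_scan`.
#' @param path output file.
#' @param significant_only write only the significant subset?
#' @return `path`, invisibly.
#' @export
write_assoc <- function(scan, path, significant_only = TRUE) {
  tab <- if (significant_only) scan$significant else scan$table
  out <- data.frame(trait = tab$trait, snpldb = tab$marker,
                    chromosome = tab$chrom, p_value = tab$p_value,
                    r2_pct = tab$r2_pct, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
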