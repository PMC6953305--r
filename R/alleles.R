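#' Trait polarity registry for the nine grain-quality traits
#'
#' A superior allele raises GCA where "higher is better" and lowers it
#' where "lower is better". Defaults: brown/milled/head rice rate and gel
#' consistency are higher-better; percentage of chalky grains, chalky area
#' size, chalkiness degree, gelatinization temperature (alkali spreading
#' score) and amylose content are lower-better.
#'
#' @param overrides optional named character vector trait -> polarity to
#'   override the defaults.
#' @return data.frame with columns `trait` and `polarity`.
#' @export
trait_directions <- function(overrides = NULL) {
  d <- data.frame(
    trait = c("BRR", "MRR", "HRR", "GC", "PCG", "CAS", "CD", "GT", "AC"),
    polarity = c(rep("higher_better", 4), rep("lower_better", 5)),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), d$trait)
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
    if (!all(overrides %in% c("higher_better", "lower_better"))) {
      stop("polarity must be 'higher_better' or 'lower_better'")
    }
    d$polarity[match(names(overrides), d$trait)] <- unname(overrides)
  }
  d
}

polarity_of <- function(dirs, trait) {
  i <- match(trait, dirs$trait)
  if (is.na(i)) stop("trait ", trait, " not in the direction registry")
  dirs$polarity[i]
}

#' Superior allele of an association result
#'
#' The allele class whose group mean GCA is maximal (higher-better) or
#' minimal (lower-better); ties break to the lexicographically smallest
#' allele id.
#'
#' @param res an `assoc_result` from [associate()] (must be testable).
#' @param polarity `"higher_better"` or `"lower_better"`.
#' @return Allele class label (character).
#' @export
superior_allele <- function(res, polarity = c("higher_better", "lower_better")) {
  polarity <- match.arg(polarity)
  if (!isTRUE(res$testable)) stop("untestable association result")
  m <- res$group_means
  best <- if (polarity == "higher_better") max(m) else min(m)
  cand <- sort(names(m)[m == best])
  cand[1]
}

#' Superior-allele carrier matrix over significant loci
#'
#' For each significant (trait, marker) pair, determines the superior
#' allele and which parents carry it. A parent carries the superior allele
#' when its assigned class equals it; at a singleton marker a residual
#' heterozygote (`"A/G"`) counts as a carrier if either allele copy
#' matches.
#'
#' @param scan an `assoc_scan` from [scan_markers()].
#' @param markers the marker list used for the scan.
#' @param dirs a [trait_directions()] registry.
#' @return Logical matrix, parents x significant loci; column names are
#'   `"<trait>|<marker id>"`, with the locus trait in attribute
#'   `"locus_trait"` and the superior allele in `"superior_allele"`.
#' @export
superior_carriers <- function(scan, markers, dirs = trait_directions()) {
  sig <- scan$significant
  marker_by_id <- stats::setNames(markers, vapply(markers, `[[`, "", "id"))
  parents <- names(markers[[1]]$assign)
  cn <- if (nrow(sig)) paste0(sig$trait, "|", sig$marker) else character()
  mat <- matrix(FALSE, length(parents), nrow(sig),
                dimnames = list(parents, cn))
  sup <- character(nrow(sig))
  for (r in seq_len(nrow(sig))) {
    key <- paste0(sig$trait[r], "|", sig$marker[r])
    res <- scan$results[[key]]
    m <- marker_by_id[[sig$marker[r]]]
    s <- superior_allele(res, polarity_of(dirs, sig$trait[r]))
    sup[r] <- s
    carrier <- m$assign == s
    if (m$type == "snp") {
      het <- grepl("/", m$assign, fixed = TRUE)
      carrier <- carrier | (het & vapply(strsplit(m$assign, "/", fixed = TRUE),
                                         function(a) s %in% a, logical(1)))
    }
    mat[, r] <- carrier[parents]
  }
  attr(mat, "locus_trait") <- sig$trait
  attr(mat, "superior_allele") <- sup
  mat
}

#' Tally superior alleles per parent and trait
#'
#' Cell (parent, trait) counts the significant trait loci at which the
#' parent carries the superior allele.
#'
#' @param carriers matrix from [superior_carriers()].
#' @param traits optional trait order for the columns (defaults to the
#'   nine-trait registry order restricted to observed traits).
#' @return Integer matrix, parents x traits.
#' @export
tally_superior <- function(carriers, traits = NULL) {
  locus_trait <- attr(carriers, "locus_trait")
  if (is.null(traits)) {
    reg <- trait_directions()$trait
    traits <- c(intersect(reg, unique(locus_trait)),
                setdiff(unique(locus_trait), reg))
  }
  out <- matrix(0L, nrow(carriers), length(traits),
                dimnames = list(rownames(carriers), traits))
  for (tr in traits) {
    cols <- which(locus_trait == tr)
    if (length(cols)) {
      out[, tr] <- as.integer(rowSums(carriers[, cols, drop = FALSE]))
    }
  }
  out
}

#' Group-mean increment between two genotype classes
#'
#' Percentage change of the class-2 mean relative to the class-1 mean,
#' `(mean2 - mean1) / mean1 * 100`, on the scale of the supplied values
#' (the published comparison uses trait-scale averages of a homozygous
#' group (1) versus a heterozygous/carrier group (2)).
#'
#' @param values named numeric vector (per parent or per cross).
#' @param classes named character vector of genotype classes for the same
#'   names.
#' @param class1,class2 the two class labels compared.
#' @return A list (class `increment_record`): `mean1`, `mean2`, `n1`,
#'   `n2`, `increment_pct` (NA with a flag when `mean1 == 0`).
#' @export
group_increment <- function(values, classes, class1, class2) {
  cl <- classes[names(values)]
  v1 <- values[!is.na(cl) & cl == class1]
  v2 <- values[!is.na(cl) & cl == class2]
  if (length(v1) == 0 || length(v2) == 0) stop("both classes must be non-empty")
  m1 <- mean(v1)
  m2 <- mean(v2)
  structure(
    list(mean1 = m1, mean2 = m2, n1 = length(v1), n2 = length(v2),
         increment_pct = increment_pct(m1, m2),
         flag = if (m1 == 0) "undefined: class-1 mean is zero" else NA_character_),
    class = "increment_record"
  )
}

#' @rdname group_increment
#' @param mean1,mean2 the two group means.
#' @export
increment_pct <- function(mean1, mean2) {
  ifelse(mean1 == 0, NA_real_, (mean2 - mean1) / mean1 * 100)
}

#' Rank crosses by combined superior-allele coverage
#'
#' Scores every (female, male) pair by the number of significant loci at
#' which at least one of the two parents carries the superior allele (the
#' pyramiding potential of the cross). Ties are ordered by female then
#' male label.
#'
#' @param carriers matrix from [superior_carriers()].
#' @param females,males parent ids (rows of `carriers`).
#' @return data.frame: female, male, score, sorted by decreasing score.
#' @export
rank_crosses <- function(carriers, females, males) {
  stopifnot(all(c(females, males) %in% rownames(carriers)))
  pairs <- expand.grid(female = females, male = males,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs$score <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(carriers[pairs$female[i], ] | carriers[pairs$male[i], ])
  }, numeric(1))
  pairs <- pairs[order(-pairs$score, pairs$female, pairs$male), ]
  rownames(pairs) <- NULL
  pairs
}

#' Write a superior-allele tally as CSV
#'
#' Zeroes are rendered as dashes, matching the published presentation.
#'
#' @param tally matrix from [tally_superior()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tally <- function(tally, path) {
  ch <- matrix(as.character(tally), nrow(tally), ncol(tally),
               dimnames = dimnames(tally))
  ch[tally == 0] <- "-"
  utils::write.csv(data.frame(parent = rownames(ch), ch, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
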