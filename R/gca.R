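#' NCII mating design
#'
#' A North Carolina design II crosses every female with every male. The
#' design may consist of several independent NCII sets (e.g. one per
#' subspecies), each a complete factorial; combining-ability estimation is
#' carried out within each set.
#'
#' @param groups named list; each element is `list(females =, males =)`
#'   giving parent ids. A single set can be passed directly as
#'   `mating_design(list(all = list(females = ..., males = ...)))`.
#' @return An object of class `mating_design` with elements `groups` and
#'   `crosses` (data.frame: female, male, group).
#' @export
mating_design <- function(groups) {
  if (is.null(names(groups))) stop("`groups` must be a named list")
  crosses <- NULL
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (length(g$females) < 2 || length(g$males) < 2) {
      stop("each group needs at least 2 females and 2 males")
    }
    if (length(intersect(g$females, g$males))) {
      stop("a parent cannot be both female and male in group ", gname)
    }
    cr <- expand.grid(female = g$females, male = g$males,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cr$group <- gname
    crosses <- rbind(crosses, cr)
  }
  structure(list(groups = groups, crosses = crosses), class = "mating_design")
}

#' @export
print.mating_design <- function(x, ...) {
  for (gname in names(x$groups)) {
    g <- x$groups[[gname]]
    cat(sprintf("group %s: %d females x %d males = %d crosses\n",
                gname, length(g$females), length(g$males),
                length(g$females) * length(g$males)))
  }
  invisible(x)
}

check_trait_table <- function(traits, design) {
  need <- c("female", "male", "replicate", "trait", "value")
  if (!all(need %in% names(traits))) {
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  }
  for (tr in unique(traits$trait)) {
    tt <- traits[traits$trait == tr, ]
    have <- paste(tt$female, tt$male)
    want <- paste(design$crosses$female, design$crosses$male)
    miss <- setdiff(want, unique(have))
    if (length(miss)) {
      stop("trait ", tr, ": missing cross(es): ", paste(miss, collapse = "; "))
    }
    reps <- table(have)
    if (length(unique(reps)) != 1) {
      stop("trait ", tr, ": unequal replicate counts across crosses")
    }
  }
  invisible(TRUE)
}

#' Estimate general combining ability effects
#'
#' Per group and trait, a parent's GCA effect is the mean of all replicate
#' values of its crosses minus the group grand mean (the line x tester
#' main-effect estimate for a balanced complete factorial). Effects sum to
#' zero within each (group, class). When `letters = TRUE` and there are
#' at least two replicates, parents within each (group, class) also get an
#' LSD letter group computed from the replicate-level ANOVA error mean
#' square at level `alpha` (shared letters mean not significantly
#' different).
#'
#' @param traits long trait table (female, male, replicate, trait, value).
#' @param design a [mating_design()].
#' @param letters add LSD letter groups? (default TRUE when possible).
#' @param alpha significance level for the LSD grouping (default 0.01).
#' @return A `gca_table`: data.frame with columns parent, class, group,
#'   trait, effect, letters.
#' @export
fit_gca <- function(traits, design, letters = TRUE, alpha = 0.01) {
  check_trait_table(traits, design)
  out <- NULL
  for (gname in names(design$groups)) {
    grp <- design$groups[[gname]]
    for (tr in unique(traits$trait)) {
      tt <- traits[traits$trait == tr & traits$female %in% grp$females &
                     traits$male %in% grp$males, ]
      grand <- mean(tt$value)
      gf <- tapply(tt$value, tt$female, mean)[grp$females] - grand
      gm <- tapply(tt$value, tt$male, mean)[grp$males] - grand
      n_reps <- max(tt$replicate)
      res <- data.frame(
        parent = c(grp$females, grp$males),
        class = rep(c("female", "male"), c(length(gf), length(gm))),
        group = gname, trait = tr, effect = unname(c(gf, gm)),
        letters = NA_character_, stringsAsFactors = FALSE
      )
      if (letters && n_reps >= 2) {
        av <- anova_gca_one(tt)
        mse <- av$ms[av$term == "error"]
        dfe <- av$df[av$term == "error"]
        res$letters[res$class == "female"] <-
          lsd_letters(gf, mse, dfe, length(grp$males) * n_reps, alpha)
        res$letters[res$class == "male"] <-
          lsd_letters(gm, mse, dfe, length(grp$females) * n_reps, alpha)
      }
      out <- rbind(out, res)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("gca_table", "data.frame")
  out
}

# two-way ANOVA of one group x trait slice (replicate-level values)
anova_gca_one <- function(tt) {
  tt$female <- factor(tt$female)
  tt$male <- factor(tt$male)
  n_reps <- max(tt$replicate)
  fml <- if (n_reps >= 2) value ~ female + male + female:male else value ~ female + male
  fit <- stats::aov(fml, data = tt)
  s <- summary(fit)[[1]]
  term <- trimws(rownames(s))
  term[term == "Residuals"] <- "error"
  term[term == "female:male"] <- "female:male"
  data.frame(
    term = term, df = s$Df, ss = s$`Sum Sq`, ms = s$`Mean Sq`,
    f_value = s$`F value`, p_value = s$`Pr(>F)`,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Two-way ANOVA of the NCII trait table
#'
#' Decomposes replicate-level values into female, male, female x male
#' interaction, and error strata per group and trait. With a single
#' replicate the interaction is confounded with error and its row is
#' absent.
#'
#' @inheritParams fit_gca
#' @return data.frame: group, trait, term, df, ss, ms, f_value, p_value.
#' @export
anova_gca <- function(traits, design) {
  check_trait_table(traits, design)
  out <- NULL
  for (gname in names(design$groups)) {
    grp <- design$groups[[gname]]
    for (tr in unique(traits$trait)) {
      tt <- traits[traits$trait == tr & traits$female %in% grp$females &
                     traits$male %in% grp$males, ]
      av <- anova_gca_one(tt)
      av <- cbind(group = gname, trait = tr, av, stringsAsFactors = FALSE)
      out <- rbind(out, av)
    }
  }
  rownames(out) <- NULL
  out
}

#' LSD letter grouping of a set of means
#'
#' Classic least-significant-difference display: means are sorted in
#' descending order and means whose difference does not exceed
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 * mse / n_per_mean)` share a
#' letter. Groups are the maximal runs of sorted means spanning at most
#' one LSD; letters are assigned in order `a`, `b`, ...
#'
#' @param means named numeric vector of means (or effects).
#' @param mse error mean square from the ANOVA.
#' @param df_error error degrees of freedom.
#' @param n_per_mean number of observations behind each mean.
#' @param alpha significance level (default 0.01).
#' @return Character vector of letter groups, in the order of `means`.
#' @export
lsd_letters <- function(means, mse, df_error, n_per_mean, alpha = 0.01) {
  lsd <- stats::qt(1 - alpha / 2, df_error) * sqrt(2 * mse / n_per_mean)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  # maximal intervals [i, j] with m[i] - m[j] <= lsd
  groups <- list()
  for (i in seq_len(k)) {
    j <- max(which(m[i] - m <= lsd + 1e-12))
    groups[[i]] <- c(i, j)
  }
  # drop intervals contained in an earlier (wider) one
  keep <- rep(TRUE, k)
  for (i in seq_len(k)[-1]) {
    if (groups[[i]][2] <= groups[[i - 1]][2]) keep[i] <- FALSE
  }
  groups <- groups[keep]
  lab <- character(k)
  for (gi in seq_along(groups)) {
    rng <- groups[[gi]][1]:groups[[gi]][2]
    lab[rng] <- paste0(lab[rng], letters[gi])
  }
  out <- character(k)
  out[ord] <- lab
  names(out) <- names(means)
  out
}

#' Write a GCA table to CSV
#' @param g a `gca_table` from [fit_gca()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gca <- function(g, path) {
  utils::write.csv(as.data.frame(g), path, row.names = FALSE)
  invisible(path)
}
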