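#' Five-level quality scoring tables
#'
#' Grain-quality grading assigns each trait value one of five levels
#' (level 1 best) and a score per level; the nine-trait total has a full
#' score of 90. A level table holds, per trait, the grading direction,
#' four ordered cut points separating the five levels (from the best level
#' down), five non-increasing scores, and an optional admissible value
#' range.
#'
#' For a `higher_better` trait with cuts `b1 > b2 > b3 > b4`, a value `v`
#' is level 1 when `v >= b1`, level 2 when `v >= b2`, ..., level 5
#' otherwise; boundary values land in the better level. `lower_better`
#' traits use ascending cuts with `<=`.
#'
#' @param traits named list; each element a list with `direction`
#'   (`"higher_better"`/`"lower_better"`), `cuts` (length 4), `scores`
#'   (length 5, non-increasing), and optional `range` (length-2 admissible
#'   interval).
#' @return An object of class `level_table`.
#' @export
level_table <- function(traits) {
  for (tr in names(traits)) {
    x <- traits[[tr]]
    if (!x$direction %in% c("higher_better", "lower_better")) {
      stop(tr, ": bad direction")
    }
    if (length(x$cuts) != 4) stop(tr, ": need 4 cut points")
    ord <- if (x$direction == "higher_better") -x$cuts else x$cuts
    if (is.unsorted(ord, strictly = TRUE)) {
      stop(tr, ": cuts must be strictly ordered from the best level down")
    }
    if (length(x$scores) != 5) stop(tr, ": need 5 scores")
    if (is.unsorted(rev(x$scores))) stop(tr, ": scores must be non-increasing")
  }
  structure(traits, class = "level_table")
}

#' Read/write level tables as YAML
#' @param path YAML file.
#' @return [read_level_table()]: a `level_table`.
#' @export
read_level_table <- function(path) {
  level_table(yaml::read_yaml(path))
}

#' @rdname read_level_table
#' @param lt a `level_table`.
#' @return [write_level_table()]: `path`, invisibly.
#' @export
write_level_table <- function(lt, path) {
  yaml::write_yaml(unclass(lt), path)
  invisible(path)
}

#' Score one trait value
#'
#' @param value trait value.
#' @param trait trait label (must be covered by `lt`).
#' @param lt a [level_table()].
#' @return Named numeric vector `c(level =, score =)`.
#' @export
score_trait <- function(value, trait, lt) {
  x <- lt[[trait]]
  if (is.null(x)) stop("level table does not cover trait ", trait)
  if (!is.null(x$range) && (value < x$range[1] || value > x$range[2])) {
    stop(sprintf("%s value %g outside admissible range [%g, %g]",
                 trait, value, x$range[1], x$range[2]))
  }
  level <- if (x$direction == "higher_better") {
    5L - sum(value >= x$cuts)
  } else {
    5L - sum(value <= x$cuts)
  }
  c(level = level, score = x$scores[level])
}

#' Comprehensive quality score of one cross
#'
#' Sums the per-trait scores of the nine quality traits of an F2 bulk.
#'
#' @param values named numeric vector of trait values (all names must be
#'   covered by `lt`).
#' @param lt a [level_table()].
#' @param cross optional cross id.
#' @return A list (class `cross_score`): `cross`, `levels`, `scores`,
#'   `total`.
#' @export
comprehensive_score <- function(values, lt, cross = NA_character_) {
  per <- vapply(names(values), function(tr) score_trait(values[[tr]], tr, lt),
                numeric(2))
  structure(
    list(cross = cross, levels = as.integer(per["level", ]),
         scores = per["score", ], total = sum(per["score", ])),
    class = "cross_score"
  )
}

#' @export
print.cross_score <- function(x, ...) {
  cat(sprintf("cross %s: total score %g\n",
              if (is.na(x$cross)) "<unnamed>" else x$cross, x$total))
  invisible(x)
}

#' Score a table of crosses and write CSV
#'
#' @param trait_values data.frame with a `cross` column plus one column
#'   per trait.
#' @param lt a [level_table()].
#' @param path optional CSV output path.
#' @return data.frame: cross, per-trait scores, total.
#' @export
score_crosses <- function(trait_values, lt, path = NULL) {
  traits <- setdiff(names(trait_values), "cross")
  rows <- lapply(seq_len(nrow(trait_values)), function(i) {
    cs <- comprehensive_score(unlist(trait_values[i, traits]), lt,
                              cross = trait_values$cross[i])
    c(list(cross = cs$cross), as.list(cs$scores), list(total = cs$total))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Synthetic default level table
#'
#' A placeholder grading table in the style of the Chinese edible-rice
#' quality standard (NY/T 593-2002): five levels scored 10/8/6/4/2 per
#' trait so that nine level-1 traits reach the full score of 90. The cut
#' points are synthetic, plausible values for indica rice, not a
#' transcription of any published standard; edit the YAML to use real
#' grading thresholds.
#'
#' @return A `level_table`.
#' @export
default_level_table <- function() {
  read_level_table(system.file("extdata", "level_table_synthetic.yaml",
                               package = "gcaldb", mustWork = TRUE))
}
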