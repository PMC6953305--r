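fake_result <- function(means) {
  structure(list(marker_id = "m", testable = TRUE, group_means = means),
            class = "assoc_result")
}

test_that("the trait registry covers the nine traits with stated polarity", {
  d <- trait_directions()
  expect_equal(nrow(d), 9L)
  expect_setequal(d$trait[d$polarity == "higher_better"],
                  c("BRR", "MRR", "HRR", "GC"))
  expect_setequal(d$trait[d$polarity == "lower_better"],
                  c("PCG", "CAS", "CD", "GT", "AC"))
  d2 <- trait_directions(c(GT = "higher_better"))
  expect_equal(d2$polarity[d2$trait == "GT"], "higher_better")
  expect_error(trait_directions(c(XX = "higher_better")), "unknown")
})

test_that("superior allele follows polarity, ties break lexicographically", {
  expect_equal(superior_allele(fake_result(c(A = 1, B = 2)), "higher_better"), "B")
  expect_equal(superior_allele(fake_result(c(A = 1, B = 2)), "lower_better"), "A")
  expect_equal(superior_allele(fake_result(c(B = 2, A = 2, C = 1)),
                               "higher_better"), "A")
  expect_error(superior_allele(structure(list(testable = FALSE),
                                         class = "assoc_result")),
               "untestable")
})

test_that("flipping polarity flips the superior allele for unique extremes", {
  set.seed(7)
  for (i in 1:20) {
    means <- setNames(sample(seq(0, 10, 0.5), 3), c("A", "B", "C"))
    hi <- superior_allele(fake_result(means), "higher_better")
    lo <- superior_allele(fake_result(means), "lower_better")
    if (max(means) > min(means)) expect_false(hi == lo)
  }
})

# a tiny end-to-end scan with one clear QTL per trait for carrier tests
carrier_setup <- function() {
  g <- simulate_parents(recovery_blocks(), 14, het_rate = 0,
                        missing_rate = 0, seed = 31)
  qtls <- list(qtl_spec("BRR", 1:3, c("222" = 4)),
               qtl_spec("AC", 7L, c("2" = -4), "lower_better"))
  sim <- simulate_ncii(g, qtls, sim_config(8, 6, sca_sd = 0, error_sd = 0.2,
                                           seed = 31))
  fit <- fit_gca(sim$traits, sim$design, letters = FALSE)
  gi <- filter_maf(impute_missing(g), 0.01)
  markers <- build_markers(gi, partition_blocks(gi))
  scan <- scan_markers(fit, markers, alpha_policy())
  list(g = g, markers = markers, scan = scan, sim = sim)
}

test_that("carrier matrix and tally count exactly the superior-allele parents", {
  s <- carrier_setup()
  expect_gt(nrow(s$scan$significant), 0)
  carriers <- superior_carriers(s$scan, s$markers)
  tally <- tally_superior(carriers)
  expect_true(all(tally >= 0))
  # counts never exceed the number of significant loci for the trait
  for (tr in colnames(tally)) {
    expect_true(all(tally[, tr] <= sum(s$scan$significant$trait == tr)))
  }
  # BRR superior allele = the GGG haplotype (+4 on a higher-better trait);
  # its carriers are exactly the 222-genotype parents
  brr_cols <- which(attr(carriers, "locus_trait") == "BRR")
  qtl_carrier <- apply(s$g$calls[, 1:3] == 2L, 1, all)
  blk <- grep("BLOCK", colnames(carriers)[brr_cols], value = FALSE)
  if (length(blk)) {
    expect_equal(unname(carriers[, brr_cols[blk[1]]]), unname(qtl_carrier))
  }
})

test_that("an empty significant set gives an all-zero tally", {
  s <- carrier_setup()
  scan0 <- s$scan
  scan0$significant <- scan0$significant[0, ]
  carriers <- superior_carriers(scan0, s$markers)
  expect_equal(ncol(carriers), 0L)
  tally <- tally_superior(carriers, traits = c("BRR", "AC"))
  expect_true(all(tally == 0))
})

test_that("het parents at singleton markers carry a matching allele copy", {
  m <- structure(
    list(id = "S1_100", type = "snp", chrom = "1", start_bp = 100L,
         end_bp = 100L, snp_idx = 1L,
         assign = c(P1 = "A", P2 = "A/G", P3 = "G", P4 = "G", P5 = "A",
                    P6 = "G")),
    class = "snpldb_marker"
  )
  values <- setNames(c(0, 1, 5, 5, 0, 5), paste0("P", 1:6))
  r <- associate(values, m)
  scan <- structure(
    list(significant = data.frame(trait = "BRR", marker = "S1_100",
                                  stringsAsFactors = FALSE),
         results = list("BRR|S1_100" = r)),
    class = "assoc_scan"
  )
  carriers <- superior_carriers(scan, list(m))
  # superior allele is G (higher mean); P2 is het A/G -> counted as carrier
  expect_equal(attr(carriers, "superior_allele"), "G")
  expect_equal(unname(carriers[, 1]),
               c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("group increments reproduce the published arithmetic", {
  expect_equal(round(increment_pct(68.59, 75.64), 2), 10.28)
  expect_equal(round(increment_pct(48.63, 43.46), 2), -10.63)
  expect_equal(increment_pct(5, 5), 0)
  expect_true(is.na(increment_pct(0, 3)))

  values <- setNames(c(10, 12, 20, 22), paste0("P", 1:4))
  classes <- setNames(c("hom", "hom", "het", "het"), names(values))
  rec <- group_increment(values, classes, "hom", "het")
  expect_equal(rec$mean1, 11)
  expect_equal(rec$mean2, 21)
  expect_equal(rec$increment_pct, (21 - 11) / 11 * 100)
  expect_error(group_increment(values, classes, "hom", "none"), "non-empty")
  z <- group_increment(setNames(c(-1, 1, 5), paste0("P", 1:3)),
                       setNames(c("a", "a", "b"), paste0("P", 1:3)), "a", "b")
  expect_true(is.na(z$increment_pct))
  expect_match(z$flag, "zero")
})

test_that("cross ranking scores the union of parental superior alleles", {
  carriers <- rbind(
    F1 = c(TRUE, TRUE, FALSE, FALSE),
    F2 = c(FALSE, FALSE, FALSE, FALSE),
    M1 = c(FALSE, FALSE, TRUE, TRUE),
    M2 = c(TRUE, FALSE, FALSE, FALSE)
  )
  colnames(carriers) <- paste0("BRR|m", 1:4)
  attr(carriers, "locus_trait") <- rep("BRR", 4)
  rk <- rank_crosses(carriers, c("F1", "F2"), c("M1", "M2"))
  score <- setNames(rk$score, paste(rk$female, rk$male))
  # disjoint loci: union = sum of individual counts
  expect_equal(score[["F1 M1"]], 4)
  expect_equal(score[["F2 M1"]], 2)
  expect_equal(score[["F1 M2"]], 2)
  expect_equal(score[["F2 M2"]], 1)
  expect_equal(rk$score[1], max(rk$score))
  # union monotonicity: pair score >= each parent's own count
  for (i in seq_len(nrow(rk))) {
    expect_gte(rk$score[i], sum(carriers[rk$female[i], ]))
    expect_gte(rk$score[i], sum(carriers[rk$male[i], ]))
  }
  # empty tally: all scores zero
  rk0 <- rank_crosses(carriers[, 0, drop = FALSE], c("F1", "F2"), c("M1", "M2"))
  expect_true(all(rk0$score == 0))
})

test_that("tally CSV renders zeroes as dashes", {
  tally <- matrix(c(0L, 2L, 1L, 0L), 2, 2,
                  dimnames = list(c("p1", "p2"), c("BRR", "AC")))
  path <- file.path(tempdir(), "tally.csv")
  write_tally(tally, path)
  back <- read.csv(path, check.names = FALSE, colClasses = "character")
  expect_equal(back$BRR, c("-", "2"))
  expect_equal(back$AC, c("1", "-"))
})
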