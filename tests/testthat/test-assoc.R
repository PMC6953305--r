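snp_marker <- function(classes, id = "S1_100") {
  structure(
    list(id = id, type = "snp", chrom = "1", start_bp = 100L, end_bp = 100L,
         snp_idx = 1L, assign = classes),
    class = "snpldb_marker"
  )
}

test_that("worked sums-of-squares example: {1,2,3} vs {4,5,6}", {
  values <- setNames(c(1, 2, 3, 4, 5, 6), paste0("P", 1:6))
  m <- snp_marker(setNames(rep(c("A", "G"), each = 3), paste0("P", 1:6)))
  r <- associate(values, m)
  expect_true(r$testable)
  expect_equal(r$f_stat, 13.5)
  expect_equal(r$r_squared, 13.5 / 17.5)
  expect_equal(unname(r$group_means), c(2, 5))
  expect_equal(unname(r$group_sizes), c(3L, 3L))
  expect_equal(sum(r$group_sizes), r$n_used)
  expect_equal(r$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
})

test_that("equal class means give F = 0 and R^2 = 0", {
  values <- setNames(c(1, 3, 1, 3), paste0("P", 1:4))
  m <- snp_marker(setNames(c("A", "A", "G", "G"), paste0("P", 1:4)))
  r <- associate(values, m)
  expect_equal(r$f_stat, 0)
  expect_equal(r$r_squared, 0)
})

test_that("degenerate inputs are flagged, not thrown", {
  values <- setNames(rnorm(6), paste0("P", 1:6))
  one_class <- snp_marker(setNames(rep("A", 6), paste0("P", 1:6)))
  r <- associate(values, one_class)
  expect_false(r$testable)
  expect_match(r$flag, "untestable")

  # a 1-parent class is dropped by min_group_size, leaving one class
  m <- snp_marker(setNames(c(rep("A", 5), "G"), paste0("P", 1:6)))
  expect_false(associate(values, m)$testable)

  # zero within-class variance with distinct means
  values2 <- setNames(c(1, 1, 1, 2, 2, 2), paste0("P", 1:6))
  m2 <- snp_marker(setNames(rep(c("A", "G"), each = 3), paste0("P", 1:6)))
  r2 <- associate(values2, m2)
  expect_true(r2$testable)
  expect_equal(r2$p_value, .Machine$double.xmin)
  expect_match(r2$flag, "zero within-class variance")
})

test_that("associate agrees with lm() and with F = t^2 on 2-class cases", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(8:30, 1)
    cl <- sample(c("A", "G"), n, replace = TRUE)
    if (length(unique(cl)) < 2 || min(table(cl)) < 2) next
    v <- setNames(rnorm(n, mean = (cl == "A")), paste0("P", 1:n))
    names(cl) <- names(v)
    r <- associate(v, snp_marker(cl))
    o <- oracle_oneway(v, cl)
    expect_equal(r$f_stat, o$f, tolerance = 1e-8)
    expect_equal(r$p_value, o$p, tolerance = 1e-8)
    expect_equal(r$r_squared, o$r2, tolerance = 1e-8)
    # cross-check against the standard linear-model fit
    fit <- anova(lm(v ~ factor(cl)))
    expect_equal(r$f_stat, fit$`F value`[1], tolerance = 1e-8)
    # and against the pooled-variance t-test
    tt <- t.test(v ~ factor(cl), var.equal = TRUE)
    expect_equal(r$f_stat, unname(tt$statistic)^2, tolerance = 1e-8)
  }
})

test_that("R^2 is invariant to affine rescaling of the response", {
  set.seed(4)
  v <- setNames(rnorm(12), paste0("P", 1:12))
  cl <- setNames(rep(c("A", "G", "other"), each = 4), names(v))
  r1 <- associate(v, snp_marker(cl))
  r2 <- associate(3.7 * v - 11, snp_marker(cl))
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
  expect_equal(r1$f_stat, r2$f_stat, tolerance = 1e-8)
})

test_that("scan applies the per-trait alpha policy and sorts results", {
  pol <- alpha_policy()
  expect_equal(gcaldb:::policy_alpha(pol, "BRR"), 0.001)
  expect_equal(gcaldb:::policy_alpha(pol, "CAS"), 0.01)
  expect_equal(gcaldb:::policy_alpha(pol, "AC"), 0.01)
  expect_error(alpha_policy(0), "default_alpha")

  g <- simulate_parents(recovery_blocks(), 14, het_rate = 0,
                        missing_rate = 0, seed = 21)
  qtls <- list(qtl_spec("BRR", 1:3, c("222" = 3)),
               qtl_spec("CAS", 7L, c("2" = -2), "lower_better"))
  sim <- simulate_ncii(g, qtls, sim_config(8, 6, seed = 21))
  fit <- fit_gca(sim$traits, sim$design, letters = FALSE)
  gi <- filter_maf(impute_missing(g), 0.01)
  markers <- build_markers(gi, partition_blocks(gi))
  scan <- scan_markers(fit, markers, pol)
  expect_true(all(diff(order(scan$table$trait, scan$table$chrom,
                             scan$table$start_bp)) == 1))
  expect_true(all(scan$significant$p_value <= scan$significant$alpha))
  expect_equal(scan$table$r2_pct, round(100 * scan$table$r_squared, 1))
})

test_that("scanning an empty marker list yields empty results", {
  fit <- data.frame(parent = c("P1", "P2"), trait = "BRR", effect = c(-1, 1))
  scan <- scan_markers(fit, list(), alpha_policy())
  expect_equal(nrow(scan$table), 0L)
  expect_equal(nrow(scan$significant), 0L)
})

test_that("null scan: significant fraction tracks alpha", {
  # 200 independent markers, no QTL: rejections at alpha = 0.05 should be
  # within 3 binomial SDs of 0.05
  set.seed(30)
  n_parents <- 33
  p <- numeric(200)
  for (i in 1:200) {
    v <- setNames(rnorm(n_parents), sprintf("P%02d", 1:n_parents))
    cl <- setNames(sample(c("A", "G"), n_parents, replace = TRUE,
                          prob = c(0.6, 0.4)), names(v))
    r <- associate(v, snp_marker(cl))
    p[i] <- if (r$testable) r$p_value else NA
  }
  frac <- mean(p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
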