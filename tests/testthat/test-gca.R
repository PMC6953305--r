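two_by_two <- function(vals = c(10, 12, 14, 16), n_reps = 1) {
  design <- mating_design(list(all = list(females = c("F1", "F2"),
                                          males = c("M1", "M2"))))
  tt <- expand.grid(female = c("F1", "F2"), male = c("M1", "M2"),
                    replicate = seq_len(n_reps), stringsAsFactors = FALSE)
  key <- paste(tt$female, tt$male)
  means <- setNames(vals, c("F1 M1", "F2 M1", "F1 M2", "F2 M2"))
  tt$trait <- "Y"
  tt$value <- unname(means[key])
  list(traits = tt, design = design)
}

test_that("2x2 worked example: effects are cross-mean deviations", {
  d <- two_by_two(c(10, 14, 12, 16))   # (F1,M1)=10 (F2,M1)=14 (F1,M2)=12 (F2,M2)=16
  g <- fit_gca(d$traits, d$design)
  eff <- setNames(g$effect, g$parent)
  expect_equal(eff[["F1"]], -2)
  expect_equal(eff[["F2"]], 2)
  expect_equal(eff[["M1"]], -1)
  expect_equal(eff[["M2"]], 1)
})

test_that("constant data gives all-zero effects", {
  d <- two_by_two(rep(7, 4), n_reps = 3)
  g <- fit_gca(d$traits, d$design)
  expect_true(all(g$effect == 0))
})

test_that("effects sum to zero within each (group, class, trait)", {
  set.seed(9)
  g <- simulate_parents(recovery_blocks(), 33, seed = 9)
  groups <- list(
    indica = list(females = parent_ids(g)[1:8], males = parent_ids(g)[9:14]),
    japonica = list(females = parent_ids(g)[15:27], males = parent_ids(g)[28:33])
  )
  sim <- simulate_ncii(g, list(qtl_spec("BRR", 1:3, c("222" = 2))),
                       sim_config(8, 6, seed = 9, groups = groups))
  fit <- fit_gca(sim$traits, sim$design)
  sums <- tapply(fit$effect, paste(fit$group, fit$class, fit$trait), sum)
  expect_true(all(abs(sums) < 1e-9))
})

test_that("with zero noise the fit recovers the true GCA exactly", {
  g <- simulate_parents(recovery_blocks(), 14, het_rate = 0,
                        missing_rate = 0, seed = 10)
  sim <- simulate_ncii(g, list(qtl_spec("BRR", 1:3, c("222" = 3))),
                       sim_config(8, 6, sca_sd = 0, error_sd = 0, seed = 10))
  fit <- fit_gca(sim$traits, sim$design)
  m <- merge(fit, sim$truth, by = c("parent", "class", "group", "trait"))
  expect_equal(nrow(m), 14)
  expect_lt(max(abs(m$effect.x - m$effect.y)), 1e-6)
})

test_that("missing crosses are reported by name", {
  d <- two_by_two()
  tt <- d$traits[!(d$traits$female == "F2" & d$traits$male == "M2"), ]
  expect_error(fit_gca(tt, d$design), "F2 M2")
})

test_that("ANOVA sums of squares decompose the total (brute force check)", {
  set.seed(12)
  d <- two_by_two(rnorm(4), n_reps = 3)
  d$traits$value <- d$traits$value + rnorm(nrow(d$traits))
  av <- anova_gca(d$traits, d$design)
  ss_total_direct <- sum((d$traits$value - mean(d$traits$value))^2)
  expect_equal(sum(av$ss), ss_total_direct, tolerance = 1e-8)
  expect_setequal(av$term, c("female", "male", "female:male", "error"))
})

test_that("pure additive zero-noise data has no interaction or error SS", {
  design <- mating_design(list(all = list(females = c("F1", "F2", "F3"),
                                          males = c("M1", "M2"))))
  gf <- c(F1 = -1, F2 = 0, F3 = 1)
  gm <- c(M1 = -2, M2 = 2)
  tt <- expand.grid(female = names(gf), male = names(gm), replicate = 1:2,
                    stringsAsFactors = FALSE)
  tt$trait <- "Y"
  tt$value <- 50 + gf[tt$female] + gm[tt$male]
  av <- anova_gca(tt, design)
  expect_lt(av$ss[av$term == "female:male"], 1e-20)
  expect_lt(av$ss[av$term == "error"], 1e-20)
})

test_that("single-replicate designs confound interaction with error", {
  d <- two_by_two(n_reps = 1)
  av <- anova_gca(d$traits, d$design)
  expect_false("female:male" %in% av$term)
})

test_that("LSD letters: clear separation and clear overlap", {
  # LSD = qt(.995, 10) * sqrt(2 * 1 / 4) = 2.24
  lsd <- qt(0.995, 10) * sqrt(2 * 1 / 4)
  expect_equal(unname(lsd_letters(c(A = 1, B = 1.5), 1, 10, 4)), c("a", "a"))
  expect_equal(unname(lsd_letters(c(A = 10, B = 1), 1, 10, 4)), c("a", "b"))
  # chain: 10, 9, 8 with LSD ~2.24 -> overlapping groups get shared letters
  got <- lsd_letters(c(A = 10, B = 9, C = 8, D = 0), 1, 10, 4)
  expect_equal(got[["D"]], "b")
  expect_equal(got[["A"]], "a")
})

test_that("LSD letters match the all-pairs grouping oracle", {
  for (seed in 1:30) {
    set.seed(seed)
    k <- sample(3:8, 1)
    means <- setNames(round(rnorm(k, sd = 2), 2), paste0("p", 1:k))
    means <- means + seq_len(k) * 1e-4   # avoid exact ties in means
    got <- lsd_letters(means, mse = 1.3, df_error = 12, n_per_mean = 3)
    want <- oracle_letters(means, mse = 1.3, df_error = 12, n_per_mean = 3)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("fit_gca attaches LSD letters consistent with effect separation", {
  g <- simulate_parents(recovery_blocks(), 14, het_rate = 0,
                        missing_rate = 0, seed = 13)
  sim <- simulate_ncii(g, list(qtl_spec("BRR", 1:3, c("222" = 5))),
                       sim_config(8, 6, sca_sd = 0, error_sd = 0.5, seed = 13))
  fit <- fit_gca(sim$traits, sim$design)
  expect_false(anyNA(fit$letters))
  fem <- fit[fit$class == "female", ]
  # carriers (effect ~ +2.5) and non-carriers (~ -2.5) must not share letters
  top <- fem$letters[which.max(fem$effect)]
  bottom <- fem$letters[which.min(fem$effect)]
  expect_false(any(strsplit(top, "")[[1]] %in% strsplit(bottom, "")[[1]]))
})

test_that("estimated effects track truth within design precision", {
  # 8x6 NCII, 3 reps, error_sd 1: RMSE(ghat - g) <= 2 x design-predicted SE
  n_sim <- 50
  err <- numeric(0)
  for (s in seq_len(n_sim)) {
    g <- simulate_parents(recovery_blocks(), 14, het_rate = 0,
                          missing_rate = 0, seed = 100 + s)
    sim <- simulate_ncii(g, list(qtl_spec("BRR", 1:3, c("222" = 2))),
                         sim_config(8, 6, n_reps = 3, sca_sd = 0,
                                    error_sd = 1, seed = 100 + s))
    fit <- fit_gca(sim$traits, sim$design, letters = FALSE)
    m <- merge(fit, sim$truth, by = c("parent", "class", "group", "trait"))
    err <- c(err, m$effect.x - m$effect.y)
  }
  rmse <- sqrt(mean(err^2))
  # var(ghat_f) = sigma^2 (1/(m r) - 1/(f m r)); females 8, males 6, r = 3
  var_f <- 1 / 18 - 1 / 144
  var_m <- 1 / 24 - 1 / 144
  se_pred <- sqrt((8 * var_f + 6 * var_m) / 14)
  expect_lte(rmse, 2 * se_pred)
})
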