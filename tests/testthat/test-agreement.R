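test_that("correlation wrappers match their definitions and guard degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_r(x, rep(1, 4)), "zero variance")
  # rank invariance under strictly monotone transforms
  y <- withr::with_seed(1, stats::runif(20))
  expect_equal(spearman_rho(y, exp(3 * y)), 1.0)
  expect_equal(spearman_rho(y, log(y + 1)), 1.0)
  expect_error(spearman_rho(y, rep(2, 20)), "constant input")
})

test_that("single-measure ICC matches explicit ANOVA mean squares", {
  x <- c(3.1, 4.7, 5.2, 6.8, 7.7, 9.1)
  y <- c(3.5, 4.1, 5.9, 6.1, 8.2, 8.8)
  long <- data.frame(subject = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)),
                     value = c(x, y))
  # one-way oracle via stats::aov
  ms1 <- summary(stats::aov(value ~ subject, data = long))[[1]]
  msb <- ms1["subject", "Mean Sq"]
  msw <- ms1["Residuals", "Mean Sq"]
  expect_equal(as.numeric(icc_single(x, y, "oneway")),
               (msb - msw) / (msb + msw))
  # two-way absolute-agreement oracle
  ms2 <- summary(stats::aov(value ~ subject + rater, data = long))[[1]]
  msr <- ms2["subject", "Mean Sq"]
  msc <- ms2["rater", "Mean Sq"]
  mse <- ms2["Residuals", "Mean Sq"]
  expect_equal(as.numeric(icc_single(x, y, "twoway_agreement")),
               (msr - mse) / (msr + mse + 2 * (msc - mse) / 6))
  # perfect agreement
  expect_equal(as.numeric(icc_single(x, x, "oneway")), 1.0)
  expect_equal(as.numeric(icc_single(x, x, "twoway_agreement")), 1.0)
  # a large constant offset: correlation blind, absolute agreement not
  expect_equal(pearson_r(x, x + 50), 1.0)
  expect_lt(as.numeric(icc_single(x, x + 50, "twoway_agreement")), 0.2)
})

test_that("variance-components ICC recovers simulated reliability", {
  # zero within-subject variance
  reps <- data.frame(subject = rep(1:5, each = 3),
                     value = rep(c(1, 3, 5, 7, 9), each = 3))
  expect_equal(as.numeric(icc_mixed(reps)), 1.0)
  # null case: a single common mean, pure noise
  est0 <- sapply(1:40, function(s) withr::with_seed(s, {
    as.numeric(icc_mixed(data.frame(subject = rep(1:20, each = 3),
                                    value = stats::rnorm(60))))
  }))
  expect_lt(mean(est0), 0.1)
  # parameter recovery: sigma2_s = 4, sigma2_e = 1 -> ICC 0.8
  est <- sapply(1:50, function(s) withr::with_seed(s, {
    subj <- rep(1:30, each = 3)
    v <- stats::rnorm(30, sd = 2)[subj] + stats::rnorm(90, sd = 1)
    as.numeric(icc_mixed(data.frame(subject = subj, value = v)))
  }))
  expect_lt(abs(mean(est) - 0.8), 0.1)
  # balanced-design estimate agrees with the REML variance components
  one <- withr::with_seed(7, {
    subj <- rep(1:25, each = 3)
    data.frame(subject = subj,
               value = stats::rnorm(25, sd = 2)[subj] + stats::rnorm(75))
  })
  fit <- lme4::lmer(value ~ 1 | subject, data = one)
  vc <- as.data.frame(lme4::VarCorr(fit))$vcov
  expect_equal(as.numeric(icc_mixed(one)), vc[1] / sum(vc), tolerance = 1e-4)
  expect_error(icc_mixed(data.frame(subject = 1:5, value = rnorm(5))),
               "estimation error")
})

test_that("area binning thresholds values into ordered categories", {
  expect_identical(bin_areas(1:10, "fixed_edges", edges = c(3, 7)),
                   c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L))
  expect_identical(bin_areas(rep(4, 6), "fixed_edges", edges = c(3, 7)),
                   rep(2L, 6))
  expect_error(bin_areas(1:10, "fixed_edges", edges = c(7, 3)),
               "parameter error")
  expect_error(bin_areas(rep(1, 10), "quintile"), "5 distinct")
  # quintile bins against a sort-and-cut oracle
  v <- withr::with_seed(8, stats::runif(30))
  got <- bin_areas(v, "quintile")
  edges <- stats::quantile(v, c(0.2, 0.4, 0.6, 0.8))
  oracle <- integer(30)
  for (i in 1:30) oracle[i] <- 1L + sum(v[i] >= edges)
  expect_identical(got, oracle)
  expect_equal(as.vector(table(got)), rep(6L, 5))
})

test_that("kappa reproduces hand-computed agreement and its special cases", {
  a <- c(rep(1, 5), rep(2, 5), rep(3, 5))
  for (w in c("none", "linear", "quadratic")) {
    expect_equal(cohen_kappa(a, a, weights = w)$kappa, 1.0)
  }
  # 2x2 table with counts 45/15/25/15: p_o = 0.60, p_e = 0.54
  r1 <- c(rep(1, 60), rep(2, 40))
  r2 <- c(rep(1, 45), rep(2, 15), rep(1, 25), rep(2, 15))
  k <- cohen_kappa(r1, r2, weights = "none")
  expect_equal(k$kappa, (0.60 - 0.54) / (1 - 0.54), tolerance = 1e-12)
  expect_lte(k$ci[1], k$kappa)
  expect_gte(k$ci[2], k$kappa)
  # two categories with linear weights reduce to unweighted kappa
  k_lin <- cohen_kappa(r1, r2, weights = "linear")
  expect_equal(k_lin$kappa, k$kappa)
  expect_error(cohen_kappa(rep(1, 10), rep(1, 10)), "single category")
})

test_that("outlier exclusion filters by id and rejects unknown ids", {
  records <- pi_case_table()
  expect_equal(nrow(records), 30)
  kept <- exclude_outliers(records)
  expect_equal(nrow(kept), 23)
  expect_false(any(kept$outlier))
  expect_identical(exclude_outliers(records, character(0))$case_id,
                   records$case_id)
  expect_equal(nrow(exclude_outliers(records, records$case_id)), 0)
  expect_error(exclude_outliers(records, "Case 99"), "lookup error")
})

test_that("stage summary counts the NPUAP categories", {
  s <- summarize_stages(pi_case_table())
  expect_equal(s$n[s$stage == "2"], 13L)
  expect_equal(s$n[s$stage == "unstageable"], 4L)
  expect_equal(s$n, c(2L, 13L, 10L, 1L, 4L))
  empty <- summarize_stages(data.frame(stage = character(0)))
  expect_equal(sum(empty$n), 0L)
  expect_error(summarize_stages(data.frame(stage = "stage nine")),
               "data error")
})

test_that("the full agreement table behaves on degenerate and fixture input", {
  # identical columns: perfect scores everywhere
  d <- data.frame(case_id = sprintf("c%02d", 1:12), stage = "2",
                  nurse_lw_cm2 = seq(1, 23, 2),
                  machine_lw_cm2 = seq(1, 23, 2),
                  machine_morph_cm2 = seq(1, 23, 2), outlier = FALSE)
  tab <- reproduce_table4(d)
  same <- tab[tab$pairing == "nurse_vs_machine_lw" &
                tab$subset == "with_outliers", ]
  expect_equal(same$pearson_r, 1.0)
  expect_equal(same$spearman_rho, 1.0)
  expect_equal(same$icc_oneway, 1.0)
  expect_equal(same$kappa_weighted, 1.0)
  # fixture: all coefficients in [-1, 1], CIs bracket the estimates
  ft <- reproduce_table4(pi_case_table())
  expect_equal(nrow(ft), 6)
  num <- c("pearson_r", "spearman_rho", "icc_oneway", "icc_agreement",
           "kappa_unweighted", "kappa_weighted")
  expect_true(all(abs(as.matrix(ft[num])) <= 1))
  expect_true(all(ft$kappa_weighted_lo <= ft$kappa_weighted))
  expect_true(all(ft$kappa_weighted_hi >= ft$kappa_weighted))
  expect_equal(ft$n, c(30, 30, 30, 23, 23, 23))
})
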