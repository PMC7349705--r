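test_that("LTL/MTL ratio is recomputed, flagged above 1, and errors on nonpositive input", {
  d <- data.frame(ltl_kb = c(6.71, 8.0), mtl_kb = c(8.57, 8.0),
                  ratio = c(99, 99))  # incoming ratio column must be ignored
  out <- compute_ratio(d)
  expect_equal(out$ratio[1], 6.71 / 8.57, tolerance = 1e-12)
  expect_equal(out$ratio[2], 1)
  expect_identical(out$ratio_gt1_flag, c(FALSE, TRUE))
  expect_error(compute_ratio(data.frame(ltl_kb = 6, mtl_kb = 0)), "positive")
})

test_that("age slope matches closed-form OLS on collinear points and converts kb to bp", {
  d <- data.frame(age_years = c(40, 50, 60, 70), sex = "M",
                  ltl_kb = c(7.0, 6.7, 6.4, 6.1), mtl_kb = 8.5)
  s <- suppressWarnings(age_slope(d, "ltl"))
  expect_equal(s$slope, -30, tolerance = 1e-9)       # bp/year from kb inputs
  expect_equal(s$units, "bp/year")
  expect_lt(s$se, 1e-9)                               # exactly collinear
  ## ratio slope is dimensionless per year (no factor 1000)
  s2 <- suppressWarnings(age_slope(compute_ratio(d), "ratio"))
  expect_equal(s2$units, "per year")
  expect_equal(s2$slope, unname(coef(lm(I(ltl_kb / mtl_kb) ~ age_years, d))[2]),
               tolerance = 1e-9)
})

test_that("age slope handles a constant phenotype and rejects constant age", {
  d <- data.frame(age_years = c(40, 50, 60, 70), sex = "M",
                  ltl_kb = 6.5, mtl_kb = 8.5)
  s <- suppressWarnings(age_slope(d, "ltl"))
  expect_equal(s$slope, 0, tolerance = 1e-9)
  d$age_years <- 50
  expect_error(age_slope(d, "ltl"), "zero variance")
  expect_error(age_slope(d[1:2, ], "ltl"), "at least 3")
})

test_that("adjusted group means: equal groups, no-op adjustment, centering invariance", {
  d <- toy_cohort()
  ## both sexes share the -0.03 kb/year slope; F(age) = 8.55 - 0.03 age and
  ## M(age) = 8.20 - 0.03 age, so the age-adjusted offset is 0.35 kb
  am <- suppressWarnings(adjusted_group_means(d, "ltl"))
  expect_equal(am$mean[am$group == "F"] - am$mean[am$group == "M"], 0.35,
               tolerance = 1e-9)

  ## no age effect: adjusted means equal raw group means
  d2 <- d
  d2$ltl_kb <- rep(c(6.4, 6.8), each = 4)
  am2 <- suppressWarnings(adjusted_group_means(d2, "ltl"))
  expect_equal(sort(am2$mean), c(6.4, 6.8), tolerance = 1e-9)

  ## centering age leaves adjusted means unchanged
  d3 <- d
  d3$age_years <- d3$age_years - mean(d3$age_years)
  am3 <- suppressWarnings(adjusted_group_means(d3, "ltl"))
  expect_equal(am3$mean, am$mean, tolerance = 1e-9)
  expect_equal(am3$se, am$se, tolerance = 1e-9)

  expect_error(adjusted_group_means(d[d$sex == "M", ], "ltl"), "two groups")
})

test_that("synthetic cohort recovers the configured sex offset as an adjusted difference", {
  sim <- simulate_cohort(cohort_config(n = 5000, seed = 61))
  am <- adjusted_group_means(sim$cohort, "ltl")
  diff_fm <- am$mean[am$group == "F"] - am$mean[am$group == "M"]
  se <- sqrt(sum(am$se^2))
  expect_lt(abs(diff_fm - 0.22), 3 * se)
})

test_that("pairwise comparisons match hand-evaluated statistics", {
  x <- c(6.1, 6.4, 6.9, 7.2, 7.8)
  mw <- pairwise_compare(x, x, kind = "mann_whitney")
  expect_equal(mw$p, 1, tolerance = 1e-12)

  even <- pairwise_compare(matrix(c(10, 10, 10, 10), 2), kind = "chi2")
  expect_equal(even$statistic, 0, tolerance = 1e-12)
  expect_equal(even$p, 1, tolerance = 1e-12)

  skew <- pairwise_compare(matrix(c(30, 10, 10, 30), 2), kind = "chi2")
  expect_equal(skew$statistic, 20, tolerance = 1e-12)

  expect_error(pairwise_compare(numeric(0), x, kind = "mann_whitney"), "empty")
  expect_error(pairwise_compare(matrix(c(-1, 2, 3, 4), 2), kind = "chi2"),
               "negative")
})

test_that("Pearson correlation handles exact linear and null relationships", {
  x <- seq(1, 10, by = 0.5)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(71)
  r0 <- pearson_corr(rnorm(1000), rnorm(1000))
  expect_lt(abs(r0$r), 0.1)
  expect_error(pearson_corr(x, rep(1, length(x))), "zero variance")
  expect_error(pearson_corr(1:2, 2:3), "at least 3")
})

test_that("null Pearson p-values are approximately uniform", {
  set.seed(72)
  ps <- replicate(200, pearson_corr(rnorm(60), rnorm(60))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("dynamics report aggregates descriptives, adjusted means and slopes", {
  sim <- simulate_cohort(cohort_config(n = 300, seed = 62))
  rep <- dynamics_report(sim$cohort)
  expect_equal(nrow(rep$descriptives), 3)
  expect_equal(nrow(rep$adjusted_sex_means), 6)  # 3 phenotypes x 2 sexes
  expect_equal(nrow(rep$slopes), 6)              # 3 phenotypes x (raw, sex-adj)
  expect_true(all(rep$slopes$slope[rep$slopes$phenotype != "ratio"] < 0))
})
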