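test_that("minor allele frequency counts alleles and flips major-allele coding", {
  g <- rep(c(0L, 1L, 2L), c(81, 18, 1))
  r <- compute_maf(g)
  expect_equal(r$maf, 0.10)
  expect_false(r$flipped)

  expect_equal(compute_maf(rep(0L, 40))$maf, 0)

  ## coded allele at frequency 0.71: flipped to 0.29 with orientation note
  g2 <- rep(c(2L, 1L, 0L), c(50, 42, 8))  # coded freq (100+42)/200 = 0.71
  r2 <- compute_maf(g2)
  expect_true(r2$flipped)
  expect_equal(r2$maf, 0.29)
  expect_equal(r2$genotypes, 2L - g2)

  expect_error(compute_maf(c(NA, NA)), "all genotypes missing")
  expect_error(compute_maf(c(0, 3)), "0/1/2")
})

test_that("Hardy-Weinberg chi-squared matches closed-form cases", {
  r1 <- hwe_chisq(c(25, 50, 25))
  expect_equal(r1$chi2, 0, tolerance = 1e-12)
  expect_true(r1$pass)

  expect_equal(hwe_chisq(c(36, 48, 16))$chi2, 0, tolerance = 1e-12)

  ## complete heterozygote deficit at p = q = 0.5: chi2 = n
  r3 <- hwe_chisq(c(50, 0, 50))
  expect_equal(r3$chi2, 100, tolerance = 1e-12)
  expect_false(r3$pass)

  expect_error(hwe_chisq(c(-1, 5, 5)), "negative")
  expect_error(hwe_chisq(c(3, 3, 3)), "fewer than")
})

test_that("Hardy-Weinberg chi-squared matches a brute-force expected-count oracle", {
  ## independent oracle: expectation from multinomial HWE probabilities at
  ## the allele frequency implied by the counts
  oracle <- function(counts) {
    n <- sum(counts)
    q <- (counts[2] + 2 * counts[3]) / (2 * n)
    probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    expected <- n * probs
    ok <- expected > 0
    sum((counts[ok] - expected[ok])^2 / expected[ok])
  }
  for (total in 20:50) {
    for (n_aa in seq(0, total, by = 3)) {
      for (n_het in seq(0, total - n_aa, by = 3)) {
        counts <- c(total - n_aa - n_het, n_het, n_aa)
        q <- (counts[2] + 2 * counts[3]) / (2 * total)
        expected_chi2 <- if (q == 0 || q == 1) 0 else oracle(counts)
        expect_equal(hwe_chisq(counts)$chi2, expected_chi2, tolerance = 1e-9)
      }
    }
  }
})

test_that("a 15-SNP panel with 2 disequilibrium SNPs yields 13 analysed SNPs", {
  sim <- simulate_cohort(cohort_config(snp_panel = default_snp_panel(full = TRUE),
                                       seed = 2024))
  f <- filter_hwe(sim$genotypes, sim$panel, alpha = 0.05)
  expect_equal(nrow(f$panel) + nrow(f$exclusions), 15)
  expect_setequal(f$exclusions$rsid, c("rs7726159", "rs755017"))
  expect_equal(ncol(f$genotypes), 13)
  expect_true(all(f$exclusions$p < 0.05))
})

test_that("a panel fully in equilibrium passes the filter unchanged", {
  sim <- simulate_cohort(cohort_config(n = 2000, seed = 2025))
  f <- filter_hwe(sim$genotypes, sim$panel, alpha = 0.001)
  expect_equal(f$panel$rsid, sim$panel$rsid)
  expect_equal(nrow(f$exclusions), 0)
  expect_warning(out <- filter_hwe(sim$genotypes,
                                   sim$panel[0, , drop = FALSE]), "empty")
  expect_equal(nrow(out$panel), 0)
})

test_that("additive association equals the closed-form normal-equations solution", {
  ## exact noiseless fit
  g <- c(0, 1, 2, 0, 1, 2)
  y <- 0.5 * g
  r <- suppressWarnings(additive_assoc(y, g))
  expect_equal(r$beta, 0.5, tolerance = 1e-10)
  expect_lt(r$p, 1e-10)

  ## random fixture against hand-solved OLS with covariates
  set.seed(55)
  n <- 40
  X <- cbind(1, g = sample(0:2, n, TRUE), age = rnorm(n, 60, 10))
  yy <- drop(X %*% c(1.9, -0.05, -0.003)) + rnorm(n, 0, 0.1)
  beta_hat <- solve(crossprod(X), crossprod(X, yy))
  resid <- yy - X %*% beta_hat
  sigma2 <- sum(resid^2) / (n - ncol(X))
  se_hat <- sqrt(diag(sigma2 * solve(crossprod(X))))
  r2 <- additive_assoc(yy, X[, "g"], data.frame(age = X[, "age"]))
  expect_equal(r2$beta, beta_hat["g", 1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(r2$se, se_hat["g"], tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(additive_assoc(yy, rep(1, n)), "monomorphic")
  expect_error(additive_assoc(yy, X[1:10, "g"]), "aligned")
})

test_that("permuted genotypes show no association (null case)", {
  sim <- simulate_cohort(cohort_config(seed = 808))
  g_perm <- sample(sim$genotypes[, "rs12696304"])
  r <- additive_assoc(log(sim$cohort$ltl_kb), g_perm,
                      data.frame(age = sim$cohort$age_years,
                                 sex = factor(sim$cohort$sex)))
  expect_lt(abs(r$beta), 3 * r$se)
})

test_that("flipping allele coding negates beta and leaves the p-value unchanged", {
  sim <- simulate_cohort(cohort_config(n = 300, seed = 57))
  y <- log(sim$cohort$ltl_kb)
  covs <- data.frame(age = sim$cohort$age_years, sex = factor(sim$cohort$sex))
  g <- sim$genotypes[, "rs2736100"]
  a <- additive_assoc(y, g, covs)
  b <- additive_assoc(y, 2 - g, covs)
  expect_equal(b$beta, -a$beta, tolerance = 1e-12)
  expect_equal(b$se, a$se, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("gated testing restricts stage 2 to stage-1-significant SNPs", {
  ## two strongly associated SNPs among 13
  panel <- default_snp_panel()
  panel$beta_logltl <- 0
  panel$beta_logltl[panel$rsid %in% c("rs12696304", "rs10936599")] <- -0.05
  sim <- simulate_cohort(cohort_config(n = 2000, snp_panel = panel, seed = 90))
  res <- gated_testing(sim$cohort, sim$genotypes, sim$panel, gate_alpha = 0.05)
  expect_true(all(c("rs12696304", "rs10936599") %in% res$gated_rsids))
  not_gated <- setdiff(panel$rsid, res$gated_rsids)
  s2 <- res$stage2
  expect_true(all(!s2$tested[s2$rsid %in% not_gated]))
  expect_true(all(is.na(s2$p[!s2$tested])))
  expect_true(all(s2$tested[s2$rsid %in% res$gated_rsids]))

  ## disabled gate tests every SNP on every phenotype
  res_all <- gated_testing(sim$cohort, sim$genotypes, sim$panel, gate_alpha = 1)
  expect_true(all(res_all$stage2$tested))
})

test_that("when no SNP passes the gate, stage 2 is explicitly not tested", {
  panel <- default_snp_panel()[1:4, ]
  panel$beta_logltl <- 0
  sim <- simulate_cohort(cohort_config(n = 200, snp_panel = panel, seed = 91))
  res <- gated_testing(sim$cohort, sim$genotypes, sim$panel,
                       gate_alpha = 1e-6)
  expect_length(res$gated_rsids, 0)
  expect_true(all(!res$stage2$tested))
  expect_equal(nrow(res$stage2), 8)  # every cell present, marked untested
})

test_that("epistasis scan recovers a pure interaction effect and counts pairs", {
  set.seed(92)
  n <- 2000
  panel <- default_snp_panel()[c(3, 4, 6), ]
  g <- sapply(panel$maf, function(q) rbinom(n, 2, q))
  colnames(g) <- panel$rsid
  age <- runif(n, 20, 90)
  cohort <- data.frame(id = sprintf("S%04d", 1:n), age_years = age,
                       sex = sample(c("F", "M"), n, TRUE),
                       ltl_kb = exp(0.9 + 0.08 * g[, 1] * g[, 2] +
                                      rnorm(n, 0, 0.1)),
                       mtl_kb = 8.5)
  scan <- epistasis_scan(cohort, g, panel, phenotype = "logLTL")
  expect_equal(nrow(scan), choose(3, 2))
  hit <- scan[scan$rsid1 == "rs12696304" & scan$rsid2 == "rs10936599", ]
  expect_lt(abs(hit$beta_int - 0.08), 3 * hit$se)
  expect_lt(hit$p_bonferroni, 0.05)
})

test_that("an additive-only phenotype yields null interactions across all pairs", {
  sim <- simulate_cohort(cohort_config(n = 1500, seed = 93))
  scan <- epistasis_scan(sim$cohort, sim$genotypes, sim$panel,
                         phenotype = "logLTL")
  expect_equal(nrow(scan), choose(13, 2))  # 78 pairs
  expect_true(all(scan$p_bonferroni >= scan$p))
  ## a pure-additive generator: interaction terms are null; allow the
  ## expected Monte Carlo excursions across 78 correlated tests
  expect_gt(mean(abs(scan$beta_int) < 3 * scan$se), 0.95)
  expect_true(all(scan$p_bonferroni > 0.05))
})

test_that("monomorphic SNPs are skipped with a log entry", {
  sim <- simulate_cohort(cohort_config(n = 100, seed = 94))
  g <- sim$genotypes[, 1:3]
  g[, 2] <- 0L
  scan <- epistasis_scan(sim$cohort, g, sim$panel[1:3, ], phenotype = "logLTL")
  expect_equal(nrow(scan), 1)  # only the pair without the monomorphic SNP
  expect_length(attr(scan, "skipped"), 2)
})

test_that("association tables carry the publication column layout", {
  sim <- simulate_cohort(cohort_config(n = 300, seed = 95))
  res <- gated_testing(sim$cohort, sim$genotypes, sim$panel, gate_alpha = 1)
  tab <- association_table(res$stage1, sim$panel, sim$genotypes)
  expect_equal(names(tab)[1:7],
               c("SNP", "CHR", "Position", "Gene", "Effect Allele",
                 "Other Allele", "MAF"))
  expect_true(all(c("BETA", "SE", "P") %in% names(tab)))
  expect_equal(tab$SNP, sim$panel$rsid)
})
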