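#' Default SNP panel for cohort simulation
#'
#' Thirteen SNPs from loci repeatedly associated with leukocyte telomere
#' length in GWAS (ACYP2, PXK, TERC, NAF1, TERT, OBFC1, CTC1, ZNF208,
#' ZNF676, DHX35), with minor-allele frequencies and per-minor-allele
#' effects on log-LTL used as generator truth.  With `full = TRUE` two
#' further slots (rs7726159, rs755017) are appended whose genotypes are
#' drawn with a strong heterozygote deficit (`hwe_fis = 0.5`), producing a
#' 15-typed / 13-analysed panel after Hardy-Weinberg filtering; their
#' positions are synthetic placeholders (NA) and their effects are zero.
#'
#' @param full if TRUE include the two Hardy-Weinberg-violating slots.
#' @return data.frame with columns `rsid`, `chr`, `position_bp`, `gene`,
#'   `effect_allele`, `other_allele`, `maf`, `beta_logltl`, `beta_mtl`,
#'   `hwe_fis`.
#' @export
default_snp_panel <- function(full = FALSE) {
  panel <- data.frame(
    rsid = c("rs11125529", "rs6772228", "rs12696304", "rs10936599",
             "rs7675998", "rs2736100", "rs9419958", "rs9420907",
             "rs4387287", "rs3027234", "rs8105767", "rs412658", "rs6028466"),
    chr = c(2, 3, 3, 3, 4, 5, 10, 10, 10, 17, 19, 19, 20),
    position_bp = c(54248729, 58390292, 169763483, 169774313, 163086668,
                    1286401, 103916188, 103916707, 103918139, 8232774,
                    22032639, 22176638, 39500359),
    gene = c("ACYP2", "PXK", "TERC", "TERC", "NAF1", "TERT", "OBFC1",
             "OBFC1", "OBFC1", "CTC1", "ZNF208", "ZNF676", "DHX35"),
    effect_allele = c("A", "A", "G", "T", "A", "A", "T", "C", "A", "T",
                      "G", "T", "A"),
    other_allele = c("C", "T", "C", "C", "G", "C", "C", "A", "C", "C",
                     "A", "C", "G"),
    maf = c(0.12, 0.045, 0.29, 0.25, 0.24, 0.47, 0.16, 0.17, 0.21, 0.21,
            0.30, 0.39, 0.070),
    beta_logltl = c(0.000024, -0.0094, -0.0074, -0.0080, -0.0012, -0.0038,
                    -0.00093, 0.00032, 0.0038, 0.0017, -0.0027, -0.0016,
                    -0.0022),
    beta_mtl = 0,
    hwe_fis = 0,
    stringsAsFactors = FALSE)
  if (full) {
    extra <- data.frame(
      rsid = c("rs7726159", "rs755017"),
      chr = c(5, 20), position_bp = NA_real_,
      gene = c("TERT", "ZBTB46"),
      effect_allele = c("A", "G"), other_allele = c("C", "A"),
      maf = c(0.34, 0.13), beta_logltl = 0, beta_mtl = 0, hwe_fis = 0.5,
      stringsAsFactors = FALSE)
    panel <- rbind(panel, extra)
  }
  panel
}

#' Cohort simulation configuration
#'
#' Defines the generative model for a blood-and-muscle cohort.  Ages are
#' truncated-normal; muscle telomere length (MTL, the proxy for telomere
#' length at birth) declines linearly with age; leukocyte telomere length
#' is MTL minus an always-positive gap (the cumulative early-life leukocyte
#' attrition) that widens with age and carries the per-allele SNP effects.
#' Sex offsets are applied centred on the female fraction so population
#' means equal the configured means, and intercepts are anchored at the
#' mean of the (truncated) age distribution.
#'
#' Defaults emulate a cohort of surgical patients of mean age 60 (SD 15,
#' range 20-94, 32% female) with LTL 6.71 +/- 0.84 kb, MTL 8.57 +/- 0.72 kb,
#' LTL slope -31 bp/year, MTL slope -15 bp/year, and age-adjusted
#' female-male offsets of +0.22 kb (LTL) and +0.25 kb (MTL).  `mtl_sd` and
#' `ltl_gap_sd` are residual SDs chosen so the marginal SDs reproduce
#' 0.72 / 0.84 kb once the age-slope and sex-offset variance components are
#' added.
#'
#' @param n cohort size.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age model, years.
#' @param female_fraction proportion female, in (0, 1).
#' @param mtl_mean_at_ref population mean MTL (kb) at the reference age.
#' @param mtl_sd residual SD of MTL, kb.
#' @param ltl_gap_mean,ltl_gap_sd mean and residual SD of the MTL - LTL gap
#'   (kb) at the reference age; the mean must be positive so LTL < MTL holds
#'   for essentially all individuals.
#' @param ltl_slope,mtl_slope age slopes in kb/year, both <= 0 and
#'   `ltl_slope <= mtl_slope` (leukocyte attrition is steeper).
#' @param sex_offset_ltl,sex_offset_mtl age-adjusted female-minus-male
#'   offsets, kb.
#' @param snp_panel data.frame as [default_snp_panel()].
#' @param ref_age age (years) at which intercepts are anchored; `NULL`
#'   (default) uses the analytic mean of the truncated age distribution.
#' @param seed master seed; per-stage streams are derived from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 402, age_mean = 60, age_sd = 15,
                          age_min = 20, age_max = 94,
                          female_fraction = 0.32,
                          mtl_mean_at_ref = 8.57, mtl_sd = 0.678,
                          ltl_gap_mean = 1.86, ltl_gap_sd = 0.204,
                          ltl_slope = -0.031, mtl_slope = -0.015,
                          sex_offset_ltl = 0.22, sex_offset_mtl = 0.25,
                          snp_panel = default_snp_panel(),
                          ref_age = NULL, seed = NULL) {
  stop_if(!is_count(n) || n <= 0, "n must be a positive integer")
  stop_if(age_min >= age_max || age_sd <= 0, "invalid age model")
  stop_if(!is_prob(female_fraction) || female_fraction <= 0 ||
            female_fraction >= 1, "female_fraction must be in (0, 1)")
  stop_if(ltl_slope > 0 || mtl_slope > 0,
          "age slopes must be <= 0 (telomeres shorten with age)")
  stop_if(ltl_slope > mtl_slope,
          "ltl_slope must be <= mtl_slope (leukocyte attrition is steeper)")
  stop_if(ltl_gap_mean < 0, "ltl_gap_mean must be >= 0")
  stop_if(mtl_sd < 0 || ltl_gap_sd < 0, "residual SDs must be >= 0")
  if (!is.null(snp_panel)) {
    stopifnot(is.data.frame(snp_panel),
              all(c("rsid", "maf", "beta_logltl") %in% names(snp_panel)))
    stop_if(any(snp_panel$maf <= 0) || any(snp_panel$maf > 0.5),
            "panel MAFs must be in (0, 0.5]")
    if (is.null(snp_panel$beta_mtl)) snp_panel$beta_mtl <- 0
    if (is.null(snp_panel$hwe_fis)) snp_panel$hwe_fis <- 0
  }
  if (is.null(ref_age)) {
    ref_age <- trunc_norm_moments(age_mean, age_sd, age_min, age_max)$mean
  }
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 female_fraction = female_fraction,
                 mtl_mean_at_ref = mtl_mean_at_ref, mtl_sd = mtl_sd,
                 ltl_gap_mean = ltl_gap_mean, ltl_gap_sd = ltl_gap_sd,
                 ltl_slope = ltl_slope, mtl_slope = mtl_slope,
                 sex_offset_ltl = sex_offset_ltl,
                 sex_offset_mtl = sex_offset_mtl,
                 snp_panel = snp_panel, ref_age = ref_age, seed = seed),
            class = "cohort_config")
}

#' Calibrate kb-scale allele effects from log-LTL betas
#'
#' Converts a per-minor-allele effect on log(LTL) (natural log) into a
#' kb-scale shift of the early-life gap, solving
#' beta = -delta * E\[1/LTL\] so the fitted regression coefficient of
#' log(LTL) on allele dosage recovers `beta_logltl` in expectation.
#' E\[1/LTL\] is evaluated by a second-order moment expansion,
#' (1/mu) * (1 + sigma^2/mu^2), with mu and sigma^2 the marginal LTL mean
#' and variance implied by the configuration.
#'
#' @param config a [cohort_config()].
#' @return numeric vector of per-allele gap increments (kb), one per panel
#'   SNP (positive = shorter LTL per minor allele).
#' @export
calibrate_allele_effects <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(config$snp_panel)) return(numeric(0))
  age <- trunc_norm_moments(config$age_mean, config$age_sd,
                            config$age_min, config$age_max)
  ff <- config$female_fraction
  mu <- config$mtl_mean_at_ref - config$ltl_gap_mean
  v <- config$ltl_slope^2 * age$var +
    config$sex_offset_ltl^2 * ff * (1 - ff) +
    config$mtl_sd^2 + config$ltl_gap_sd^2
  e_inv <- (1 + v / mu^2) / mu
  -config$snp_panel$beta_logltl / e_inv
}

## Genotype draw at one SNP under HWE, optionally with inbreeding
## coefficient f (heterozygote deficit for f > 0).
draw_genotypes <- function(n, maf, fis = 0) {
  q <- maf
  p <- 1 - q
  probs <- c(p^2 + fis * p * q, 2 * p * q * (1 - fis), q^2 + fis * p * q)
  probs <- pmax(probs, 0)
  sample(0:2, n, replace = TRUE, prob = probs)
}

#' Simulate a genotyped blood-and-muscle cohort
#'
#' Draws ages, sexes and HWE genotypes, then builds MTL and LTL from the
#' generative model in [cohort_config()].  SNP effects act on the
#' early-life gap with centred dosages, so allele effects change neither the
#' population mean LTL nor its calibration.  All latent components are
#' returned in a truth record.
#'
#' @param config a [cohort_config()].
#' @return object of class `sim_cohort`: list with
#'   \describe{
#'     \item{cohort}{data.frame `id`, `age_years`, `sex` ("F"/"M"),
#'       `ltl_kb`, `mtl_kb`, `ratio`.}
#'     \item{genotypes}{n x S integer matrix of minor-allele counts, rows
#'       named by id, columns by rsid (NULL when no panel).}
#'     \item{panel}{the panel with the calibrated `delta_kb` column.}
#'     \item{truth}{data.frame of latent components (gap, residuals).}
#'     \item{config}{the resolved configuration, including the seed used.}
#'   }
#' @examples
#' sim <- simulate_cohort(cohort_config(n = 50, seed = 1))
#' colMeans(sim$cohort[c("ltl_kb", "mtl_kb", "ratio")])
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  ff <- config$female_fraction
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_min, config$age_max)
  female <- as.integer(stats::runif(n) < ff)
  dage <- age - config$ref_age

  geno <- NULL
  gap_gene <- 0
  mtl_gene <- 0
  panel <- config$snp_panel
  if (!is.null(panel) && nrow(panel) > 0) {
    geno <- matrix(0L, n, nrow(panel), dimnames = list(NULL, panel$rsid))
    for (j in seq_len(nrow(panel))) {
      geno[, j] <- draw_genotypes(n, panel$maf[j], panel$hwe_fis[j])
    }
    panel$delta_kb <- calibrate_allele_effects(config)
    centred <- sweep(geno, 2, 2 * panel$maf)
    gap_gene <- drop(centred %*% panel$delta_kb)
    mtl_gene <- drop(centred %*% panel$beta_mtl)
  }

  e_mtl <- stats::rnorm(n, 0, config$mtl_sd)
  e_gap <- stats::rnorm(n, 0, config$ltl_gap_sd)
  sexc <- female - ff
  mtl <- config$mtl_mean_at_ref + config$mtl_slope * dage +
    config$sex_offset_mtl * sexc + mtl_gene + e_mtl
  gap <- config$ltl_gap_mean + (config$mtl_slope - config$ltl_slope) * dage +
    (config$sex_offset_mtl - config$sex_offset_ltl) * sexc +
    gap_gene + e_gap
  ltl <- mtl - gap
  stop_if(any(ltl <= 0) || any(mtl <= 0),
          "simulated non-positive telomere length; check configuration")

  id <- sprintf("S%04d", seq_len(n))
  cohort <- data.frame(id = id, age_years = age,
                       sex = ifelse(female == 1, "F", "M"),
                       ltl_kb = ltl, mtl_kb = mtl, ratio = ltl / mtl,
                       stringsAsFactors = FALSE)
  if (!is.null(geno)) rownames(geno) <- id
  truth <- data.frame(id = id, age_years = age, female = female,
                      gap_kb = gap, gap_genetic_kb = gap_gene,
                      mtl_genetic_kb = mtl_gene,
                      mtl_residual_kb = e_mtl, gap_residual_kb = e_gap,
                      stringsAsFactors = FALSE)
  structure(list(cohort = cohort, genotypes = geno, panel = panel,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> n = %d, %d SNPs, seed = %s\n",
              nrow(x$cohort),
              if (is.null(x$genotypes)) 0L else ncol(x$genotypes),
              format(x$config$seed)))
  cat(sprintf("  LTL %.2f +/- %.2f kb, MTL %.2f +/- %.2f kb, ratio %.3f\n",
              mean(x$cohort$ltl_kb), stats::sd(x$cohort$ltl_kb),
              mean(x$cohort$mtl_kb), stats::sd(x$cohort$mtl_kb),
              mean(x$cohort$ratio)))
  invisible(x)
}
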