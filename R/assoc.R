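#' Minor allele frequency of one SNP
#'
#' Frequency of the less common allele from 0/1/2 dosage codes.  If the
#' coded allele turns out to be the major one (frequency > 0.5) the coding
#' is flipped to `2 - count` and the flip recorded.
#'
#' @param genotypes integer vector of allele counts in 0/1/2, NA = missing.
#' @return list with `maf`, `flipped` (logical), `genotypes` (minor-allele
#'   oriented), `n` non-missing.
#' @export
compute_maf <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  stop_if(length(g) == 0, "all genotypes missing")
  stop_if(!all(g %in% 0:2), "genotypes must be coded 0/1/2")
  freq <- sum(g) / (2 * length(g))
  flipped <- freq > 0.5
  if (flipped) {
    genotypes <- 2L - genotypes
    freq <- 1 - freq
  }
  list(maf = freq, flipped = flipped, genotypes = genotypes, n = length(g))
}

#' Hardy-Weinberg chi-squared test
#'
#' Compares observed genotype counts with the p^2, 2pq, q^2 expectations
#' from the observed allele frequencies (chi-squared, 1 df).
#'
#' @param counts integer vector (n_AA, n_Aa, n_aa): major homozygote,
#'   heterozygote, minor homozygote.
#' @param alpha significance level for the pass flag, default 0.05.
#' @param min_total minimum typed individuals, default 20.
#' @return object of class `hwe_result`: `counts`, `chi2`, `p`, `pass`,
#'   `alpha`.
#' @examples
#' hwe_chisq(c(25, 50, 25))$chi2  # exact HWE proportions -> 0
#' @export
hwe_chisq <- function(counts, alpha = 0.05, min_total = 20) {
  stop_if(length(counts) != 3, "counts must be (n_AA, n_Aa, n_aa)")
  stop_if(any(counts < 0), "negative genotype counts")
  n <- sum(counts)
  stop_if(n < min_total,
          sprintf("fewer than %d typed individuals (%d)", min_total, n))
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected, na.rm = TRUE)
  if (p == 0 || q == 0) chi2 <- 0  # monomorphic: trivially in equilibrium
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(counts = stats::setNames(as.numeric(counts),
                                          c("n_AA", "n_Aa", "n_aa")),
                 chi2 = chi2, p = pval, pass = pval >= alpha, alpha = alpha),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("<hwe_result> counts %d/%d/%d  chi2 = %.3f  p = %.3g  %s\n",
              x$counts[1], x$counts[2], x$counts[3], x$chi2, x$p,
              if (x$pass) "pass" else sprintf("FAIL (alpha = %g)", x$alpha)))
  invisible(x)
}

#' Genotype counts from a dosage vector
#'
#' @param genotypes 0/1/2 minor-allele counts, NA dropped.
#' @return integer vector (n_AA, n_Aa, n_aa).
#' @export
genotype_counts <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  c(sum(g == 0), sum(g == 1), sum(g == 2))
}

#' Hardy-Weinberg panel filter
#'
#' Tests each SNP and retains those in equilibrium; every excluded SNP is
#' named in the exclusion log together with its chi-squared p-value.
#'
#' @param genotypes n x S matrix of minor-allele counts (columns = rsids).
#' @param panel SNP metadata data.frame with an `rsid` column matching the
#'   genotype columns.
#' @param alpha exclusion threshold, default 0.05 (SNPs with p < alpha are
#'   dropped).
#' @return list with `panel` (retained rows), `genotypes` (retained
#'   columns), `exclusions` (data.frame `rsid`, `chi2`, `p`), `hwe`
#'   (per-SNP results).
#' @export
filter_hwe <- function(genotypes, panel, alpha = 0.05) {
  stopifnot(is.data.frame(panel), "rsid" %in% names(panel))
  if (nrow(panel) == 0) {
    warning("empty SNP panel: nothing to filter")
    return(list(panel = panel, genotypes = genotypes,
                exclusions = data.frame(rsid = character(), chi2 = numeric(),
                                        p = numeric()),
                hwe = list()))
  }
  stopifnot(is.matrix(genotypes), all(panel$rsid %in% colnames(genotypes)))
  hwe <- lapply(panel$rsid, function(rs) {
    hwe_chisq(genotype_counts(genotypes[, rs]), alpha = alpha)
  })
  names(hwe) <- panel$rsid
  pass <- vapply(hwe, `[[`, TRUE, "pass")
  exclusions <- data.frame(rsid = panel$rsid[!pass],
                           chi2 = vapply(hwe[!pass], `[[`, 0, "chi2"),
                           p = vapply(hwe[!pass], `[[`, 0, "p"),
                           row.names = NULL, stringsAsFactors = FALSE)
  list(panel = panel[pass, , drop = FALSE],
       genotypes = genotypes[, panel$rsid[pass], drop = FALSE],
       exclusions = exclusions, hwe = hwe)
}

#' Additive single-SNP association
#'
#' Ordinary least squares of a phenotype on minor-allele dosage (0/1/2)
#' plus covariates; the reported beta is the per-allele-copy coefficient
#' with its two-sided t-test p-value.  Complete-case per SNP: rows with any
#' missing value in the design are dropped and the fitted n reported.
#'
#' @param phenotype numeric response vector.
#' @param dosage minor-allele counts, 0/1/2 (NA allowed).
#' @param covariates optional data.frame of covariates aligned with the
#'   phenotype (e.g. age, sex).
#' @return list with `beta`, `se`, `p`, `n`, `covariates`.
#' @export
additive_assoc <- function(phenotype, dosage, covariates = NULL) {
  stop_if(length(phenotype) != length(dosage),
          "phenotype and dosage must be aligned")
  dat <- data.frame(y = phenotype, g = as.numeric(dosage))
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == length(phenotype))
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  stop_if(nrow(dat) <= ncol(dat), "not enough complete rows for the fit")
  stop_if(stats::var(dat$g) == 0, "monomorphic genotype: no dosage variance")
  fit <- stats::lm(y ~ ., data = dat)
  stop_if(anyNA(stats::coef(fit)), "collinear design")
  sm <- summary(fit)$coefficients
  list(beta = unname(sm["g", "Estimate"]), se = unname(sm["g", "Std. Error"]),
       p = unname(sm["g", "Pr(>|t|)"]), n = nrow(dat),
       covariates = setdiff(names(dat), c("y", "g")))
}

## Covariate set per phenotype: age and sex for the sex-dependent length
## phenotypes, age only for the ratio.
assoc_covariates <- function(cohort, phenotype) {
  if (phenotype == "ratio") {
    data.frame(age = cohort$age_years)
  } else {
    data.frame(age = cohort$age_years, sex = factor(cohort$sex))
  }
}

assoc_phenotype <- function(cohort, phenotype, log_base = exp(1)) {
  switch(phenotype,
         logLTL = log(cohort$ltl_kb, base = log_base),
         MTL = cohort$mtl_kb,
         ratio = cohort$ltl_kb / cohort$mtl_kb)
}

#' Gated SNP association testing
#'
#' Hierarchical strategy limiting multiple testing: stage 1 tests every SNP
#' against log-transformed LTL (age- and sex-adjusted); only SNPs with a
#' stage-1 p-value below `gate_alpha` advance to stage 2, where they are
#' tested against MTL (age- and sex-adjusted) and the LTL/MTL ratio
#' (age-adjusted).  Phenotype/SNP cells not tested are reported explicitly
#' with `tested = FALSE` rather than as failed fits.
#'
#' @param cohort data.frame `id`, `age_years`, `sex`, `ltl_kb`, `mtl_kb`.
#' @param genotypes n x S minor-allele count matrix, rows aligned to
#'   `cohort$id` (checked via rownames when present).
#' @param panel SNP metadata (`rsid` column; other columns carried through).
#' @param gate_alpha stage-1 gate, default 0.05.
#' @param log_base base of the LTL log transform, default natural log.
#' @return object of class `gated_assoc`: list with `stage1`, `stage2`
#'   data.frames (columns `rsid`, `phenotype`, `beta`, `se`, `p`, `n`,
#'   `tested`) and `gate_alpha`.
#' @export
gated_testing <- function(cohort, genotypes, panel, gate_alpha = 0.05,
                          log_base = exp(1)) {
  stopifnot(is.matrix(genotypes), is.data.frame(panel),
            all(panel$rsid %in% colnames(genotypes)))
  if (!is.null(rownames(genotypes))) {
    stop_if(!identical(rownames(genotypes), cohort$id),
            "genotype rows are not aligned with cohort ids")
  } else {
    stop_if(nrow(genotypes) != nrow(cohort),
            "genotype rows are not aligned with cohort ids")
  }
  fit_one <- function(rs, phenotype) {
    r <- additive_assoc(assoc_phenotype(cohort, phenotype, log_base),
                        genotypes[, rs],
                        assoc_covariates(cohort, phenotype))
    data.frame(rsid = rs, phenotype = phenotype, beta = r$beta, se = r$se,
               p = r$p, n = r$n, tested = TRUE, stringsAsFactors = FALSE)
  }
  stage1 <- do.call(rbind, lapply(panel$rsid, fit_one, phenotype = "logLTL"))
  gated <- stage1$rsid[stage1$p < gate_alpha]
  stage2 <- do.call(rbind, lapply(panel$rsid, function(rs) {
    do.call(rbind, lapply(c("MTL", "ratio"), function(ph) {
      if (rs %in% gated) {
        fit_one(rs, ph)
      } else {
        data.frame(rsid = rs, phenotype = ph, beta = NA_real_, se = NA_real_,
                   p = NA_real_, n = NA_integer_, tested = FALSE,
                   stringsAsFactors = FALSE)
      }
    }))
  }))
  structure(list(stage1 = stage1, stage2 = stage2, gate_alpha = gate_alpha,
                 gated_rsids = gated, log_base = log_base),
            class = "gated_assoc")
}

#' @export
print.gated_assoc <- function(x, ...) {
  cat(sprintf("<gated_assoc> stage 1: %d SNPs on logLTL; %d passed the gate (alpha = %g)\n",
              nrow(x$stage1), length(x$gated_rsids), x$gate_alpha))
  if (length(x$gated_rsids)) {
    cat("  gated:", paste(x$gated_rsids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pairwise epistasis scan
#'
#' For every SNP pair, fits phenotype ~ g1 + g2 + g1:g2 + covariates and
#' reports the interaction coefficient with raw and Bonferroni-adjusted
#' (over tested pairs) p-values.  Pairs containing a monomorphic SNP are
#' skipped with a log entry.
#'
#' @param cohort cohort data.frame as in [gated_testing()].
#' @param genotypes minor-allele count matrix.
#' @param panel SNP metadata; all C(S, 2) pairs are scanned.
#' @param phenotype "logLTL", "MTL" or "ratio" (covariates follow the
#'   phenotype as in [gated_testing()]).
#' @param log_base base of the LTL log transform.
#' @return data.frame `rsid1`, `rsid2`, `beta_int`, `se`, `p`,
#'   `p_bonferroni`, `n`; skipped pairs in attribute `"skipped"`.
#' @export
epistasis_scan <- function(cohort, genotypes, panel,
                           phenotype = c("logLTL", "MTL", "ratio"),
                           log_base = exp(1)) {
  phenotype <- match.arg(phenotype)
  stop_if(nrow(panel) < 2, "need at least 2 SNPs for an epistasis scan")
  y <- assoc_phenotype(cohort, phenotype, log_base)
  covs <- assoc_covariates(cohort, phenotype)
  pairs <- utils::combn(panel$rsid, 2)
  rows <- list()
  skipped <- character()
  for (j in seq_len(ncol(pairs))) {
    rs1 <- pairs[1, j]; rs2 <- pairs[2, j]
    g1 <- as.numeric(genotypes[, rs1]); g2 <- as.numeric(genotypes[, rs2])
    dat <- cbind(data.frame(y = y, g1 = g1, g2 = g2, gi = g1 * g2), covs)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    if (stats::var(dat$g1) == 0 || stats::var(dat$g2) == 0 ||
        stats::var(dat$gi) == 0) {
      skipped <- c(skipped, sprintf("%s:%s (monomorphic or constant product)",
                                    rs1, rs2))
      next
    }
    fit <- stats::lm(y ~ ., data = dat)
    sm <- summary(fit)$coefficients
    if (!"gi" %in% rownames(sm)) {
      skipped <- c(skipped, sprintf("%s:%s (collinear interaction)", rs1, rs2))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      rsid1 = rs1, rsid2 = rs2,
      beta_int = unname(sm["gi", "Estimate"]),
      se = unname(sm["gi", "Std. Error"]),
      p = unname(sm["gi", "Pr(>|t|)"]), n = nrow(dat),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rsid1 = character(), rsid2 = character(), beta_int = numeric(),
               se = numeric(), p = numeric(), n = integer())
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  attr(out, "skipped") <- skipped
  out
}

#' Association table in publication column layout
#'
#' Joins association results with SNP metadata into the conventional
#' SNP / CHR / Position / Gene / Effect Allele / Other Allele / MAF /
#' BETA / SE / P layout.
#'
#' @param results stage data.frame from [gated_testing()].
#' @param panel SNP metadata with `rsid`, `chr`, `position_bp`, `gene`,
#'   `effect_allele`, `other_allele`, `maf`.
#' @param genotypes optional dosage matrix; when given, MAF is recomputed
#'   from the data instead of taken from the panel.
#' @return data.frame in the publication layout.
#' @export
association_table <- function(results, panel, genotypes = NULL) {
  maf <- panel$maf
  if (!is.null(genotypes)) {
    maf <- vapply(panel$rsid, function(rs) compute_maf(genotypes[, rs])$maf, 0)
  }
  meta <- data.frame(SNP = panel$rsid, CHR = panel$chr,
                     Position = panel$position_bp, Gene = panel$gene,
                     `Effect Allele` = panel$effect_allele,
                     `Other Allele` = panel$other_allele, MAF = maf,
                     check.names = FALSE, stringsAsFactors = FALSE)
  out <- merge(meta, stats::setNames(
    results[c("rsid", "phenotype", "beta", "se", "p", "tested")],
    c("SNP", "Phenotype", "BETA", "SE", "P", "Tested")),
    by = "SNP", sort = FALSE)
  out[order(match(out$SNP, panel$rsid)), , drop = FALSE]
}
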