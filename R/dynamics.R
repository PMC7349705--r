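#' Compute the LTL/MTL ratio
#'
#' Adds (or recomputes — an incoming `ratio` column is never trusted) the
#' per-individual leukocyte/muscle telomere length ratio.  A ratio above 1
#' means leukocyte telomeres longer than muscle telomeres, which is
#' biologically anomalous for these paired measurements; such rows are
#' flagged, not dropped.
#'
#' @param table data.frame with columns `ltl_kb`, `mtl_kb` (both positive).
#' @return the table with columns `ratio` and logical `ratio_gt1_flag`.
#' @export
compute_ratio <- function(table) {
  stopifnot(is.data.frame(table), all(c("ltl_kb", "mtl_kb") %in% names(table)))
  stop_if(any(table$ltl_kb <= 0) || any(table$mtl_kb <= 0),
          "telomere lengths must be positive")
  table$ratio <- table$ltl_kb / table$mtl_kb
  table$ratio_gt1_flag <- table$ratio >= 1
  table
}

#' Cross-sectional age slope of a telomere phenotype
#'
#' Ordinary least-squares slope of the phenotype on age, optionally
#' sex-adjusted.  Telomere-length slopes are reported in bp/year (kb inputs
#' scaled by 1000); the ratio slope is per year.
#'
#' @param table cohort data.frame with `age_years`, `sex` and the phenotype
#'   columns (`ltl_kb`, `mtl_kb`; `ratio` is computed if absent).
#' @param phenotype one of "ltl", "mtl", "ratio".
#' @param adjust_sex also include sex in the model.
#' @return object of class `slope_estimate`: `slope`, `se`, `intercept`,
#'   `n`, `units`, `phenotype`, `adjusted_for`.
#' @examples
#' d <- data.frame(age_years = c(40, 50, 60, 70), sex = "M",
#'                 ltl_kb = c(7.0, 6.7, 6.4, 6.1), mtl_kb = 8.5)
#' age_slope(d, "ltl")$slope  # -30 bp/year
#' @export
age_slope <- function(table, phenotype = c("ltl", "mtl", "ratio"),
                      adjust_sex = FALSE) {
  phenotype <- match.arg(phenotype)
  stopifnot(is.data.frame(table), "age_years" %in% names(table))
  stop_if(nrow(table) < 3, "need at least 3 rows")
  stop_if(stats::var(table$age_years) == 0, "age has zero variance")
  if (phenotype == "ratio" && is.null(table$ratio)) table <- compute_ratio(table)
  y <- switch(phenotype, ltl = table$ltl_kb, mtl = table$mtl_kb,
              ratio = table$ratio)
  dat <- data.frame(y = y, age = table$age_years)
  form <- y ~ age
  if (adjust_sex) {
    dat$sex <- factor(table$sex)
    form <- y ~ age + sex
  }
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)$coefficients
  scale <- if (phenotype == "ratio") 1 else 1000
  structure(list(slope = unname(sm["age", "Estimate"]) * scale,
                 se = unname(sm["age", "Std. Error"]) * scale,
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 n = nrow(dat),
                 units = if (phenotype == "ratio") "per year" else "bp/year",
                 phenotype = phenotype,
                 adjusted_for = if (adjust_sex) "sex" else "none"),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("<slope_estimate> %s on age: %.4g +/- %.2g %s (n = %d%s)\n",
              x$phenotype, x$slope, x$se, x$units, x$n,
              if (x$adjusted_for != "none") paste0(", adj. ", x$adjusted_for) else ""))
  invisible(x)
}

#' Covariate-adjusted group means (least-squares means)
#'
#' Fits phenotype ~ covariate + group and evaluates each group's predicted
#' mean at the pooled covariate mean, with model-based standard errors.
#' Used for age-adjusted sex comparisons of telomere phenotypes.
#'
#' @param table cohort data.frame.
#' @param phenotype one of "ltl", "mtl", "ratio".
#' @param group grouping column name, default "sex".
#' @param adjust_for covariate column name, default "age_years".
#' @return data.frame with one row per group: `group`, `mean`, `se`, `n`.
#' @export
adjusted_group_means <- function(table, phenotype = c("ltl", "mtl", "ratio"),
                                 group = "sex", adjust_for = "age_years") {
  phenotype <- match.arg(phenotype)
  stopifnot(is.data.frame(table), group %in% names(table),
            adjust_for %in% names(table))
  if (phenotype == "ratio" && is.null(table$ratio)) table <- compute_ratio(table)
  g <- factor(table[[group]])
  stop_if(nlevels(droplevels(g)) < 2, "need at least two groups")
  y <- switch(phenotype, ltl = table$ltl_kb, mtl = table$mtl_kb,
              ratio = table$ratio)
  dat <- data.frame(y = y, x = table[[adjust_for]], g = g)
  fit <- stats::lm(y ~ x + g, data = dat)
  xbar <- mean(dat$x)
  levs <- levels(g)
  mm <- stats::model.matrix(~ x + g,
                            data = data.frame(x = xbar, g = factor(levs, levels = levs)))
  est <- drop(mm %*% stats::coef(fit))
  se <- sqrt(diag(mm %*% stats::vcov(fit) %*% t(mm)))
  data.frame(group = levs, mean = est, se = se,
             n = as.integer(table(g)[levs]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pairwise comparison tests
#'
#' Two-sided Mann-Whitney (midranks; exact when both samples have n <= 20,
#' normal approximation without continuity correction otherwise) for
#' continuous variables, or a chi-squared test (no Yates correction by
#' default) for a contingency table.
#'
#' @param x,y numeric samples for `mann_whitney`; for `chi2`, `x` is a
#'   contingency table or matrix of non-negative counts and `y` is ignored.
#' @param kind "mann_whitney" or "chi2".
#' @param correct continuity/Yates correction, default FALSE.
#' @return list with `statistic`, `p`, `kind`.
#' @export
pairwise_compare <- function(x, y = NULL, kind = c("mann_whitney", "chi2"),
                             correct = FALSE) {
  kind <- match.arg(kind)
  if (kind == "mann_whitney") {
    stop_if(length(x) == 0 || length(y) == 0, "empty sample")
    exact <- length(x) <= 20 && length(y) <= 20 && !any(duplicated(c(x, y)))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = correct))
    list(statistic = unname(ht$statistic), p = ht$p.value, kind = kind)
  } else {
    tab <- as.matrix(x)
    stop_if(any(tab < 0), "negative counts in contingency table")
    stop_if(sum(tab) == 0, "empty contingency table")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ht$statistic), p = ht$p.value, kind = kind)
  }
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors, n >= 3, both with positive variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stop_if(length(x) != length(y), "x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  stop_if(length(x) < 3, "need at least 3 complete pairs")
  stop_if(stats::var(x) == 0 || stats::var(y) == 0, "zero variance")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Descriptive telomere-dynamics report
#'
#' Means +/- SD, covariate-adjusted sex means +/- SE, and age slopes
#' (unadjusted and sex-adjusted) for LTL, MTL and their ratio.
#'
#' @param table cohort data.frame (`id`, `age_years`, `sex`, `ltl_kb`,
#'   `mtl_kb`).
#' @return list with `descriptives`, `adjusted_sex_means`, `slopes` data
#'   frames.
#' @export
dynamics_report <- function(table) {
  table <- compute_ratio(table)
  phen <- c("ltl", "mtl", "ratio")
  val <- list(ltl = table$ltl_kb, mtl = table$mtl_kb, ratio = table$ratio)
  desc <- data.frame(phenotype = phen,
                     mean = vapply(val, mean, 0),
                     sd = vapply(val, stats::sd, 0),
                     n = nrow(table), row.names = NULL)
  adj <- do.call(rbind, lapply(phen, function(p) {
    d <- adjusted_group_means(table, p)
    d$phenotype <- p
    d
  }))
  slopes <- do.call(rbind, lapply(phen, function(p) {
    do.call(rbind, lapply(c(FALSE, TRUE), function(adj_sex) {
      s <- age_slope(table, p, adjust_sex = adj_sex)
      data.frame(phenotype = p, slope = s$slope, se = s$se, units = s$units,
                 adjusted_for = s$adjusted_for)
    }))
  }))
  list(descriptives = desc, adjusted_sex_means = adj, slopes = slopes)
}
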