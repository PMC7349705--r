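#' End-to-end run configuration
#'
#' Bundles the cohort, gel, quantification and association options for
#' [run_all()].  Every option has a default; the fully resolved
#' configuration is written as YAML into the output directory so a run can
#' be reproduced from its artefacts alone.
#'
#' @param seed master seed; per-stage streams are derived from it.
#' @param cohort a [cohort_config()] (its own seed field is ignored; the
#'   run seed governs).
#' @param gel a [gel_config()].
#' @param window mean-TRF kb window.
#' @param background background-subtraction method.
#' @param max_disagreement duplicate QC threshold, kb.
#' @param gate_alpha stage-1 association gate.
#' @param hwe_alpha Hardy-Weinberg exclusion threshold.
#' @param log_base base of the LTL log transform.
#' @param quantify_gel if TRUE, LTL/MTL entering dynamics and association
#'   are re-measured from simulated membranes; if FALSE the simulated
#'   cohort values are used directly (fast path).
#' @param write_lanes if TRUE, write every lane profile TSV under
#'   `out/lanes/` (verbose; off by default).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort = cohort_config(),
                       gel = gel_config(), window = c(3, 20),
                       background = "rolling_min", max_disagreement = 0.5,
                       gate_alpha = 0.05, hwe_alpha = 0.05,
                       log_base = exp(1), quantify_gel = TRUE,
                       write_lanes = FALSE) {
  stop_if(!is_count(seed), "seed must be an integer")
  stopifnot(inherits(cohort, "cohort_config"), inherits(gel, "gel_config"))
  stop_if(length(window) != 2 || window[1] >= window[2],
          "window must be c(low, high) with low < high")
  stop_if(!background %in% c("rolling_min", "lane_flanks", "none"),
          "unknown background method")
  stop_if(!is_prob(gate_alpha) || !is_prob(hwe_alpha), "alphas must be in [0, 1]")
  structure(list(seed = as.integer(seed), cohort = cohort, gel = gel,
                 window = window, background = background,
                 max_disagreement = max_disagreement,
                 gate_alpha = gate_alpha, hwe_alpha = hwe_alpha,
                 log_base = log_base, quantify_gel = quantify_gel,
                 write_lanes = write_lanes),
            class = "run_config")
}

config_as_list <- function(config) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.list(v) && !is.data.frame(v)) strip(v) else v)
  }
  out <- strip(config)
  out$cohort$snp_panel <- NULL  # dumped separately as panel.csv
  out
}

#' Run the full simulate-quantify-dynamics-association pipeline
#'
#' Simulates a genotyped cohort, optionally re-measures LTL/MTL through
#' simulated membranes and densitometric quantification, computes the
#' dynamics report, applies Hardy-Weinberg QC and gated association
#' testing, and writes all tables plus a human-readable report and a run
#' log into `out`.  Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @param out output directory (created if needed).
#' @return (invisibly) list with all in-memory results: `cohort`,
#'   `quantified`, `dynamics`, `hwe`, `assoc`, `paths`.
#' @export
run_all <- function(config = run_config(), out) {
  stopifnot(inherits(config, "run_config"))
  stop_if(missing(out) || !is.character(out), "an output directory is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(out), "could not create output directory")
  seeds <- derive_seeds(config$seed, 3L)
  log_lines <- c(sprintf("telodyn %s", as.character(utils::packageVersion("telodyn"))),
                 sprintf("R %s", R.version.string),
                 sprintf("master seed %d; stage seeds %s", config$seed,
                         paste(seeds, collapse = ", ")))
  stage <- "simulate"
  res <- tryCatch({
    cc <- config$cohort
    cc$seed <- seeds[1]
    sim <- simulate_cohort(cc)
    write_cohort(sim$cohort, file.path(out, "cohort.csv"))
    utils::write.csv(sim$truth, file.path(out, "truth.csv"), row.names = FALSE)
    if (!is.null(sim$genotypes)) {
      write_genotypes_long(sim$genotypes, file.path(out, "genotypes.csv"))
      write_ped_map(sim$genotypes, sim$panel, file.path(out, "panel"),
                    cohort = sim$cohort)
      utils::write.csv(sim$panel, file.path(out, "panel.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(config_as_list(config),
                     file.path(out, "config_resolved.yaml"))

    stage <- "quantify"
    measured <- sim$cohort
    quantified <- NULL
    if (config$quantify_gel) {
      set.seed(seeds[2])
      quantified <- quantify_membranes(
        simulate_membrane(sim$cohort, config$gel),
        window = config$window, background = config$background,
        max_disagreement = config$max_disagreement)
      utils::write.table(quantified$lanes, file.path(out, "lanes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (config$write_lanes) {
        ## re-simulate with the same stage seed to dump the raw profiles
        set.seed(seeds[2])
        mems <- simulate_membrane(sim$cohort, config$gel)
        dir.create(file.path(out, "lanes"), showWarnings = FALSE)
        for (mem in mems) for (ln in mem$lanes) {
          md <- ln$metadata
          write_lane_profile(ln, file.path(out, "lanes",
            sprintf("%s_lane%02d_%s.tsv", md$membrane_id, md$lane,
                    if (is.na(md$sample_id)) md$type
                    else paste0(md$sample_id, "_", md$tissue))))
        }
      }
      measured <- merge(sim$cohort[c("id", "age_years", "sex")],
                        quantified$samples, by = "id")
      n_flag <- sum(nzchar(quantified$lanes$flags))
      log_lines <- c(log_lines,
                     sprintf("quantified %d lanes (%d flagged)",
                             nrow(quantified$lanes), n_flag))
    }
    measured <- compute_ratio(measured)
    utils::write.csv(measured, file.path(out, "measured_cohort.csv"),
                     row.names = FALSE)

    stage <- "dynamics"
    dyn <- dynamics_report(measured)
    utils::write.table(dyn$descriptives, file.path(out, "dynamics_descriptives.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(dyn$slopes, file.path(out, "dynamics_slopes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(dyn$adjusted_sex_means,
                       file.path(out, "dynamics_adjusted_means.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    stage <- "assoc"
    hwe <- assoc <- NULL
    if (!is.null(sim$genotypes)) {
      hwe <- filter_hwe(sim$genotypes, sim$panel, alpha = config$hwe_alpha)
      if (nrow(hwe$exclusions)) {
        utils::write.table(hwe$exclusions, file.path(out, "hwe_exclusions.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        log_lines <- c(log_lines,
                       sprintf("HWE excluded: %s",
                               paste(hwe$exclusions$rsid, collapse = ", ")))
      }
      assoc <- gated_testing(measured, hwe$genotypes, hwe$panel,
                             gate_alpha = config$gate_alpha,
                             log_base = config$log_base)
      utils::write.table(
        association_table(assoc$stage1, hwe$panel, hwe$genotypes),
        file.path(out, "assoc_stage1.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(
        association_table(assoc$stage2, hwe$panel, hwe$genotypes),
        file.path(out, "assoc_stage2.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }

    stage <- "report"
    rep_path <- file.path(out, "report.txt")
    writeLines(render_report(measured, dyn, hwe, assoc, quantified), rep_path)
    writeLines(c(log_lines, "status: complete"), file.path(out, "run.log"))
    list(cohort = sim, quantified = quantified, measured = measured,
         dynamics = dyn, hwe = hwe, assoc = assoc,
         paths = list(out = out, report = rep_path))
  }, error = function(e) {
    writeLines(c(log_lines, sprintf("status: failed at stage '%s'", stage),
                 conditionMessage(e)), file.path(out, "run.log"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

render_report <- function(measured, dyn, hwe, assoc, quantified) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c("Blood-and-muscle telomere dynamics report",
             strrep("=", 42), "",
             sprintf("n = %d individuals", nrow(measured)), "",
             "Descriptives (mean +/- SD):")
  for (i in seq_len(nrow(dyn$descriptives))) {
    d <- dyn$descriptives[i, ]
    unit <- if (d$phenotype == "ratio") "" else " kb"
    lines <- c(lines, sprintf("  %-6s %s +/- %s%s", toupper(d$phenotype),
                              fmt(d$mean, 2), fmt(d$sd, 2), unit))
  }
  lines <- c(lines, "", "Age slopes (OLS):")
  for (i in seq_len(nrow(dyn$slopes))) {
    s <- dyn$slopes[i, ]
    lines <- c(lines, sprintf("  %-6s %s +/- %s %s (%s-adjusted)",
                              toupper(s$phenotype), fmt(s$slope, 4),
                              fmt(s$se, 4), s$units, s$adjusted_for))
  }
  lines <- c(lines, "", "Age-adjusted means by sex (mean +/- SE):")
  for (i in seq_len(nrow(dyn$adjusted_sex_means))) {
    a <- dyn$adjusted_sex_means[i, ]
    lines <- c(lines, sprintf("  %-6s %s: %s +/- %s", toupper(a$phenotype),
                              a$group, fmt(a$mean, 2), fmt(a$se, 3)))
  }
  if (!is.null(quantified)) {
    ref <- quantified$reference_drift
    lines <- c(lines, "",
               sprintf("Reference-lane drift across membranes: %s kb",
                       paste(fmt(ref$mean_trf_kb, 2), collapse = " / ")))
  }
  if (!is.null(hwe)) {
    lines <- c(lines, "",
               sprintf("SNP QC: %d typed, %d retained after Hardy-Weinberg filtering",
                       nrow(hwe$panel) + nrow(hwe$exclusions), nrow(hwe$panel)))
    if (nrow(hwe$exclusions)) {
      lines <- c(lines, sprintf("  excluded: %s",
                                paste(sprintf("%s (p=%.2g)", hwe$exclusions$rsid,
                                              hwe$exclusions$p), collapse = ", ")))
    }
  }
  if (!is.null(assoc)) {
    lines <- c(lines, "",
               sprintf("Gated association (stage-1 gate alpha = %g):",
                       assoc$gate_alpha),
               sprintf("  stage 1 (logLTL): %d SNPs tested, %d passed the gate",
                       nrow(assoc$stage1), length(assoc$gated_rsids)))
    if (length(assoc$gated_rsids)) {
      for (rs in assoc$gated_rsids) {
        s1 <- assoc$stage1[assoc$stage1$rsid == rs, ]
        lines <- c(lines, sprintf("    %s: beta = %.4g, p = %.3g", rs,
                                  s1$beta, s1$p))
      }
      lines <- c(lines,
                 "  stage 2 (MTL, LTL/MTL ratio) restricted to gated SNPs; see assoc_stage2.tsv")
    } else {
      lines <- c(lines, "  stage 2: not tested (no SNP passed the gate)")
    }
  }
  lines
}
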