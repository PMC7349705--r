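## File formats: lane profiles and ladders as 2-column TSV (lane profiles
## carry a "# key: value" metadata header), cohort and truth tables as CSV,
## genotypes as PLINK-style .ped/.map or a long CSV.

#' Read and write lane-profile TSV files
#'
#' Two columns (`pixel`, `od`) preceded by a comment block of
#' `# key: value` lines carrying the lane metadata (sample id, tissue,
#' replicate, membrane id, ...).
#'
#' @param profile a [lane_profile()].
#' @param path file path.
#' @return `write_lane_profile()` returns the path invisibly;
#'   `read_lane_profile()` returns a [lane_profile()].
#' @export
write_lane_profile <- function(profile, path) {
  stopifnot(inherits(profile, "lane_profile"))
  meta <- profile$metadata
  keep <- vapply(meta, function(v) is.atomic(v) && length(v) == 1, TRUE)
  hdr <- sprintf("# %s: %s", names(meta)[keep],
                 vapply(meta[keep], function(v) format(v, digits = 15),
                        character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "pixel\tod"), con)
  utils::write.table(data.frame(pixel = profile$positions, od = profile$od),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_lane_profile
#' @export
read_lane_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) {
      val <- kv[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(kv[2])]] <- if (!is.na(num)) num else val
    }
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  lane_profile(dat$pixel, dat$od, metadata = meta)
}

#' Read and write ladder TSV files
#'
#' Two columns: `distance_px`, `kb`.
#'
#' @param ladder data.frame with `distance_px`, `kb` columns.
#' @param path file path.
#' @export
write_ladder <- function(ladder, path) {
  utils::write.table(ladder[c("distance_px", "kb")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ladder
#' @export
read_ladder <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Read and write cohort CSV files
#'
#' Columns: `id`, `age_years`, `sex` (F/M), `ltl_kb`, `mtl_kb`.  The ratio
#' is recomputed on read, never trusted from the file.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("id", "age_years", "sex", "ltl_kb", "mtl_kb")
  stopifnot(all(cols %in% names(cohort)))
  utils::write.csv(cohort[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "age_years", "sex", "ltl_kb", "mtl_kb") %in% names(d)))
  stop_if(any(d$age_years < 18 | d$age_years > 110),
          "ages outside the plausible range [18, 110]")
  compute_ratio(d)
}

#' Write genotypes as a PLINK-style .ped/.map pair
#'
#' One row per individual in the .ped (family id, individual id, paternal,
#' maternal, sex, phenotype, then two allele letters per SNP; missing coded
#' `0 0`), and one row per SNP in the .map (chromosome, rsid, genetic
#' distance 0, position).  Dosages are minor-allele counts; the panel's
#' effect allele is the minor allele.
#'
#' @param genotypes n x S minor-allele count matrix with rsid columns.
#' @param panel SNP metadata with `rsid`, `chr`, `position_bp`,
#'   `effect_allele`, `other_allele`.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param cohort optional cohort data.frame supplying sex codes.
#' @return character vector of the two paths, invisibly.
#' @export
write_ped_map <- function(genotypes, panel, prefix, cohort = NULL) {
  stopifnot(is.matrix(genotypes), all(panel$rsid %in% colnames(genotypes)))
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(genotypes)))
  sex_code <- rep(0L, nrow(genotypes))
  if (!is.null(cohort)) {
    sex_code <- ifelse(cohort$sex[match(ids, cohort$id)] == "M", 1L, 2L)
    sex_code[is.na(sex_code)] <- 0L
  }
  allele_cols <- lapply(seq_len(nrow(panel)), function(j) {
    g <- genotypes[, panel$rsid[j]]
    minor <- panel$effect_allele[j]
    major <- panel$other_allele[j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, minor, major))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, minor, major))
    cbind(a1, a2)
  })
  ped <- cbind(ids, ids, "0", "0", sex_code, "-9", do.call(cbind, allele_cols))
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  map <- data.frame(chr = panel$chr, rsid = panel$rsid, cm = 0,
                    pos = ifelse(is.na(panel$position_bp), 0,
                                 panel$position_bp))
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' Read a PLINK-style .ped/.map pair into a dosage matrix
#'
#' Counts the minor allele per SNP (minor = less frequent observed allele;
#' ties and orientation flips are recorded in the result's panel).
#'
#' @param ped,map file paths.
#' @return list with `genotypes` (n x S minor-allele count matrix),
#'   `map` (data.frame `chr`, `rsid`, `cm`, `pos`, `minor_allele`,
#'   `major_allele`, `maf`), `sex` codes from the .ped.
#' @export
read_ped_map <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, sep = "\t",
                          col.names = c("chr", "rsid", "cm", "pos"),
                          stringsAsFactors = FALSE)
  pd <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE)
  n_snp <- nrow(mp)
  stop_if(ncol(pd) != 6 + 2 * n_snp, ".ped column count does not match .map")
  ids <- as.character(pd[[2]])
  geno <- matrix(NA_integer_, nrow(pd), n_snp,
                 dimnames = list(ids, mp$rsid))
  minor <- major <- character(n_snp)
  maf <- numeric(n_snp)
  for (j in seq_len(n_snp)) {
    a1 <- as.character(pd[[6 + 2 * j - 1]])
    a2 <- as.character(pd[[6 + 2 * j]])
    miss <- a1 == "0" | a2 == "0"
    alleles <- c(a1[!miss], a2[!miss])
    tab <- sort(table(alleles))
    if (length(tab) == 1) tab <- c(tab, stats::setNames(0L, "?"))
    minor[j] <- names(tab)[1]
    major[j] <- names(tab)[2]
    g <- (a1 == minor[j]) + (a2 == minor[j])
    g[miss] <- NA_integer_
    geno[, j] <- g
    maf[j] <- tab[[1]] / sum(tab)
  }
  mp$minor_allele <- minor
  mp$major_allele <- major
  mp$maf <- maf
  list(genotypes = geno, map = mp, sex = as.integer(pd[[5]]))
}

#' Read and write genotypes as a long CSV
#'
#' Columns: `id`, `rsid`, `minor_allele_count`.
#'
#' @param genotypes n x S minor-allele count matrix with rsid columns and
#'   id rownames.
#' @param path file path.
#' @export
write_genotypes_long <- function(genotypes, path) {
  stopifnot(is.matrix(genotypes))
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(genotypes)))
  long <- data.frame(id = rep(ids, times = ncol(genotypes)),
                     rsid = rep(colnames(genotypes), each = nrow(genotypes)),
                     minor_allele_count = as.vector(genotypes))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_long
#' @export
read_genotypes_long <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "rsid", "minor_allele_count") %in% names(d)))
  ids <- unique(d$id)
  rsids <- unique(d$rsid)
  geno <- matrix(NA_integer_, length(ids), length(rsids),
                 dimnames = list(ids, rsids))
  geno[cbind(match(d$id, ids), match(d$rsid, rsids))] <-
    as.integer(d$minor_allele_count)
  geno
}
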