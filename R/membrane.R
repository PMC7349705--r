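#' Simulate duplicate Southern-blot membranes for a cohort subset
#'
#' For each individual, leukocyte (L) and muscle (M) DNA are resolved on
#' adjacent lanes of the same membrane, and the whole measurement is
#' performed in duplicate on a second, independently noised membrane.  Each
#' membrane also carries molecular-weight ladder lanes spread across the gel
#' (first, middle and last lane positions) and one reference lane of known
#' TRF length used as a between-membrane drift check.
#'
#' Replicate disagreement is generated by a per-lane multiplicative
#' calibration drift (`lane_scale_jitter`, lognormal SD on the migration
#' scale) emulating gel distortion: with pixel noise alone duplicate
#' estimates would be essentially identical.
#'
#' @param cohort_subset data.frame with columns `id`, `ltl_kb`, `mtl_kb`
#'   (e.g. rows of a simulated cohort).
#' @param gel a [gel_config()].
#' @param smear_sd within-sample TRF smear SD, kb.
#' @param ladder_kb ladder band sizes, kb.
#' @param ladder_jitter_sd ladder band-position jitter, pixels.
#' @param lane_scale_jitter SD of the per-lane log-scale calibration drift;
#'   default 0.008 reproduces a duplicate ICC in the ~0.99 regime.
#' @param reference_kb TRF length of the reference lane, kb.
#' @param seed master seed for the membrane pair.
#' @return object of class `membrane_set`: list of two membranes, each a
#'   list with `lanes` (list of [lane_profile()]s with metadata `lane`,
#'   `type` in sample/reference, `sample_id`, `tissue` L/M, `replicate`,
#'   `membrane_id`) and `ladders` (list of `ladder_calibration`s with
#'   positions).
#' @export
simulate_membrane <- function(cohort_subset, gel = gel_config(),
                              smear_sd = 1.5, ladder_kb = default_ladder_kb(),
                              ladder_jitter_sd = 0.5,
                              lane_scale_jitter = 0.008,
                              reference_kb = 8, seed = NULL) {
  stopifnot(is.data.frame(cohort_subset),
            all(c("id", "ltl_kb", "mtl_kb") %in% names(cohort_subset)))
  stop_if(nrow(cohort_subset) == 0, "cohort subset must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort_subset)
  ## lane layout: ladder, reference, then L/M pairs with a middle and final
  ## ladder; sample lane i of 2n sits between the flanking ladders.
  n_sample_lanes <- 2L * n
  ladder_positions <- c(1L, 3L + ceiling(n_sample_lanes / 2),
                        n_sample_lanes + 4L)
  ladder_positions <- unique(ladder_positions)

  make_membrane <- function(replicate) {
    membrane_id <- sprintf("M%d", replicate)
    ladders <- lapply(seq_along(ladder_positions), function(i) {
      bands <- simulate_ladder(ladder_kb, gel, jitter_sd = ladder_jitter_sd)
      fit_ladder_calibration(bands, position = ladder_positions[i],
                             id = sprintf("%s_L%d", membrane_id, i))
    })
    lane_at <- function(pos, trf_mean, type, sample_id = NA, tissue = NA) {
      drift <- exp(stats::rnorm(1, 0, lane_scale_jitter))
      gel_lane <- gel
      gel_lane$power_coefficient <- gel$power_coefficient * drift
      simulate_lane_profile(trf_mixture(trf_mean, smear_sd), gel_lane,
                            metadata = list(lane = pos, type = type,
                                            sample_id = sample_id,
                                            tissue = tissue,
                                            replicate = replicate,
                                            membrane_id = membrane_id))
    }
    lanes <- list(lane_at(2L, reference_kb, "reference"))
    pos <- 3L
    for (i in seq_len(n)) {
      if (pos %in% ladder_positions) pos <- pos + 1L
      lanes <- c(lanes, list(
        lane_at(pos, cohort_subset$ltl_kb[i], "sample",
                cohort_subset$id[i], "L")))
      pos <- pos + 1L
      if (pos %in% ladder_positions) pos <- pos + 1L
      lanes <- c(lanes, list(
        lane_at(pos, cohort_subset$mtl_kb[i], "sample",
                cohort_subset$id[i], "M")))
      pos <- pos + 1L
    }
    list(membrane_id = membrane_id, lanes = lanes, ladders = ladders)
  }
  structure(list(make_membrane(1L), make_membrane(2L)),
            class = "membrane_set")
}

#' Quantify all lanes of a membrane set
#'
#' Runs background subtraction, nearest-ladder calibration and windowed
#' mean-TRF estimation on every lane, then averages the duplicate
#' measurements per sample and tissue.
#'
#' @param membranes a [simulate_membrane()] result (or any list of
#'   membranes with `lanes` and `ladders`).
#' @param window kb window for [mean_trf()].
#' @param background background method, see [subtract_background()].
#' @param max_disagreement duplicate QC threshold, kb.
#' @return list with
#'   \describe{
#'     \item{lanes}{per-lane data.frame: `sample_id`, `tissue`, `replicate`,
#'       `type`, `mean_trf_kb`, `fraction_in_window`, `ladder_id`, `flags`.}
#'     \item{samples}{per-sample data.frame `id`, `ltl_kb`, `mtl_kb` from
#'       duplicate-averaged L and M lanes.}
#'     \item{reference_drift}{per-membrane reference-lane estimates, a
#'       drift QC statistic (no normalisation is applied).}
#'   }
#' @export
quantify_membranes <- function(membranes, window = c(3, 20),
                               background = "rolling_min",
                               max_disagreement = 0.5) {
  results <- list()
  for (mem in membranes) {
    for (lane in mem$lanes) {
      cal <- select_nearest_ladder(lane$metadata$lane, mem$ladders)
      prof <- subtract_background(lane, background)
      res <- mean_trf(prof, cal, window)
      results[[length(results) + 1L]] <- res
    }
  }
  lanes_df <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = as.character(r$metadata$sample_id %||% NA),
               tissue = as.character(r$metadata$tissue %||% NA),
               replicate = r$metadata$replicate %||% NA_integer_,
               type = r$metadata$type %||% "sample",
               mean_trf_kb = r$mean_trf,
               fraction_in_window = r$fraction_od_in_window,
               ladder_id = r$calibration_used %||% NA_character_,
               flags = paste(r$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  ## duplicate averaging per sample x tissue
  is_sample <- lanes_df$type == "sample"
  keys <- unique(lanes_df[is_sample, c("sample_id", "tissue")])
  avg <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- which(is_sample & lanes_df$sample_id == keys$sample_id[i] &
                   lanes_df$tissue == keys$tissue[i])
    rs <- results[sel]
    r <- if (length(rs) >= 2) {
      average_duplicates(rs[[1]], rs[[2]], max_disagreement)
    } else {
      rs[[1]]
    }
    data.frame(id = keys$sample_id[i], tissue = keys$tissue[i],
               mean_trf_kb = r$mean_trf,
               flags = paste(r$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  avg <- do.call(rbind, avg)
  samples <- merge(
    stats::setNames(avg[avg$tissue == "L", c("id", "mean_trf_kb")],
                    c("id", "ltl_kb")),
    stats::setNames(avg[avg$tissue == "M", c("id", "mean_trf_kb")],
                    c("id", "mtl_kb")),
    by = "id", all = TRUE)
  ref <- lanes_df[lanes_df$type == "reference",
                  c("replicate", "mean_trf_kb"), drop = FALSE]
  list(lanes = lanes_df, samples = samples, reference_drift = ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
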