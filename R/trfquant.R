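#' Fit a power-law ladder calibration
#'
#' Maps migration distance (pixels) to molecular weight (kb) via
#' MW = A * d^B, fitted by least squares on the log-log scale:
#' log(kb) = log(A) + B * log(distance).  Exact parameter recovery on
#' noiseless power-law bands.
#'
#' @param bands data.frame with columns `distance_px` and `kb`, or a
#'   two-column matrix (distance, kb).  At least 3 bands; kb must be
#'   strictly decreasing in distance.
#' @param position optional lane index/offset of the ladder on the membrane,
#'   used by [select_nearest_ladder()].
#' @param id optional ladder identifier.
#' @return object of class `ladder_calibration` with fields `scale_A`,
#'   `exponent_B`, `source_bands`, `fit_rmse` (log-kb scale), `position`,
#'   `id`.
#' @examples
#' b <- data.frame(distance_px = c(50, 100, 200), kb = 100 * c(50, 100, 200)^-0.8)
#' cal <- fit_ladder_calibration(b)
#' c(cal$scale_A, cal$exponent_B)
#' @export
fit_ladder_calibration <- function(bands, position = NA_real_, id = NULL) {
  if (is.matrix(bands)) bands <- data.frame(distance_px = bands[, 1], kb = bands[, 2])
  stopifnot(is.data.frame(bands), all(c("distance_px", "kb") %in% names(bands)))
  stop_if(nrow(bands) < 3, "need at least 3 ladder bands to fit a calibration")
  stop_if(any(bands$distance_px <= 0) || any(bands$kb <= 0),
          "band distances and sizes must be positive")
  bands <- bands[order(bands$distance_px), , drop = FALSE]
  stop_if(any(diff(bands$distance_px) == 0), "duplicate band distances")
  stop_if(any(diff(bands$kb) >= 0),
          "kb must be strictly decreasing in migration distance")
  fit <- stats::lm(log(kb) ~ log(distance_px), data = bands)
  b <- unname(stats::coef(fit))
  structure(list(scale_A = exp(b[1]), exponent_B = b[2],
                 source_bands = bands,
                 fit_rmse = sqrt(mean(stats::residuals(fit)^2)),
                 position = position, id = id),
            class = "ladder_calibration")
}

#' @export
print.ladder_calibration <- function(x, ...) {
  cat(sprintf("<ladder_calibration> MW = %.4g * d^%.4f  (%d bands, rmse %.2e log-kb)\n",
              x$scale_A, x$exponent_B, nrow(x$source_bands), x$fit_rmse))
  invisible(x)
}

#' Convert migration distance to kb under a fitted calibration
#'
#' @param cal a [fit_ladder_calibration()] result.
#' @param distance_px migration distances, pixels.
#' @return kb values.
#' @export
calibration_kb <- function(cal, distance_px) {
  stopifnot(inherits(cal, "ladder_calibration"))
  cal$scale_A * distance_px^cal$exponent_B
}

#' Select the ladder nearest to a sample lane
#'
#' Several ladders are resolved across a membrane; the one closest to a
#' given sample lane is used for its mean TRF.  Ties are broken toward the
#' leftmost (lowest-position) ladder.
#'
#' @param lane_position the sample's lane index/offset.
#' @param ladders list of `ladder_calibration` objects, each with a
#'   `position` field.
#' @return the nearest `ladder_calibration`.
#' @export
select_nearest_ladder <- function(lane_position, ladders) {
  stop_if(length(ladders) == 0, "no ladders available")
  pos <- vapply(ladders, function(l) as.numeric(l$position), numeric(1))
  stop_if(anyNA(pos), "every ladder needs a position for nearest-ladder selection")
  dist <- abs(lane_position - pos)
  cand <- which(dist == min(dist))
  ladders[[cand[which.min(pos[cand])]]]
}

#' Subtract lane background
#'
#' `rolling_min` subtracts a running minimum (window a fraction of lane
#' length), `lane_flanks` subtracts the mean OD of the outer flank pixels,
#' `none` is the identity.  The result is clamped at zero so OD stays
#' non-negative; the method and parameters are recorded in the profile
#' metadata.
#'
#' @param profile a [lane_profile()].
#' @param method background model.
#' @param window_frac rolling-minimum window as a fraction of the lane
#'   length (default 0.1).
#' @param flank_frac fraction of pixels at each lane end treated as
#'   signal-free for `lane_flanks`.
#' @return a background-subtracted [lane_profile()].
#' @export
subtract_background <- function(profile,
                                method = c("rolling_min", "lane_flanks", "none"),
                                window_frac = 0.1, flank_frac = 0.05) {
  stopifnot(inherits(profile, "lane_profile"))
  method <- match.arg(method)
  od <- profile$od
  n <- length(od)
  bg <- switch(method,
    none = 0,
    rolling_min = {
      w <- max(3L, as.integer(round(window_frac * n)))
      zoo::rollapply(od, width = w, FUN = min, partial = TRUE, align = "center")
    },
    lane_flanks = {
      k <- max(1L, as.integer(round(flank_frac * n)))
      mean(od[c(seq_len(k), seq(n - k + 1L, n))])
    })
  out <- profile
  out$od <- pmax(od - bg, 0)
  out$metadata$background <- list(method = method,
                                  window_frac = if (method == "rolling_min") window_frac,
                                  flank_frac = if (method == "lane_flanks") flank_frac)
  out
}

#' Windowed weighted mean TRF length
#'
#' Converts each profile position to molecular weight via the ladder
#' calibration, restricts to positions whose MW lies in the closed window,
#' and returns sum(OD) / sum(OD / MW).  Dividing each OD by its MW converts
#' the mass-weighted densitometric signal into molecule counts, so the ratio
#' is the molecule-number mean fragment length.  The estimate is invariant
#' to uniform rescaling of OD.
#'
#' @param profile a background-handled [lane_profile()].
#' @param cal a [fit_ladder_calibration()] result.
#' @param window closed kb window, default `c(3, 20)`.
#' @return object of class `trf_result` with fields `mean_trf`, `window`,
#'   `fraction_od_in_window`, `calibration_used`, `qc_flags`, `metadata`.
#' @examples
#' gel <- gel_config(blur_sd = 0, background_level = 0, noise_sd = 0)
#' cal <- fit_ladder_calibration(simulate_ladder(default_ladder_kb(), gel))
#' p <- simulate_lane_profile(trf_mixture(6.7, 1), gel)
#' mean_trf(p, cal)$mean_trf
#' @export
mean_trf <- function(profile, cal, window = c(3, 20)) {
  stopifnot(inherits(profile, "lane_profile"), inherits(cal, "ladder_calibration"))
  stop_if(length(window) != 2 || window[1] >= window[2],
          "window must be c(low, high) with low < high")
  mw <- calibration_kb(cal, profile$positions)
  ## closed window; the tiny relative tolerance keeps positions that map
  ## exactly onto an edge inside despite floating-point conversion error
  eps <- 1e-9
  inside <- mw >= window[1] * (1 - eps) & mw <= window[2] * (1 + eps)
  od_in <- profile$od[inside]
  total <- sum(profile$od)
  stop_if(sum(od_in) <= 0,
          "no OD mass inside the kb window; cannot estimate mean TRF")
  est <- sum(od_in) / sum(od_in / mw[inside])
  structure(list(mean_trf = est, window = window,
                 fraction_od_in_window = if (total > 0) sum(od_in) / total else 0,
                 calibration_used = cal$id, qc_flags = character(),
                 metadata = profile$metadata),
            class = "trf_result")
}

#' @export
print.trf_result <- function(x, ...) {
  cat(sprintf("<trf_result> mean TRF %.3f kb  window [%g, %g] kb  %.1f%% OD in window%s\n",
              x$mean_trf, x$window[1], x$window[2],
              100 * x$fraction_od_in_window,
              if (length(x$qc_flags)) paste0("  flags: ", paste(x$qc_flags, collapse = ",")) else ""))
  invisible(x)
}

#' Average duplicate TRF measurements
#'
#' Duplicate measurements made on separate membranes are combined as their
#' arithmetic mean.  Disagreement beyond `max_disagreement` raises a QC flag
#' on the result (not an error): the pair is reported, flagged for review.
#'
#' @param r1,r2 `trf_result` objects for the same sample and tissue.
#' @param max_disagreement absolute difference (kb) above which the
#'   `duplicate_disagreement` flag is raised; default 0.5 kb.
#' @return a `trf_result` with the averaged estimate.
#' @export
average_duplicates <- function(r1, r2, max_disagreement = 0.5) {
  stopifnot(inherits(r1, "trf_result"), inherits(r2, "trf_result"))
  same <- function(field) identical(r1$metadata[[field]], r2$metadata[[field]])
  stop_if(!same("sample_id") || !same("tissue"),
          "duplicates must share sample id and tissue")
  flags <- union(r1$qc_flags, r2$qc_flags)
  delta <- abs(r1$mean_trf - r2$mean_trf)
  if (delta > max_disagreement) {
    flags <- union(flags, sprintf("duplicate_disagreement:%.3fkb", delta))
  }
  out <- r1
  out$mean_trf <- (r1$mean_trf + r2$mean_trf) / 2
  out$qc_flags <- flags
  out$metadata$replicate <- NULL
  out
}
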