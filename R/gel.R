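#' Gel model configuration
#'
#' Parameters of the simulated electrophoresis/densitometry system.  Fragment
#' migration follows the power law MW(kb) = A * d^B with B < 0 (longer
#' fragments migrate less), the inverse of the calibration fitted by
#' [fit_ladder_calibration()].  The densitometric signal is mass-proportional:
#' a fragment of length m kb present in n copies contributes optical density
#' proportional to n * m.  This is exactly the weighting that the windowed
#' mean-TRF formula sum(OD)/sum(OD/MW) inverts to recover a molecule-number
#' mean, so the simulator encodes the assumption the estimator relies on.
#'
#' The default reciprocal law (A = 1000 kb, B = -1) places the 2-25 kb
#' fragment range at 40-500 px of the 10-600 px lane, leaving the outer
#' flanks of the lane signal-free for background estimation.
#'
#' @param power_coefficient scale A of the migration law, kb.
#' @param power_exponent exponent B; must be negative.
#' @param blur_sd Gaussian band-spread of the detection system, pixels.
#' @param background_level constant membrane background, OD units.
#' @param noise_sd additive pixel noise SD, OD units.
#' @param n_pixels number of samples along the lane (>= 100).
#' @param pixel_range numeric length-2, first and last pixel position.
#' @param od_mass total integrated OD assigned to the lane signal before
#'   background and noise.  Mean TRF is invariant to this scale; fixing the
#'   integral (rather than the peak) keeps signal-to-background independent
#'   of smear width.
#' @return object of class `gel_config`.
#' @examples
#' gel <- gel_config()
#' migration_distance(c(3, 20), gel)
#' @export
gel_config <- function(power_coefficient = 1000, power_exponent = -1,
                       blur_sd = 2, background_level = 0.02, noise_sd = 0.001,
                       n_pixels = 1000, pixel_range = c(10, 600),
                       od_mass = 70) {
  stop_if(power_exponent >= 0, "power_exponent must be negative: longer fragments migrate less")
  stop_if(power_coefficient <= 0, "power_coefficient must be positive")
  stop_if(blur_sd < 0, "blur_sd must be >= 0")
  stop_if(background_level < 0, "background_level must be >= 0")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  stop_if(!is_count(n_pixels) || n_pixels < 100, "n_pixels must be an integer >= 100")
  stop_if(length(pixel_range) != 2 || pixel_range[1] <= 0 ||
            pixel_range[2] <= pixel_range[1], "pixel_range must be increasing and positive")
  structure(list(power_coefficient = power_coefficient,
                 power_exponent = power_exponent, blur_sd = blur_sd,
                 background_level = background_level, noise_sd = noise_sd,
                 n_pixels = as.integer(n_pixels), pixel_range = pixel_range,
                 od_mass = od_mass),
            class = "gel_config")
}

#' Migration distance for a fragment size (and back)
#'
#' `migration_distance()` maps kb to pixels under the gel's power law,
#' `migration_kb()` is its inverse.
#'
#' @param kb fragment sizes, kb.
#' @param distance migration distances, pixels.
#' @param gel a [gel_config()].
#' @return numeric vector.
#' @export
migration_distance <- function(kb, gel) {
  (kb / gel$power_coefficient)^(1 / gel$power_exponent)
}

#' @rdname migration_distance
#' @export
migration_kb <- function(distance, gel) {
  gel$power_coefficient * distance^gel$power_exponent
}

#' Discretised TRF smear distribution
#'
#' Builds a discrete approximation (atoms of fragment size and molecule
#' count) to a within-sample TRF size distribution.  The default family is
#' lognormal truncated to `kb_range`; the lognormal is a modelling choice
#' for the right-skewed TRF smear, not a claim about any particular dataset,
#' and `family = "normal"` is available.  Parameters are the arithmetic
#' mean and SD of the untruncated distribution.
#'
#' @param mean_kb,sd_kb arithmetic mean and SD of fragment length, kb.
#' @param family "lognormal" or "normal".
#' @param kb_range support truncation, kb; must contain the 3-20 kb window
#'   of interest.
#' @param n_atoms number of grid atoms.
#' @return data.frame with columns `kb` and `molecules` (relative molecule
#'   counts summing to 1), with the realised molecule-number mean in
#'   attribute `"number_mean_kb"`.
#' @examples
#' d <- trf_mixture(6.71, 0.84)
#' attr(d, "number_mean_kb")
#' @export
trf_mixture <- function(mean_kb, sd_kb, family = c("lognormal", "normal"),
                        kb_range = c(2, 25), n_atoms = 512) {
  family <- match.arg(family)
  stop_if(mean_kb <= 0 || sd_kb <= 0, "mean_kb and sd_kb must be positive")
  stop_if(kb_range[1] <= 0 || kb_range[2] <= kb_range[1], "invalid kb_range")
  edges <- seq(kb_range[1], kb_range[2], length.out = n_atoms + 1)
  kb <- (edges[-1] + edges[-length(edges)]) / 2
  w <- diff(edges)
  dens <- switch(family,
    lognormal = {
      sdlog <- sqrt(log(1 + (sd_kb / mean_kb)^2))
      meanlog <- log(mean_kb) - sdlog^2 / 2
      stats::dlnorm(kb, meanlog, sdlog)
    },
    normal = stats::dnorm(kb, mean_kb, sd_kb)
  )
  molecules <- dens * w
  stop_if(sum(molecules) <= 0, "distribution has no mass inside kb_range")
  molecules <- molecules / sum(molecules)
  out <- data.frame(kb = kb, molecules = molecules)
  attr(out, "number_mean_kb") <- sum(kb * molecules) / sum(molecules)
  out
}

#' Lane profile container
#'
#' @param positions migration positions, pixels, strictly increasing.
#' @param od optical density at each position.
#' @param metadata named list (sample id, tissue, replicate, membrane, ...).
#' @return object of class `lane_profile`: list with `positions`, `od`,
#'   `metadata`.
#' @export
lane_profile <- function(positions, od, metadata = list()) {
  stop_if(length(positions) != length(od), "positions and od must have equal length")
  stop_if(length(positions) < 100, "a lane profile needs >= 100 points")
  stop_if(any(diff(positions) <= 0), "positions must be strictly increasing")
  structure(list(positions = as.numeric(positions), od = as.numeric(od),
                 metadata = metadata),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile> %d points, positions %.1f-%.1f px, total OD %.3g\n",
              length(x$positions), min(x$positions), max(x$positions), sum(x$od)))
  if (length(x$metadata)) {
    cat("  ", paste(names(x$metadata),
                    vapply(x$metadata, function(v) paste(format(v), collapse = ","),
                           character(1)),
                    sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

## Deposit point masses at fractional pixel indices with linear splitting,
## then convolve with a Gaussian kernel of sd blur_sd (pixels).
deposit_and_blur <- function(mass, distance, px, blur_sd) {
  n <- length(px)
  step <- px[2] - px[1]
  fidx <- (distance - px[1]) / step + 1
  lo <- floor(fidx)
  frac <- fidx - lo
  sig <- numeric(n)
  ok_lo <- lo >= 1 & lo <= n
  ok_hi <- (lo + 1) >= 1 & (lo + 1) <= n
  sig_lo <- tapply(mass[ok_lo] * (1 - frac[ok_lo]), lo[ok_lo], sum)
  sig[as.integer(names(sig_lo))] <- sig[as.integer(names(sig_lo))] + sig_lo
  sig_hi <- tapply(mass[ok_hi] * frac[ok_hi], lo[ok_hi] + 1, sum)
  sig[as.integer(names(sig_hi))] <- sig[as.integer(names(sig_hi))] + sig_hi
  if (blur_sd > 0) {
    sd_steps <- blur_sd / step
    half <- max(1L, ceiling(5 * sd_steps))
    kern <- stats::dnorm(seq(-half, half), sd = sd_steps)
    kern <- kern / sum(kern)
    sig <- stats::convolve(c(numeric(half), sig, numeric(half)), rev(kern),
                           type = "filter")
  }
  sig
}

#' Simulate a Southern-blot lane profile from a TRF distribution
#'
#' Each fragment-size atom m with molecule count n contributes OD mass
#' proportional to n * m (mass-proportional signal) at migration distance
#' (m / A)^(1/B).  The deposited signal is convolved with Gaussian blur,
#' scaled to the configured total OD mass, and overlaid with background and
#' pixel noise.  The realised molecule-number mean of the deposited atoms is
#' recorded in the profile metadata as `true_mean_kb` for round-trip
#' validation.
#'
#' @param trf data.frame with columns `kb`, `molecules` (e.g. from
#'   [trf_mixture()]).
#' @param gel a [gel_config()].
#' @param metadata named list stored on the profile.
#' @param seed optional seed for the pixel noise.
#' @return a [lane_profile()].
#' @examples
#' gel <- gel_config(blur_sd = 0, background_level = 0, noise_sd = 0)
#' p <- simulate_lane_profile(data.frame(kb = 7, molecules = 1), gel)
#' p$positions[which.max(p$od)]
#' migration_distance(7, gel)
#' @export
simulate_lane_profile <- function(trf, gel = gel_config(), metadata = list(),
                                  seed = NULL) {
  stopifnot(is.data.frame(trf), all(c("kb", "molecules") %in% names(trf)))
  stop_if(any(trf$kb <= 0) || any(trf$molecules < 0), "invalid TRF atoms")
  keep <- trf$molecules > 0
  trf <- trf[keep, , drop = FALSE]
  stop_if(nrow(trf) == 0, "TRF distribution has no mass")
  d <- migration_distance(trf$kb, gel)
  rng <- gel$pixel_range
  if (any(d < rng[1] | d > rng[2])) {
    bad <- range(trf$kb[d < rng[1] | d > rng[2]])
    stop(sprintf(paste0("TRF mass at %.2f-%.2f kb migrates outside the ",
                        "representable pixel range [%g, %g]"),
                 bad[1], bad[2], rng[1], rng[2]), call. = FALSE)
  }
  px <- seq(rng[1], rng[2], length.out = gel$n_pixels)
  mass <- trf$kb * trf$molecules
  sig <- deposit_and_blur(mass, d, px, gel$blur_sd)
  if (sum(sig) > 0) sig <- sig * gel$od_mass / sum(sig)
  od <- with_seed(seed, sig + gel$background_level +
                    stats::rnorm(length(sig), 0, gel$noise_sd))
  od <- pmax(od, 0)
  metadata$true_mean_kb <- sum(trf$kb * trf$molecules) / sum(trf$molecules)
  lane_profile(px, od, metadata)
}

#' Simulate a molecular-weight ladder lane
#'
#' Places bands of known size at the positions implied by the gel's power
#' law, with optional positional jitter emulating band-calling error.
#'
#' @param known_mws band sizes, kb; at least 3, all distinct.
#' @param gel a [gel_config()].
#' @param jitter_sd positional jitter SD, pixels.
#' @param seed optional seed for the jitter.
#' @return data.frame with columns `distance_px`, `kb`, sorted by distance.
#' @export
simulate_ladder <- function(known_mws, gel = gel_config(), jitter_sd = 0,
                            seed = NULL) {
  stop_if(length(known_mws) < 3, "need at least 3 ladder bands")
  stop_if(anyDuplicated(known_mws) > 0, "duplicate ladder molecular weights")
  stop_if(any(known_mws <= 0), "ladder sizes must be positive")
  d <- migration_distance(known_mws, gel)
  d <- with_seed(seed, d + stats::rnorm(length(d), 0, jitter_sd))
  out <- data.frame(distance_px = d, kb = known_mws)
  out[order(out$distance_px), , drop = FALSE]
}

#' Default ladder band sizes
#'
#' Band sizes (kb) spanning the telomere-relevant 2-25 kb range.
#' @return numeric vector of kb sizes.
#' @export
default_ladder_kb <- function() c(25, 20, 15, 12, 10, 8, 6, 5, 4, 3, 2)
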