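## Shared fixture builders for the telodyn test suite.

## Noise-free gel for exactness tests.
clean_gel <- function(...) {
  gel_config(blur_sd = 0, background_level = 0, noise_sd = 0, ...)
}

## Calibration fitted on noiseless ladder bands of the given gel.
exact_calibration <- function(gel) {
  fit_ladder_calibration(simulate_ladder(default_ladder_kb(), gel))
}

## Smallest closed kb window covering the given coverage of a discretised
## TRF mixture's molecule mass.
support_window <- function(trf, cover = 0.9999) {
  cum <- cumsum(trf$molecules) / sum(trf$molecules)
  c(trf$kb[max(1, findInterval(1 - cover, cum))],
    trf$kb[min(length(cum), findInterval(cover, cum) + 1)])
}

## Lane profile whose OD is nonzero exactly at the lane positions of the
## given kb values (so mean TRF can be hand-computed), under a gel's
## migration law.
spike_profile <- function(kb, od, gel, metadata = list()) {
  d <- migration_distance(kb, gel)
  filler <- seq(min(d) * 0.5, max(d) * 1.5, length.out = 198)
  filler <- setdiff(filler, d)
  pos <- sort(c(filler, d))
  dens <- numeric(length(pos))
  dens[match(d, pos)] <- od
  lane_profile(pos, dens, metadata = metadata)
}

## Small deterministic cohort table for dynamics hand checks.
toy_cohort <- function() {
  data.frame(id = sprintf("T%02d", 1:8),
             age_years = c(40, 50, 60, 70, 45, 55, 65, 75),
             sex = rep(c("M", "F"), each = 4),
             ltl_kb = c(7.0, 6.7, 6.4, 6.1, 7.2, 6.9, 6.6, 6.3),
             mtl_kb = c(8.6, 8.5, 8.4, 8.3, 8.8, 8.7, 8.6, 8.5),
             stringsAsFactors = FALSE)
}

## trf_result with given value and metadata, bypassing a full profile.
toy_trf_result <- function(value, sample_id = "S1", tissue = "L",
                           replicate = 1) {
  structure(list(mean_trf = value, window = c(3, 20),
                 fraction_od_in_window = 1, calibration_used = "cal",
                 qc_flags = character(),
                 metadata = list(sample_id = sample_id, tissue = tissue,
                                 replicate = replicate)),
            class = "trf_result")
}
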