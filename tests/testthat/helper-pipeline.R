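# Shared end-to-end fixtures, computed once per test run and cached.
# The main cohort reflects the study conditions the pipeline targets:
# heterogeneous person intercepts, a positive exposure-outcome link, all
# four prevalence-trajectory classes represented, injected GPS errors,
# and possible dropout.

.fixture_cache <- new.env(parent = emptyenv())

pipeline_fixture <- function() {
  if (!is.null(.fixture_cache$main)) return(.fixture_cache$main)
  ss <- surface_spec(grid_shape = c(60, 60), n_parcels = 120, seed = 2024)
  cs <- cohort_spec(n_participants = 12, weeks = 8, seed = 77)
  study <- simulate_study(ss, cs)
  pre <- preprocess_gps(study$gps)
  samples <- sample_exposure(study$surface, pre$gps_clean)
  bins <- forward_fill(bin_exposure(samples, pre$gps_clean))
  instances <- build_instances(bins, study$ema, study$profiles, "heroin")
  predictions <- run_cohort_protocol(instances, forest_spec(seed = 7))
  .fixture_cache$main <- list(
    surface_spec = ss, cohort_spec = cs, study = study,
    preprocess = pre, samples = samples, bins = bins,
    instances = instances, predictions = predictions,
    summaries = summarize_runs(predictions)
  )
  .fixture_cache$main
}

# Null-calibration cohort: no exposure effect, no person heterogeneity,
# one trajectory class - participants are exchangeable, so no classifier
# can beat the majority-class rate.
null_fixture <- function() {
  if (!is.null(.fixture_cache$null)) return(.fixture_cache$null)
  ss <- surface_spec(grid_shape = c(60, 60), n_parcels = 120, seed = 2024)
  cs <- cohort_spec(
    n_participants = 8, weeks = 3, seed = 78,
    exposure_effect = c(heroin = 0, cocaine = 0, stress = 0),
    intercept_sd = 0, dropout_hazard = 0,
    cluster_mix = c("low" = 1, "medium-decreasing" = 0,
                    "medium-increasing" = 0, "high" = 0))
  study <- simulate_study(ss, cs)
  pre <- preprocess_gps(study$gps)
  bins <- forward_fill(bin_exposure(
    sample_exposure(study$surface, pre$gps_clean), pre$gps_clean))
  instances <- build_instances(bins, study$ema, study$profiles, "heroin")
  predictions <- run_cohort_protocol(instances, forest_spec(seed = 9),
                                     runs = 0L)
  .fixture_cache$null <- list(study = study, instances = instances,
                              summaries = summarize_runs(predictions))
  .fixture_cache$null
}

# A small cohort for cheap integration tests.
small_study <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  ss <- surface_spec(grid_shape = c(40, 40), n_parcels = 60, seed = 5)
  cs <- cohort_spec(n_participants = 4, weeks = 2, seed = 6,
                    dropout_hazard = 0)
  .fixture_cache$small <- simulate_study(ss, cs)
  .fixture_cache$small
}
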