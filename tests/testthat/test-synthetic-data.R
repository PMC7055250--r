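test_that("surface generation is deterministic and honors road_fraction = 0", {
  sp <- surface_spec(grid_shape = c(20, 20), n_parcels = 25,
                     road_fraction = 0, seed = 10)
  a <- generate_surface(sp)
  b <- generate_surface(sp)
  expect_identical(a$values, b$values)
  expect_identical(a$categories, b$categories)
  expect_false(any(a$road_mask))
  expect_false(anyNA(a$values))   # wall-to-wall coverage without roads
})

test_that("invalid surface specs are rejected", {
  expect_error(surface_spec(grid_shape = c(0, 10)), "grid_shape")
  expect_error(surface_spec(n_parcels = 0), "n_parcels")
  expect_error(surface_spec(road_fraction = 1), "road_fraction")
})

test_that("a positive poverty gradient shows up as an east-west value trend", {
  sp <- surface_spec(grid_shape = c(30, 30), n_parcels = 200,
                     road_fraction = 0, poverty_gradient = 2, seed = 12)
  surf <- generate_surface(sp)
  # brute-force correlation over all pixels
  px <- expand.grid(i = 1:30, j = 1:30)
  lv <- log(surf$values[cbind(px$i, px$j)])
  expect_gt(cor(px$j, lv), 0.2)
})

test_that("a stationary participant logs fixes exactly 15 minutes apart", {
  ss <- surface_spec(grid_shape = c(20, 20), n_parcels = 10, seed = 1)
  surf <- fill_roads_idw(generate_surface(ss))
  cs <- cohort_spec(n_participants = 1, weeks = 1, seed = 2,
                    gps_error_rate = 0, dropout_hazard = 0,
                    trips_per_day_range = c(0L, 0L), gps_jitter_sd = 0)
  truth <- generate_truth(cs, surf)
  gps <- generate_tracks(surf, cs, truth)$gps
  expect_true(all(diff(as.numeric(gps$timestamp)) == 900))
})

test_that("error-free tracks never imply an implausible speed", {
  ss <- surface_spec(grid_shape = c(30, 30), n_parcels = 40, seed = 3)
  surf <- fill_roads_idw(generate_surface(ss))
  cs <- cohort_spec(n_participants = 2, weeks = 1, seed = 4,
                    gps_error_rate = 0, dropout_hazard = 0)
  truth <- generate_truth(cs, surf)
  gps <- generate_tracks(surf, cs, truth)$gps
  for (id in unique(gps$participant_id)) {
    tr <- gps[gps$participant_id == id, ]
    expect_true(all(diff(as.numeric(tr$timestamp)) > 0))
    sp <- gmapredict:::adjacent_speeds(tr)     # exhaustive pairwise scan
    expect_lt(max(sp), 31.3)
  }
})

test_that("injected error counts follow the configured rate", {
  ss <- surface_spec(grid_shape = c(30, 30), n_parcels = 40, seed = 3)
  surf <- fill_roads_idw(generate_surface(ss))
  cs <- cohort_spec(n_participants = 2, weeks = 2, seed = 8,
                    gps_error_rate = 0.02, dropout_hazard = 0)
  truth <- generate_truth(cs, surf)
  tracks <- generate_tracks(surf, cs, truth)
  n_fix <- nrow(tracks$gps)
  n_err <- nrow(tracks$error_log)
  # seed-fixed binomial count, checked against a wide binomial band
  expect_gt(n_err, qbinom(0.0005, n_fix, 0.02))
  expect_lt(n_err, qbinom(0.9995, n_fix, 0.02))
  # the same spec and seed reproduce the same injections
  tracks2 <- generate_tracks(surf, cs, truth)
  expect_identical(tracks$error_log, tracks2$error_log)
  expect_identical(tracks$gps, tracks2$gps)
})

test_that("anchors outside the region are rejected", {
  ss <- surface_spec(grid_shape = c(10, 10), n_parcels = 5, seed = 1)
  surf <- fill_roads_idw(generate_surface(ss))
  cs <- cohort_spec(n_participants = 1, weeks = 1, seed = 2)
  truth <- generate_truth(cs, surf)
  truth$anchors[[1]][1, 1] <- 1e6
  expect_error(generate_tracks(surf, cs, truth), "inside the surface region")
})

test_that("EMA positivity tracks the configured logistic intercept", {
  # no exposure effect, no heterogeneity, no extra noise: positivity of the
  # medium-increasing class at week 0 must equal plogis(qlogis(0.10)) = 0.10
  cs <- cohort_spec(n_participants = 240, weeks = 1, seed = 31,
                    exposure_effect = c(heroin = 0, cocaine = 0, stress = 0),
                    intercept_sd = 0, noise_sd = 0, dropout_hazard = 0,
                    outcome_offsets = c(heroin = 0, cocaine = 0, stress = 0),
                    cluster_mix = c("low" = 0, "medium-decreasing" = 0,
                                    "medium-increasing" = 1, "high" = 0))
  truth <- data.frame(participant_id = sprintf("P%03d", 1:240),
                      true_cluster = "medium-increasing",
                      latent_intercept = 0, dropout_week = NA_integer_,
                      slope_heroin = 0, slope_cocaine = 0, slope_stress = 0,
                      stringsAsFactors = FALSE)
  ema <- generate_ema(cs, truth)
  n <- nrow(ema)
  expect_gte(n, 5000)
  frac <- mean(ema$heroin >= 2)
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  expect_true(all(ema$heroin %in% 1:5))
  expect_true(all(ema$cocaine %in% 1:5))
  expect_true(all(ema$stress %in% 1:5))
})

test_that("three daily prompts fall in the waking window with 30-min spacing", {
  cs <- cohort_spec(n_participants = 3, weeks = 1, seed = 5,
                    dropout_hazard = 0)
  truth <- data.frame(participant_id = c("A", "B", "C"),
                      true_cluster = "low", latent_intercept = 0,
                      dropout_week = NA_integer_, slope_heroin = 0,
                      slope_cocaine = 0, slope_stress = 0,
                      stringsAsFactors = FALSE)
  ema <- generate_ema(cs, truth)
  hrs <- as.numeric(format(ema$timestamp, "%H", tz = "UTC")) +
    as.numeric(format(ema$timestamp, "%M", tz = "UTC")) / 60
  expect_true(all(hrs >= 9 & hrs <= 21.01))
  day <- format(ema$timestamp, "%Y-%m-%d")
  for (k in split(seq_len(nrow(ema)), paste(ema$participant_id, day))) {
    expect_equal(length(k), 3)
    expect_true(all(diff(sort(as.numeric(ema$timestamp[k]))) >= 1800))
  }
})

test_that("the medium-increasing class rises from week 0 to week 15", {
  cs <- cohort_spec(n_participants = 50, weeks = 16, seed = 41,
                    exposure_effect = c(heroin = 0, cocaine = 0, stress = 0),
                    intercept_sd = 0.2, dropout_hazard = 0,
                    cluster_mix = c("low" = 0, "medium-decreasing" = 0,
                                    "medium-increasing" = 1, "high" = 0))
  set.seed(41)
  truth <- data.frame(participant_id = sprintf("P%03d", 1:50),
                      true_cluster = "medium-increasing",
                      latent_intercept = rnorm(50, 0, 0.2),
                      dropout_week = NA_integer_, slope_heroin = 0,
                      slope_cocaine = 0, slope_stress = 0,
                      stringsAsFactors = FALSE)
  ema <- generate_ema(cs, truth)
  wk <- ema$study_week
  # brute-force weekly means of the dichotomized outcome
  w0 <- mean(ema$heroin[wk == 0] >= 2)
  w15 <- mean(ema$heroin[wk == 15] >= 2)
  expect_gt(w15, w0)
})

test_that("dropout truncates EMA and GPS after the dropout week", {
  ss <- surface_spec(grid_shape = c(20, 20), n_parcels = 10, seed = 1)
  surf <- fill_roads_idw(generate_surface(ss))
  cs <- cohort_spec(n_participants = 10, weeks = 8, seed = 13,
                    dropout_hazard = 0.5)
  truth <- generate_truth(cs, surf)
  expect_true(any(!is.na(truth$dropout_week)))
  ema <- generate_ema(cs, truth)
  for (p in which(!is.na(truth$dropout_week))) {
    id <- truth$participant_id[p]
    expect_lt(max(ema$study_week[ema$participant_id == id]),
              truth$dropout_week[p])
  }
})

test_that("a full simulated study is reproducible and writes valid files", {
  study <- small_study()
  study2 <- simulate_study(surface_spec(grid_shape = c(40, 40),
                                        n_parcels = 60, seed = 5),
                           cohort_spec(n_participants = 4, weeks = 2,
                                       seed = 6, dropout_hazard = 0))
  expect_identical(study$gps, study2$gps)
  expect_identical(study$ema, study2$ema)
  expect_identical(study$profiles, study2$profiles)

  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir, c("gps.csv", "ema.csv",
                                               "profiles.csv", "truth.json",
                                               "surface/values.csv")))))
  gps <- read.csv(file.path(dir, "gps.csv"))
  expect_named(gps, c("participant_id", "timestamp", "x_m", "y_m",
                      "nsat", "hdop", "pdop"))
  ema <- read.csv(file.path(dir, "ema.csv"))
  expect_true(all(unlist(ema[c("heroin", "cocaine", "stress")]) %in% 1:5))
})
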