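#' Specify a synthetic GMA cohort
#'
#' A `cohort_spec` fixes the study conditions for the synthetic-data
#' generator: cohort size, follow-up length (up to 16 weeks), the
#' 3-random-prompts-per-day EMA schedule inside a waking window, the mix of
#' prevalence-trajectory classes, the strength of the exposure-outcome
#' link, person-level heterogeneity, GPS error injection, and dropout.
#'
#' @param n_participants cohort size.
#' @param weeks follow-up weeks per participant (1..16).
#' @param prompts_per_day random EMA prompts per day (default 3).
#' @param waking_window clock-hour interval of typical waking hours,
#'   default `c(9, 21)` (09:00-21:00).
#' @param cluster_mix probabilities over the four prevalence-trajectory
#'   classes `low`, `medium-decreasing`, `medium-increasing`, `high`
#'   (must sum to 1).
#' @param exposure_effect named per-outcome coefficients linking the past
#'   5-h exposure index (centered mean log10 tax value) to outcome
#'   log-odds.
#' @param intercept_sd SD of the person-level latent intercept (log-odds).
#' @param noise_sd SD of the person-day Gaussian noise on the latent
#'   log-odds.
#' @param outcome_offsets named log-odds offsets shifting the shared
#'   trajectory per outcome (cocaine craving rarer than heroin craving,
#'   stress more common).
#' @param dropout_hazard weekly probability of leaving the study after a
#'   failed completion week (applied from week 1 on).
#' @param gps_error_rate fraction of GPS fixes replaced by signal errors
#'   (teleport outliers or degraded-QA points).
#' @param trips_per_day_range integer range of anchor-to-anchor trips per
#'   day during waking hours.
#' @param gps_jitter_sd SD (m) of stationary GPS jitter.
#' @param start_date study start date (UTC midnight), ISO string.
#' @param seed RNG seed.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 12L,
                        weeks = 8L,
                        prompts_per_day = 3L,
                        waking_window = c(9, 21),
                        cluster_mix = c("low" = 0.45,
                                        "medium-decreasing" = 0.20,
                                        "medium-increasing" = 0.15,
                                        "high" = 0.20),
                        exposure_effect = c(heroin = 0.5, cocaine = 0.5,
                                            stress = 0.5),
                        intercept_sd = 0.8,
                        noise_sd = 0.5,
                        outcome_offsets = c(heroin = 0, cocaine = -0.7,
                                            stress = 0.9),
                        dropout_hazard = 0.02,
                        gps_error_rate = 0.01,
                        trips_per_day_range = c(2L, 4L),
                        gps_jitter_sd = 2,
                        start_date = "2020-01-06",
                        seed = 1L) {
  abort_if(n_participants < 1, "n_participants must be positive")
  abort_if(weeks < 1 || weeks > 16, "weeks must be in 1..16")
  abort_if(prompts_per_day != 3L,
           "the EMA schedule is three random prompts per day")
  abort_if(abs(sum(cluster_mix) - 1) > 1e-8, "cluster_mix must sum to 1")
  abort_if(!setequal(names(cluster_mix), trajectory_classes()),
           "cluster_mix must be named by the four trajectory classes")
  abort_if(waking_window[1] >= waking_window[2],
           "waking_window must be an increasing clock interval")
  structure(list(
    n_participants = as.integer(n_participants),
    weeks = as.integer(weeks),
    prompts_per_day = as.integer(prompts_per_day),
    waking_window = waking_window,
    cluster_mix = cluster_mix[trajectory_classes()],
    exposure_effect = exposure_effect,
    intercept_sd = intercept_sd,
    noise_sd = noise_sd,
    outcome_offsets = outcome_offsets,
    dropout_hazard = dropout_hazard,
    gps_error_rate = gps_error_rate,
    trips_per_day_range = as.integer(trips_per_day_range),
    gps_jitter_sd = gps_jitter_sd,
    start_date = start_date,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' The four prevalence-trajectory classes
#'
#' @return Character vector of class labels in their conventional order.
#' @export
trajectory_classes <- function() {
  c("low", "medium-decreasing", "medium-increasing", "high")
}

#' Latent prevalence trajectory of a class
#'
#' Class-level weekly prevalence on the log-odds scale, evaluated at week
#' `w` (0-based). The low and high classes are flat at 5% and 55%; the two
#' medium classes move linearly between 10% and 30% over a 16-week course.
#'
#' @param cluster one of [trajectory_classes()].
#' @param week 0-based week index (vectorized).
#' @return Log-odds of outcome positivity attributable to the class.
#' @export
cluster_trajectory_logit <- function(cluster, week) {
  f <- pmin(week, 15) / 15
  switch(cluster,
    "low" = rep(stats::qlogis(0.05), length(week)),
    "medium-decreasing" =
      stats::qlogis(0.30) + (stats::qlogis(0.10) - stats::qlogis(0.30)) * f,
    "medium-increasing" =
      stats::qlogis(0.10) + (stats::qlogis(0.30) - stats::qlogis(0.10)) * f,
    "high" = rep(stats::qlogis(0.55), length(week)),
    stop("unknown trajectory class: ", cluster)
  )
}

#' Draw per-participant ground truth
#'
#' Samples each participant's latent trajectory class, person-level
#' intercept, exposure slopes, dropout week, and home/anchor locations
#' inside the surface region. The result is the generator's truth log:
#' tests may read it, the analysis pipeline never does.
#'
#' @param cohort a [cohort_spec()].
#' @param surface an `exposure_surface` delimiting the region.
#' @return data.frame with one row per participant plus an `anchors`
#'   list-column of planar coordinates (first row is home).
#' @export
generate_truth <- function(cohort, surface) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(surface, "exposure_surface"))
  set.seed(derive_seed(cohort$seed, 101))
  n <- cohort$n_participants
  cluster <- sample(trajectory_classes(), n, replace = TRUE,
                    prob = cohort$cluster_mix)
  intercept <- stats::rnorm(n, 0, cohort$intercept_sd)
  dropout <- rep(NA_integer_, n)
  for (p in seq_len(n)) {
    for (w in seq_len(cohort$weeks - 1)) {
      if (stats::runif(1) < cohort$dropout_hazard) { dropout[p] <- w; break }
    }
  }
  ext_x <- ncol(surface$values) * surface$pixel_size
  ext_y <- nrow(surface$values) * surface$pixel_size
  margin <- min(100, ext_x / 4, ext_y / 4)
  anchors <- lapply(seq_len(n), function(p) {
    k <- sample(2:4, 1)            # anchors in addition to home
    cbind(
      x = surface$origin[1] + stats::runif(k + 1, margin, ext_x - margin),
      y = surface$origin[2] + stats::runif(k + 1, margin, ext_y - margin))
  })
  out <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    true_cluster = cluster,
    latent_intercept = intercept,
    dropout_week = dropout,
    stringsAsFactors = FALSE
  )
  for (oc in names(cohort$exposure_effect)) {
    out[[paste0("slope_", oc)]] <- cohort$exposure_effect[[oc]]
  }
  out$anchors <- anchors
  out
}

# Number of observed days for a participant (dropout truncates whole weeks).
observed_days <- function(cohort, dropout_week) {
  w <- if (is.na(dropout_week)) cohort$weeks else dropout_week
  w * 7L
}

#' Generate synthetic GPS tracks
#'
#' Each participant follows a daily routine among their anchor locations:
#' stationary dwells (with small positional jitter) separated by straight
#' walks at pedestrian speed. Fixes are emitted per the device logging
#' rule - every 20 m of displacement while moving, or every 15 min while
#' stationary, whichever comes first. A fraction `gps_error_rate` of fixes
#' is turned into signal errors: teleport outliers (position displaced
#' tens of km, clean QA fields) or degraded-QA points (position kept, HDOP/
#' PDOP/satellite count pushed past plausible QA thresholds). Injected
#' errors are recorded in the returned error log.
#'
#' @param surface an `exposure_surface` delimiting the region.
#' @param cohort a [cohort_spec()].
#' @param truth the truth table from [generate_truth()].
#' @return list with `gps` (data.frame: `participant_id`, `timestamp`,
#'   `x_m`, `y_m`, `nsat`, `hdop`, `pdop`) and `error_log` (data.frame of
#'   injected errors with true coordinates).
#' @export
generate_tracks <- function(surface, cohort, truth) {
  stopifnot(inherits(surface, "exposure_surface"))
  ext_x <- ncol(surface$values) * surface$pixel_size
  ext_y <- nrow(surface$values) * surface$pixel_size
  for (p in seq_len(nrow(truth))) {
    a <- truth$anchors[[p]]
    abort_if(any(a[, 1] < surface$origin[1] | a[, 1] > surface$origin[1] + ext_x |
                 a[, 2] < surface$origin[2] | a[, 2] > surface$origin[2] + ext_y),
             "anchor locations must lie inside the surface region")
  }
  t0 <- as.POSIXct(paste0(cohort$start_date, " 00:00:00"), tz = "UTC")
  wake <- cohort$waking_window * 3600
  day_len <- 86400

  all_gps <- vector("list", nrow(truth))
  all_err <- vector("list", nrow(truth))
  for (p in seq_len(nrow(truth))) {
    set.seed(derive_seed(cohort$seed, 200 + p))
    anchors <- truth$anchors[[p]]
    n_days <- observed_days(cohort, truth$dropout_week[p])
    cur <- 1L                                  # start at home
    fixes <- vector("list", n_days)
    for (d in seq_len(n_days) - 1L) {
      day0 <- d * day_len
      n_trips <- if (cohort$trips_per_day_range[2] == 0) 0L else
        sample(cohort$trips_per_day_range[1]:cohort$trips_per_day_range[2], 1)
      trip_starts <- sort(stats::runif(n_trips, wake[1], wake[2] - 1800))
      times <- numeric(0); xs <- numeric(0); ys <- numeric(0)
      seg_start <- 0
      pos <- anchors[cur, ]
      emit_dwell <- function(from, to, at) {
        if (to - from < 900) return(NULL)
        tt <- seq(from + 900, to, by = 900)
        cbind(tt, at[1] + stats::rnorm(length(tt), 0, cohort$gps_jitter_sd),
              at[2] + stats::rnorm(length(tt), 0, cohort$gps_jitter_sd))
      }
      for (tr in seq_len(n_trips)) {
        # a trip cannot start before the previous walk has arrived
        start_t <- max(trip_starts[tr], seg_start)
        dw <- emit_dwell(seg_start, start_t, pos)
        if (!is.null(dw)) {
          times <- c(times, dw[, 1]); xs <- c(xs, dw[, 2]); ys <- c(ys, dw[, 3])
        }
        dest <- if (nrow(anchors) > 1)
          sample(setdiff(seq_len(nrow(anchors)), cur), 1) else cur
        q <- anchors[dest, ]
        dist <- sqrt(sum((q - pos)^2))
        speed <- stats::runif(1, 1.0, 1.6)
        n_fix <- floor(dist / 20)
        if (n_fix > 0) {
          fr <- (seq_len(n_fix) * 20) / dist
          tt <- start_t + (seq_len(n_fix) * 20) / speed
          xs <- c(xs, pos[1] + fr * (q[1] - pos[1]) + stats::rnorm(n_fix, 0, 3))
          ys <- c(ys, pos[2] + fr * (q[2] - pos[2]) + stats::rnorm(n_fix, 0, 3))
          times <- c(times, tt)
        }
        seg_start <- start_t + dist / speed
        pos <- q; cur <- dest
      }
      dw <- emit_dwell(seg_start, day_len, pos)
      if (!is.null(dw)) {
        times <- c(times, dw[, 1]); xs <- c(xs, dw[, 2]); ys <- c(ys, dw[, 3])
      }
      ord <- order(times)
      keep <- !duplicated(round(times[ord]))
      fixes[[d + 1L]] <- cbind(day0 + round(times[ord])[keep],
                               xs[ord][keep], ys[ord][keep])
    }
    f <- do.call(rbind, fixes)
    n_fix <- nrow(f)
    gps <- data.frame(
      participant_id = truth$participant_id[p],
      timestamp = t0 + f[, 1],
      x_m = f[, 2], y_m = f[, 3],
      nsat = sample(6:12, n_fix, replace = TRUE),
      hdop = round(stats::runif(n_fix, 0.6, 2.5), 2),
      pdop = round(stats::runif(n_fix, 1.0, 4.0), 2),
      stringsAsFactors = FALSE
    )
    err_idx <- which(stats::runif(n_fix) < cohort$gps_error_rate)
    err <- NULL
    if (length(err_idx)) {
      kind <- sample(c("teleport", "qa"), length(err_idx), replace = TRUE,
                     prob = c(0.6, 0.4))
      err <- data.frame(
        participant_id = truth$participant_id[p],
        timestamp = gps$timestamp[err_idx],
        kind = kind,
        true_x = gps$x_m[err_idx], true_y = gps$y_m[err_idx],
        stringsAsFactors = FALSE
      )
      tele <- err_idx[kind == "teleport"]
      if (length(tele)) {
        ang <- stats::runif(length(tele), 0, 2 * pi)
        # large enough that even a 15-min fix gap implies >= 31.3 m/s
        rad <- stats::runif(length(tele), 40000, 90000)
        gps$x_m[tele] <- gps$x_m[tele] + rad * cos(ang)
        gps$y_m[tele] <- gps$y_m[tele] + rad * sin(ang)
      }
      qa <- err_idx[kind == "qa"]
      if (length(qa)) {
        gps$nsat[qa] <- sample(0:2, length(qa), replace = TRUE)
        gps$hdop[qa] <- round(stats::runif(length(qa), 8, 20), 2)
        gps$pdop[qa] <- round(stats::runif(length(qa), 10, 25), 2)
      }
    }
    all_gps[[p]] <- gps
    all_err[[p]] <- err
  }
  list(
    gps = do.call(rbind, all_gps),
    error_log = if (all(vapply(all_err, is.null, TRUE))) {
      data.frame(participant_id = character(0), timestamp = t0[0],
                 kind = character(0), true_x = numeric(0), true_y = numeric(0))
    } else do.call(rbind, all_err)
  )
}

#' Generate synthetic EMA responses
#'
#' For each participant-day, draws 3 random prompt times inside the waking
#' window with at least 30 min spacing. For each prompt and outcome the
#' latent log-odds of a positive response is the class trajectory at that
#' study week, plus the person intercept, plus the exposure slope times the
#' past-5-h exposure index at the prompt, plus person-day Gaussian noise;
#' positivity is Bernoulli on the logistic of that value. Positive
#' responses map to ratings 2-5 via fixed thresholds on the latent value,
#' negative responses to rating 1. Dropout truncates a participant's
#' entries after their dropout week.
#'
#' @param cohort a [cohort_spec()].
#' @param truth the truth table from [generate_truth()].
#' @param exposure_series data.frame of binned exposure per participant
#'   (`participant_id`, `bin_start`, `mean_log_value`, `missing`), used to
#'   compute the past-5-h exposure index; `NULL` means no exposure signal
#'   (index 0 everywhere).
#' @param ref_log_value centering constant for the exposure index
#'   (typically the surface-wide mean of log10(value + 1)).
#' @return data.frame of EMA entries: `participant_id`, `timestamp`,
#'   `heroin`, `cocaine`, `stress` (integer ratings 1-5), plus the
#'   generator-truth columns `study_week` and `exposure_index`.
#' @export
generate_ema <- function(cohort, truth, exposure_series = NULL,
                         ref_log_value = 0) {
  stopifnot(inherits(cohort, "cohort_spec"))
  t0 <- as.POSIXct(paste0(cohort$start_date, " 00:00:00"), tz = "UTC")
  wake <- cohort$waking_window * 3600
  outcomes <- names(cohort$outcome_offsets)
  out <- vector("list", nrow(truth))
  for (p in seq_len(nrow(truth))) {
    set.seed(derive_seed(cohort$seed, 500 + p))
    n_days <- observed_days(cohort, truth$dropout_week[p])
    expo <- NULL
    if (!is.null(exposure_series)) {
      expo <- exposure_series[
        exposure_series$participant_id == truth$participant_id[p] &
          !exposure_series$missing, , drop = FALSE]
    }
    rows <- vector("list", n_days)
    for (d in seq_len(n_days) - 1L) {
      repeat {
        pt <- sort(round(stats::runif(cohort$prompts_per_day,
                                      wake[1], wake[2])))
        if (all(diff(pt) >= 1800)) break
      }
      ts <- t0 + d * 86400 + pt
      week <- d %/% 7L
      idx <- vapply(ts, function(tt) {
        if (is.null(expo) || !nrow(expo)) return(0)
        b <- floor_bin(tt)
        win <- expo$bin_start >= b - 5 * 3600 & expo$bin_start < b
        if (!any(win)) return(0)
        mean(expo$mean_log_value[win]) - ref_log_value
      }, 0)
      day <- data.frame(participant_id = truth$participant_id[p],
                        timestamp = ts, stringsAsFactors = FALSE)
      for (oc in outcomes) {
        latent <- cluster_trajectory_logit(truth$true_cluster[p],
                                           rep(week, length(ts))) +
          cohort$outcome_offsets[[oc]] +
          truth$latent_intercept[p] +
          truth[[paste0("slope_", oc)]][p] * idx +
          stats::rnorm(length(ts), 0, cohort$noise_sd)
        pos <- stats::runif(length(ts)) < stats::plogis(latent)
        rating <- rep(1L, length(ts))
        if (any(pos)) {
          z <- latent[pos]
          rating[pos] <- pmin(5L, 2L + (z > 0) + (z > 1) + (z > 2))
        }
        day[[oc]] <- rating
      }
      day$study_week <- week
      day$exposure_index <- idx
      rows[[d + 1L]] <- day
    }
    out[[p]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Generate a synthetic person-level profile table
#'
#' One row per participant with the person-level predictors used by the
#' forecasting models: sex, age, race, Hispanic ethnicity, high-school
#' graduation, years of education, marital status, professional training,
#' current employment, days of use of heroin / other opioids / cocaine in
#' the 30 days before enrollment, lifetime years of use of each, and
#' typical route of administration of each. Marginal distributions follow
#' typical opioid-use-disorder treatment cohorts; profiles are sampled
#' independently of the latent outcome process.
#'
#' @param cohort a [cohort_spec()].
#' @param truth the truth table from [generate_truth()].
#' @return data.frame of participant profiles.
#' @export
generate_profiles <- function(cohort, truth) {
  set.seed(derive_seed(cohort$seed, 900))
  n <- nrow(truth)
  tnorm <- function(n, mean, sd, lo, hi) {
    pmin(hi, pmax(lo, round(stats::rnorm(n, mean, sd), 1)))
  }
  data.frame(
    participant_id = truth$participant_id,
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.75, 0.25)),
    age = tnorm(n, 41.5, 9.6, 18, 75),
    race = sample(c("AfAm", "EurAm"), n, TRUE, prob = c(0.65, 0.35)),
    hispanic = sample(c("no", "yes"), n, TRUE, prob = c(0.97, 0.03)),
    hs_grad = sample(c("yes", "no"), n, TRUE, prob = c(0.6, 0.4)),
    years_education = tnorm(n, 12.1, 1.5, 6, 20),
    marital_status = sample(c("never", "married", "sep_div_wid"), n, TRUE,
                            prob = c(0.62, 0.14, 0.24)),
    professional_training = sample(c("any", "none"), n, TRUE,
                                   prob = c(0.3, 0.7)),
    employed = sample(c("any", "none"), n, TRUE, prob = c(0.68, 0.32)),
    days_heroin_30 = tnorm(n, 19.3, 11.9, 0, 30),
    days_opioid_30 = tnorm(n, 8.3, 10.4, 0, 30),
    days_cocaine_30 = tnorm(n, 4.4, 8.4, 0, 30),
    years_heroin = tnorm(n, 14.1, 10.2, 0, 50),
    years_opioid = tnorm(n, 1.5, 2.6, 0, 50),
    years_cocaine = tnorm(n, 5.6, 7.8, 0, 50),
    route_heroin = sample(c("intranasal", "intravenous"), n, TRUE,
                          prob = c(0.61, 0.39)),
    route_opioid = sample(c("oral", "intranasal", "smoking"), n, TRUE,
                          prob = c(0.92, 0.07, 0.01)),
    route_cocaine = sample(c("smoking", "intranasal", "intravenous"), n,
                           TRUE, prob = c(0.54, 0.24, 0.22)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic GMA study
#'
#' Runs the full generator: exposure surface (with inverse-distance road
#' fill), participant truth, GPS tracks with injected signal errors, the
#' exposure series along the error-free track, EMA responses driven by the
#' latent exposure-outcome model, and the profile table.
#'
#' The EMA generator is fed exposure binned from the error-free positions:
#' outcomes respond to where participants actually were, while the emitted
#' GPS includes the measurement errors the preprocessing stage must remove.
#'
#' @param surf_spec a [surface_spec()].
#' @param cohort a [cohort_spec()].
#' @return list with `surface` (road-filled), `truth`, `gps`, `error_log`,
#'   `ema`, `profiles`, and `ref_log_value` (the exposure-index centering
#'   constant).
#' @export
simulate_study <- function(surf_spec, cohort) {
  surface <- fill_roads_idw(generate_surface(surf_spec))
  truth <- generate_truth(cohort, surface)
  tracks <- generate_tracks(surface, cohort, truth)

  # exposure along the error-free track drives the latent outcome model
  gps_true <- tracks$gps
  if (nrow(tracks$error_log)) {
    key <- paste(tracks$error_log$participant_id,
                 format_utc(tracks$error_log$timestamp))
    m <- match(paste(gps_true$participant_id, format_utc(gps_true$timestamp)),
               key)
    hit <- !is.na(m)
    gps_true$x_m[hit] <- tracks$error_log$true_x[m[hit]]
    gps_true$y_m[hit] <- tracks$error_log$true_y[m[hit]]
  }
  samples <- sample_exposure(surface, gps_true)
  bins <- bin_exposure(samples, gps_true)
  bins <- forward_fill(bins)
  ref <- mean(log10(surface$values[!is.na(surface$values)] + 1))
  ema <- generate_ema(cohort, truth, exposure_series = bins,
                      ref_log_value = ref)
  profiles <- generate_profiles(cohort, truth)
  list(surface = surface, truth = truth, gps = tracks$gps,
       error_log = tracks$error_log, ema = ema, profiles = profiles,
       ref_log_value = ref)
}

#' Write a simulated study to disk
#'
#' Emits `gps.csv`, `ema.csv`, `profiles.csv`, the surface files (see
#' [write_surface()]) under `surface/`, and `truth.json` (the generator
#' truth log, for tests only - the analysis pipeline must never read it).
#'
#' @param study result of [simulate_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gps <- study$gps
  gps$timestamp <- format_utc(gps$timestamp)
  utils::write.csv(gps, file.path(dir, "gps.csv"), row.names = FALSE)
  ema <- study$ema[c("participant_id", "timestamp",
                     "heroin", "cocaine", "stress")]
  ema$timestamp <- format_utc(ema$timestamp)
  utils::write.csv(ema, file.path(dir, "ema.csv"), row.names = FALSE)
  utils::write.csv(study$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  write_surface(study$surface, file.path(dir, "surface"))
  truth <- study$truth
  truth$anchors <- lapply(truth$anchors, function(a) unclass(a))
  err <- study$error_log
  err$timestamp <- format_utc(err$timestamp)
  jsonlite::write_json(
    list(truth = truth, error_log = err,
         ref_log_value = study$ref_log_value),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
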