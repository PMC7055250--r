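ts_utc <- function(s) as.POSIXct(s, tz = "UTC")

test_that("dichotomization maps 1 to 0 and 2-5 to 1, rejecting anything else", {
  expect_identical(dichotomize(c(1L, 2L, 3L, 4L, 5L)), c(0L, 1L, 1L, 1L, 1L))
  expect_error(dichotomize(0L), "1..5")
  expect_error(dichotomize(6L), "1..5")
  expect_error(dichotomize(NA_integer_), "1..5")
})

test_that("binning averages log values within clock-aligned 30-min bins", {
  samples <- data.frame(
    participant_id = "P",
    timestamp = ts_utc(c("2020-01-01 10:05:00", "2020-01-01 10:20:00")),
    value = c(999, 99999),
    category = c("a", "a"),
    in_region = TRUE, stringsAsFactors = FALSE)
  bins <- bin_exposure(samples)
  expect_equal(nrow(bins), 1)
  expect_equal(format(bins$bin_start, "%H:%M"), "10:00")
  expect_equal(bins$mean_log_value, 4.0)   # mean of log10 1e3 and 1e5
  expect_equal(bins$prop_a, 1)
})

test_that("bins with no usable sample are missing, including all-out-of-region", {
  samples <- data.frame(
    participant_id = "P",
    timestamp = ts_utc(c("2020-01-01 10:05:00", "2020-01-01 11:10:00")),
    value = c(100, NA),
    category = c("a", NA),
    in_region = c(TRUE, FALSE), stringsAsFactors = FALSE)
  bins <- bin_exposure(samples)
  expect_equal(nrow(bins), 3)              # 10:00, 10:30, 11:00
  expect_identical(bins$missing, c(FALSE, TRUE, TRUE))
  expect_true(is.na(bins$mean_log_value[3]))
})

test_that("bin assignment matches brute-force interval membership", {
  set.seed(9)
  n <- 300
  t0 <- ts_utc("2020-01-01 08:00:00")
  samples <- data.frame(
    participant_id = "P",
    timestamp = t0 + sort(round(runif(n, 0, 6 * 3600))),
    value = runif(n, 10, 1e6),
    category = sample(c("a", "b"), n, TRUE),
    in_region = runif(n) > 0.1, stringsAsFactors = FALSE)
  samples$value[!samples$in_region] <- NA
  samples$category[!samples$in_region] <- NA
  bins <- bin_exposure(samples)
  for (r in seq_len(nrow(bins))) {
    lo <- bins$bin_start[r]; hi <- lo + 1800
    memb <- samples$timestamp >= lo & samples$timestamp < hi
    expect_equal(bins$n_samples[r], sum(memb))
    ok <- memb & samples$in_region
    if (any(ok)) {
      expect_equal(bins$mean_log_value[r],
                   mean(log10(samples$value[ok] + 1)))
      expect_equal(bins$prop_a[r], mean(samples$category[ok] == "a"))
      expect_false(bins$missing[r])
    } else {
      expect_true(bins$missing[r])
    }
  }
})

make_bins <- function(missing_pattern, t0 = ts_utc("2020-01-01 00:00:00")) {
  nb <- length(missing_pattern)
  data.frame(
    participant_id = "P",
    bin_start = t0 + (seq_len(nb) - 1) * 1800,
    mean_log_value = ifelse(missing_pattern, NA, seq_len(nb)),
    prop_a = ifelse(missing_pattern, NA, 1),
    distance_m = ifelse(missing_pattern, NA, 10),
    n_samples = ifelse(missing_pattern, 0L, 2L),
    missing = missing_pattern,
    filled = FALSE, stringsAsFactors = FALSE)
}

test_that("forward fill carries the most recent observed bin within 24 h", {
  bins <- make_bins(c(FALSE, TRUE, TRUE, FALSE, TRUE))
  out <- forward_fill(bins)
  expect_equal(out$mean_log_value, c(1, 1, 1, 4, 4))
  expect_identical(out$filled, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$distance_m[2], 0)       # filled bins carry no movement
  expect_false(any(out$missing))

  # a missing bin with no observed bin in the previous 24 h stays missing
  far <- make_bins(c(FALSE, rep(TRUE, 49)))
  out2 <- forward_fill(far)
  expect_false(any(out2$missing[1:49]))    # within 24 h: filled
  expect_true(out2$missing[50])            # 24.5 h after the observation
})

test_that("forward fill matches an independent scan oracle on 48 bins", {
  set.seed(17)
  pattern <- runif(48) < 0.5
  pattern[1] <- FALSE
  bins <- make_bins(pattern)
  out <- forward_fill(bins)
  # oracle: for each missing bin take the nearest earlier observed bin
  expected <- bins$mean_log_value
  for (r in which(pattern)) {
    prev <- which(!pattern[1:(r - 1)])
    prev <- prev[length(prev)]
    if (length(prev) &&
        (r - prev) * 1800 <= 24 * 3600) expected[r] <- bins$mean_log_value[prev]
  }
  expect_equal(out$mean_log_value, expected)
})

test_that("instances carry 5-h windows, 90-min labels, and no leakage", {
  # one participant, one fully observed day, three prompts
  bins <- make_bins(rep(FALSE, 48))
  bins$mean_log_value <- seq_len(48)
  ema <- data.frame(
    participant_id = "P",
    timestamp = ts_utc(c("2020-01-01 10:15:00", "2020-01-01 14:10:00",
                         "2020-01-01 19:45:00")),
    heroin = c(3L, 1L, 1L), cocaine = c(1L, 1L, 2L), stress = c(1L, 1L, 1L),
    stringsAsFactors = FALSE)
  profiles <- data.frame(participant_id = "P", sex = "male", age = 40,
                         stringsAsFactors = FALSE)
  inst <- build_instances(bins, ema, profiles, "heroin")

  # hand enumeration: anchors are all grid times with an entry in (t, t+90]
  grid <- bins$bin_start[1] + (0:47) * 1800
  expected_anchors <- grid[vapply(grid, function(t)
    any(ema$timestamp > t & ema$timestamp <= t + 5400), TRUE)]
  expect_equal(inst$anchor, expected_anchors)

  # labels: OR of dichotomized heroin over the window
  for (r in seq_len(nrow(inst))) {
    win <- ema$timestamp > inst$anchor[r] & ema$timestamp <= inst$anchor[r] + 5400
    expect_equal(inst$label[r], as.integer(any(ema$heroin[win] >= 2)))
  }

  # the feature window is the 10 bins ending exactly at the anchor
  r <- which(inst$anchor == ts_utc("2020-01-01 09:30:00"))
  expect_equal(inst$bin09_value[r],
               bins$mean_log_value[bins$bin_start == ts_utc("2020-01-01 09:00:00")])
  expect_equal(inst$bin00_value[r],
               bins$mean_log_value[bins$bin_start == ts_utc("2020-01-01 04:30:00")])

  # no leakage: perturbing bins at or after an anchor leaves features alone
  bins2 <- bins
  bins2$mean_log_value[bins2$bin_start >= ts_utc("2020-01-01 09:30:00")] <- 999
  inst2 <- build_instances(bins2, ema, profiles, "heroin")
  feature_cols <- grep("^bin0[0-9]_value$", names(inst), value = TRUE)
  expect_equal(unlist(inst2[r, feature_cols]), unlist(inst[r, feature_cols]))
})

test_that("an entry in any of the next three bins labels the anchor positive", {
  bins <- make_bins(rep(FALSE, 48))
  t0 <- bins$bin_start[1]
  # entries at +1, +2, +3 bins after a 06:00 anchor, dichotomized 0,1,0
  ema <- data.frame(
    participant_id = "P",
    timestamp = t0 + 12 * 1800 + c(900, 2700, 4500),
    heroin = c(1L, 4L, 1L), cocaine = c(1L, 1L, 1L), stress = c(1L, 1L, 1L),
    stringsAsFactors = FALSE)
  profiles <- data.frame(participant_id = "P", age = 35,
                         stringsAsFactors = FALSE)
  inst <- build_instances(bins, ema, profiles, "heroin")
  expect_equal(inst$label[inst$anchor == t0 + 12 * 1800], 1L)
  # cocaine never rises above 1: all labels are 0
  inst_c <- build_instances(bins, ema, profiles, "cocaine")
  expect_true(all(inst_c$label == 0L))
})

test_that("instances with entirely missing feature windows are dropped", {
  bins <- make_bins(c(FALSE, rep(TRUE, 47)))
  bins$missing[2:48] <- TRUE               # nothing to fill from beyond 24 h
  bins$mean_log_value[2:48] <- NA
  # an anchor late in the day has 10 all-missing feature bins
  ema <- data.frame(participant_id = "P",
                    timestamp = bins$bin_start[1] + 40 * 1800 + 900,
                    heroin = 2L, cocaine = 1L, stress = 1L,
                    stringsAsFactors = FALSE)
  profiles <- data.frame(participant_id = "P", age = 35,
                         stringsAsFactors = FALSE)
  expect_error(build_instances(bins, ema, profiles, "heroin"),
               "no prediction instances")
})

test_that("study weeks count whole weeks since the first entry", {
  study <- small_study()
  pre <- preprocess_gps(study$gps)
  bins <- forward_fill(bin_exposure(
    sample_exposure(study$surface, pre$gps_clean), pre$gps_clean))
  inst <- build_instances(bins, study$ema, study$profiles, "heroin")
  expect_true(all(inst$study_week %in% 0:1))
  # label consistency: relabeling from raw ratings reproduces the labels
  for (r in sample(nrow(inst), 25)) {
    id <- inst$participant_id[r]
    e <- study$ema[study$ema$participant_id == id, ]
    win <- e$timestamp > inst$anchor[r] & e$timestamp <= inst$anchor[r] + 5400
    expect_equal(inst$label[r], as.integer(any(dichotomize(e$heroin[win]) == 1)))
  }
})
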