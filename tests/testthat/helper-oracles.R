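# Independent reference implementations used as test oracles. These stay
# deliberately naive (full recomputation, double loops) so they cannot
# share bugs with the package implementations.

# O(n^2) reference speed filter: after every single removal, recompute all
# adjacent speeds from scratch and remove the later member of the first
# offending pair.
reference_speed_filter <- function(track, v_max = 31.3) {
  repeat {
    n <- nrow(track)
    if (n <= 1) return(track)
    dt <- diff(as.numeric(track$timestamp))
    dd <- sqrt(diff(track$x_m)^2 + diff(track$y_m)^2)
    sp <- ifelse(dt > 0, dd / dt, Inf)
    bad <- which(sp >= v_max)
    if (!length(bad)) return(track)
    track <- track[-(bad[1] + 1L), , drop = FALSE]
  }
}

# Brute-force inverse-distance road fill: double loop over all pixel pairs.
reference_idw_fill <- function(surface, max_dist = 50, power = 2) {
  ps <- surface$pixel_size
  rows <- nrow(surface$values); cols <- ncol(surface$values)
  donors <- which(!is.na(surface$values) & !surface$road_mask, arr.ind = TRUE)
  out <- surface
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      if (!surface$road_mask[i, j] || !surface$region_mask[i, j]) next
      dists <- ps * sqrt((donors[, 1] - i)^2 + (donors[, 2] - j)^2)
      sel <- dists <= max_dist & dists > 0
      if (!any(sel)) next
      w <- dists[sel]^(-power)
      v <- surface$values[donors[sel, , drop = FALSE]]
      out$values[i, j] <- sum(w * v) / sum(w)
      near <- which(sel)[which.min(dists[sel])]
      out$categories[i, j] <- surface$categories[donors[near, 1],
                                                 donors[near, 2]]
    }
  }
  out
}

# Random walk track with optional teleport outliers, for filter testing.
random_walk_track <- function(n, n_teleports = 0, speed = 1.5,
                              dt_range = c(10, 60), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- round(runif(n - 1, dt_range[1], dt_range[2]))
  tt <- cumsum(c(0, dt))
  ang <- runif(n - 1, 0, 2 * pi)
  step <- speed * dt
  x <- cumsum(c(0, step * cos(ang)))
  y <- cumsum(c(0, step * sin(ang)))
  if (n_teleports > 0) {
    at <- sample(2:n, n_teleports)
    x[at] <- x[at] + runif(n_teleports, 5e4, 2e5)
    y[at] <- y[at] + runif(n_teleports, 5e4, 2e5)
  }
  data.frame(
    participant_id = "T001",
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + tt,
    x_m = x, y_m = y,
    nsat = 8L, hdop = 1.0, pdop = 1.5,
    stringsAsFactors = FALSE
  )
}

# Weekly prevalence trajectories drawn around known class curves, for
# latent-class recovery tests.
sim_series <- function(n_per_class, fns, sd = 0.03, weeks = 0:15,
                       seed = 1) {
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (c in seq_along(fns)) {
    for (i in seq_len(n_per_class)) {
      pid <- pid + 1
      rows[[pid]] <- data.frame(
        participant_id = sprintf("S%03d", pid),
        week = weeks,
        value = fns[[c]](weeks) + rnorm(length(weeks), 0, sd),
        truth = names(fns)[c],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# A tiny fake instance table with controllable weeks and labels, for
# protocol-membership tests that do not need real features.
fake_instances <- function(participants, weeks_per, seed = 1) {
  set.seed(seed)
  rows <- list()
  t0 <- as.POSIXct("2020-01-06", tz = "UTC")
  for (p in seq_along(participants)) {
    for (w in 0:(weeks_per[p] - 1)) {
      for (r in 1:6) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = participants[p],
          anchor = t0 + w * 7 * 86400 + r * 3600,
          study_week = w,
          label = rbinom(1, 1, 0.4),
          f1 = rnorm(1), f2 = rnorm(1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
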