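#' QA thresholds for GPS cleaning
#'
#' Signal-quality thresholds for dropping individual fixes (satellite
#' count, HDOP, PDOP) plus the implausible-velocity threshold used by the
#' iterative speed filter. The speed threshold is 31.3 m/s; a land-based
#' participant cannot move that fast, so any adjacent pair implying it
#' marks a signal error.
#'
#' @param min_nsat minimum satellite count (default 3).
#' @param max_hdop maximum horizontal dilution of precision (default 5).
#' @param max_pdop maximum position dilution of precision (default 6).
#' @param v_max implausible-velocity threshold in m/s (default 31.3).
#' @return An object of class `qa_thresholds`.
#' @export
qa_thresholds <- function(min_nsat = 3, max_hdop = 5, max_pdop = 6,
                          v_max = 31.3) {
  abort_if(v_max <= 0, "v_max must be positive")
  structure(list(min_nsat = min_nsat, max_hdop = max_hdop,
                 max_pdop = max_pdop, v_max = v_max),
            class = "qa_thresholds")
}

#' Remove GPS fixes failing signal-quality thresholds
#'
#' Drops every point whose satellite count is below `min_nsat` or whose
#' HDOP/PDOP exceeds the configured maxima. Point order is preserved; the
#' number of removals is attached as attribute `n_removed`.
#'
#' @param track data.frame of one participant's fixes (`timestamp`, `x_m`,
#'   `y_m`, `nsat`, `hdop`, `pdop`), time-ordered.
#' @param thresholds a [qa_thresholds()].
#' @return The filtered track.
#' @export
qa_filter <- function(track, thresholds = qa_thresholds()) {
  if (nrow(track) == 0) {
    warning("qa_filter: empty track")
    attr(track, "n_removed") <- 0L
    return(track)
  }
  ok <- track$nsat >= thresholds$min_nsat &
    track$hdop <= thresholds$max_hdop &
    track$pdop <= thresholds$max_pdop
  out <- track[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!ok)
  out
}

# Implied speed (m/s) between adjacent rows; non-positive elapsed time is
# physically impossible and treated as infinite speed.
adjacent_speeds <- function(track) {
  n <- nrow(track)
  if (n < 2) return(numeric(0))
  dt <- diff(as.numeric(track$timestamp))
  dd <- sqrt(diff(track$x_m)^2 + diff(track$y_m)^2)
  sp <- ifelse(dt > 0, dd / dt, Inf)
  sp
}

#' Iterative implausible-velocity filter
#'
#' Removes GPS points whose adjacency implies a speed at or above `v_max`
#' (default 31.3 m/s), working iteratively until no such pair remains.
#' When a pair offends, the later point of the pair (the arriving fix) is
#' removed and the scan resumes; because removing a point only alters the
#' pair it participated in, this is equivalent to restarting the scan from
#' the beginning after every removal. A pair with non-positive elapsed
#' time is treated as exceeding `v_max` (duplicate timestamps are
#' physically impossible). Tracks of one or zero points are returned
#' unchanged. On return the maximum implied adjacent speed is below
#' `v_max`.
#'
#' @param track a QA-filtered single-participant track.
#' @param v_max speed threshold in m/s.
#' @return The filtered track, with attribute `n_removed`.
#' @export
speed_filter <- function(track, v_max = 31.3) {
  abort_if(v_max <= 0, "v_max must be positive")
  n <- nrow(track)
  if (n <= 1) {
    attr(track, "n_removed") <- 0L
    return(track)
  }
  tt <- as.numeric(track$timestamp)
  xx <- track$x_m; yy <- track$y_m
  keep <- seq_len(n)
  i <- 1L
  while (i < length(keep)) {
    a <- keep[i]; b <- keep[i + 1L]
    dt <- tt[b] - tt[a]
    sp <- if (dt > 0) sqrt((xx[b] - xx[a])^2 + (yy[b] - yy[a])^2) / dt else Inf
    if (sp >= v_max) {
      keep <- keep[-(i + 1L)]
      # the pair (i, new i+1) must be rechecked; earlier pairs are unchanged
    } else {
      i <- i + 1L
    }
  }
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n - length(keep)
  out
}

#' Recompute per-point speed and distance
#'
#' After filtering, derives for each surviving point the planar distance
#' and implied speed to its previous and next neighbors. The first point
#' has undefined "before" fields and the last undefined "after" fields; a
#' single-point track has all derived fields undefined.
#'
#' @param track a filtered single-participant track.
#' @return The track with `distance_before`, `distance_after`,
#'   `speed_before`, `speed_after` columns (meters, m/s).
#' @export
recompute_kinematics <- function(track) {
  n <- nrow(track)
  dist <- if (n >= 2) sqrt(diff(track$x_m)^2 + diff(track$y_m)^2)
          else numeric(0)
  dt <- if (n >= 2) diff(as.numeric(track$timestamp)) else numeric(0)
  sp <- ifelse(dt > 0, dist / dt, NA_real_)
  track$distance_before <- c(NA_real_, dist)
  track$distance_after <- c(dist, NA_real_)
  track$speed_before <- c(NA_real_, sp)
  track$speed_after <- c(sp, NA_real_)
  track
}

#' Clean a multi-participant GPS table
#'
#' Applies, per participant: QA filtering, the iterative speed filter, and
#' kinematics recomputation. Returns the cleaned table plus a filtering
#' report.
#'
#' @param gps data.frame of raw fixes for one or more participants.
#' @param thresholds a [qa_thresholds()].
#' @return list with `gps_clean` (cleaned, kinematics recomputed) and
#'   `report` (per-participant data.frame: points in, removed by QA,
#'   removed by the speed filter, points out).
#' @export
preprocess_gps <- function(gps, thresholds = qa_thresholds()) {
  ids <- unique(gps$participant_id)
  cleaned <- vector("list", length(ids))
  report <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    tr <- gps[gps$participant_id == ids[k], , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    qa <- qa_filter(tr, thresholds)
    sf <- speed_filter(qa, thresholds$v_max)
    cleaned[[k]] <- recompute_kinematics(sf)
    report[[k]] <- data.frame(
      participant_id = ids[k],
      n_in = nrow(tr),
      n_qa_removed = attr(qa, "n_removed"),
      n_speed_removed = attr(sf, "n_removed"),
      n_out = nrow(sf),
      stringsAsFactors = FALSE
    )
  }
  list(gps_clean = do.call(rbind, cleaned),
       report = do.call(rbind, report))
}
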