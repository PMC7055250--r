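#' Dichotomize a 1-5 EMA rating
#'
#' Momentary ratings form an L-shaped distribution dominated by
#' "not at all"; ratings of 1 are recoded as 0 and ratings of 2-5 as 1.
#'
#' @param rating integer vector of ratings in 1..5.
#' @return Integer vector of 0/1.
#' @export
dichotomize <- function(rating) {
  abort_if(any(is.na(rating)) || any(!rating %in% 1:5),
           "ratings must be integers in 1..5")
  as.integer(rating >= 2)
}

# constant bin width: 30 minutes
BIN_SECONDS <- 1800L

#' Aggregate exposure samples into 30-min bins
#'
#' Aggregates the unevenly spaced GPS-linked exposure samples into
#' clock-aligned 30-min bins (half-open, boundaries at :00/:30 UTC). Each
#' bin carries the mean of log10(value + 1) over its in-region samples,
#' the proportions of property categories among them, the within-bin
#' travel distance from the cleaned track, and a sample count. Bins with
#' no in-region sample (including bins spent entirely outside the covered
#' region) are coded missing. The per-participant bin grid runs
#' contiguously from the first to the last observed bin.
#'
#' @param samples data.frame from [sample_exposure()].
#' @param clean_track cleaned GPS table (for within-bin distances); may be
#'   `NULL`, in which case distances are 0.
#' @param categories category level set for the proportion columns
#'   (default: sorted unique categories observed in `samples`).
#' @return data.frame of exposure bins: `participant_id`, `bin_start`,
#'   `mean_log_value`, `prop_*`, `distance_m`, `n_samples`, `missing`,
#'   `filled`.
#' @export
bin_exposure <- function(samples, clean_track = NULL, categories = NULL) {
  if (is.null(categories)) {
    categories <- sort(unique(samples$category[!is.na(samples$category)]))
  }
  ids <- unique(samples$participant_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    s <- samples[samples$participant_id == ids[k], , drop = FALSE]
    s <- s[order(s$timestamp), , drop = FALSE]
    b0 <- as.numeric(floor_bin(min(s$timestamp)))
    b1 <- as.numeric(floor_bin(max(s$timestamp)))
    starts <- seq(b0, b1, by = BIN_SECONDS)
    sbin <- floor(as.numeric(s$timestamp) / BIN_SECONDS) * BIN_SECONDS
    idx <- match(sbin, starts)
    nb <- length(starts)

    n_samples <- tabulate(idx, nb)
    ok <- s$in_region
    mean_log <- rep(NA_real_, nb)
    props <- matrix(NA_real_, nb, length(categories),
                    dimnames = list(NULL, categories))
    has <- tabulate(idx[ok], nb) > 0
    if (any(ok)) {
      lg <- log10(s$value[ok] + 1)
      sums <- tapply(lg, idx[ok], sum)
      cnts <- tapply(lg, idx[ok], length)
      at <- as.integer(names(sums))
      mean_log[at] <- sums / cnts
      for (cat in categories) {
        hit <- tapply(s$category[ok] == cat, idx[ok], mean)
        props[as.integer(names(hit)), cat] <- hit
      }
    }
    dist_m <- rep(0, nb)
    if (!is.null(clean_track)) {
      tr <- clean_track[clean_track$participant_id == ids[k], , drop = FALSE]
      if (nrow(tr) >= 2) {
        tr <- tr[order(tr$timestamp), , drop = FALSE]
        dd <- sqrt(diff(tr$x_m)^2 + diff(tr$y_m)^2)
        # each step's distance accrues to the bin of its arriving point
        tb <- floor(as.numeric(tr$timestamp)[-1] / BIN_SECONDS) * BIN_SECONDS
        di <- match(tb, starts)
        keep <- !is.na(di)
        if (any(keep)) {
          acc <- tapply(dd[keep], di[keep], sum)
          dist_m[as.integer(names(acc))] <- acc
        }
      }
    }
    df <- data.frame(
      participant_id = ids[k],
      bin_start = structure(starts, class = c("POSIXct", "POSIXt"),
                            tzone = "UTC"),
      mean_log_value = mean_log,
      stringsAsFactors = FALSE
    )
    for (cat in categories) df[[paste0("prop_", cat)]] <- props[, cat]
    df$distance_m <- ifelse(has, dist_m, NA_real_)
    df$n_samples <- n_samples
    df$missing <- !has
    df$filled <- FALSE
    out[[k]] <- df
  }
  do.call(rbind, out)
}

#' Forward-fill missing exposure bins
#'
#' Replaces each missing 30-min bin with the most recent prior observed
#' bin's exposure features, provided that bin lies within `max_lookback`
#' (default 24 h). Filled bins represent no observed movement, so their
#' travel distance is reset to 0 and they are flagged `filled = TRUE`.
#' Missing bins with no observed bin within the lookback stay missing.
#'
#' @param bins data.frame from [bin_exposure()], time-sorted per
#'   participant.
#' @param max_lookback lookback horizon in seconds (default 24 h).
#' @return The bins with fills applied.
#' @export
forward_fill <- function(bins, max_lookback = 24 * 3600) {
  feature_cols <- c("mean_log_value",
                    grep("^prop_", names(bins), value = TRUE))
  for (id in unique(bins$participant_id)) {
    rows <- which(bins$participant_id == id)
    rows <- rows[order(bins$bin_start[rows])]
    last_obs <- NA_integer_
    for (r in rows) {
      if (!bins$missing[r]) {
        if (!bins$filled[r]) last_obs <- r
        next
      }
      if (!is.na(last_obs) &&
          as.numeric(bins$bin_start[r]) -
            as.numeric(bins$bin_start[last_obs]) <= max_lookback) {
        bins[r, feature_cols] <- bins[last_obs, feature_cols]
        bins$distance_m[r] <- 0
        bins$missing[r] <- FALSE
        bins$filled[r] <- TRUE
      }
    }
  }
  bins
}

#' Build 90-min-ahead prediction instances
#'
#' For every 30-min grid boundary `t` with at least one EMA entry in the
#' lookahead window `(t, t + 90 min]`, emits one instance per outcome:
#' features are the 10 exposure bins covering `[t - 5 h, t)` (each
#' contributing mean log value, category proportions, travel distance and
#' the filled flag) concatenated with the participant's person-level
#' predictors; the label is the OR of the dichotomized outcome over the
#' EMA entries in the window. Instances whose 10 feature bins are all
#' missing are dropped; residual missing bins stay `NA` for downstream
#' training-set median imputation. `study_week` is the number of whole
#' weeks since the participant's first EMA entry.
#'
#' @param bins forward-filled exposure bins from [forward_fill()].
#' @param ema data.frame of raw EMA entries (`participant_id`,
#'   `timestamp`, one integer 1-5 column per outcome).
#' @param profiles person-level profile table.
#' @param outcome one of `"heroin"`, `"cocaine"`, `"stress"`.
#' @param n_feature_bins feature-window length in bins (default 10 = 5 h).
#' @param horizon_bins lookahead length in bins (default 3 = 90 min).
#' @return data.frame of prediction instances: `participant_id`, `anchor`,
#'   `study_week`, `label`, `bin00_*` (oldest) through `bin09_*` (most
#'   recent), and the person-level predictor columns (factors encoded with
#'   levels from the full profile table).
#' @export
build_instances <- function(bins, ema, profiles, outcome,
                            n_feature_bins = 10L, horizon_bins = 3L) {
  abort_if(!outcome %in% names(ema),
           paste0("outcome column '", outcome, "' not present in EMA table"))
  horizon <- horizon_bins * BIN_SECONDS
  prop_cols <- grep("^prop_", names(bins), value = TRUE)
  feat_cols <- c("mean_log_value", prop_cols, "distance_m", "filled")

  person <- profiles[setdiff(names(profiles), "participant_id")]
  for (j in seq_along(person)) {
    if (is.character(person[[j]])) {
      person[[j]] <- factor(person[[j]], levels = sort(unique(person[[j]])))
    }
    abort_if(is.factor(person[[j]]) && any(is.na(person[[j]])),
             "unknown category level in profile table")
  }

  out <- list()
  for (id in unique(ema$participant_id)) {
    e <- ema[ema$participant_id == id, , drop = FALSE]
    e <- e[order(e$timestamp), , drop = FALSE]
    y <- dichotomize(e[[outcome]])
    et <- as.numeric(e$timestamp)
    first_entry <- min(et)

    cand <- rep(floor(et / BIN_SECONDS) * BIN_SECONDS,
                each = horizon_bins + 1L) -
      rep(seq_len(horizon_bins + 1L) - 1L, times = length(et)) * BIN_SECONDS
    anchors <- sort(unique(cand))
    in_win <- function(t) et > t & et <= t + horizon
    anchors <- anchors[vapply(anchors, function(t) any(in_win(t)), TRUE)]
    if (!length(anchors)) next

    pb <- bins[bins$participant_id == id, , drop = FALSE]
    key <- as.numeric(pb$bin_start)
    fmat <- as.matrix(
      data.frame(lapply(pb[feat_cols], as.numeric),
                 check.names = FALSE))

    blocks <- vector("list", n_feature_bins)
    for (j in seq_len(n_feature_bins)) {
      # bin (j-1) covers [t - (n-j+1)*30min, t - (n-j)*30min)
      bs <- anchors - (n_feature_bins - j + 1L) * BIN_SECONDS
      m <- match(bs, key)
      blk <- fmat[ifelse(is.na(m), 1L, m), , drop = FALSE]
      blk[is.na(m), ] <- NA_real_
      # bins present but never observed nor filled carry no information
      miss <- !is.na(m) & pb$missing[ifelse(is.na(m), 1L, m)]
      blk[miss, ] <- NA_real_
      colnames(blk) <- paste0(sprintf("bin%02d_", j - 1L),
                              c("value", prop_cols, "distance", "filled"))
      blocks[[j]] <- blk
    }
    feats <- do.call(cbind, blocks)
    value_cols <- grep("_value$", colnames(feats))
    keep <- rowSums(!is.na(feats[, value_cols, drop = FALSE])) > 0
    if (!any(keep)) next

    label <- vapply(anchors, function(t) as.integer(any(y[in_win(t)])), 0L)
    week <- pmax(0, floor((anchors - first_entry) / (7 * 86400)))

    df <- data.frame(
      participant_id = id,
      anchor = structure(anchors, class = c("POSIXct", "POSIXt"),
                         tzone = "UTC"),
      study_week = as.integer(week),
      label = label,
      stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(feats))
    prow <- person[match(id, profiles$participant_id), , drop = FALSE]
    df <- cbind(df, prow[rep(1, nrow(df)), , drop = FALSE])
    rownames(df) <- NULL
    out[[length(out) + 1L]] <- df[keep, , drop = FALSE]
  }
  abort_if(!length(out), "no prediction instances could be built")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "outcome") <- outcome
  res
}
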