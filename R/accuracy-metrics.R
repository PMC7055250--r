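#' Confusion matrix and the five accuracy measures
#'
#' Tallies the confusion counts of aligned binary label/prediction
#' sequences and derives overall accuracy, sensitivity, specificity, PPV
#' and NPV. A measure whose denominator is zero is undefined and reported
#' as `NA` - never 0 or any other default: PPV is undefined when there was
#' no prediction of presence (tp + fp = 0), sensitivity when the target
#' event never occurred (tp + fn = 0), and symmetrically for NPV and
#' specificity.
#'
#' @param labels binary 0/1 vector of observed outcomes.
#' @param predictions binary 0/1 vector of model calls, same length.
#' @return One-row data.frame: `tp`, `fp`, `fn`, `tn`, `n`, `prevalence`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
confusion <- function(labels, predictions) {
  abort_if(length(labels) != length(predictions),
           "labels and predictions must have the same length")
  abort_if(any(!labels %in% 0:1) || any(!predictions %in% 0:1),
           "labels and predictions must be binary 0/1")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  n <- length(labels)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(
    tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    prevalence = ratio(tp + fn, n),
    accuracy = ratio(tp + tn, n),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
}

#' Per-participant, per-run accuracy summaries
#'
#' Collapses tailoring-protocol predictions into one confusion summary per
#' participant per run.
#'
#' @param run_predictions output of [run_cohort_protocol()] or
#'   [run_protocol()].
#' @return data.frame with one row per participant-run and the [confusion()]
#'   columns.
#' @export
summarize_runs <- function(run_predictions) {
  parts <- split(run_predictions,
                 list(run_predictions$participant_id, run_predictions$run),
                 drop = TRUE)
  out <- lapply(parts, function(d) {
    cbind(data.frame(participant_id = d$participant_id[1], run = d$run[1],
                     stringsAsFactors = FALSE),
          confusion(d$label, d$prediction))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$participant_id, res$run), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Weekly raw and cumulative prevalence per participant
#'
#' For each participant and study week (whole weeks since their first
#' entry), the raw prevalence is that week's positives over that week's
#' responses; the cumulative prevalence is the running tally of positives
#' over the running tally of responses through that week. Weeks with no
#' responses have undefined raw prevalence and inherit the previous
#' cumulative value.
#'
#' @param ema data.frame of raw EMA entries (`participant_id`,
#'   `timestamp`, integer 1-5 rating columns).
#' @param outcome outcome column to dichotomize and summarize.
#' @return Long data.frame: `participant_id`, `week`, `n_responses`,
#'   `n_positive`, `raw`, `cumulative`.
#' @export
prevalence_series <- function(ema, outcome) {
  out <- list()
  for (id in unique(ema$participant_id)) {
    e <- ema[ema$participant_id == id, , drop = FALSE]
    y <- dichotomize(e[[outcome]])
    wk <- floor(as.numeric(difftime(e$timestamp, min(e$timestamp),
                                    units = "days")) / 7)
    grid <- 0:max(wk)
    n_resp <- vapply(grid, function(w) sum(wk == w), 0L)
    n_pos <- vapply(grid, function(w) sum(y[wk == w]), 0L)
    cum_resp <- cumsum(n_resp)
    cum_pos <- cumsum(n_pos)
    out[[length(out) + 1L]] <- data.frame(
      participant_id = id, week = grid,
      n_responses = n_resp, n_positive = n_pos,
      raw = ifelse(n_resp > 0, n_pos / n_resp, NA_real_),
      cumulative = ifelse(cum_resp > 0, cum_pos / cum_resp, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate accuracy summaries by run and group
#'
#' Per run index and group, the mean over participants for whom each
#' measure is defined, with the per-measure n reported. Undefined values
#' are excluded from the mean, never zero-filled. Empty groups are
#' dropped with a warning.
#'
#' @param summaries per-participant-run summaries from [summarize_runs()].
#' @param grouping named group label per participant (a named character
#'   vector or a data.frame with `participant_id` and `group`), or `NULL`
#'   for a whole-sample aggregate.
#' @param measures measures to aggregate.
#' @return Long data.frame: `group`, `run`, `measure`, `mean`, `n`.
#' @export
aggregate_accuracy <- function(summaries, grouping = NULL,
                               measures = c("prevalence", "accuracy",
                                            "sensitivity", "specificity",
                                            "ppv", "npv")) {
  if (is.null(grouping)) {
    grp <- rep("all", nrow(summaries))
  } else {
    if (is.data.frame(grouping)) {
      grouping <- stats::setNames(grouping$group, grouping$participant_id)
    }
    grp <- unname(grouping[summaries$participant_id])
    abort_if(anyNA(grp), "grouping variable missing for some participants")
  }
  out <- list()
  for (g in unique(grp)) {
    for (r in sort(unique(summaries$run[grp == g]))) {
      sel <- grp == g & summaries$run == r
      if (!any(sel)) {
        warning("empty group ", g, " at run ", r)
        next
      }
      for (m in measures) {
        v <- summaries[[m]][sel]
        v <- v[!is.na(v)]
        out[[length(out) + 1L]] <- data.frame(
          group = g, run = r, measure = m,
          mean = if (length(v)) mean(v) else NA_real_,
          n = length(v),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
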