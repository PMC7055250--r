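#' Cohen's d from a t statistic with noncentral-t confidence limits
#'
#' Converts a between-group t statistic into a standardized mean
#' difference via `d = 2 t / sqrt(df)`. The 95% confidence limits invert
#' the noncentral-t distribution (the noncentrality parameters whose
#' upper/lower tail probability at the observed t equals alpha/2), scaled
#' by the same `2/sqrt(df)` factor; if the inversion fails numerically the
#' normal approximation `se(d) = sqrt(4/df + d^2/(2 df))` is used.
#'
#' @param t_statistic observed t.
#' @param df its degrees of freedom (must be positive).
#' @param conf confidence level (default 0.95).
#' @return One-row data.frame: `d`, `ci_low`, `ci_high`.
#' @export
cohen_d_from_test <- function(t_statistic, df, conf = 0.95) {
  abort_if(!is.finite(df) || df <= 0, "df must be positive")
  d <- 2 * t_statistic / sqrt(df)
  alpha <- 1 - conf
  ncp_at <- function(p_target) {
    f <- function(ncp) {
      suppressWarnings(stats::pt(t_statistic, df, ncp = ncp)) - p_target
    }
    lo <- t_statistic - 10 - 5 * abs(t_statistic)
    hi <- t_statistic + 10 + 5 * abs(t_statistic)
    tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-8)$root,
             error = function(e) NA_real_)
  }
  ncp_lo <- ncp_at(1 - alpha / 2)
  ncp_hi <- ncp_at(alpha / 2)
  if (is.na(ncp_lo) || is.na(ncp_hi)) {
    se <- sqrt(4 / df + d^2 / (2 * df))
    z <- stats::qnorm(1 - alpha / 2)
    ncp_lo <- (d - z * se) * sqrt(df) / 2
    ncp_hi <- (d + z * se) * sqrt(df) / 2
  }
  data.frame(d = d, ci_low = 2 * ncp_lo / sqrt(df),
             ci_high = 2 * ncp_hi / sqrt(df))
}

# Order prevalence clusters 1..4 for the linear-trend contrast.
cluster_linear_code <- function(cluster) {
  code <- match(cluster, trajectory_classes())
  abort_if(anyNA(code), "unknown cluster label")
  code
}

#' Multilevel model of person-level correlates of accuracy
#'
#' Fits a random-intercept multilevel model (restricted likelihood) to
#' per-participant per-run accuracy values: fixed effects for the group
#' predictor, run index (centered), and - for a single predictor - their
#' interaction; a random intercept per participant. Satterthwaite t tests
#' per fixed effect are converted to Cohen's d with confidence limits via
#' [cohen_d_from_test()]. The four-level prevalence cluster enters as a
#' linear contrast over ordered cluster codes (low = 1 ... high = 4). The
#' joint `race+cluster` model includes both main effects plus run, with no
#' interactions, to assess whether the race effect survives adjustment
#' for prevalence cluster.
#'
#' Runs where the measure is undefined are simply absent; multilevel
#' models accommodate incomplete repeated measures without imputation.
#'
#' @param summaries per-participant-run accuracy table (from
#'   [summarize_runs()], merged with person-level columns as needed).
#' @param measure which accuracy column to model (e.g. `"ppv"`).
#' @param predictor one of `"sex"`, `"race"`, `"cluster"`,
#'   `"race+cluster"` (columns of those names must be present;
#'   `cluster` must contain [trajectory_classes()] labels).
#' @return data.frame with one row per tested fixed effect: `measure`,
#'   `predictor`, `term`, `estimate`, `statistic` (t), `df`, `p`, `d`,
#'   `ci_low`, `ci_high`.
#' @export
fit_accuracy_model <- function(summaries, measure, predictor) {
  abort_if(!measure %in% names(summaries),
           paste0("measure column '", measure, "' absent"))
  d <- summaries[!is.na(summaries[[measure]]), , drop = FALSE]
  d$.y <- d[[measure]]
  d$.run_c <- d$run - mean(d$run)

  # (prefix, wants-interaction-row, reported term name)
  if (predictor == "sex" || predictor == "race") {
    abort_if(length(unique(d[[predictor]])) < 2,
             "need at least two groups with defined values")
    d$.g <- factor(d[[predictor]])
    form <- .y ~ .g * .run_c + (1 | participant_id)
    terms <- list(list(".g", FALSE, "group"),
                  list(".g", TRUE, "group:run"))
  } else if (predictor == "cluster") {
    d$.cl <- cluster_linear_code(d$cluster)
    abort_if(length(unique(d$.cl)) < 2,
             "need at least two clusters with defined values")
    form <- .y ~ .cl * .run_c + (1 | participant_id)
    terms <- list(list(".cl", FALSE, "cluster"),
                  list(".cl", TRUE, "cluster:run"))
  } else if (predictor == "race+cluster") {
    d$.g <- factor(d$race)
    d$.cl <- cluster_linear_code(d$cluster)
    abort_if(length(unique(d$.g)) < 2 || length(unique(d$.cl)) < 2,
             "need at least two groups and two clusters")
    form <- .y ~ .g + .cl + .run_c + (1 | participant_id)
    terms <- list(list(".g", FALSE, "group"),
                  list(".cl", FALSE, "cluster"))
  } else {
    stop("unknown predictor: ", predictor)
  }

  fit <- lmerTest::lmer(form, data = d, REML = TRUE)
  co <- summary(fit)$coefficients
  find_row <- function(prefix, interaction) {
    rn <- rownames(co)
    rn <- if (interaction) rn[grepl(":", rn, fixed = TRUE)]
          else rn[!grepl(":", rn, fixed = TRUE)]
    rn[startsWith(rn, prefix)][1]
  }
  out <- list()
  for (tm_spec in terms) {
    row <- find_row(tm_spec[[1]], tm_spec[[2]])
    tm <- tm_spec[[3]]
    est <- co[row, "Estimate"]
    tval <- co[row, "t value"]
    dfree <- co[row, "df"]
    dd <- cohen_d_from_test(tval, dfree)
    out[[length(out) + 1L]] <- data.frame(
      measure = measure, predictor = predictor, term = tm,
      estimate = est, statistic = tval, df = dfree,
      p = co[row, "Pr(>|t|)"],
      d = dd$d, ci_low = dd$ci_low, ci_high = dd$ci_high,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
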