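#' Random-forest specification for presence forecasting
#'
#' The forecasting models are random forests of 200 classification trees
#' with the number of candidate variables per split set to one third of
#' the total candidates, and a majority-vote presence threshold.
#'
#' @param n_trees number of trees (default 200).
#' @param classification_threshold vote-fraction cutoff for predicting
#'   presence (default 0.5; presence is called when the fraction of trees
#'   voting presence is `>=` the threshold).
#' @param seed RNG seed for tree growing.
#' @return An object of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 200L, classification_threshold = 0.5,
                        seed = 1L) {
  structure(list(n_trees = as.integer(n_trees),
                 classification_threshold = classification_threshold,
                 seed = as.integer(seed)),
            class = "forest_spec")
}

instance_feature_cols <- function(instances) {
  setdiff(names(instances),
          c("participant_id", "anchor", "study_week", "label"))
}

# Training-set median imputation for numeric features. Factor predictors
# are validated NA-free upstream.
fit_imputer <- function(x) {
  vapply(x, function(col) {
    if (is.numeric(col)) stats::median(col, na.rm = TRUE) else NA_real_
  }, 0)
}

apply_imputer <- function(x, medians) {
  for (j in names(x)) {
    if (is.numeric(x[[j]]) && anyNA(x[[j]])) {
      fill <- medians[[j]]
      if (is.na(fill)) fill <- 0   # feature all-missing in training
      x[[j]][is.na(x[[j]])] <- fill
    }
  }
  x
}

#' Fit a presence-forecasting random forest
#'
#' Grows `n_trees` classification trees on bootstrap samples of the
#' training instances, with `ceiling(p/3)` candidate features per split.
#' Missing numeric features are median-imputed with medians estimated on
#' the training set only; the imputation medians are stored with the model
#' and reused at prediction time. A training set containing only one
#' class yields a constant classifier for that class.
#'
#' @param train_set prediction instances from [build_instances()].
#' @param spec a [forest_spec()].
#' @return An object of class `gma_forest`.
#' @export
fit_forest <- function(train_set, spec = forest_spec()) {
  abort_if(is.null(train_set) || nrow(train_set) == 0,
           "protocol error: empty training set")
  cols <- instance_feature_cols(train_set)
  x <- train_set[cols]
  medians <- fit_imputer(x)
  x <- apply_imputer(x, medians)
  y <- factor(train_set$label, levels = c(0L, 1L))
  out <- list(feature_cols = cols, medians = medians, spec = spec)
  if (length(unique(train_set$label)) == 1L) {
    out$constant <- unique(train_set$label)
    class(out) <- "gma_forest"
    return(out)
  }
  p <- length(cols)
  fit_data <- cbind(x, .label = y)
  out$engine <- ranger::ranger(
    dependent.variable.name = ".label",
    data = fit_data,
    num.trees = spec$n_trees,
    mtry = ceiling(p / 3),
    seed = spec$seed,
    num.threads = 1,
    classification = TRUE
  )
  class(out) <- "gma_forest"
  out
}

#' @export
print.gma_forest <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<gma_forest> constant classifier (always %d)\n", x$constant))
  } else {
    cat(sprintf("<gma_forest> %d trees, mtry %d, %d features\n",
                x$spec$n_trees, x$engine$mtry, length(x$feature_cols)))
  }
  invisible(x)
}

#' Predict presence in the next 90 minutes
#'
#' The reported probability is the fraction of trees voting presence; the
#' binary call is presence when that fraction is at or above the
#' classification threshold.
#'
#' @param model a fitted [fit_forest()] model.
#' @param instances instances to score.
#' @param threshold overrides the model's classification threshold.
#' @return data.frame with `probability` and `prediction` (0/1) per
#'   instance.
#' @export
predict_presence <- function(model, instances, threshold = NULL) {
  stopifnot(inherits(model, "gma_forest"))
  threshold <- threshold %||% model$spec$classification_threshold
  if (!is.null(model$constant)) {
    prob <- rep(as.numeric(model$constant), nrow(instances))
  } else {
    x <- apply_imputer(instances[model$feature_cols], model$medians)
    pr <- stats::predict(model$engine, data = x, predict.all = TRUE,
                         num.threads = 1)$predictions
    # per-tree votes are level indices into the training factor (0 first)
    presence_code <- 2L
    prob <- rowMeans(pr == presence_code)
  }
  data.frame(probability = prob,
             prediction = as.integer(prob >= threshold))
}

#' Train/test split for one tailoring run
#'
#' Run `k` trains on all other participants' instances plus the target
#' participant's instances from study weeks before `k`, and tests on the
#' target's instances from week `k` onward. Run 0 is the "off the shelf"
#' model: no target data in training, all target weeks in the test set.
#'
#' @param instances full instance table.
#' @param target target participant id.
#' @param k run index (0-based week count of target data in training).
#' @return list with `train` and `test` instance tables (disjoint).
#' @export
tailoring_splits <- function(instances, target, k) {
  tgt <- instances$participant_id == target
  abort_if(!any(tgt), "target participant has no instances")
  abort_if(all(tgt), "protocol error: no other participants in the database")
  train <- instances[!tgt | instances$study_week < k, , drop = FALSE]
  test <- instances[tgt & instances$study_week >= k, , drop = FALSE]
  list(train = train, test = test)
}

#' Run the leave-one-out week-by-week tailoring protocol
#'
#' For each run index `k` from 0 up to the target's last observed study
#' week (capped at 15, i.e. up to 16 model runs), fits a forest on the
#' other participants' full data plus the target's first `k` weeks, and
#' scores the target's remaining weeks. Imputation medians are re-fit on
#' each run's training set. Tree-growing seeds are derived from the spec
#' seed, the target id and the run index, so cohort-level results are
#' reproducible regardless of scheduling order.
#'
#' @param instances full instance table for one outcome.
#' @param target target participant id.
#' @param spec a [forest_spec()].
#' @param runs run indices to execute (default all available for target).
#' @return data.frame of test-set predictions: `participant_id`, `run`,
#'   `anchor`, `study_week`, `label`, `probability`, `prediction`.
#' @export
run_protocol <- function(instances, target, spec = forest_spec(),
                         runs = NULL) {
  tgt_weeks <- instances$study_week[instances$participant_id == target]
  abort_if(!length(tgt_weeks), "target participant has no instances")
  last_week <- min(max(tgt_weeks), 15L)
  if (is.null(runs)) runs <- 0:last_week
  runs <- runs[runs <= last_week]
  id_hash <- sum(utf8ToInt(target))
  out <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    k <- runs[r]
    sp <- tailoring_splits(instances, target, k)
    # temporal-leakage guard: target data in training must predate run k
    in_train_tgt <- sp$train$participant_id == target
    abort_if(any(sp$train$study_week[in_train_tgt] >= k),
             "leakage: target training instance at or after run week")
    run_spec <- spec
    run_spec$seed <- derive_seed(spec$seed, id_hash * 37 + k)
    model <- fit_forest(sp$train, run_spec)
    pred <- predict_presence(model, sp$test)
    out[[r]] <- data.frame(
      participant_id = target,
      run = k,
      anchor = sp$test$anchor,
      study_week = sp$test$study_week,
      label = sp$test$label,
      probability = pred$probability,
      prediction = pred$prediction,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the tailoring protocol for every participant
#'
#' @param instances full instance table for one outcome.
#' @param spec a [forest_spec()].
#' @param targets participants to evaluate (default all).
#' @param runs run indices to execute per target (default all available).
#' @return Long data.frame of predictions across targets and runs.
#' @export
run_cohort_protocol <- function(instances, spec = forest_spec(),
                                targets = NULL, runs = NULL) {
  targets <- targets %||% unique(instances$participant_id)
  res <- lapply(targets, function(id)
    run_protocol(instances, id, spec, runs = runs))
  do.call(rbind, res)
}
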