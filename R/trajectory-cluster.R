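#' Fit a latent-class growth model to weekly prevalence trajectories
#'
#' Gaussian latent-class growth model (LCGM): each of `K` classes has a
#' polynomial mean trajectory over study week, observations scatter around
#' their class trajectory with a shared residual variance, and class
#' membership is a latent multinomial. There are no within-class random
#' effects. Fitting is by EM: the E-step computes posterior class
#' memberships from each participant's observed weekly values, the M-step
#' refits the class polynomials by posterior-weighted least squares and
#' updates the class weights and residual variance. The log-likelihood is
#' non-decreasing across iterations (asserted); the best of `restarts`
#' random initializations is returned. A class whose weight falls below
#' `1/(10N)` is pruned and the model refit with `K - 1` classes.
#'
#' Weekly prevalence values are treated as Gaussian observations, the
#' standard LCGM convention; set `logit = TRUE` to model
#' empirical-logit-transformed proportions instead.
#'
#' @param series long data.frame: `participant_id`, `week` (0-based),
#'   `value` (weekly prevalence; missing weeks simply absent).
#' @param K number of latent classes.
#' @param degree polynomial degree of the class trajectories (default 2).
#' @param restarts random restarts (default 20).
#' @param seed RNG seed.
#' @param max_iter,tol EM stopping rule: absolute log-likelihood change
#'   below `tol` or `max_iter` iterations.
#' @param logit model empirical-logit values instead of raw proportions.
#' @return An object of class `lcgm`: `K`, `degree`, `coefficients`
#'   (K x (degree+1)), `sigma2`, `weights`, `log_likelihood`, `bic`,
#'   `posterior` (participants x K), `converged`.
#' @export
fit_lcgm <- function(series, K, degree = 2L, restarts = 20L, seed = 1L,
                     max_iter = 500L, tol = 1e-6, logit = FALSE) {
  ids <- unique(series$participant_id)
  N <- length(ids)
  abort_if(K > N, "more classes than participants")
  obs_per <- table(factor(series$participant_id, levels = ids))
  abort_if(sum(obs_per >= 2) < K,
           "need at least K participants with >= 2 observed weeks")
  y <- series$value
  if (logit) {
    eps <- 0.5 / max(table(series$participant_id))
    y <- log((y + eps) / (1 - y + eps))
  }
  X <- stats::poly(series$week, degree = degree, raw = TRUE)
  X <- cbind(1, X)
  idx <- match(series$participant_id, ids)

  em_once <- function(post) {
    loglik_prev <- -Inf
    pi_k <- rep(1 / K, K)
    sigma2 <- stats::var(y)
    beta <- matrix(0, K, degree + 1L)
    loglik <- NA_real_
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # M-step from current posteriors
      w_obs <- post[idx, , drop = FALSE]     # n_obs x K
      rss <- 0
      for (k in seq_len(K)) {
        fit <- stats::lm.wfit(X, y, w = w_obs[, k])
        beta[k, ] <- fit$coefficients
      }
      resid <- y - X %*% t(beta)             # n_obs x K
      rss <- sum(w_obs * resid^2)
      sigma2 <- max(rss / length(y), 1e-10)
      pi_k <- pmax(colMeans(post), 1e-12)
      pi_k <- pi_k / sum(pi_k)
      # E-step
      ll_obs <- stats::dnorm(resid, sd = sqrt(sigma2), log = TRUE)
      ll_i <- rowsum(ll_obs, idx)            # N x K
      ll_i <- sweep(ll_i, 2, log(pi_k), "+")
      mx <- apply(ll_i, 1, max)
      lse <- mx + log(rowSums(exp(ll_i - mx)))
      loglik <- sum(lse)
      post <- exp(ll_i - lse)
      abort_if(loglik < loglik_prev - 1e-6,
               "EM log-likelihood decreased; numerical failure")
      if (abs(loglik - loglik_prev) < tol) { converged <- TRUE; break }
      loglik_prev <- loglik
    }
    list(beta = beta, sigma2 = sigma2, pi = pi_k, loglik = loglik,
         post = post, converged = converged)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, 7000 + r))
    hard <- sample.int(K, N, replace = TRUE)
    # guarantee every class is seeded
    hard[sample.int(N, K)] <- seq_len(K)
    post0 <- matrix(0.05 / max(K - 1, 1), N, K)
    post0[cbind(seq_len(N), hard)] <- 0.95
    if (K == 1L) post0 <- matrix(1, N, 1)
    fit <- em_once(post0)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) warning("EM did not converge within max_iter")

  # prune degenerate classes and refit smaller
  if (K > 1L && any(best$pi < 1 / (10 * N))) {
    return(fit_lcgm(series, K - 1L, degree, restarts, seed,
                    max_iter, tol, logit))
  }

  p <- K * (degree + 1L) + (K - 1L) + 1L
  rownames(best$post) <- ids
  structure(list(
    K = K, degree = degree,
    coefficients = best$beta,
    sigma2 = best$sigma2,
    weights = best$pi,
    log_likelihood = best$loglik,
    bic = -2 * best$loglik + p * log(N),
    posterior = best$post,
    converged = best$converged,
    weeks = sort(unique(series$week)),
    logit = logit
  ), class = "lcgm")
}

#' @export
print.lcgm <- function(x, ...) {
  cat(sprintf("<lcgm> K = %d, degree %d, logLik %.2f, BIC %.2f\n",
              x$K, x$degree, x$log_likelihood, x$bic))
  cat("  class weights:", paste(sprintf("%.3f", x$weights), collapse = ", "),
      "\n")
  invisible(x)
}

# Fitted class trajectory evaluated on the observed week grid.
lcgm_trajectories <- function(model) {
  Xg <- cbind(1, stats::poly(model$weeks, degree = model$degree, raw = TRUE))
  Xg %*% t(model$coefficients)   # weeks x K
}

#' Name LCGM classes by level and slope
#'
#' Deterministic labeling of a fitted model's classes. For a 4-class fit
#' the lowest-mean class is `low`, the highest-mean class `high`, and the
#' two middle classes are `medium-decreasing` / `medium-increasing` by the
#' sign (rank) of their fitted change from first to last week. Other class
#' counts get `class_1` (lowest mean) through `class_K`.
#'
#' @param model an [fit_lcgm()] model.
#' @return Character vector of labels, one per class column.
#' @export
label_classes <- function(model) {
  traj <- lcgm_trajectories(model)
  lev <- colMeans(traj)
  slope <- traj[nrow(traj), ] - traj[1, ]
  ord <- order(lev)
  labels <- character(model$K)
  if (model$K == 4L) {
    labels[ord[1]] <- "low"
    labels[ord[4]] <- "high"
    mid <- ord[2:3]
    dec <- mid[order(slope[mid])]   # more negative change first
    labels[dec[1]] <- "medium-decreasing"
    labels[dec[2]] <- "medium-increasing"
  } else {
    labels[ord] <- paste0("class_", seq_len(model$K))
  }
  labels
}

#' Select the number of trajectory classes by BIC
#'
#' Fits [fit_lcgm()] for each candidate `K`, returns the minimum-BIC model
#' (ties go to the smaller `K`), with classes named via [label_classes()]
#' and hard assignments by maximum posterior.
#'
#' @param series long prevalence series (see [fit_lcgm()]).
#' @param K_range candidate class counts (default 1..5).
#' @param degree,restarts,seed,logit passed to [fit_lcgm()].
#' @return list with `model` (the selected `lcgm`), `labels` (per class),
#'   `assignments` (data.frame: `participant_id`, `class_label`,
#'   `posterior_max`), and `bic_table`.
#' @export
select_lcgm <- function(series, K_range = 1:5, degree = 2L, restarts = 20L,
                        seed = 1L, logit = FALSE) {
  K_range <- sort(K_range)
  fits <- lapply(K_range, function(K)
    fit_lcgm(series, K, degree = degree, restarts = restarts,
             seed = derive_seed(seed, K), logit = logit))
  bics <- vapply(fits, function(f) f$bic, 0)
  pick <- which.min(bics)      # first minimum: ties favor smaller K
  model <- fits[[pick]]
  labels <- label_classes(model)
  hard <- apply(model$posterior, 1, which.max)
  assignments <- data.frame(
    participant_id = rownames(model$posterior),
    class_label = labels[hard],
    posterior_max = model$posterior[cbind(seq_along(hard), hard)],
    stringsAsFactors = FALSE
  )
  list(model = model, labels = labels, assignments = assignments,
       bic_table = data.frame(K = vapply(fits, function(f) f$K, 0L),
                              bic = bics))
}
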