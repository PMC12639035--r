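# Model evaluation: PSIS-LOO expected log predictive density, paired model
# comparison, and posterior predictive checks.

# Generalized Pareto fit (location 0) by the profile posterior-mean method
# of Zhang & Stephens, with the usual weak prior pulling k toward 1/2.
gpd_fit <- function(x, min_grid_pts = 30, wip = TRUE) {
  N <- length(x)
  x <- sort.int(x)
  if (x[N] <= 0 || N < 2) return(list(k = NA_real_, sigma = NA_real_))
  prior_bs <- 3
  prior_k <- 10
  M <- min_grid_pts + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  if (xstar <= 0) xstar <- x[N] / 2
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / prior_bs / xstar
  l_theta <- N * vapply(theta, function(th) {
    k <- mean(log1p(-th * x))
    log(-th / k) - k - 1
  }, numeric(1))
  w_theta <- 1 / vapply(seq_len(M), function(j) {
    sum(exp(l_theta - l_theta[j]))
  }, numeric(1))
  theta_hat <- sum(theta * w_theta)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  if (wip) k <- (k * N + prior_k * 0.5) / (N + prior_k)
  list(k = k, sigma = sigma)
}

qgpd0 <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth one vector of log importance weights (already max-shifted).
# Returns smoothed (still max-truncated) log weights and the tail index.
psis_smooth <- function(lw, tail_frac = 0.2, min_tail = 5) {
  S <- length(lw)
  M <- ceiling(tail_frac * S)
  if (M < min_tail || length(unique(lw)) < 5) {
    return(list(lw = pmin(lw, 0), khat = NA_real_))
  }
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exp_cutoff <- exp(cutoff)
  exc <- exp(lw[tail_ids]) - exp_cutoff
  if (max(exc) <= 0) return(list(lw = pmin(lw, 0), khat = NA_real_))
  fit <- gpd_fit(exc)
  if (!is.finite(fit$k)) return(list(lw = pmin(lw, 0), khat = NA_real_))
  p <- (seq_len(M) - 0.5) / M
  qq <- vapply(p, qgpd0, numeric(1), k = fit$k, sigma = fit$sigma) + exp_cutoff
  # assign expected order statistics to the tail draws in rank order
  lw[tail_ids[order(lw[tail_ids])]] <- log(qq)
  list(lw = pmin(lw, 0), khat = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Leave-one-out cross-validation approximated by Pareto-smoothed
#' importance sampling: per observation, the importance ratios are
#' proportional to one over the likelihood; the largest 20% of the log
#' ratios are replaced by expected order statistics of a generalized
#' Pareto distribution fitted to that tail, and the pointwise elpd is the
#' log of the smoothed-weighted average of the per-draw likelihoods.
#' Observations with tail-shape `k > 0.7` are reported (not refit).
#'
#' @param loglik Draws x observations matrix of pointwise log-likelihoods,
#'   or a `hier_fit` carrying one.
#' @return A `loo_result`: `elpd`, `pointwise_elpd`, `pareto_k`,
#'   `n_high_k`, `n_obs`, `n_draws`.
#' @export
psis_loo <- function(loglik) {
  if (inherits(loglik, "hier_fit")) loglik <- loglik$loglik
  loglik <- as.matrix(loglik)
  S <- nrow(loglik); N <- ncol(loglik)
  if (S < 100) stop_validation("need at least 100 draws for PSIS-LOO")
  if (!all(is.finite(loglik))) stop_validation("non-finite log-likelihoods")
  if (all(apply(loglik, 2, function(c_) stats::var(c_) == 0))) {
    stop_validation("degenerate importance weights: all draws identical")
  }
  pointwise <- khat <- numeric(N)
  for (i in seq_len(N)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    sm <- psis_smooth(lw)
    pointwise[i] <- logsumexp(sm$lw + ll) - logsumexp(sm$lw)
    khat[i] <- sm$khat
  }
  structure(list(elpd = sum(pointwise), pointwise_elpd = pointwise,
                 pareto_k = khat,
                 n_high_k = sum(khat > 0.7, na.rm = TRUE),
                 n_obs = N, n_draws = S),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.1f over %d observations (%d draws)\n",
              x$elpd, x$n_obs, x$n_draws))
  if (x$n_high_k > 0) {
    cat(sprintf("  %d observation(s) with Pareto k > 0.7\n", x$n_high_k))
  }
  invisible(x)
}

#' Compare models by ELPD
#'
#' Differences in expected log predictive density against the best model,
#' with the standard error of each paired difference
#' `sqrt(N * var(pointwise differences))`.
#'
#' @param results Named list of [psis_loo()] results computed on the same
#'   observations in the same order.
#' @return A `comparison_table` data frame (`model`, `elpd`, `elpd_diff`,
#'   `se_diff`), ordered by decreasing elpd.
#' @export
elpd_compare <- function(results) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("model", seq_along(results))
  }
  ns <- vapply(results, function(r) r$n_obs, numeric(1))
  if (length(unique(ns)) != 1) {
    stop_validation("models evaluated on different numbers of observations")
  }
  N <- ns[[1]]
  elpd <- vapply(results, function(r) r$elpd, numeric(1))
  best <- which.max(elpd)
  pw_best <- results[[best]]$pointwise_elpd
  diff <- elpd - elpd[best]
  se <- vapply(results, function(r) {
    d <- r$pointwise_elpd - pw_best
    sqrt(N * stats::var(d))
  }, numeric(1))
  se[best] <- 0
  out <- data.frame(model = names(results), elpd = unname(elpd),
                    elpd_diff = unname(diff), se_diff = unname(se),
                    row.names = NULL)
  out <- out[order(-out$elpd), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Proportion of (rounded) zeros
#'
#' Test statistic for posterior predictive checks. Values are rounded to
#' the nearest integer first, so the statistic is well-defined for the
#' continuous replicates of the Gaussian family (which would otherwise
#' almost surely contain no exact zeros).
#'
#' @param x Numeric vector.
#' @return Share of entries equal to zero after rounding.
#' @export
proportion_of_zeros <- function(x) mean(round(x) == 0)

ppc_statistics <- function(name) {
  switch(name,
         proportion_of_zeros = proportion_of_zeros,
         mean = mean,
         max = max,
         stop_config("unknown PPC statistic: ", name))
}

#' Posterior predictive check
#'
#' Simulates full replicated panels of outcomes from the likelihood at
#' posterior draws (using the observed predictors), computes the test
#' statistic on each, and compares against the observed value with a
#' two-sided posterior predictive p-value
#' `2 * min(P(rep >= obs), P(rep <= obs))`. When `n_rep` exceeds the
#' number of retained draws, draws are resampled with replacement.
#'
#' @param fit A `hier_fit`.
#' @param n_rep Number of replicated datasets (default 8000).
#' @param statistic Function of a count vector, or the name of a built-in
#'   (`"proportion_of_zeros"`, `"mean"`, `"max"`).
#' @param seed Integer seed.
#' @return A `ppc_result`: `replicated_stats`, `observed_stat`, `ppp`.
#' @export
ppc_replicate <- function(fit, n_rep = 8000,
                          statistic = proportion_of_zeros, seed = 1) {
  if (is.character(statistic)) statistic <- ppc_statistics(statistic)
  model <- fit$model
  y <- model$meta$y
  S <- nrow(fit$draws)
  set.seed(seed)
  idx <- if (n_rep <= S) sample.int(S, n_rep) else {
    sample.int(S, n_rep, replace = TRUE)
  }
  nb <- model$spec$family == "negbin"
  stats_rep <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    par <- fit$draws[idx[r], ]
    mu <- draw_mu(model, par)
    yrep <- if (nb) {
      stats::rnbinom(length(mu), size = par[["theta"]], mu = mu)
    } else {
      stats::rnorm(length(mu), mu, par[["sigma_y"]])
    }
    stats_rep[r] <- statistic(yrep)
  }
  obs <- statistic(y)
  ppp <- min(1, 2 * min(mean(stats_rep >= obs), mean(stats_rep <= obs)))
  structure(list(replicated_stats = stats_rep, observed_stat = obs,
                 ppp = ppp, n_rep = n_rep),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf(
    "PPC: observed statistic %.4f vs replicated [%.4f, %.4f] (central 95%%)\n",
    x$observed_stat,
    stats::quantile(x$replicated_stats, 0.025),
    stats::quantile(x$replicated_stats, 0.975)))
  cat(sprintf("  two-sided posterior predictive p = %.4f (%d replicates)\n",
              x$ppp, x$n_rep))
  invisible(x)
}
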