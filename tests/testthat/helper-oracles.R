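# Independent oracles used by the unit and acceptance suites. Each is a
# deliberately naive implementation (literal loops, dummy expansion, grid
# quadrature) kept separate from the package's code paths.

# FE slopes by explicit dummy expansion through lm().
dummy_ols_oracle <- function(panel, treatments, fes) {
  dat <- data.frame(y = panel$conflict,
                    as.data.frame(panel)[, treatments, drop = FALSE])
  terms <- treatments
  if (fes$region) { dat$fr <- factor(panel$region); terms <- c(terms, "fr") }
  if (fes$period) { dat$fp <- factor(panel$period); terms <- c(terms, "fp") }
  if (fes$region_month) {
    dat$frm <- factor(paste(panel$region, panel$month))
    terms <- c(terms, "frm")
  }
  fit <- stats::lm(stats::as.formula(
    paste("y ~", paste(terms, collapse = " + "))), data = dat)
  stats::coef(fit)[treatments]
}

# HAC sandwich by the literal quadruple-loop double sum over all
# observation pairs.
brute_force_hac <- function(fit, geometry, cfg) {
  X <- fit$design_demeaned
  e <- fit$residuals
  n <- nrow(X); k <- ncol(X)
  D <- geometry$distances
  ks_ <- function(d) {
    if (cfg$spatial_kernel == "uniform") as.numeric(d <= cfg$distance_cutoff)
    else max(0, 1 - d / cfg$distance_cutoff)
  }
  kt_ <- function(l) {
    if (cfg$temporal_kernel == "uniform") as.numeric(abs(l) <= cfg$lag_cutoff)
    else max(0, 1 - abs(l) / (cfg$lag_cutoff + 1))
  }
  meat <- matrix(0, k, k)
  for (o1 in seq_len(n)) {
    for (o2 in seq_len(n)) {
      w <- ks_(D[fit$region[o1], fit$region[o2]]) *
        kt_(fit$period[o1] - fit$period[o2])
      if (w == 0) next
      meat <- meat + w * (X[o1, ] * e[o1]) %o% (X[o2, ] * e[o2])
    }
  }
  bread <- solve(crossprod(X))
  bread %*% ((meat + t(meat)) / 2) %*% bread
}

# NB2 log-likelihood, term-wise gamma-function form (no dnbinom).
nb2_loglik_brute <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lfactorial(y) +
        theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu)))
}

# Literal-loop run-length counter.
drought_length_loop <- function(ta) {
  out <- integer(length(ta))
  run <- 0L
  for (t in seq_along(ta)) {
    run <- if (ta[t] > 0) run + 1L else 0L
    out[t] <- run
  }
  out
}

# Tiny Bayesian NB regression on a 2-d parameter grid: intercept + slope,
# known theta, flat-normal prior. Returns the grid, its log posterior, and
# a draws x n log-likelihood matrix from grid sampling. Exact LOO comes
# from quadrature reweighting of the same grid (posterior without obs i is
# proportional to posterior / likelihood_i), which never touches PSIS.
grid_nb_regression <- function(y, x, theta = 1.5, n_grid = 121,
                               n_draws = 4000, prior_sd = 5, seed = 1) {
  mle <- suppressWarnings(stats::glm(y ~ x, family = stats::poisson()))
  ctr <- stats::coef(mle)
  se <- summary(mle)$coefficients[, 2]
  b0 <- seq(ctr[1] - 6 * se[1], ctr[1] + 6 * se[1], length.out = n_grid)
  b1 <- seq(ctr[2] - 6 * se[2], ctr[2] + 6 * se[2], length.out = n_grid)
  grid <- expand.grid(b0 = b0, b1 = b1)
  n <- length(y)
  loglik_grid <- matrix(NA_real_, nrow(grid), n)  # grid cells x observations
  for (g in seq_len(nrow(grid))) {
    mu <- exp(grid$b0[g] + grid$b1[g] * x)
    loglik_grid[g, ] <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  }
  log_prior <- stats::dnorm(grid$b0, 0, prior_sd, log = TRUE) +
    stats::dnorm(grid$b1, 0, prior_sd, log = TRUE)
  log_post <- rowSums(loglik_grid) + log_prior
  w <- exp(log_post - max(log_post))
  w <- w / sum(w)
  set.seed(seed)
  cells <- sample.int(nrow(grid), n_draws, replace = TRUE, prob = w)
  list(grid = grid, loglik_grid = loglik_grid, log_post = log_post,
       loglik_draws = loglik_grid[cells, , drop = FALSE])
}

# Exact leave-one-out elpd by grid quadrature: for each observation,
# renormalize the grid posterior without its likelihood term and integrate
# the held-out likelihood.
grid_exact_loo <- function(gr) {
  n <- ncol(gr$loglik_grid)
  vapply(seq_len(n), function(i) {
    lp_minus <- gr$log_post - gr$loglik_grid[, i]
    wm <- exp(lp_minus - max(lp_minus))
    wm <- wm / sum(wm)
    log(sum(wm * exp(gr$loglik_grid[, i])))
  }, numeric(1))
}
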