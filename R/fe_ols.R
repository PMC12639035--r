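# Gaussian fixed-effects regression: multi-way FE absorption by alternating
# within-group demeaning, fit statistics, and Gaussian residual diagnostics.

#' Fixed-effects specification
#'
#' Which indicator sets the model absorbs: region intercepts, year-month
#' (period) intercepts, and region-by-calendar-month interactions.
#'
#' @param region,period,region_month Logical flags.
#' @return A `fixed_effects_spec`.
#' @export
fe_spec <- function(region = TRUE, period = TRUE, region_month = TRUE) {
  if (!region && !period && !region_month) {
    stop_config("at least one fixed-effect set (or explicit intercept) required")
  }
  structure(list(region = region, period = period,
                 region_month = region_month),
            class = "fixed_effects_spec")
}

# List of grouping factors implied by a spec, in panel row order.
fe_factors <- function(panel, fes) {
  g <- list()
  if (fes$region) g$region <- factor(panel$region)
  if (fes$period) g$period <- factor(panel$period)
  if (fes$region_month) {
    g$region_month <- factor(paste(panel$region, panel$month, sep = ":"))
  }
  g
}

# Alternating within-group demeaning of the columns of M over the grouping
# factors, iterated until the largest change is below tol.
demean_fe <- function(M, groups, tol = 1e-10, max_iter = 2000L) {
  M <- as.matrix(M)
  if (!length(groups)) return(M)
  idx <- lapply(groups, function(g) as.integer(g))
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (g in idx) {
      for (j in seq_len(ncol(M))) {
        mu <- tapply(M[, j], g, mean)
        adj <- mu[g]
        M[, j] <- M[, j] - adj
        delta <- max(delta, max(abs(adj)))
      }
    }
    if (delta < tol) break
  }
  M
}

# Number of linearly independent coefficients spanned by the FE dummies
# (including one overall intercept), via QR rank of the dummy design.
fe_rank <- function(panel, fes) {
  groups <- fe_factors(panel, fes)
  if (!length(groups)) return(1L)
  mm <- stats::model.matrix(
    ~ ., data = as.data.frame(groups, stringsAsFactors = TRUE))
  qr(mm, LAPACK = FALSE)$rank
}

#' Fit the Gaussian fixed-effects panel model
#'
#' Ordinary least squares of the conflict count on the climate treatments
#' with the requested fixed-effect sets absorbed. Two numerically distinct
#' paths are available: `"demean"` (alternating within-group demeaning, the
#' default -- scales to many FE levels) and `"dummy"` (explicit dummy
#' expansion through [stats::lm()]); both give identical slopes and serve as
#' mutual cross-checks.
#'
#' @param panel A `regional_panel`.
#' @param treatments Character vector of regressor columns.
#' @param fes A [fe_spec()].
#' @param method `"demean"` or `"dummy"`.
#' @return An `fe_ols_fit` with elements `slopes`, `se` (classical),
#'   `vcov`, `residuals`, `fitted`, `sigma`, `r2`, `within_r2`,
#'   `adj_within_r2`, `aic`, `n`, `fe_estimates` (per-factor group
#'   constants), and internals used by [hac_vcov()].
#' @export
fit_fe_ols <- function(panel, treatments = c("TA", "DL", "PA"),
                       fes = fe_spec(), method = c("demean", "dummy")) {
  method <- match.arg(method)
  absent <- setdiff(treatments, names(panel))
  if (length(absent)) {
    stop_config("treatment columns not in panel: ",
                paste(absent, collapse = ", "))
  }
  y <- as.numeric(panel$conflict)
  X <- as.matrix(as.data.frame(panel)[, treatments, drop = FALSE])
  groups <- fe_factors(panel, fes)
  n <- length(y)
  k <- ncol(X)
  p_fe <- fe_rank(panel, fes)

  constant_outcome <- stats::var(y) == 0
  if (method == "dummy") {
    dat <- data.frame(.y = y, X, as.data.frame(groups), check.names = FALSE)
    form <- stats::as.formula(paste(
      ".y ~", paste(c(colnames(X), names(groups)), collapse = " + ")))
    lmfit <- stats::lm(form, data = dat)
    beta <- stats::coef(lmfit)[colnames(X)]
    e <- stats::residuals(lmfit)
    Md <- demean_fe(cbind(y, X), groups)
    yd <- Md[, 1]; Xd <- Md[, -1, drop = FALSE]
  } else {
    Md <- demean_fe(cbind(y, X), groups)
    yd <- Md[, 1]
    Xd <- Md[, -1, drop = FALSE]
    colnames(Xd) <- colnames(X)
    qx <- qr(Xd)
    if (qx$rank < k) {
      kept <- colnames(X)[qx$pivot[seq_len(qx$rank)]]
      dropped <- setdiff(colnames(X), kept)
      stop_validation(
        "rank-deficient after FE absorption; collinear or fully absorbed: ",
        paste(if (length(dropped)) dropped else colnames(X), collapse = ", "))
    }
    beta <- if (constant_outcome) {
      stats::setNames(rep(0, k), colnames(X))
    } else {
      stats::setNames(qr.coef(qx, yd), colnames(X))
    }
    e <- yd - as.numeric(Xd %*% beta)
  }

  ssr <- sum(e^2)
  sst <- sum((y - mean(y))^2)
  df_resid <- n - p_fe - k
  sigma2 <- ssr / df_resid
  XtXinv <- solve(crossprod(Xd))
  vcov_cl <- sigma2 * XtXinv
  dimnames(vcov_cl) <- list(colnames(X), colnames(X))

  # Within R^2: share of the region-demeaned outcome variation explained.
  y_within <- y - stats::ave(y, panel$region)
  ssw <- sum(y_within^2)
  within_r2 <- if (ssw > 0) 1 - ssr / ssw else NA_real_
  p_abs <- p_fe + k
  adj_within_r2 <- if (is.na(within_r2)) NA_real_ else {
    1 - (1 - within_r2) * (n - 1) / (n - p_abs)
  }
  r2 <- if (constant_outcome) NA_real_ else 1 - ssr / sst
  # Gaussian AIC from the ML variance estimate; parameter count includes the
  # absorbed FE coefficients and sigma.
  aic <- n * log(2 * pi * ssr / n) + n + 2 * (p_abs + 1)

  fe_est <- fe_effects(y - as.numeric(X %*% beta), groups)
  structure(list(
    slopes = beta,
    se = sqrt(diag(vcov_cl)),
    vcov = vcov_cl,
    residuals = as.numeric(e),
    fitted = y - as.numeric(e),
    sigma = sqrt(sigma2),
    r2 = r2, within_r2 = within_r2, adj_within_r2 = adj_within_r2,
    aic = aic, n = n,
    n_fe_coefficients = p_fe,
    fe_estimates = fe_est,
    constant_outcome = constant_outcome,
    design_demeaned = Xd,
    region = panel$region, period = panel$period,
    treatments = treatments, fes = fes, method = method),
    class = "fe_ols_fit")
}

# Per-factor additive group constants for the FE part, by alternating
# projection of the slope-adjusted outcome.
fe_effects <- function(u, groups, tol = 1e-10, max_iter = 2000L) {
  if (!length(groups)) return(list())
  eff <- lapply(groups, function(g) {
    stats::setNames(rep(0, nlevels(g)), levels(g))
  })
  r <- u
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (nm in names(groups)) {
      g <- groups[[nm]]
      mu <- tapply(r, g, mean)
      eff[[nm]] <- eff[[nm]] + mu
      r <- r - mu[as.integer(g)]
      delta <- max(delta, max(abs(mu)))
    }
    if (delta < tol) break
  }
  eff
}

#' @export
print.fe_ols_fit <- function(x, ...) {
  cat("Gaussian fixed-effects fit (", x$method, " path)\n", sep = "")
  tab <- cbind(estimate = x$slopes, se = x$se)
  print(round(tab, 4))
  cat(sprintf("n = %d, R2 = %.3f, within R2 = %.3f (adj %.3f), AIC = %.1f\n",
              x$n, x$r2, x$within_r2, x$adj_within_r2, x$aic))
  invisible(x)
}

#' Gaussian residual diagnostics
#'
#' Standardized residuals, normal Q-Q coordinates, Kolmogorov-Smirnov and
#' Shapiro-Wilk tests of residual normality, and outlier flags
#' (|standardized residual| > 3).
#'
#' @param fit An `fe_ols_fit`.
#' @return A `diagnostics_report` list.
#' @export
gaussian_diagnostics <- function(fit) {
  e <- fit$residuals
  if (length(e) < 3) stop_validation("need at least 3 residuals")
  s <- stats::sd(e)
  if (s == 0) {
    return(structure(list(
      std_residuals = rep(0, length(e)), qq = NULL,
      ks = list(statistic = NA_real_, p_value = NA_real_),
      shapiro = list(statistic = NA_real_, p_value = NA_real_),
      outliers = integer(0), degenerate = TRUE),
      class = "diagnostics_report"))
  }
  z <- e / s
  qq <- stats::qqnorm(z, plot.it = FALSE)
  ks <- suppressWarnings(stats::ks.test(e, "pnorm", 0, s))
  sw <- if (length(e) <= 5000) stats::shapiro.test(e) else {
    stats::shapiro.test(sample(e, 5000))
  }
  structure(list(
    std_residuals = z,
    qq = data.frame(theoretical = qq$x, sample = qq$y),
    ks = list(statistic = unname(ks$statistic), p_value = ks$p.value),
    shapiro = list(statistic = unname(sw$statistic), p_value = sw$p.value),
    outliers = which(abs(z) > 3), degenerate = FALSE),
    class = "diagnostics_report")
}

#' Correlation of two columns after removing fixed effects
#'
#' Pearson correlation of two panel columns after partialling out the
#' requested fixed-effect sets from each.
#'
#' @param panel A `regional_panel`.
#' @param cols Character vector of two column names.
#' @param fes A [fe_spec()].
#' @return Correlation coefficient; `NA` (with a warning) if either
#'   residualized column has zero variance.
#' @export
residualized_correlation <- function(panel, cols = c("TA", "DL"),
                                     fes = fe_spec()) {
  stopifnot(length(cols) == 2)
  M <- as.matrix(as.data.frame(panel)[, cols])
  Md <- demean_fe(M, fe_factors(panel, fes))
  v <- apply(Md, 2, stats::var)
  if (any(v == 0)) {
    warning("zero residual variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(Md[, 1], Md[, 2])
}
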