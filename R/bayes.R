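# The Bayesian model ladder: single-level NB regression with region and
# period intercepts, region partial pooling with MVN coefficients and
# group-mean (within-between) correction, and the temporally pooled
# extension whose period effects follow a climate-forcing level model.
# Backend: JAGS (adaptive Gibbs/slice sampling) through rjags.

#' Default weakly informative priors
#'
#' Standard deviations of the zero-centred normal priors on location
#' parameters, the half-normal scale priors, and the Wishart degrees of
#' freedom of the scaled-Wishart prior on the between-region covariance.
#' The dispersion prior acts on `1/sqrt(theta)`. All entries can be
#' overridden through `hier_model_spec(priors = ...)`.
#'
#' @return Named list of prior settings.
#' @export
default_priors <- function() {
  list(hypermean_sd = 5,   # alpha0, gamma0, delta0, phi0 and Eq.-5 slopes
       eta_sd = 5,         # group-mean (within-between) coefficients
       fe_sd = 5,          # unpooled region / period intercepts
       psi_sd = 5,         # period-level model coefficients psi0..psi3
       xi_sd = 1,          # half-normal scale factors of the scaled Wishart
       wishart_df = 5,     # dim + 1: uniform-ish marginal correlations
       theta_invsqrt_sd = 1,
       sigma_w_sd = 2,     # scale of the pooled period effects
       sigma_y_sd = 5)     # residual scale, Gaussian family only
}

#' Declarative specification of a hierarchical model
#'
#' @param family `"negbin"` (NB2 likelihood, log link) or `"normal"`
#'   (Gaussian likelihood, identity link -- the original functional form).
#' @param pooling `"none"` (unpooled region and period intercepts, shared
#'   slopes), `"region"` (region coefficients partially pooled through a
#'   4-variate normal with group-mean correction), or `"region_time"`
#'   (additionally pools period effects through a linear level model on
#'   period-mean climate and the country-wide forcing).
#' @param priors See [default_priors()]; entries override the defaults.
#' @param include_region_month_fe Add region-by-calendar-month intercepts
#'   (only meaningful, and only allowed, for `pooling = "none"`; the
#'   multilevel models omit this term).
#' @param group_mean_correction Include the region-mean covariates (the
#'   within-between correction) in the pooled models? Disabling it exposes
#'   the time-invariant confounding bias the correction exists to absorb;
#'   intended for simulation studies.
#' @param forcing_variable,forcing_mode Column and mode for
#'   [climate_forcing()], used when `pooling = "region_time"`.
#' @return A `hier_model_spec`.
#' @export
hier_model_spec <- function(family = c("negbin", "normal"),
                            pooling = c("none", "region", "region_time"),
                            priors = list(),
                            include_region_month_fe = FALSE,
                            group_mean_correction = TRUE,
                            forcing_variable = "PA",
                            forcing_mode = c("median_ratio", "mean_deviation")) {
  family <- match.arg(family)
  pooling <- match.arg(pooling)
  forcing_mode <- match.arg(forcing_mode)
  pr <- utils::modifyList(default_priors(), priors)
  if (include_region_month_fe && pooling != "none") {
    stop_config("region-month intercepts are only supported with pooling = 'none'")
  }
  structure(list(family = family, pooling = pooling, priors = pr,
                 include_region_month_fe = include_region_month_fe,
                 group_mean_correction = isTRUE(group_mean_correction),
                 forcing_variable = forcing_variable,
                 forcing_mode = forcing_mode),
            class = "hier_model_spec")
}

#' Build the generative model for a panel
#'
#' Assembles the JAGS model description, the data block, and the monitors
#' for the requested rung of the model ladder. The MVN random-coefficient
#' block uses a non-centred construction: zero-mean raw coefficients with a
#' Wishart-prior precision, scaled by half-normal factors and shifted by
#' the hypermeans, so that the implied covariance is
#' `diag(xi) Sigma_raw diag(xi)`.
#'
#' @param spec A [hier_model_spec()].
#' @param panel A `regional_panel`.
#' @param forcing Optional precomputed [climate_forcing()]; built from the
#'   panel when `pooling = "region_time"` and omitted here.
#' @return A `hier_model` list: `code`, `data`, `monitors`, `spec`, and the
#'   index/meta information needed to reconstruct per-draw means.
#' @export
build_model <- function(spec, panel, forcing = NULL) {
  regions <- attr(panel, "regions")
  periods <- attr(panel, "periods")
  R <- length(regions); Tn <- length(periods); N <- nrow(panel)
  region <- match(panel$region, regions)
  period <- match(panel$period, periods)
  pr <- spec$priors
  prec <- function(sd) 1 / sd^2

  dat <- list(y = panel$conflict, N = N, R = R, T = Tn,
              region = region, period = period,
              TA = panel$TA, DL = as.numeric(panel$DL), PA = panel$PA)
  gm <- group_means(panel)
  meta <- list(regions = regions, periods = periods, region = region,
               period = period, TA = panel$TA, DL = as.numeric(panel$DL),
               PA = panel$PA, y = panel$conflict, group_means = gm)

  lik_open <- if (spec$family == "negbin") {
    paste0("    y[o] ~ dnegbin(pnb[o], theta)\n",
           "    pnb[o] <- theta / (theta + mu[o])\n",
           "    log(mu[o]) <- lp[o]\n")
  } else {
    "    y[o] ~ dnorm(mu[o], prec_y)\n    mu[o] <- lp[o]\n"
  }
  disp_block <- if (spec$family == "negbin") {
    sprintf(paste0("  ist ~ dnorm(0, %g) T(0,)\n",
                   "  theta <- 1 / (ist * ist)\n"),
            prec(pr$theta_invsqrt_sd))
  } else {
    sprintf(paste0("  sigma_y ~ dnorm(0, %g) T(0,)\n",
                   "  prec_y <- pow(sigma_y, -2)\n"),
            prec(pr$sigma_y_sd))
  }

  if (spec$pooling == "none") {
    rm_term <- ""
    rm_block <- ""
    if (spec$include_region_month_fe) {
      rmf <- factor(paste(panel$region, panel$month, sep = ":"))
      dat$rmonth <- as.integer(rmf)
      dat$RM <- nlevels(rmf)
      meta$rmonth <- as.integer(rmf)
      meta$rmonth_levels <- levels(rmf)
      rm_term <- " + omega[rmonth[o]]"
      rm_block <- sprintf(
        "  for (q in 1:RM) { omega[q] ~ dnorm(0, %g) }\n", prec(pr$fe_sd))
    }
    code <- paste0(
      "model {\n",
      "  for (o in 1:N) {\n", lik_open,
      "    lp[o] <- alpha * TA[o] + gamma * DL[o] + delta * PA[o]",
      " + phi[region[o]] + psi[period[o]]", rm_term, "\n",
      "  }\n",
      sprintf("  alpha ~ dnorm(0, %g)\n  gamma ~ dnorm(0, %g)\n  delta ~ dnorm(0, %g)\n",
              prec(pr$hypermean_sd), prec(pr$hypermean_sd), prec(pr$hypermean_sd)),
      sprintf("  for (i in 1:R) { phi[i] ~ dnorm(0, %g) }\n", prec(pr$fe_sd)),
      sprintf("  for (t in 1:T) { psi[t] ~ dnorm(0, %g) }\n", prec(pr$fe_sd)),
      rm_block, disp_block, "}\n")
    monitors <- c("alpha", "gamma", "delta", "phi", "psi",
                  if (spec$include_region_month_fe) "omega",
                  if (spec$family == "negbin") "theta" else "sigma_y")
  } else {
    use_eta <- spec$group_mean_correction
    if (use_eta) {
      dat$TAbar_i <- gm$region_means$TA
      dat$DLbar_i <- gm$region_means$DL
      dat$PAbar_i <- gm$region_means$PA
    }
    dat$I4 <- diag(4)
    dat$zero4 <- rep(0, 4)
    eta_priors <- if (use_eta) {
      sprintf("  eta1 ~ dnorm(0, %g)\n  eta2 ~ dnorm(0, %g)\n  eta3 ~ dnorm(0, %g)\n",
              prec(pr$eta_sd), prec(pr$eta_sd), prec(pr$eta_sd))
    } else ""
    mvn_block <- paste0(
      "  for (i in 1:R) {\n",
      "    raw[i, 1:4] ~ dmnorm(zero4[1:4], PrecRaw[1:4, 1:4])\n",
      "    for (j in 1:4) { coef[i, j] <- mu0[j] + xi[j] * raw[i, j] }\n",
      "  }\n",
      sprintf("  for (j in 1:4) { mu0[j] ~ dnorm(0, %g) }\n",
              prec(pr$hypermean_sd)),
      sprintf("  for (j in 1:4) { xi[j] ~ dnorm(0, %g) T(0,) }\n",
              prec(pr$xi_sd)),
      sprintf("  PrecRaw[1:4, 1:4] ~ dwish(I4[1:4, 1:4], %g)\n",
              pr$wishart_df),
      "  SigRaw[1:4, 1:4] <- inverse(PrecRaw[, ])\n",
      "  for (j in 1:4) { tau[j] <- xi[j] * sqrt(SigRaw[j, j]) }\n",
      eta_priors)
    lp_core <- paste0(
      "    lp[o] <- coef[region[o], 1] * TA[o] + coef[region[o], 2] * DL[o]",
      " + coef[region[o], 3] * PA[o] + coef[region[o], 4]",
      if (use_eta) paste0(
        " + eta1 * TAbar_i[region[o]] + eta2 * DLbar_i[region[o]]",
        " + eta3 * PAbar_i[region[o]]") else "")
    if (spec$pooling == "region") {
      code <- paste0(
        "model {\n  for (o in 1:N) {\n", lik_open,
        lp_core, " + psi[period[o]]\n  }\n",
        sprintf("  for (t in 1:T) { psi[t] ~ dnorm(0, %g) }\n", prec(pr$fe_sd)),
        mvn_block, disp_block, "}\n")
      monitors <- c("coef", "mu0", if (use_eta) c("eta1", "eta2", "eta3"),
                    "tau", "xi", "SigRaw", "psi",
                    if (spec$family == "negbin") "theta" else "sigma_y")
    } else {
      if (is.null(forcing)) {
        forcing <- climate_forcing(panel, spec$forcing_variable,
                                   spec$forcing_mode)
      }
      dat$TAbar_t <- gm$period_means$TA
      dat$DLbar_t <- gm$period_means$DL
      dat$C <- forcing$C
      meta$forcing <- forcing
      code <- paste0(
        "model {\n  for (o in 1:N) {\n", lik_open,
        lp_core, " + w[period[o]]\n  }\n",
        "  for (t in 1:T) {\n",
        "    w[t] ~ dnorm(psi0 + psi1 * TAbar_t[t] + psi2 * DLbar_t[t]",
        " + psi3 * C[t], prec_w)\n  }\n",
        sprintf("  psi0 ~ dnorm(0, %g)\n  psi1 ~ dnorm(0, %g)\n  psi2 ~ dnorm(0, %g)\n  psi3 ~ dnorm(0, %g)\n",
                prec(pr$psi_sd), prec(pr$psi_sd), prec(pr$psi_sd), prec(pr$psi_sd)),
        sprintf("  sigma_w ~ dnorm(0, %g) T(0,)\n  prec_w <- pow(sigma_w, -2)\n",
                prec(pr$sigma_w_sd)),
        mvn_block, disp_block, "}\n")
      monitors <- c("coef", "mu0", if (use_eta) c("eta1", "eta2", "eta3"),
                    "tau", "xi", "SigRaw", "w", "psi0", "psi1", "psi2",
                    "psi3", "sigma_w",
                    if (spec$family == "negbin") "theta" else "sigma_y")
    }
  }
  structure(list(code = code, data = dat, monitors = monitors, spec = spec,
                 meta = meta),
            class = "hier_model")
}

# Linear predictor for one posterior draw (named numeric vector of
# parameters), reconstructed from the model meta. Returns the
# observation-level mean mu (response scale).
draw_mu <- function(model, par) {
  m <- model$meta
  spec <- model$spec
  r <- m$region; t_ <- m$period
  if (spec$pooling == "none") {
    lp <- par[["alpha"]] * m$TA + par[["gamma"]] * m$DL +
      par[["delta"]] * m$PA +
      par[paste0("phi[", r, "]")] + par[paste0("psi[", t_, "]")]
    if (!is.null(m$rmonth)) lp <- lp + par[paste0("omega[", m$rmonth, "]")]
  } else {
    a <- par[paste0("coef[", r, ",1]")]
    b <- par[paste0("coef[", r, ",2]")]
    cc <- par[paste0("coef[", r, ",3]")]
    f <- par[paste0("coef[", r, ",4]")]
    gm <- m$group_means$region_means
    lp <- a * m$TA + b * m$DL + cc * m$PA + f
    if ("eta1" %in% names(par)) {
      lp <- lp + par[["eta1"]] * gm$TA[r] + par[["eta2"]] * gm$DL[r] +
        par[["eta3"]] * gm$PA[r]
    }
    lp <- lp + if (spec$pooling == "region") {
      par[paste0("psi[", t_, "]")]
    } else {
      par[paste0("w[", t_, "]")]
    }
  }
  lp <- unname(lp)
  if (spec$family == "negbin") exp(lp) else lp
}

# Pointwise log-likelihood matrix (draws x observations).
pointwise_loglik <- function(model, draws) {
  y <- model$meta$y
  S <- nrow(draws)
  out <- matrix(NA_real_, S, length(y))
  nb <- model$spec$family == "negbin"
  for (s in seq_len(S)) {
    par <- draws[s, ]
    mu <- draw_mu(model, par)
    out[s, ] <- if (nb) {
      stats::dnbinom(y, size = par[["theta"]], mu = mu, log = TRUE)
    } else {
      stats::dnorm(y, mu, par[["sigma_y"]], log = TRUE)
    }
  }
  out
}

#' Fit a hierarchical model by MCMC
#'
#' Samples the model with JAGS (adaptive Gibbs/slice sampling). Chain seeds
#' are derived deterministically from the single master seed. The fit is
#' flagged -- not silently accepted -- when the maximum rank-normalized
#' split R-hat exceeds 1.01 or the minimum bulk effective sample size falls
#' below 400; a divergence count is not defined for this family of
#' samplers and is recorded as `NA`.
#'
#' @param model A [build_model()] result.
#' @param chains Number of chains (default 4).
#' @param warmup Adaptation + burn-in iterations per chain (default 1000).
#' @param draws Retained iterations per chain (default 1000).
#' @param seed Master seed.
#' @param thin Thinning interval.
#' @param compute_loglik Record the pointwise log-likelihood matrix
#'   (needed for PSIS-LOO)?
#' @param quiet Suppress JAGS progress output.
#' @return A `hier_fit`: `draws` (matrix, chains stacked), `draws_array`
#'   (iterations x chains x parameters), `loglik`, `diagnostics`
#'   (per-parameter R-hat/ESS, `converged`, `flags`), `model`, `seed`.
#' @export
fit_bayes <- function(model, chains = 4, warmup = 1000, draws = 1000,
                      seed = 1, thin = 1, compute_loglik = TRUE,
                      quiet = TRUE) {
  stopifnot(inherits(model, "hier_model"))
  chain_seeds <- derive_seeds(seed, chains)
  inits <- lapply(chain_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
  n_adapt <- max(100L, floor(warmup / 2))
  # "Adaptation incomplete" is routine under a fixed warmup budget (most of
  # JAGS's samplers here are non-adaptive); other warnings pass through.
  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(model$code), data = model$data,
                      inits = inits, n.chains = chains,
                      n.adapt = n_adapt, quiet = quiet),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  burn <- warmup - n_adapt
  if (burn > 0) {
    if (quiet) {
      invisible(utils::capture.output(
        stats::update(jm, burn, progress.bar = "none")))
    } else {
      stats::update(jm, burn, progress.bar = "none")
    }
  }
  samp <- rjags::coda.samples(jm, model$monitors, n.iter = draws * thin,
                              thin = thin, progress.bar = "none")
  mats <- lapply(samp, as.matrix)
  pnames <- colnames(mats[[1]])
  arr <- array(NA_real_, c(nrow(mats[[1]]), chains, length(pnames)),
               dimnames = list(NULL, NULL, pnames))
  for (c_ in seq_len(chains)) arr[, c_, ] <- mats[[c_]]
  dm <- do.call(rbind, mats)
  diag_ <- mcmc_diagnostics(arr)
  ll <- if (compute_loglik) pointwise_loglik(model, dm) else NULL
  flags <- character(0)
  if (is.finite(diag_$max_rhat) && diag_$max_rhat >= 1.01) {
    flags <- c(flags, sprintf(
      "max split R-hat %.3f >= 1.01: consider more warmup/draws", diag_$max_rhat))
  }
  if (is.finite(diag_$min_ess_bulk) && diag_$min_ess_bulk <= 400) {
    flags <- c(flags, sprintf(
      "min bulk ESS %.0f <= 400: consider longer chains or thinning",
      diag_$min_ess_bulk))
  }
  structure(list(draws = dm, draws_array = arr, loglik = ll,
                 diagnostics = c(diag_, list(divergences = NA_integer_,
                                             flags = flags,
                                             converged = !length(flags))),
                 model = model, chains = chains, warmup = warmup,
                 n_draws = nrow(dm), seed = seed),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  sp <- x$model$spec
  cat(sprintf("Hierarchical %s model, pooling = %s: %d chains, %d draws\n",
              sp$family, sp$pooling, x$chains, x$n_draws))
  cat(sprintf("  max split R-hat %.3f, min bulk ESS %.0f%s\n",
              x$diagnostics$max_rhat, x$diagnostics$min_ess_bulk,
              if (x$diagnostics$converged) "" else "  [FLAGGED]"))
  for (f in x$diagnostics$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Posterior summaries: median, MAD-scaled SD, 95% credible interval
#'
#' The spread estimate is `1.4826 * median(|x - median(x)|)`, the
#' normal-consistent scaling of the median absolute deviation.
#'
#' @param fit A `hier_fit`, or a draws matrix with named columns.
#' @param pars Optional regular expression selecting parameters.
#' @return Data frame with `parameter`, `median`, `mad_sd`, `q2.5`, `q97.5`.
#' @export
summarize_posterior <- function(fit, pars = NULL) {
  dm <- if (inherits(fit, "hier_fit")) fit$draws else as.matrix(fit)
  if (nrow(dm) < 100) stop_validation("need at least 100 draws to summarize")
  if (!is.null(pars)) {
    dm <- dm[, grepl(pars, colnames(dm)), drop = FALSE]
  }
  med <- apply(dm, 2, stats::median)
  mad_sd <- apply(dm, 2, stats::mad)  # constant 1.4826 by default
  qs <- t(apply(dm, 2, stats::quantile, probs = c(0.025, 0.975)))
  data.frame(parameter = colnames(dm), median = unname(med),
             mad_sd = unname(mad_sd), q2.5 = unname(qs[, 1]),
             q97.5 = unname(qs[, 2]), row.names = NULL)
}

#' Between-region correlation summaries
#'
#' Posterior draws of the correlation matrix implied by the scaled-Wishart
#' covariance block (the correlation of `Sigma` equals that of the raw
#' Wishart draw, as the scale factors cancel).
#'
#' @param fit A `hier_fit` with `pooling != "none"`.
#' @return Summary data frame (one row per off-diagonal element).
#' @export
posterior_correlations <- function(fit) {
  dm <- fit$draws
  pairs_ <- utils::combn(4, 2)
  out <- matrix(NA_real_, nrow(dm), ncol(pairs_))
  labs <- character(ncol(pairs_))
  nm <- c("a", "b", "c", "f")
  for (p in seq_len(ncol(pairs_))) {
    j <- pairs_[1, p]; k <- pairs_[2, p]
    out[, p] <- dm[, sprintf("SigRaw[%d,%d]", j, k)] /
      sqrt(dm[, sprintf("SigRaw[%d,%d]", j, j)] *
             dm[, sprintf("SigRaw[%d,%d]", k, k)])
    labs[p] <- paste0("Omega[", nm[j], ",", nm[k], "]")
  }
  colnames(out) <- labs
  summarize_posterior(out)
}
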