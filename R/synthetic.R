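# Synthetic Somalia-like panels with known ground truth: seasonal,
# spatially correlated AR(1) climate anomalies; deterministic drought
# length; MVN region coefficients with a built-in time-invariant
# confounding device; climate-forced period effects; NB2 counts.

#' Configuration of the synthetic panel generator
#'
#' Defaults emulate the structure of the study panel: 18 regions observed
#' monthly over 1997--2009 (156 periods), heavy zero share and occasional
#' large counts. The climate block controls the anomaly processes; the
#' truth block holds the generative parameters of the hierarchical model,
#' which are returned alongside the panel for recovery tests.
#'
#' @param n_regions,n_years,first_year Panel dimensions.
#' @param seasonal_amplitude Amplitude of the seasonal sine component of
#'   the anomaly series (degrees C for TA-like series).
#' @param ar1 AR(1) coefficient of the anomaly noise.
#' @param innovation_sd Innovation standard deviation.
#' @param spatial_range Exponential-decay range (km) of the spatial
#'   correlation of innovations; the default 300 km keeps the 263 km HAC
#'   cutoff meaningfully exercised.
#' @param hypermeans Named vector `(alpha0, gamma0, delta0, phi0)`: the
#'   population-level TA, DL, PA slopes and baseline intercept.
#' @param tau Between-region SDs of `(a_i, b_i, c_i, f_i)`.
#' @param omega_corr Common off-diagonal correlation of the between-region
#'   coefficient correlation matrix.
#' @param eta Group-mean (within-between) coefficients `(eta1, eta2, eta3)`.
#' @param psi Period-level model coefficients `(psi0, psi1, psi2, psi3)`
#'   acting on (1, period-mean TA, period-mean DL, forcing C).
#' @param sigma_w SD of the period effects around their level model.
#' @param theta NB2 dispersion (size) parameter.
#' @param confounding_strength Additive loading of the standardized
#'   realized region-mean TA on the baseline `f_i`, inducing the
#'   correlation between region effects and treatment that the group-mean
#'   correction exists to absorb.
#' @param forcing_mode Mode for the generative [climate_forcing()]
#'   (`"mean_deviation"` by default: anomaly series have near-zero
#'   medians, where the median-ratio form is undefined).
#' @param seed Master seed; every random element flows from it.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 18, n_years = 13, first_year = 1997,
                             seasonal_amplitude = 0.3, ar1 = 0.6,
                             innovation_sd = 0.5, spatial_range = 300,
                             hypermeans = c(alpha0 = 0.10, gamma0 = 0.05,
                                            delta0 = -0.05, phi0 = -0.5),
                             tau = c(0.10, 0.05, 0.08, 0.70),
                             omega_corr = 0.2,
                             eta = c(-2.0, 0.2, 0.5),
                             psi = c(0.0, 0.5, -0.05, 0.02),
                             sigma_w = 0.3, theta = 0.8,
                             confounding_strength = 0.8,
                             forcing_mode = "mean_deviation",
                             seed = 1) {
  Omega <- matrix(omega_corr, 4, 4); diag(Omega) <- 1
  Sigma <- diag(tau) %*% Omega %*% diag(tau)
  ok <- tryCatch({ chol(Sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop_config("implied coefficient covariance is not positive definite")
  if (theta <= 0) stop_config("theta must be > 0")
  structure(list(n_regions = n_regions, n_years = n_years,
                 first_year = first_year,
                 seasonal_amplitude = seasonal_amplitude, ar1 = ar1,
                 innovation_sd = innovation_sd, spatial_range = spatial_range,
                 hypermeans = hypermeans, tau = tau, Omega = Omega,
                 Sigma = Sigma, eta = eta, psi = psi, sigma_w = sigma_w,
                 theta = theta, confounding_strength = confounding_strength,
                 forcing_mode = forcing_mode, seed = seed),
            class = "synthetic_config")
}

# One spatially correlated seasonal AR(1) anomaly field:
# regions x periods matrix.
simulate_anomaly_field <- function(n_regions, n_periods, month_of_period,
                                   amplitude, ar1, innovation_sd, chol_K,
                                   phase = 0) {
  seasonal <- amplitude * sin(2 * pi * (month_of_period / 12) + phase)
  z <- matrix(0, n_regions, n_periods)
  marg <- innovation_sd / sqrt(max(1 - ar1^2, 1e-8))
  z[, 1] <- (marg / innovation_sd) * drop(crossprod(chol_K, stats::rnorm(n_regions)))
  for (t in 2:n_periods) {
    z[, t] <- ar1 * z[, t - 1] + drop(crossprod(chol_K, stats::rnorm(n_regions)))
  }
  sweep(z, 2, seasonal, `+`)
}

#' Simulate a Somalia-like panel with known truth
#'
#' Generates (1) region centroids on a jittered grid with haversine
#' distances; (2) per-region temperature and precipitation anomaly series
#' (seasonal sine plus spatially correlated AR(1) noise with exponential
#' distance decay), smoothed with the 3-month trailing mean; (3) drought
#' length derived deterministically from the TA sign runs; (4) region
#' coefficients from the configured MVN with the confounding loading on
#' the baseline; (5) period effects from their climate-forcing level
#' model; (6) NB2 counts from the resulting log-linear means.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `panel` (a `regional_panel`), `geometry`
#'   (a `region_geometry`), and `truth` (a `synthetic_truth` list of all
#'   realized generative quantities).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  R <- cfg$n_regions
  Tn <- 12L * cfg$n_years
  regions <- sprintf("R%02d", seq_len(R))

  # Centroids: jittered grid over a Somalia-sized box (lat 1..11, lon 41..50).
  nc <- ceiling(sqrt(R))
  gx <- ((seq_len(R) - 1) %% nc) / max(nc - 1, 1)
  gy <- ((seq_len(R) - 1) %/% nc) / max(nc - 1, 1)
  lat <- 1 + 10 * gy + stats::runif(R, -0.4, 0.4)
  lon <- 41 + 9 * gx + stats::runif(R, -0.4, 0.4)
  geometry <- region_geometry(data.frame(region = regions, lat = lat,
                                         lon = lon))
  D <- geometry$distances[regions, regions]

  K <- cfg$innovation_sd^2 * exp(-D / cfg$spatial_range)
  chol_K <- chol(K + diag(1e-10, R))
  month_of_period <- ((seq_len(Tn) - 1L) %% 12L) + 1L

  ta_raw <- simulate_anomaly_field(R, Tn, month_of_period,
                                   cfg$seasonal_amplitude, cfg$ar1,
                                   cfg$innovation_sd, chol_K, phase = 0)
  pa_raw <- simulate_anomaly_field(R, Tn, month_of_period,
                                   cfg$seasonal_amplitude, cfg$ar1,
                                   cfg$innovation_sd, chol_K, phase = pi / 2)
  TA <- t(apply(ta_raw, 1, rolling_mean, window = 3))
  PA <- t(apply(pa_raw, 1, rolling_mean, window = 3))
  DL <- t(apply(TA, 1, drought_length))

  # Region coefficients with the confounding device on the baseline.
  coefs <- MASS::mvrnorm(R, mu = unname(cfg$hypermeans), Sigma = cfg$Sigma)
  colnames(coefs) <- c("a", "b", "c", "f")
  ta_bar_i <- rowMeans(TA)
  if (cfg$confounding_strength != 0 && stats::sd(ta_bar_i) > 0) {
    coefs[, "f"] <- coefs[, "f"] +
      cfg$confounding_strength * as.numeric(scale(ta_bar_i))
  }

  df <- data.frame(
    region = rep(regions, each = Tn),
    year = rep(cfg$first_year + (seq_len(Tn) - 1L) %/% 12L, times = R),
    month = rep(month_of_period, times = R),
    conflict = 0L,
    TA = as.numeric(t(TA)), DL = as.integer(t(DL)), PA = as.numeric(t(PA)))

  tmp_panel <- regional_panel(df, first_year = cfg$first_year)
  forcing <- climate_forcing(tmp_panel, "PA", cfg$forcing_mode)
  gm <- group_means(tmp_panel)
  w_mean <- cfg$psi[1] + cfg$psi[2] * gm$period_means$TA +
    cfg$psi[3] * gm$period_means$DL + cfg$psi[4] * forcing$C
  w <- stats::rnorm(Tn, w_mean, cfg$sigma_w)

  ridx <- match(tmp_panel$region, regions)
  tidx <- match(tmp_panel$period, attr(tmp_panel, "periods"))
  dl_bar_i <- stats::setNames(gm$region_means$DL, gm$region_means$region)
  pa_bar_i <- stats::setNames(gm$region_means$PA, gm$region_means$region)
  ta_bar_named <- stats::setNames(ta_bar_i, regions)
  lp <- coefs[ridx, "a"] * tmp_panel$TA + coefs[ridx, "b"] * tmp_panel$DL +
    coefs[ridx, "c"] * tmp_panel$PA + coefs[ridx, "f"] +
    cfg$eta[1] * ta_bar_named[tmp_panel$region] +
    cfg$eta[2] * dl_bar_i[tmp_panel$region] +
    cfg$eta[3] * pa_bar_i[tmp_panel$region] +
    w[tidx]
  mu <- exp(unname(lp))
  counts <- stats::rnbinom(length(mu), size = cfg$theta, mu = mu)

  df2 <- as.data.frame(tmp_panel)
  df2$conflict <- counts
  panel <- regional_panel(df2[, PANEL_COLUMNS],
                          first_year = cfg$first_year)
  truth <- structure(list(
    config = cfg, coefficients = coefs, w = w, forcing = forcing,
    region_means = gm$region_means, period_means = gm$period_means,
    mu = mu),
    class = "synthetic_truth")
  list(panel = panel, geometry = geometry, truth = truth)
}

#' Shift a climate variable by a multiple of its per-region SD
#'
#' Scenario construction: adds `shift` times the region's historical SD of
#' `variable` to every observation of that region. When TA is shifted,
#' drought length is re-derived from the shifted TA series (the
#' deterministic TA-to-DL link always holds).
#'
#' @param panel A `regional_panel`.
#' @param variable `"TA"` or `"PA"`.
#' @param shift Shift in per-region SD units.
#' @return The shifted `regional_panel`.
#' @export
scenario_shift <- function(panel, variable = "TA", shift = 1) {
  if (!variable %in% c("TA", "PA")) {
    stop_config("unknown scenario variable: ", variable)
  }
  df <- as.data.frame(panel)
  s <- stats::ave(df[[variable]], df$region, FUN = stats::sd)
  df[[variable]] <- df[[variable]] + shift * s
  if (variable == "TA") {
    df <- df[order(df$region, df$period), , drop = FALSE]
    df$DL <- as.integer(stats::ave(df$TA, df$region, FUN = drought_length))
  }
  regional_panel(df[, PANEL_COLUMNS], first_year = attr(panel, "first_year"))
}
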