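# Predictive projections: combine posterior draws with (possibly shifted)
# climate scenarios, propagating parameter, period-level and sampling
# uncertainty.

#' Project conflict counts under a climate scenario
#'
#' For each posterior draw, computes the observation-level means from the
#' region coefficients and the scenario predictors and samples counts from
#' the likelihood. With `horizon = "in_sample"` the posterior period
#' effects are reused. With `horizon = "out_of_sample"` -- available only
#' for the temporally pooled model, since unpooled period intercepts have
#' no generative model for new periods -- the period effects are drawn
#' from their level model, with period-mean climate and the forcing
#' recomputed from the scenario panel so that the level model's inputs are
#' scenario-consistent.
#'
#' @param fit A `hier_fit`.
#' @param scenario A `regional_panel` (e.g. from [scenario_shift()]) with
#'   the same regions and periods as the training panel.
#' @param horizon `"in_sample"` or `"out_of_sample"`.
#' @param n_draws Number of posterior draws to use (default: all).
#' @param seed Integer seed for the sampling stages.
#' @param scenario_name Label carried into the summaries.
#' @return A `projection_result`: `region_totals` (draws x regions matrix
#'   of whole-horizon totals), `aggregate` (their row sums), `summaries`
#'   (per region x period medians and 95% intervals), `scenario`.
#' @export
project <- function(fit, scenario, horizon = c("in_sample", "out_of_sample"),
                    n_draws = NULL, seed = 1, scenario_name = "scenario") {
  horizon <- match.arg(horizon)
  spec <- fit$model$spec
  if (horizon == "out_of_sample" && spec$pooling != "region_time") {
    stop_config(
      "out-of-sample projection requires pooling = 'region_time': models ",
      "with unpooled period intercepts have no generative model for new ",
      "periods")
  }
  if (spec$family != "negbin") {
    stop_config("projection implemented for the negative binomial family")
  }
  meta <- fit$model$meta
  if (!identical(attr(scenario, "regions"), meta$regions)) {
    stop_config("scenario regions differ from the fitted panel")
  }
  regions <- meta$regions
  periods <- attr(scenario, "periods")
  R <- length(regions); Tn <- length(periods)
  ridx <- match(scenario$region, regions)
  tidx <- match(scenario$period, periods)
  gm_fit <- fit$model$meta$group_means$region_means
  S <- nrow(fit$draws)
  n_draws <- min(n_draws %||% S, S)
  set.seed(seed)
  use <- if (n_draws == S) seq_len(S) else sample.int(S, n_draws)

  if (horizon == "out_of_sample") {
    gm_sc <- group_means(scenario)
    forcing_sc <- climate_forcing(scenario, spec$forcing_variable,
                                  spec$forcing_mode)
    ta_bar_t <- gm_sc$period_means$TA
    dl_bar_t <- gm_sc$period_means$DL
    C_sc <- forcing_sc$C
  }

  draws_counts <- matrix(0L, n_draws, nrow(scenario))
  for (s in seq_len(n_draws)) {
    par <- fit$draws[use[s], ]
    if (spec$pooling == "none") {
      lp <- par[["alpha"]] * scenario$TA + par[["gamma"]] * scenario$DL +
        par[["delta"]] * scenario$PA + par[paste0("phi[", ridx, "]")]
      if (!is.null(fit$model$meta$rmonth)) {
        rm_idx <- match(paste(scenario$region, scenario$month, sep = ":"),
                        fit$model$meta$rmonth_levels)
        lp <- lp + par[paste0("omega[", rm_idx, "]")]
      }
    } else {
      lp <- par[paste0("coef[", ridx, ",1]")] * scenario$TA +
        par[paste0("coef[", ridx, ",2]")] * scenario$DL +
        par[paste0("coef[", ridx, ",3]")] * scenario$PA +
        par[paste0("coef[", ridx, ",4]")]
      if ("eta1" %in% names(par)) {
        lp <- lp + par[["eta1"]] * gm_fit$TA[ridx] +
          par[["eta2"]] * gm_fit$DL[ridx] + par[["eta3"]] * gm_fit$PA[ridx]
      }
    }
    if (horizon == "in_sample") {
      lp <- lp + if (spec$pooling == "region_time") {
        par[paste0("w[", tidx, "]")]
      } else {
        par[paste0("psi[", tidx, "]")]
      }
    } else {
      w_new <- stats::rnorm(
        Tn,
        par[["psi0"]] + par[["psi1"]] * ta_bar_t +
          par[["psi2"]] * dl_bar_t + par[["psi3"]] * C_sc,
        par[["sigma_w"]])
      lp <- lp + w_new[tidx]
    }
    draws_counts[s, ] <- stats::rnbinom(length(lp), size = par[["theta"]],
                                        mu = exp(unname(lp)))
  }

  region_totals <- t(apply(draws_counts, 1, function(row) {
    tapply(row, ridx, sum)
  }))
  colnames(region_totals) <- regions
  qs <- apply(draws_counts, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  summaries <- data.frame(scenario = scenario_name,
                          region = scenario$region,
                          period = scenario$period,
                          median = qs[1, ], lo95 = qs[2, ], hi95 = qs[3, ],
                          row.names = NULL)
  structure(list(region_totals = region_totals,
                 aggregate = rowSums(region_totals),
                 summaries = summaries, horizon = horizon,
                 scenario = scenario_name, n_draws = n_draws),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  agg <- stats::quantile(x$aggregate, c(0.5, 0.025, 0.975))
  cat(sprintf(
    "Projection '%s' (%s): aggregate count median %.0f [%.0f, %.0f]\n",
    x$scenario, x$horizon, agg[1], agg[2], agg[3]))
  invisible(x)
}
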