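# Construction of the climate regressors: monthly anomalies, trailing
# averages, drought length, the country-wide climate forcing, and the
# group-mean covariates of the within-between correction.

#' Monthly anomaly with respect to a baseline climatology
#'
#' Subtracts from each value the mean of its calendar month computed over the
#' baseline years (the climatology), turning a raw monthly series into an
#' anomaly series.
#'
#' @param x Numeric series, one value per month.
#' @param month Integer calendar month (1--12) of each value.
#' @param year Integer calendar year of each value.
#' @param baseline_years Integer vector of years defining the climatology
#'   window (e.g. `1980:2009`).
#' @return Numeric anomaly series of the same length.
#' @export
monthly_anomaly <- function(x, month, year, baseline_years) {
  stopifnot(length(x) == length(month), length(x) == length(year))
  in_base <- year %in% baseline_years
  if (!any(in_base)) stop_validation("baseline window does not overlap series")
  clim <- rep(NA_real_, 12)
  for (m in sort(unique(month))) {
    sel <- in_base & month == m
    if (!any(sel)) {
      stop_validation("no baseline values for calendar month ", m)
    }
    clim[m] <- mean(x[sel])
  }
  x - clim[month]
}

#' Trailing rolling mean
#'
#' Mean over the current and previous `window - 1` months. The first
#' `window - 1` entries average over the months available so far
#' (`partial = TRUE`, the default, preserving panel balance) or are dropped
#' to `NA` (`partial = FALSE`). The trailing (rather than centered)
#' alignment keeps the regressor known at time t.
#'
#' @param x Numeric series.
#' @param window Window length in months (>= 1).
#' @param partial Average over available months at the start?
#' @return Numeric series of the same length.
#' @export
rolling_mean <- function(x, window = 3, partial = TRUE) {
  if (!is_wholenumber(window) || window < 1) {
    stop_config("window must be an integer >= 1")
  }
  n <- length(x)
  cs <- cumsum(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - window + 1L)
    out[t] <- (cs[t] - if (lo > 1L) cs[lo - 1L] else 0) / (t - lo + 1L)
  }
  if (!partial && window > 1 && n >= 1) out[seq_len(min(n, window - 1L))] <- NA_real_
  out
}

#' Drought length from a temperature-anomaly series
#'
#' Running count of consecutive months with strictly positive temperature
#' anomaly: `DL_t = DL_{t-1} + 1` if `TA_t > 0`, else 0, starting from 0.
#'
#' @param ta Numeric temperature-anomaly series for one region, in
#'   chronological order.
#' @return Integer series of run lengths, same length as `ta`.
#' @export
drought_length <- function(ta) {
  pos <- ta > 0
  if (!length(pos)) return(integer(0))
  as.integer(stats::ave(as.integer(pos), cumsum(!pos), FUN = cumsum))
}

#' Country-wide climate forcing series
#'
#' Aggregates one climate column across regions into a single period series
#' C_t. In `"median_ratio"` mode (the threshold-exceedance form)
#' `C_t = sum_i c_it / Q_i(.5)` with `Q_i(.5)` the region's median; regions
#' whose median is within `eps` of zero make the ratio meaningless and raise
#' an error directing to the `"mean_deviation"` mode, which uses
#' `C_t = sum_i (c_it - mean_i) / sd_i` (the deviation-from-average form,
#' safe for anomaly series centred near zero).
#'
#' @param panel A `regional_panel`.
#' @param variable Panel column to aggregate (default `"PA"`).
#' @param mode `"median_ratio"` or `"mean_deviation"`.
#' @param eps Floor on the absolute per-region median in `"median_ratio"`
#'   mode.
#' @return A `climate_forcing` list: `C` (length-T numeric, named by
#'   period), `denominators` (per region), `mode`, `variable`.
#' @export
climate_forcing <- function(panel, variable = "PA",
                            mode = c("median_ratio", "mean_deviation"),
                            eps = 1e-6) {
  mode <- match.arg(mode)
  if (!variable %in% names(panel)) {
    stop_config("unknown panel column: ", variable)
  }
  v <- panel[[variable]]
  reg <- panel$region
  per <- panel$period
  periods <- attr(panel, "periods")
  if (mode == "median_ratio") {
    med <- tapply(v, reg, stats::median)
    bad <- names(med)[abs(med) < eps]
    if (length(bad)) {
      stop_validation(
        "per-region median of ", variable, " is within ", eps,
        " of zero for region(s) ", paste(bad, collapse = ", "),
        "; the median-ratio forcing is undefined there. Use mode = ",
        "'mean_deviation' or supply a custom denominator.")
    }
    scaled <- v / med[reg]
    denominators <- c(med)
  } else {
    mu <- tapply(v, reg, mean)
    sd_ <- tapply(v, reg, stats::sd)
    if (any(!is.finite(sd_)) || any(sd_ <= 0)) {
      stop_validation("zero within-region variance in ", variable)
    }
    scaled <- (v - mu[reg]) / sd_[reg]
    denominators <- c(sd_)
  }
  C <- tapply(scaled, per, sum)[as.character(periods)]
  names(C) <- periods
  structure(list(C = as.numeric(C), periods = periods,
                 denominators = denominators, mode = mode,
                 variable = variable),
            class = "climate_forcing")
}

#' Group means of the climate regressors
#'
#' Per-region time averages (the between-region covariates of the
#' within-between correction) and per-period cross-region averages (the
#' inputs to the pooled period-effect level model).
#'
#' @param panel A `regional_panel`.
#' @param cols Columns to average.
#' @return A `group_means` list with data frames `region_means` and
#'   `period_means`.
#' @export
group_means <- function(panel, cols = c("TA", "DL", "PA")) {
  rm_ <- stats::aggregate(panel[cols], list(region = panel$region), mean)
  pm_ <- stats::aggregate(panel[cols], list(period = panel$period), mean)
  rm_ <- rm_[order(rm_$region), , drop = FALSE]
  pm_ <- pm_[order(pm_$period), , drop = FALSE]
  rownames(rm_) <- rownames(pm_) <- NULL
  structure(list(region_means = rm_, period_means = pm_),
            class = "group_means")
}

#' Attach group-mean columns to a panel
#'
#' Adds, for each of `cols`, a region-mean column `<col>_bar_i` (constant
#' within region) and a period-mean column `<col>_bar_t` (constant within
#' period).
#'
#' @inheritParams group_means
#' @return The panel with the extra columns.
#' @export
add_group_means <- function(panel, cols = c("TA", "DL", "PA")) {
  gm <- group_means(panel, cols)
  for (col in cols) {
    ri <- stats::setNames(gm$region_means[[col]], gm$region_means$region)
    pi_ <- stats::setNames(gm$period_means[[col]],
                           as.character(gm$period_means$period))
    panel[[paste0(col, "_bar_i")]] <- as.numeric(ri[panel$region])
    panel[[paste0(col, "_bar_t")]] <- as.numeric(pi_[as.character(panel$period)])
  }
  panel
}
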