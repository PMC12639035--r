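# Spatial-temporal HAC ("sandwich") covariance for the fixed-effects fit:
# spatial kernel over great-circle distances between region centroids,
# serial kernel over month lags.

#' HAC kernel configuration
#'
#' @param distance_cutoff Spatial cutoff in km beyond which dependence is
#'   assumed away (default 263, the maximum centroid distance between
#'   neighbouring regions in the Somalia panel).
#' @param lag_cutoff Maximum serial lag in months (default 4).
#' @param spatial_kernel,temporal_kernel `"uniform"` (weight 1 inside the
#'   cutoff) or `"bartlett"` (linear taper).
#' @return A `hac_config`.
#' @export
hac_config <- function(distance_cutoff = 263, lag_cutoff = 4,
                       spatial_kernel = c("uniform", "bartlett"),
                       temporal_kernel = c("uniform", "bartlett")) {
  if (distance_cutoff < 0 || lag_cutoff < 0) {
    stop_config("cutoffs must be >= 0")
  }
  structure(list(distance_cutoff = distance_cutoff,
                 lag_cutoff = as.integer(lag_cutoff),
                 spatial_kernel = match.arg(spatial_kernel),
                 temporal_kernel = match.arg(temporal_kernel)),
            class = "hac_config")
}

kernel_weight_spatial <- function(d, cfg) {
  if (cfg$spatial_kernel == "uniform") {
    as.numeric(d <= cfg$distance_cutoff)
  } else {
    pmax(0, 1 - d / max(cfg$distance_cutoff, .Machine$double.eps))
  }
}

kernel_weight_temporal <- function(lag, cfg) {
  if (cfg$temporal_kernel == "uniform") {
    as.numeric(abs(lag) <= cfg$lag_cutoff)
  } else {
    pmax(0, 1 - abs(lag) / (cfg$lag_cutoff + 1))
  }
}

#' Spatial-temporal HAC covariance of the slope estimates
#'
#' Sandwich estimator `(X'X)^-1 M (X'X)^-1` on the FE-absorbed design, with
#' meat `M = sum over observation pairs k_s(d_ij) k_t(|t-s|) x_it e_it e_js
#' x_js'`: observations of regions within the distance cutoff and periods
#' within the lag cutoff contribute cross products of their scores.
#' Within-region pairs have distance 0 and are always inside the spatial
#' cutoff. With both cutoffs at zero and uniform kernels the estimator
#' collapses to the heteroskedasticity-robust (White/HC0) covariance. The
#' meat is symmetrized; if it is not positive semidefinite its negative
#' eigenvalues are clipped at zero with a warning and the result flagged.
#'
#' @param fit An `fe_ols_fit`.
#' @param geometry A [region_geometry()] covering every panel region.
#' @param config A [hac_config()].
#' @param psd_fix Clip negative eigenvalues of the meat at zero (with a
#'   warning)? Disable to obtain the raw estimator.
#' @return Covariance matrix of the slopes with attributes `se` (its root
#'   diagonal) and `psd_adjusted` (eigenvalue clipping applied?).
#' @export
hac_vcov <- function(fit, geometry, config = hac_config(), psd_fix = TRUE) {
  X <- fit$design_demeaned
  e <- fit$residuals
  k <- ncol(X)
  D <- geometry$distances
  regions <- sort(unique(fit$region))
  if (!all(regions %in% rownames(D))) {
    stop_config("geometry does not cover regions: ",
                paste(setdiff(regions, rownames(D)), collapse = ", "))
  }
  S <- X * e  # scores, one row per observation
  ord <- order(fit$region, fit$period)
  Sreg <- split.data.frame(S[ord, , drop = FALSE],
                           fit$region[ord])  # per region, period-sorted
  Sreg <- lapply(Sreg, as.matrix)
  Tn <- unique(vapply(Sreg, nrow, 1L))
  if (length(Tn) != 1) stop_validation("panel is not balanced across regions")
  meat <- matrix(0, k, k)
  lags <- -config$lag_cutoff:config$lag_cutoff
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      ws <- kernel_weight_spatial(D[regions[i], regions[j]], config)
      if (ws == 0) next
      Si <- Sreg[[regions[i]]]
      Sj <- Sreg[[regions[j]]]
      for (lag in lags) {
        wt <- kernel_weight_temporal(lag, config)
        if (wt == 0) next
        t1 <- max(1L, 1L - lag)
        t2 <- min(Tn, Tn - lag)
        if (t1 > t2) next
        meat <- meat + ws * wt *
          crossprod(Si[t1:t2, , drop = FALSE],
                    Sj[(t1:t2) + lag, , drop = FALSE])
      }
    }
  }
  meat <- (meat + t(meat)) / 2
  psd_adjusted <- FALSE
  ev <- eigen(meat, symmetric = TRUE)
  if (psd_fix && min(ev$values) < -1e-8 * max(abs(ev$values))) {
    warning("HAC meat not positive semidefinite; clipping eigenvalues at 0")
    meat <- ev$vectors %*% diag(pmax(ev$values, 0), k) %*% t(ev$vectors)
    psd_adjusted <- TRUE
  }
  bread <- solve(crossprod(X))
  V <- bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  attr(V, "se") <- sqrt(pmax(diag(V), 0))
  attr(V, "psd_adjusted") <- psd_adjusted
  V
}
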