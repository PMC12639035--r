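# Rank-normalized split R-hat and bulk/tail effective sample sizes,
# computed per parameter from an iterations x chains x parameters array.

split_chains <- function(x) {
  # x: iterations x chains -> iterations/2 x (2*chains)
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

rhat_basic <- function(x) {
  # x: iterations x chains, already split/normalized as desired
  n <- nrow(x); m <- ncol(x)
  if (n < 3 || stats::var(as.vector(x)) == 0) return(NA_real_)
  chain_means <- colMeans(x)
  chain_vars <- apply(x, 2, stats::var)
  W <- mean(chain_vars)
  B <- n * stats::var(chain_means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#' @param x Matrix of draws, iterations x chains, for one parameter.
#' @return Potential scale reduction factor (NA for constant draws).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  rhat_basic(rank_normalize(split_chains(x)))
}

ess_of <- function(x) {
  # sum of per-chain effective sizes via coda
  ml <- coda::as.mcmc.list(lapply(seq_len(ncol(x)), function(c_) {
    coda::mcmc(x[, c_])
  }))
  as.numeric(coda::effectiveSize(ml))
}

#' Bulk effective sample size (rank-normalized, split chains)
#' @inheritParams split_rhat
#' @return Effective sample size.
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  if (stats::var(as.vector(x)) == 0) return(NA_real_)
  ess_of(rank_normalize(split_chains(x)))
}

#' Tail effective sample size (minimum over the 5% and 95% quantile
#' indicator sequences, split chains)
#' @inheritParams split_rhat
#' @return Effective sample size.
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  if (stats::var(as.vector(x)) == 0) return(NA_real_)
  q <- stats::quantile(as.vector(x), c(0.05, 0.95))
  lo <- split_chains(matrix(as.numeric(x <= q[1]), nrow(x), ncol(x)))
  hi <- split_chains(matrix(as.numeric(x >= q[2]), nrow(x), ncol(x)))
  min(ess_of(lo), ess_of(hi))
}

# Per-parameter diagnostics over an iterations x chains x parameters array.
mcmc_diagnostics <- function(arr) {
  pnames <- dimnames(arr)[[3]]
  rhat <- ebulk <- etail <- stats::setNames(rep(NA_real_, length(pnames)),
                                            pnames)
  for (p in seq_along(pnames)) {
    x <- arr[, , p, drop = TRUE]
    x <- as.matrix(x)
    if (stats::var(as.vector(x)) == 0) next
    rhat[p] <- split_rhat(x)
    ebulk[p] <- ess_bulk(x)
    etail[p] <- ess_tail(x)
  }
  list(rhat = rhat, ess_bulk = ebulk, ess_tail = etail,
       max_rhat = if (all(is.na(rhat))) NA_real_ else max(rhat, na.rm = TRUE),
       min_ess_bulk = if (all(is.na(ebulk))) NA_real_ else
         min(ebulk, na.rm = TRUE),
       min_ess_tail = if (all(is.na(etail))) NA_real_ else
         min(etail, na.rm = TRUE))
}
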