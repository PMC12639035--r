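# Shared fixtures, all generated in code.

# Deterministic toy panel: values filled from supplied vectors or a seeded
# RNG; counts drawn NB unless given.
make_toy_panel <- function(n_regions = 3, n_periods = 4, seed = 1,
                           conflict = NULL, TA = NULL, DL = NULL, PA = NULL,
                           first_year = 2000) {
  set.seed(seed)
  N <- n_regions * n_periods
  regions <- sprintf("r%02d", seq_len(n_regions))
  df <- data.frame(
    region = rep(regions, each = n_periods),
    year = rep(first_year + (seq_len(n_periods) - 1) %/% 12, n_regions),
    month = rep((seq_len(n_periods) - 1) %% 12 + 1, n_regions),
    conflict = conflict %||% rnbinom(N, size = 1, mu = 2),
    TA = TA %||% rnorm(N),
    DL = DL %||% rpois(N, 1),
    PA = PA %||% rnorm(N))
  regional_panel(df, first_year = first_year)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

make_toy_geometry <- function(panel, seed = 1) {
  set.seed(seed)
  regions <- attr(panel, "regions")
  region_geometry(data.frame(
    region = regions,
    lat = runif(length(regions), 0, 10),
    lon = runif(length(regions), 40, 50)))
}

# Memoized small synthetic simulation shared within a test file run.
.fixture_env <- new.env(parent = emptyenv())

get_small_sim <- function(n_regions = 6, n_years = 4, seed = 7) {
  key <- paste("sim", n_regions, n_years, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_panel(
      synthetic_config(n_regions = n_regions, n_years = n_years, seed = seed))
  }
  .fixture_env[[key]]
}

# Small shared single-level NB Bayesian fit.
get_small_nb_fit <- function() {
  if (is.null(.fixture_env$nb_fit)) {
    sim <- get_small_sim()
    model <- build_model(hier_model_spec("negbin", "none"), sim$panel)
    .fixture_env$nb_fit <- fit_bayes(model, chains = 2, warmup = 400,
                                     draws = 400, seed = 11)
  }
  .fixture_env$nb_fit
}
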