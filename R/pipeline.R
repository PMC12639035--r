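# End-to-end orchestration of the model ladder, with file artifacts and a
# machine-readable manifest. The exported function is the programmatic
# interface; inst/scripts/run_pipeline.R wraps it for shell use.

#' Default pipeline configuration
#'
#' @param output_dir Directory for artifacts.
#' @param seed Master seed for every random stage.
#' @return Nested configuration list; any entry can be overridden by the
#'   `config` argument of [run_pipeline()].
#' @export
default_run_config <- function(output_dir = tempfile("climladder_run_"),
                               seed = 1) {
  list(
    seed = seed,
    output_dir = output_dir,
    panel_path = NULL,       # read a deposited panel instead of simulating
    geometry_path = NULL,
    synthetic = list(),      # overrides for synthetic_config()
    models = c("fe_ols", "nb_glm", "bayes_normal", "bayes_nb",
               "bayes_region", "bayes_region_time"),
    hac = list(),            # overrides for hac_config()
    sampler = list(chains = 2, warmup = 500, draws = 500),
    evaluation = list(n_rep = 1000, statistic = "proportion_of_zeros"),
    projection = NULL,       # e.g. list(variable = "TA", shift = 1)
    forcing_mode = "mean_deviation",
    verbose = TRUE)
}

pipe_log <- function(verbose, ...) {
  if (verbose) message("[climladder] ", ...)
}

#' Run the full model ladder
#'
#' Simulates (or loads) a panel, fits the requested models -- Gaussian
#' fixed-effects OLS with spatial-temporal HAC errors, the frequentist NB
#' GLM, and the Bayesian ladder (Gaussian and NB single-level, NB with
#' region pooling, NB with region and time pooling) -- then runs residual
#' diagnostics, PSIS-LOO comparison, posterior predictive checks and an
#' optional scenario projection. All summary tables are written as
#' CSV/JSON under `output_dir` together with a manifest.
#'
#' @param config List of overrides of [default_run_config()], or a path to
#'   a YAML file with the same structure.
#' @return Invisibly, a list with all fitted objects and artifact paths.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)
  vb <- cfg$verbose
  artifacts <- character(0)
  results <- list(config = cfg)

  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$panel_path)) {
    pipe_log(vb, "loading panel from ", cfg$panel_path)
    panel <- load_panel(cfg$panel_path)
    geometry <- if (!is.null(cfg$geometry_path)) {
      region_geometry(cfg$geometry_path)
    } else NULL
    truth <- NULL
  } else {
    sim_cfg <- do.call(synthetic_config,
                       utils::modifyList(list(seed = cfg$seed),
                                         cfg$synthetic))
    pipe_log(vb, "simulating panel: ", sim_cfg$n_regions, " regions x ",
             12 * sim_cfg$n_years, " months (seed ", sim_cfg$seed, ")")
    sim <- simulate_panel(sim_cfg)
    panel <- sim$panel; geometry <- sim$geometry; truth <- sim$truth
    write_panel(panel, out("panel.csv"))
    utils::write.csv(geometry$centroids, out("geometry.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(hypermeans = as.list(sim_cfg$hypermeans), tau = sim_cfg$tau,
           eta = sim_cfg$eta, psi = sim_cfg$psi, theta = sim_cfg$theta,
           sigma_w = sim_cfg$sigma_w,
           confounding_strength = sim_cfg$confounding_strength,
           coefficients = as.data.frame(truth$coefficients)),
      out("truth.json"), auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, out(c("panel.csv", "geometry.csv",
                                    "truth.json")))
  }
  results$panel <- panel; results$geometry <- geometry; results$truth <- truth

  # --- frequentist rungs --------------------------------------------------
  if ("fe_ols" %in% cfg$models) {
    pipe_log(vb, "fitting Gaussian fixed-effects model")
    fe <- fit_fe_ols(panel)
    hacV <- if (!is.null(geometry)) {
      do.call(hac_config, cfg$hac)
      hac_vcov(fe, geometry, do.call(hac_config, cfg$hac))
    } else NULL
    diag_g <- gaussian_diagnostics(fe)
    results$fe_ols <- list(fit = fe, hac = hacV, diagnostics = diag_g)
    jsonlite::write_json(
      list(slopes = as.list(fe$slopes), se_classical = as.list(fe$se),
           se_hac = if (!is.null(hacV)) as.list(attr(hacV, "se")),
           r2 = fe$r2, within_r2 = fe$within_r2,
           adj_within_r2 = fe$adj_within_r2, aic = fe$aic, n = fe$n,
           ks_p = diag_g$ks$p_value, shapiro_p = diag_g$shapiro$p_value,
           n_outliers = length(diag_g$outliers)),
      out("fe_ols.json"), auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, out("fe_ols.json"))
  }
  if ("nb_glm" %in% cfg$models) {
    pipe_log(vb, "fitting negative binomial GLM")
    nb <- fit_nb_glm(panel)
    diag_nb <- nb_quantile_residuals(nb, seed = cfg$seed)
    results$nb_glm <- list(fit = nb, diagnostics = diag_nb)
    jsonlite::write_json(
      list(slopes = as.list(nb$slopes), se = as.list(nb$se),
           theta = nb$theta, loglik = nb$loglik, aic = nb$aic, n = nb$n,
           ks_p = diag_nb$ks$p_value, separation = nb$separation),
      out("nb_glm.json"), auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, out("nb_glm.json"))
  }
  if (!is.null(results$fe_ols) && !is.null(results$nb_glm)) {
    writeLines(format_fit_table(results$fe_ols$fit, results$nb_glm$fit,
                                hac_se = if (!is.null(results$fe_ols$hac)) {
                                  attr(results$fe_ols$hac, "se")
                                }),
               out("fit_table.txt"))
    artifacts <- c(artifacts, out("fit_table.txt"))
  }

  # --- Bayesian ladder ----------------------------------------------------
  bayes_specs <- list(
    bayes_normal = hier_model_spec("normal", "none"),
    bayes_nb = hier_model_spec("negbin", "none"),
    bayes_region = hier_model_spec("negbin", "region"),
    bayes_region_time = hier_model_spec("negbin", "region_time",
                                        forcing_mode = cfg$forcing_mode))
  fits <- list()
  for (nm in intersect(names(bayes_specs), cfg$models)) {
    pipe_log(vb, "MCMC: ", nm, " (", cfg$sampler$chains, " chains x ",
             cfg$sampler$draws, " draws)")
    model <- build_model(bayes_specs[[nm]], panel)
    fits[[nm]] <- fit_bayes(model, chains = cfg$sampler$chains,
                            warmup = cfg$sampler$warmup,
                            draws = cfg$sampler$draws, seed = cfg$seed)
    summ <- summarize_posterior(
      fits[[nm]],
      pars = "^(alpha|gamma|delta|mu0|eta|theta|tau|psi[0-9]|sigma)")
    utils::write.csv(summ, out(paste0(nm, "_summary.csv")),
                     row.names = FALSE)
    artifacts <- c(artifacts, out(paste0(nm, "_summary.csv")))
  }
  results$bayes <- fits

  # --- evaluation ---------------------------------------------------------
  if (length(fits) >= 2) {
    pipe_log(vb, "PSIS-LOO model comparison")
    loos <- lapply(fits, psis_loo)
    comp <- elpd_compare(loos)
    results$loo <- loos
    results$comparison <- comp
    utils::write.csv(comp, out("elpd_comparison.csv"), row.names = FALSE)
    artifacts <- c(artifacts, out("elpd_comparison.csv"))
  }
  if (length(fits)) {
    pipe_log(vb, "posterior predictive checks (", cfg$evaluation$n_rep,
             " replicates)")
    ppcs <- lapply(fits, ppc_replicate, n_rep = cfg$evaluation$n_rep,
                   statistic = cfg$evaluation$statistic, seed = cfg$seed)
    results$ppc <- ppcs
    ppc_df <- data.frame(
      model = names(ppcs),
      observed = vapply(ppcs, function(p) p$observed_stat, numeric(1)),
      rep_lo = vapply(ppcs, function(p) {
        stats::quantile(p$replicated_stats, 0.025)
      }, numeric(1)),
      rep_hi = vapply(ppcs, function(p) {
        stats::quantile(p$replicated_stats, 0.975)
      }, numeric(1)),
      ppp = vapply(ppcs, function(p) p$ppp, numeric(1)), row.names = NULL)
    utils::write.csv(ppc_df, out("ppc.csv"), row.names = FALSE)
    artifacts <- c(artifacts, out("ppc.csv"))
  }

  # --- projection ---------------------------------------------------------
  if (!is.null(cfg$projection) && "bayes_region_time" %in% names(fits)) {
    pipe_log(vb, "scenario projection: +", cfg$projection$shift, " SD of ",
             cfg$projection$variable)
    shifted <- scenario_shift(panel, cfg$projection$variable,
                              cfg$projection$shift)
    proj <- project(fits$bayes_region_time, shifted,
                    horizon = "out_of_sample", seed = cfg$seed,
                    scenario_name = paste0("+", cfg$projection$shift, "sd_",
                                           cfg$projection$variable))
    results$projection <- proj
    utils::write.csv(proj$summaries, out("projection.csv"),
                     row.names = FALSE)
    artifacts <- c(artifacts, out("projection.csv"))
  }

  manifest <- list(
    seed = cfg$seed, models = cfg$models,
    sampler = cfg$sampler,
    n_regions = attr(panel, "n_regions"),
    n_periods = attr(panel, "n_periods"),
    r_version = as.character(getRversion()),
    artifacts = basename(artifacts))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  pipe_log(vb, "done; artifacts in ", cfg$output_dir)
  invisible(results)
}

#' Plain-text coefficient table for the single-level fits
#'
#' Coefficients with standard errors beneath, Gaussian and NB columns side
#' by side.
#'
#' @param fe_fit An `fe_ols_fit`.
#' @param nb_fit An `nb_glm_fit`.
#' @param hac_se Optional HAC standard errors for the Gaussian column.
#' @return Character vector of table lines.
#' @export
format_fit_table <- function(fe_fit, nb_fit, hac_se = NULL) {
  vars <- fe_fit$treatments
  lines <- sprintf("%-8s %14s %14s", "", "Normal", "NB")
  for (v in vars) {
    lines <- c(lines, sprintf("%-8s %14.3f %14.3f", v,
                              fe_fit$slopes[[v]], nb_fit$slopes[[v]]))
    se_g <- if (!is.null(hac_se)) hac_se[[v]] else fe_fit$se[[v]]
    lines <- c(lines, sprintf("%-8s %14s %14s", "",
                              sprintf("(%.3f)", se_g),
                              sprintf("(%.3f)", nb_fit$se[[v]])))
  }
  c(lines,
    sprintf("%-8s %14d %14d", "N", fe_fit$n, nb_fit$n),
    sprintf("%-8s %14.3f %14s", "Within R2", fe_fit$within_r2, ""),
    sprintf("%-8s %14.1f %14.1f", "AIC", fe_fit$aic, nb_fit$aic))
}
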