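test_that("the generator is deterministic in its master seed", {
  cfg <- synthetic_config(n_regions = 5, n_years = 2, seed = 77)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(as.data.frame(s1$panel), as.data.frame(s2$panel))
  expect_identical(s1$truth$coefficients, s2$truth$coefficients)
  s3 <- simulate_panel(synthetic_config(n_regions = 5, n_years = 2,
                                        seed = 78))
  expect_false(identical(s1$panel$conflict, s3$panel$conflict))
})

test_that("default panels look like the study panel", {
  sim <- get_small_sim(18, 13, seed = 42)
  p <- sim$panel
  expect_identical(attr(p, "n_regions"), 18L)
  expect_identical(attr(p, "n_periods"), 156L)
  expect_identical(nrow(p), 2808L)
  z <- mean(p$conflict == 0)
  expect_gt(z, 0.3); expect_lt(z, 0.9)
  expect_gt(max(p$conflict), 10)  # occasional large counts
  # DL is exactly the run-length transform of TA in every region
  for (r in unique(p$region)) {
    expect_identical(p$DL[p$region == r],
                     drought_length(p$TA[p$region == r]))
  }
  # spatial correlation of anomalies decays with distance
  D <- sim$geometry$distances
  TA_mat <- matrix(p$TA, ncol = 18)  # periods x regions (region-major sort)
  C <- cor(TA_mat)
  near <- D < 300 & upper.tri(D)
  far <- D > 900 & upper.tri(D)
  expect_gt(mean(C[near]), mean(C[far]))
})

test_that("the dispersion limit is Poisson when theta is huge", {
  cfg <- synthetic_config(
    n_regions = 18, n_years = 13, theta = 1e6,
    hypermeans = c(alpha0 = 0, gamma0 = 0, delta0 = 0, phi0 = 0.5),
    tau = c(1e-8, 1e-8, 1e-8, 1e-8), eta = c(0, 0, 0),
    psi = c(0, 0, 0, 0), sigma_w = 1e-8, confounding_strength = 0,
    seed = 13)
  sim <- simulate_panel(cfg)
  y <- sim$panel$conflict
  expect_equal(var(y) / mean(y), 1, tolerance = 0.05)
  expect_equal(mean(y), exp(0.5), tolerance = 0.05)
})

test_that("realized coefficients follow the configured covariance", {
  cfg <- synthetic_config(n_regions = 800, n_years = 1,
                          confounding_strength = 0, seed = 99)
  sim <- simulate_panel(cfg)
  co <- sim$truth$coefficients
  emp_sd <- apply(co, 2, sd)
  expect_equal(unname(emp_sd), cfg$tau, tolerance = 0.1)
  emp_corr <- cor(co)
  expect_lt(max(abs(emp_corr - cfg$Omega)), 0.12)
  expect_equal(unname(colMeans(co)), unname(cfg$hypermeans),
               tolerance = 0.15)
})

test_that("the zero share decreases as the baseline rate rises", {
  zs <- vapply(c(-2, -0.5, 1), function(phi0) {
    hm <- c(alpha0 = 0.1, gamma0 = 0.05, delta0 = -0.05, phi0 = phi0)
    sim <- simulate_panel(synthetic_config(n_regions = 10, n_years = 5,
                                           hypermeans = hm, seed = 55))
    mean(sim$panel$conflict == 0)
  }, numeric(1))
  expect_true(all(diff(zs) < 0))
})

test_that("confounding biases the naive pooled slope but not the corrected one", {
  # frequentist surrogate of the within-between contrast. All arms control
  # for the common period drivers (period-mean climate and the forcing,
  # the known inputs of the generator's period-effect level model), so the
  # remaining bias channel is the region-level confounding between the
  # baselines and region-mean TA. The naive arm pools region baselines
  # into one intercept; the corrected arm adds the region-mean covariates.
  err_naive <- err_corr <- numeric(12)
  for (r in seq_len(12)) {
    cfg <- synthetic_config(n_regions = 30, n_years = 3, seed = 500 + r)
    sim <- simulate_panel(cfg)
    pan <- as.data.frame(add_group_means(sim$panel))
    fc <- climate_forcing(sim$panel, "PA", "mean_deviation")
    pan$C_t <- fc$C[match(pan$period, attr(sim$panel, "periods"))]
    base <- "conflict ~ TA + DL + PA + TA_bar_t + DL_bar_t + C_t"
    naive <- suppressWarnings(MASS::glm.nb(as.formula(base), data = pan))
    corr <- suppressWarnings(MASS::glm.nb(
      as.formula(paste(base, "+ TA_bar_i + DL_bar_i + PA_bar_i")),
      data = pan))
    a0 <- cfg$hypermeans[["alpha0"]]
    err_naive[r] <- coef(naive)[["TA"]] - a0
    err_corr[r] <- coef(corr)[["TA"]] - a0
  }
  expect_gt(abs(mean(err_naive)), 0.15)       # bias well away from alpha0
  expect_lt(abs(mean(err_corr)), 0.10)        # corrected bias near zero
  expect_gt(abs(mean(err_naive)), 2 * abs(mean(err_corr)))
})

test_that("scenario shifts act per region and keep DL consistent", {
  sim <- get_small_sim()
  p0 <- scenario_shift(sim$panel, "TA", 0)
  expect_equal(p0$TA, sim$panel$TA)
  expect_identical(p0$conflict, sim$panel$conflict)

  p1 <- scenario_shift(sim$panel, "TA", 1)
  sds <- tapply(sim$panel$TA, sim$panel$region, sd)
  shift_obs <- tapply(p1$TA - sim$panel$TA, p1$region, mean)
  expect_equal(unname(shift_obs), unname(sds), tolerance = 1e-10)
  for (r in unique(p1$region)) {
    expect_identical(p1$DL[p1$region == r],
                     drought_length(p1$TA[p1$region == r]))
  }
  p_dn <- scenario_shift(sim$panel, "TA", -5)  # flips signs: DL collapses
  expect_lt(sum(p_dn$DL), sum(sim$panel$DL))
  expect_error(scenario_shift(sim$panel, "conflict", 1), "unknown scenario")
})
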