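test_that("log-likelihood matches hand-computed Gaussian residual sums", {
  # two survival points with known residuals, sigma = 0.1
  ds <- dose_response(c(2, 4), exp(-c(0.5, 1.3)), endpoint = "survival")
  theta <- c(alpha0 = 0.2, beta0 = 0.02)
  pred <- 0.2 * c(2, 4) + 0.02 * c(2, 4)^2     # acute, photon
  resid <- c(0.5, 1.3) - pred
  by_hand <- sum(-log(sqrt(2 * pi) * 0.1) - resid^2 / (2 * 0.1^2))
  expect_equal(log_likelihood(ds, theta, sigma = 0.1), by_hand,
               tolerance = 1e-12)
  # perfect fit leaves only the normalization
  ds2 <- dose_response(c(2, 4), exp(-pred), endpoint = "survival")
  expect_equal(log_likelihood(ds2, theta, sigma = 0.1),
               2 * (-log(sqrt(2 * pi) * 0.1)), tolerance = 1e-10)
  expect_error(log_likelihood(ds, theta, sigma = -1), "config error")
})

test_that("chains are bit-reproducible under a fixed seed", {
  ds <- simulate_survival_dataset(params_hsg(), doses = 0:8,
    noise = noise_model("lognormal_s", 0.15, replicates = 3, seed = 3))
  cfg <- fit_config(n_burn = 100, n_samples = 300, seed = 99)
  f1 <- mcmc_fit(ds, cfg)
  f2 <- mcmc_fit(ds, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$acceptance_rate, f2$acceptance_rate)
  f3 <- mcmc_fit(ds, fit_config(n_burn = 100, n_samples = 300, seed = 100))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a flat likelihood returns the prior", {
  ds <- simulate_survival_dataset(params_hsg(), doses = 0:8,
    noise = noise_model("lognormal_s", 0.15, replicates = 3, seed = 3))
  cfg <- fit_config(n_burn = 200, n_samples = 5000, seed = 7,
                    proposal = "independence", sigma = 1e6)
  fit <- mcmc_fit(ds, cfg)
  m <- colMeans(fit$draws)
  expect_equal(m[["alpha0"]], 1, tolerance = 0.05)      # prior midpoint
  expect_equal(m[["beta0"]], 0.25, tolerance = 0.02)
  expect_true(all(fit$draws[, "alpha0"] >= 0 & fit$draws[, "alpha0"] <= 2))
})

test_that("noiseless data concentrate the posterior on the truth", {
  truth <- params_hsg()
  ds <- simulate_survival_dataset(truth, doses = 0:8,
                                  noise = noise_model("lognormal_s", 0))
  fit <- mcmc_fit(ds, fit_config(n_burn = 2000, n_samples = 8000, seed = 5,
                                 proposal = "walk", sigma = 0.01))
  m <- colMeans(fit$draws)
  expect_equal(m[["alpha0"]], truth$alpha0, tolerance = 0.01)
  expect_equal(m[["beta0"]], truth$beta0, tolerance = 0.01)
})

test_that("acute-only fits do not sample the repair rate; protracted fits do", {
  ds <- simulate_survival_dataset(params_hsg(), doses = 0:8,
    noise = noise_model("lognormal_s", 0.15, replicates = 3, seed = 3))
  fit <- mcmc_fit(ds, fit_config(n_burn = 200, n_samples = 300, seed = 1))
  expect_false("a_plus_c" %in% colnames(fit$draws))
  dsp <- simulate_survival_dataset(params_hsg(),
    schedule = continuous_schedule(4, 2), doses = 4,
    noise = noise_model("lognormal_s", 0.15, replicates = 3, seed = 3))
  fitp <- mcmc_fit(list(ds, dsp),
                   fit_config(n_burn = 400, n_samples = 400, seed = 1,
                              proposal = "walk"))
  expect_true("a_plus_c" %in% colnames(fitp$draws))
  fitf <- mcmc_fit(list(ds, dsp),
                   fit_config(n_burn = 400, n_samples = 400, seed = 1,
                              proposal = "walk", a_plus_c = 2.19))
  expect_false("a_plus_c" %in% colnames(fitf$draws))
})

test_that("h estimation is exact on proportional data and calibrated with noise", {
  exact <- simulate_survival_mn_pairs(h = 0.275, n = 30, cv = 0)
  wls <- estimate_h(exact, method = "wls")
  expect_equal(wls$mean, 0.275, tolerance = 1e-12)
  fit <- estimate_h(exact, fit_config(n_burn = 500, n_samples = 4000, seed = 2,
                                      sigma = 1e-4))
  expect_equal(fit$mean, 0.275, tolerance = 1e-3)
  noisy <- simulate_survival_mn_pairs(h = 0.275, n = 50, cv = 0.10, seed = 9)
  fitn <- estimate_h(noisy, fit_config(seed = 2))
  expect_lt(abs(fitn$mean - 0.275), 2 * fitn$sd)
  expect_error(estimate_h(data.frame(w = c(0, 0), mn = c(0, 0))),
               "degenerate-data")
})

test_that("grouped h fits recover distinct per-group values", {
  g1 <- simulate_survival_mn_pairs(h = 0.365, n = 40, cv = 0.08, seed = 21)
  g2 <- simulate_survival_mn_pairs(h = 0.196, n = 40, cv = 0.08, seed = 22)
  h1 <- estimate_h(g1, fit_config(seed = 3))
  h2 <- estimate_h(g2, fit_config(seed = 3))
  expect_lt(abs(h1$mean - 0.365), 3 * h1$sd)
  expect_lt(abs(h2$mean - 0.196), 3 * h2$sd)
  expect_gt(h1$mean, h2$mean)
})

test_that("domain-radius calibration recovers the generating radius", {
  truth <- params_hsg()
  geom_true <- domain_geometry(r_d = 0.42)
  lets <- c(13, 46, 80, 100)
  dss <- lapply(lets, function(l) {
    sp <- generate_spectrum("ion", l, width = 0.25)
    q <- quality_from_spectrum(sp, geom_true)
    simulate_survival_dataset(truth, quality = q, doses = 0:6,
      noise = noise_model("lognormal_s", 0.05, replicates = 3,
                          seed = 400 + l))
    })
  for (k in seq_along(dss)) dss[[k]]$spectrum <-
    generate_spectrum("ion", lets[k], width = 0.25)
  grid <- seq(0.30, 0.54, by = 0.04)
  cal <- calibrate_rd(dss, list(alpha0 = 0.150, beta0 = 0.0467), grid)
  expect_equal(cal$r_d, 0.42, tolerance = 1e-12)
  expect_equal(nrow(cal$profile), length(grid))
  expect_error(calibrate_rd(dss, list(alpha0 = 0.1, beta0 = 0.05),
                            numeric(0)), "config error")
})

test_that("photon-only data leave the radius unidentified", {
  sp <- generate_spectrum("photon", 0.3, width = 0.4)
  q <- quality_from_spectrum(sp, domain_geometry(0.42))
  ds <- simulate_survival_dataset(params_hsg(), quality = q, doses = 0:8,
                                  noise = noise_model("lognormal_s", 0))
  ds$spectrum <- sp
  # low-LET z1D* is ~0.1 Gy; residuals barely move across the grid
  expect_warning(
    cal <- calibrate_rd(list(ds), list(alpha0 = 0.150, beta0 = 0.0467),
                        seq(0.30, 0.60, by = 0.05)),
    "flat|identifiable")
})

test_that("credible bands nest and collapse for degenerate posteriors", {
  ds <- simulate_survival_dataset(params_hsg(), doses = 0:8,
    noise = noise_model("lognormal_s", 0.15, replicates = 3, seed = 3))
  fit <- mcmc_fit(ds, fit_config(n_burn = 300, n_samples = 2000, seed = 5,
                                 proposal = "walk"))
  doses <- c(2, 4, 6)
  fn <- function(th) th[["alpha0"]] * doses + th[["beta0"]] * doses^2
  b68 <- propagate_uncertainty(fit, fn, 0.68)
  b95 <- propagate_uncertainty(fit, fn, 0.95)
  expect_true(all(b95$lower <= b68$lower))
  expect_true(all(b95$upper >= b68$upper))
  expect_true(all(b68$lower <= b68$mean & b68$mean <= b68$upper))
  degen <- fit
  degen$draws <- matrix(rep(c(0.15, 0.05, -2), each = 100), 100, 3,
                        dimnames = list(NULL, colnames(fit$draws)))
  b <- propagate_uncertainty(degen, fn, 0.68)
  expect_equal(b$lower, b$upper, tolerance = 1e-12)
})

test_that("R^2 matches arithmetic", {
  obs <- c(1, 2, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  pred <- c(1.1, 1.8, 4.3)
  expect_equal(r_squared(obs, pred),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  expect_error(r_squared(c(1, 1), c(1, 2)), "undefined-R2")
})

test_that("a hopeless sampler configuration raises a diagnostics error", {
  ds <- simulate_survival_dataset(params_hsg(), doses = 0:8,
                                  noise = noise_model("lognormal_s", 0))
  expect_error(
    mcmc_fit(ds, fit_config(n_burn = 5, n_samples = 20, seed = 1,
                            proposal = "walk", adapt = FALSE,
                            walk_scale = 1e12, sigma = 1e-6)),
    "diagnostics error")
})
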