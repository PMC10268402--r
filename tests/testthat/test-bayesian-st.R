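short_spec <- function(..., seed = 1) {
  bst_model_spec(..., n_iterations = 1500, n_burnin = 500, thin = 2,
                 seed = seed)
}

test_that("Geweke diagnostic behaves on constant, stationary and drifting chains", {
  expect_warning(z0 <- geweke_z(rep(3, 100)), "zero-variance")
  expect_equal(as.numeric(z0), 0)

  hits <- vapply(1:100, function(seed) {
    chain <- withr::with_seed(seed, stats::rnorm(5000))
    abs(geweke_z(chain)) < 1.96
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # a deterministic drift is flagged far beyond the 1.96 criterion even
  # though the AR-spectral errors are inflated by the near-unit-root fit
  expect_gt(abs(geweke_z(as.numeric(1:5000))), 2 * 1.96)
  expect_error(geweke_z(stats::rnorm(10)), "too short")
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  sc <- synthetic_scenario(n_regions = 9, n_years = 5, lattice = "grid",
                           seed = 3)
  panel <- generate_panel(sc)
  w <- generate_adjacency(9, "grid")
  spec <- short_spec("epr", covariates = "nhtp", seed = 12)
  f1 <- fit_bst(panel, w, spec)
  f2 <- fit_bst(panel, w, spec)
  expect_identical(f1$draws, f2$draws)
})

test_that("stored draws satisfy the sum-to-zero centring invariants", {
  sc <- synthetic_scenario(n_regions = 9, n_years = 5, lattice = "grid",
                           seed = 5)
  panel <- generate_panel(sc)
  w <- generate_adjacency(9, "grid")
  fit <- fit_bst(panel, w, short_spec("epr", seed = 2))
  expect_lt(max(abs(rowSums(fit$draws$phi))), 1e-8)
  expect_lt(max(abs(rowSums(fit$draws$Phi))), 1e-8)
  year_sums <- apply(fit$draws$delta, c(1, 3), sum)
  expect_lt(max(abs(year_sums)), 1e-8)
})

test_that("a null panel yields spatial effects and relative levels near one", {
  w <- generate_adjacency(16, "grid")
  for (seed in 1:5) {
    sc <- synthetic_scenario(n_regions = 16, n_years = 6, lattice = "grid",
                             beta = c(0, 0, 0), tau_spatial = 0,
                             tau_temporal = 0, trend = 0.02,
                             tau_interaction = 0, sigma_obs = 0.01,
                             cov_tau_spatial = 0, cov_sigma = 0.01,
                             seed = seed)
    panel <- generate_panel(sc, w)
    fit <- fit_bst(panel, w, short_spec("epr", seed = seed))
    expect_lt(max(abs(colMeans(fit$draws$phi))), 0.02)
    rel <- spatial_relative_level(fit, "pooled")
    expect_true(all(rel > 0.95 & rel < 1.05))
    expect_equal(exp(mean(log(rel))), 1, tolerance = 1e-6)
  }
})

test_that("pooled and year-specific relative levels agree without interaction", {
  w <- generate_adjacency(9, "grid")
  sc <- synthetic_scenario(n_regions = 9, n_years = 6, lattice = "grid",
                           tau_spatial = 0.3, tau_interaction = 0,
                           sigma_obs = 0.01, seed = 21)
  panel <- generate_panel(sc, w)
  fit <- fit_bst(panel, w, short_spec("epr", seed = 4))
  pooled <- spatial_relative_level(fit, "pooled")
  yearly <- spatial_relative_level(fit, 2014)
  expect_equal(pooled, yearly, tolerance = 0.01)
  expect_error(spatial_relative_level(fit, 1999), "outside")
})

test_that("relative_risk transforms injected draws exactly", {
  sc <- synthetic_scenario(n_regions = 6, n_years = 4, seed = 2)
  panel <- generate_panel(sc)
  w <- generate_adjacency(6, "grid")
  fit <- fit_bst(panel, w, short_spec("epr", covariates = "nhtp", seed = 2))

  # constant injected draw: point is the exponential, zero-width interval
  fit$draws$beta[, 1] <- log(1.041) * fit$x_scale[1]
  rr <- relative_risk(fit, "nhtp")
  expect_equal(unname(rr["point"]), 1.041, tolerance = 1e-12)
  expect_equal(unname(rr["ci_high"] - rr["ci_low"]), 0)

  # per-unit rescaling contract
  rr2 <- relative_risk(fit, 1, per = 2)
  expect_equal(unname(rr2["point"]), 1.041^2, tolerance = 1e-12)

  # symmetric draws straddle 1
  fit$draws$beta[, 1] <- withr::with_seed(9, stats::rnorm(nrow(fit$draws$beta),
                                                          0, 0.01))
  rr3 <- relative_risk(fit, 1)
  expect_equal(unname(rr3["point"]), 1, tolerance = 0.02)
  expect_true(rr3["ci_low"] < 1 && rr3["ci_high"] > 1)
  expect_error(relative_risk(fit, 5), "out of range")
})

test_that("injected spatial draws propagate to the relative level", {
  sc <- synthetic_scenario(n_regions = 6, n_years = 4, seed = 2)
  panel <- generate_panel(sc)
  w <- generate_adjacency(6, "grid")
  fit <- fit_bst(panel, w, short_spec("epr", seed = 2))
  fit$draws$phi[] <- 0
  fit$draws$phi[, 3] <- log(2)
  fit$draws$delta[] <- 0
  rel <- spatial_relative_level(fit, 2012)
  expect_equal(unname(rel[3]), 2, tolerance = 1e-12)
  expect_equal(unname(rel[1]), 1, tolerance = 1e-12)
})

test_that("posterior-mean parameters fit no worse than the prior mean", {
  sc <- synthetic_scenario(n_regions = 9, n_years = 5, lattice = "grid",
                           seed = 31)
  panel <- generate_panel(sc)
  w <- generate_adjacency(9, "grid")
  fit <- fit_bst(panel, w, short_spec("epr", covariates = "nhtp", seed = 7))
  ll_post <- bst_log_likelihood(fit)
  n <- length(fit$regions); t_len <- length(fit$years)
  ll_prior <- bst_log_likelihood(fit, beta0 = 0, beta = 0,
                                 phi = rep(0, n), Phi = rep(0, t_len),
                                 delta = matrix(0, n, t_len),
                                 sigma2 = mean(fit$draws$sigma2))
  expect_gte(ll_post, ll_prior)
})

test_that("a single fit recovers a strong known covariate effect", {
  w <- generate_adjacency(25, "grid")
  sc <- synthetic_scenario(n_regions = 25, n_years = 10, lattice = "grid",
                           beta = c(0, 0.01, 0.04), seed = 17)
  panel <- generate_panel(sc, w)
  spec <- bst_model_spec("epr", covariates = c("nhi", "nbhi", "nhtp"),
                         n_iterations = 4000, n_burnin = 1500, thin = 2,
                         seed = 17)
  fit <- fit_bst(panel, w, spec)
  beta_unit <- sweep(fit$draws$beta, 2, fit$x_scale, "/")
  ci <- apply(beta_unit, 2, stats::quantile, probs = c(0.025, 0.975))
  expect_true(ci[1, "nhtp"] <= 0.04 && ci[2, "nhtp"] >= 0.04)
  expect_gt(mean(beta_unit[, "nhtp"]), 0.01)  # clearly positive
})

test_that("model misuse is rejected", {
  sc <- synthetic_scenario(n_regions = 6, n_years = 4, seed = 2)
  panel <- generate_panel(sc)
  w <- generate_adjacency(6, "grid")
  expect_error(bst_model_spec("epr", n_iterations = 100, n_burnin = 200))
  expect_error(bst_model_spec("epr", rho_spatial = 1))
  expect_error(fit_bst(panel, generate_adjacency(8, "grid"),
                       short_spec("epr")), "match")
})
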