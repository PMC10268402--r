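test_that("odds ratios follow the elementwise ratio contract", {
  v <- c(0.8, 1.0, 1.3)
  expect_equal(compute_or(v, v), rep(1, 3))
  expect_equal(compute_or(c(2, 1), c(1, 1)), c(2, 1))
  expect_equal(compute_or(3 * v, v), rep(3, 3))
  expect_error(compute_or(c(1, -1), c(1, 1)), "positive")
  expect_error(compute_or(c(a = 1, b = 2), c(b = 1, a = 2)), "mismatch")
  expect_error(compute_or(c(1, 2), c(1, 2, 3)), "length")
})

test_that("the prior IAR is the stated weighted combination", {
  expect_equal(compute_iar_prior(1, 1, 1), 1)
  expect_equal(compute_iar_prior(1, 1, 2), 1.5)  # 0.25 + 0.25 + 1.0
  expect_equal(compute_iar_prior(0.8, 1.2, 1.0), 1.0)
  expect_equal(compute_iar_prior(2, 5, 9, p = 0, q = 0), 2)  # collapses to NHI
  expect_error(compute_iar_prior(1, 1, 1, p = 0.7, q = 0.5), "p \\+ q <= 1")
  # default effective weights: NHTP counts double
  expect_equal(compute_iar_prior(1, 0, 0), 0.25)
  expect_equal(compute_iar_prior(0, 1, 0), 0.25)
  expect_equal(compute_iar_prior(0, 0, 1), 0.50)
})

test_that("standardisation divides by the mean and is exactly mean-one", {
  expect_equal(standardize_iar(c(2, 1, 1)), c(1.5, 0.75, 0.75))
  expect_equal(standardize_iar(rep(0.7, 5)), rep(1, 5))
  expect_equal(standardize_iar(4.2), 1)
  expect_error(standardize_iar(numeric(0)), "empty")
  set.seed(3)
  for (rep in 1:20) {
    v <- stats::rlnorm(sample(3:31, 1))
    expect_equal(mean(standardize_iar(v)), 1, tolerance = 1e-12)
  }
})

test_that("sufficiency is boundary-inclusive at 1", {
  expect_true(classify_sufficiency(1.0))
  expect_false(classify_sufficiency(0.99))
  expect_identical(classify_sufficiency(standardize_iar(c(2, 1, 1))),
                   c(TRUE, FALSE, FALSE))
})

test_that("raising one resource odds ratio raises that region's prior IAR and rank", {
  set.seed(8)
  or_nhi <- stats::rlnorm(10, 0, 0.1)
  or_nbhi <- stats::rlnorm(10, 0, 0.1)
  or_nhtp <- stats::rlnorm(10, 0, 0.1)
  base_prior <- compute_iar_prior(or_nhi, or_nbhi, or_nhtp)
  base_rank <- rank(standardize_iar(base_prior))
  for (bump in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    up_nhi <- or_nhi; up_nbhi <- or_nbhi; up_nhtp <- or_nhtp
    up_nhi[4] <- up_nhi[4] + bump[1]
    up_nbhi[4] <- up_nbhi[4] + bump[2]
    up_nhtp[4] <- up_nhtp[4] + bump[3]
    up_prior <- compute_iar_prior(up_nhi, up_nbhi, up_nhtp)
    expect_gt(up_prior[4], base_prior[4])
    expect_equal(up_prior[-4], base_prior[-4])
    expect_gte(rank(standardize_iar(up_prior))[4], base_rank[4])
  }
})

test_that("the full pipeline on a null panel stays near one with mean exactly one", {
  w <- generate_adjacency(9, "grid")
  for (seed in 1:5) {
    sc <- synthetic_scenario(n_regions = 9, n_years = 5, lattice = "grid",
                             beta = c(0, 0, 0), tau_spatial = 0,
                             tau_temporal = 0, trend = 0.02,
                             tau_interaction = 0, sigma_obs = 0.01,
                             cov_tau_spatial = 0, cov_sigma = 0.01,
                             seed = seed)
    panel <- generate_panel(sc, w)
    tab <- suppressWarnings(iar_pipeline(
      panel, w, 2013,
      bst_model_spec("epr", n_iterations = 1500, n_burnin = 500, thin = 2,
                     seed = seed)))
    expect_true(all(tab$iar_st > 0.9 & tab$iar_st < 1.1))
    expect_equal(mean(tab$iar_st), 1, tolerance = 1e-12)
    expect_equal(attr(tab, "p"), 0.25)
  }
})

test_that("doubling one region's resources makes it the best-matched region", {
  w <- generate_adjacency(9, "grid")
  sc <- synthetic_scenario(n_regions = 9, n_years = 5, lattice = "grid",
                           beta = c(0, 0, 0), tau_spatial = 0.05,
                           tau_interaction = 0, sigma_obs = 0.01, seed = 44)
  panel <- generate_panel(sc, w)
  df <- as.data.frame(panel)
  boosted <- df$region_id == "R5"
  df$nhi[boosted] <- 2 * df$nhi[boosted]
  df$nbhi[boosted] <- 2 * df$nbhi[boosted]
  df$nhtp[boosted] <- 2 * df$nhtp[boosted]
  panel2 <- region_panel(df)
  tab <- suppressWarnings(iar_pipeline(
    panel2, w, 2013,
    bst_model_spec("epr", n_iterations = 2000, n_burnin = 800, thin = 2,
                   seed = 44)))
  expect_equal(tab$region_id[which.max(tab$iar_st)], "R5")
})

test_that("kernel density surfaces behave like weighted Gaussian mixtures", {
  coords <- cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  # all weight on one region: mode at the nearest grid cell
  surf <- iar_kernel_density(coords, c(0, 0, 1, 0), bandwidth = 0.3,
                             grid_size = 41)
  peak <- which(surf$z == max(surf$z), arr.ind = TRUE)
  expect_equal(surf$x[peak[1]], 0, tolerance = 0.05)
  expect_equal(surf$y[peak[2]], 1, tolerance = 0.05)

  # symmetric two-point layout: mirror symmetry of the surface
  surf2 <- iar_kernel_density(cbind(c(-1, 1), c(0, 0)), c(1, 1),
                              bandwidth = 0.5, grid_size = 51)
  expect_lt(max(abs(surf2$z - surf2$z[rev(seq_along(surf2$x)), ])), 1e-10)

  # linearity in the weights
  surf3 <- iar_kernel_density(coords, 2 * c(0, 0, 1, 0), bandwidth = 0.3,
                              grid_size = 41)
  expect_equal(surf3$z, 2 * surf$z, tolerance = 1e-12)

  # mass on the grid approximates the total weight
  cell <- diff(surf$x[1:2]) * diff(surf$y[1:2])
  expect_equal(sum(surf$z) * cell, 1, tolerance = 0.02)
  w4 <- c(0.5, 1, 2, 0.25)
  surf4 <- iar_kernel_density(coords, w4, bandwidth = "auto", grid_size = 81,
                              margin = 6)
  cell4 <- diff(surf4$x[1:2]) * diff(surf4$y[1:2])
  expect_equal(sum(surf4$z) * cell4, sum(w4), tolerance = 0.02)

  expect_error(iar_kernel_density(coords[1, , drop = FALSE], 1), "at least 2")
})
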