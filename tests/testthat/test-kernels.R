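test_that("closed-form kernels evaluate the log-normal analytically", {
  p <- ref_truth()
  req <- kernel_request(44.60, 1.72, include_species_effect = FALSE)
  k <- kernel_closed_form(p, req)
  expect_equal(unname(k$quantiles["q50"]), 6.83, tolerance = 1e-2)
  expect_equal(unname(k$quantiles["q90"]),
               unname(k$quantiles["q50"]) * exp(qnorm(0.9) * 0.558),
               tolerance = 1e-10)
  expect_equal(unname(k$quantiles["q90"]), 14.0, tolerance = 0.05)

  # cdf / quantile consistency
  expect_equal(stats::plnorm(k$quantiles["q90"], k$mu, k$s), 0.9,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(k$density >= 0))
  expect_true(!is.unsorted(k$cdf))

  # species effect widens the log-scale spread
  km <- kernel_closed_form(p, kernel_request(44.60, 1.72,
                                             include_species_effect = TRUE))
  expect_equal(km$s, sqrt(0.558^2 + 0.154^2), tolerance = 1e-12)
  expect_equal(km$quantiles[["q50"]], k$quantiles[["q50"]],
               tolerance = 1e-12)

  # degenerate scale: point mass at exp(mu)
  p0 <- model_parameters(0.517, 0.186, -0.036, 0.191, 0, 0)
  k0 <- kernel_closed_form(p0, kernel_request(10, 2,
                                              include_species_effect = TRUE))
  expect_equal(unname(k0$quantiles["q50"]), unname(k0$quantiles["q90"]))
})

test_that("kernel density integrates to one over a wide grid", {
  p <- ref_truth()
  for (iwl in c(1, 10, 50)) {
    k <- kernel_closed_form(p, kernel_request(iwl, 1.72))
    grid <- exp(seq(log(stats::qlnorm(0.001, k$mu, k$s)),
                    log(stats::qlnorm(0.999, k$mu, k$s)), length.out = 2048))
    kk <- kernel_closed_form(p, kernel_request(iwl, 1.72,
                                               distance_grid = grid))
    integral <- sum(diff(grid) * (kk$density[-1] + kk$density[-2048]) / 2)
    expect_gt(integral, 0.99)
    expect_lt(integral, 1.001)
  }
})

test_that("Monte-Carlo kernels converge to the closed form", {
  p <- ref_truth()
  req <- kernel_request(20, 3, n_draws = 20000L)
  mc <- kernel_monte_carlo(p, req, rng_seed = 4)
  cf <- kernel_closed_form(p, req)
  expect_lt(max(abs(mc$cdf - stats::plnorm(mc$distance_m, cf$mu, cf$s))),
            0.02)
  expect_equal(unname(mc$quantiles["q50"]), unname(cf$quantiles["q50"]),
               tolerance = 0.05)
  # determinism
  mc2 <- kernel_monte_carlo(p, req, rng_seed = 4)
  expect_identical(mc$draws, mc2$draws)
  # monotone effect of IWL
  lo <- kernel_monte_carlo(p, kernel_request(0, 5, n_draws = 5000L), 1)
  hi <- kernel_monte_carlo(p, kernel_request(50, 5, n_draws = 5000L), 1)
  expect_gt(hi$quantiles["q50"], lo$quantiles["q50"])
  expect_error(kernel_monte_carlo(p, kernel_request(1, 1, n_draws = 50L), 1),
               "n_draws")
})

test_that("bootstrap bands contain the point kernel and collapse when degenerate", {
  d <- toy_dataset(n_species = 10, n_per = 25, seed = 37)
  fit <- fit_lmm(build_design(d, "max"))
  boot <- bootstrap_lmm(fit, B = 60, base_seed = 5)
  req <- kernel_request(20, 1.72)
  kb <- kernel_bands(boot, req)
  expect_true(all(kb$band_lower <= kb$density + 1e-12))
  expect_true(all(kb$density <= kb$band_upper + 1e-12))
  expect_true(all(kb$quantile_bands[1, ] <= kb$quantiles + 1e-12))
  expect_true(all(kb$quantiles <= kb$quantile_bands[2, ] + 1e-12))

  # identical draws collapse onto the point kernel
  degen <- boot
  degen$draws <- matrix(rep(as.numeric(fit$params), each = 50), nrow = 50,
                        dimnames = list(NULL, colnames(boot$draws)))
  kd <- kernel_bands(degen, req)
  expect_equal(kd$band_lower, kd$density, tolerance = 1e-12)
  expect_equal(kd$band_upper, kd$density, tolerance = 1e-12)

  small <- boot
  small$draws <- boot$draws[1:10, ]
  expect_error(kernel_bands(small, req), "40")
})

test_that("high-IWL species have absolutely wider uncertainty bands", {
  d <- toy_dataset(n_species = 13, n_per = 40, seed = 41)
  fit <- fit_lmm(build_design(d, "max"))
  boot <- bootstrap_lmm(fit, B = 80, base_seed = 9)
  k_hi <- kernel_bands(boot, kernel_request(44.60, 1.72))
  k_lo <- kernel_bands(boot, kernel_request(1.97, 1.72))
  w_hi <- diff(k_hi$quantile_bands[, "q90"])
  w_lo <- diff(k_lo$quantile_bands[, "q90"])
  expect_gt(w_hi, w_lo)
})

test_that("kernel grid summary is monotone where the coefficient signs imply it", {
  p <- ref_truth()
  g <- kernel_grid(p, iwl_values = seq(1, 50, by = 7),
                   wind_values = c(1, 4, 10))
  # q50 increases with IWL at every wind
  for (w in unique(g$wind)) {
    expect_true(all(diff(g$q50[g$wind == w]) > 0))
  }
  # q50 increases with wind for IWL >= 1 (beta2 + beta3*log(iwl+1) > 0 there)
  for (iwl in unique(g$iwl)) {
    expect_true(all(diff(g$q50[g$iwl == iwl]) > 0))
  }
  # single cell equals the closed form
  g1 <- kernel_grid(p, 20, 3)
  k1 <- kernel_closed_form(p, kernel_request(20, 3))
  expect_equal(g1$q50, unname(k1$quantiles["q50"]), tolerance = 1e-12)

  # relative tail ratio q90/q50 is scale-invariant in IWL
  ratios <- g$q90 / g$q50
  expect_lt(diff(range(ratios)), 1e-9)
})

test_that("empirical summaries match order-statistic oracles", {
  d <- data.frame(species = rep("s", 5), distance_m = c(1, 2, 3, 4, 5))
  s <- empirical_summaries(d)
  expect_equal(s$median[1], 3)
  expect_equal(s$p90[1], 4.6)  # type-7 on n = 5
  expect_equal(s$min[1], 1)
  expect_equal(s$max[1], 5)

  one <- empirical_summaries(data.frame(species = "x", distance_m = 2.5))
  expect_equal(one$min[1], one$p90[1])

  d2 <- data.frame(species = rep(c("a", "b"), each = 3),
                   distance_m = c(1, 2, 3, 10, 20, 30))
  s2 <- empirical_summaries(d2)
  expect_equal(nrow(s2), 3)
  expect_equal(s2$species[3], "(pooled)")
  expect_equal(s2$n[3], 6)
})
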