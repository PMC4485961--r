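test_that("design matrix applies the +1 offsets and log transforms", {
  d <- data.frame(species = c("a", "b"), iwl_cm2_per_g = c(0, 44.60),
                  max_wind_ms = c(1.72, 1.72), mean_wind_ms = c(1, 1),
                  distance_m = c(2, 8))
  des <- build_design(d, "max")
  expect_equal(des$y, log(c(2, 8)))
  expect_equal(unname(des$X[1, ]), c(1, 0, log(2.72), 0))
  expect_equal(unname(des$X[2, ]),
               c(1, log(45.60), log(2.72), log(45.60) * log(2.72)))
  expect_equal(unname(des$X[2, 2]), 3.8200, tolerance = 1e-4)
  expect_equal(nlevels(des$group), 2)

  expect_error(build_design(d[0, ], "max"), "empty")
  d_bad <- d; d_bad$distance_m[1] <- 0
  expect_error(build_design(d_bad, "max"), "> 0")
  expect_error(build_design(d, "median"), "arg")
})

test_that("profiled REML fit matches the dense brute-force oracle", {
  for (seed in c(101, 202, 303)) {
    d <- toy_dataset(n_species = 6, n_per = 12, seed = seed)
    des <- build_design(d, "max")
    fit <- fit_lmm(des)
    oracle <- brute_force_fit(des$y, des$X, des$group)
    expect_lt(abs(fit$reml_criterion - oracle$criterion), 1e-6)
    expect_equal(unname(fit$params[1:4]), oracle$beta, tolerance = 1e-4)
    expect_lt(abs(fit$params["sigma_resid"] - oracle$sigma_resid), 1e-4)
    expect_lt(abs(fit$params["sigma_species"] - oracle$sigma_species), 1e-4)
  }
})

test_that("profiled fit agrees with lme4 on a full-size dataset", {
  skip_if_not_installed("lme4")
  sim <- generate_releases(default_generator_config(rng_seed = 42))
  fit <- fit_lmm(sim$dataset)
  d <- sim$dataset
  d$li <- log(d$iwl_cm2_per_g + 1)
  d$lw <- log(d$max_wind_ms + 1)
  m <- lme4::lmer(log(distance_m) ~ li * lw + (1 | species), data = d,
                  REML = TRUE)
  expect_equal(unname(fit$params[1:4]), unname(lme4::fixef(m)),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(unname(fit$params["sigma_species"]), vc$sdcor[1],
               tolerance = 1e-5)
  expect_equal(unname(fit$params["sigma_resid"]), vc$sdcor[2],
               tolerance = 1e-5)
  expect_equal(fit$reml_criterion, as.numeric(stats::logLik(m)),
               tolerance = 1e-6)
  expect_equal(sqrt(diag(fit$fixed_cov)),
               unname(summary(m)$coefficients[, "Std. Error"]),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("zero species variance reduces the fit to ordinary least squares", {
  # data whose species-mean deviations are removed entirely: the species
  # variance estimate must land on the boundary at zero
  truth0 <- model_parameters(0.517, 0.186, -0.036, 0.191, 0, 0.558)
  d <- toy_dataset(n_species = 10, n_per = 20, truth = truth0, seed = 77)
  li <- log(d$iwl_cm2_per_g + 1); lw <- log(d$max_wind_ms + 1)
  mu <- 0.517 + 0.186 * li - 0.036 * lw + 0.191 * li * lw
  eps <- log(d$distance_m) - mu
  eps <- eps - stats::ave(eps, d$species)  # no between-species signal left
  d$distance_m <- exp(mu + eps)
  des <- build_design(d, "max")
  fit <- fit_lmm(des)
  expect_lte(unname(fit$params["sigma_species"]), 1e-3)
  ols <- stats::lm.fit(des$X, des$y)$coefficients
  expect_equal(unname(fit$params[1:4]), unname(ols), tolerance = 1e-6)

  # profiled criterion at the boundary equals the ordinary-regression
  # REML criterion computed densely with sigma_s = 0
  expect_equal(fit$reml_criterion,
               dense_loglik(des$y, des$X, des$group, 0,
                            unname(fit$params["sigma_resid"])),
               tolerance = 1e-8)
})

test_that("single-species data remain fittable", {
  d <- toy_dataset(n_species = 1, n_per = 40, seed = 12)
  fit <- fit_lmm(build_design(d, "max"))
  expect_true(fit$converged)
  expect_equal(fit$n_species, 1)
  expect_true(is.finite(fit$reml_criterion))
})

test_that("AIC identity and ML/REML criteria are coherent", {
  d <- toy_dataset(seed = 31)
  fit_ml <- fit_lmm(build_design(d, "max"), method = "ML")
  expect_equal(fit_ml$aic_ml, -2 * fit_ml$loglik_ml + 12)
  # ML criterion also matches the dense oracle
  oracle <- brute_force_fit(build_design(d, "max")$y,
                            build_design(d, "max")$X,
                            build_design(d, "max")$group, method = "ML")
  expect_lt(abs(fit_ml$loglik_ml - oracle$criterion), 1e-6)
})

test_that("variance decomposition normalises and flags droppable terms", {
  vd <- variance_decomposition(c(species = 0.154, residual = 0.558))
  expect_equal(sum(vd$share), 1, tolerance = 1e-9)
  expect_equal(vd$share[vd$component == "species"],
               0.154^2 / (0.154^2 + 0.558^2), tolerance = 1e-12)
  expect_equal(vd$share[vd$component == "species"], 0.0708, tolerance = 1e-3)
  expect_false(any(vd$droppable))

  vd0 <- variance_decomposition(c(species = 0, mother_tree = 0.005,
                                  residual = 0.558))
  expect_equal(sum(vd0$share), 1, tolerance = 1e-9)
  expect_true(vd0$droppable[vd0$component == "species"])
  expect_true(vd0$droppable[vd0$component == "mother_tree"])
  expect_false(vd0$droppable[vd0$component == "residual"])
})

test_that("negligible extra random terms are detected for model reduction", {
  # three-term truth with near-zero mother-tree variance: the dense oracle
  # fit over (sigma_species, sigma_resid) absorbs it, and the fitted
  # species/residual decomposition flags nothing but a tiny injected term
  d <- toy_dataset(n_species = 8, n_per = 12, seed = 55)
  fit <- fit_lmm(build_design(d, "max"))
  sds <- c(species = unname(fit$params["sigma_species"]),
           mother_tree = 1e-4,  # scale of a term explaining <0.1% variance
           residual = unname(fit$params["sigma_resid"]))
  vd <- variance_decomposition(sds)
  expect_true(vd$droppable[vd$component == "mother_tree"])
  expect_lt(vd$share[vd$component == "mother_tree"], 0.001)
})

test_that("wind covariate selection recovers the generating covariate", {
  d <- toy_dataset(n_species = 13, n_per = 50, seed = 8)
  cmp <- compare_wind_covariates(d)
  expect_equal(cmp$selected, "max")
  expect_lt(cmp$aic_max, cmp$aic_mean)

  # identical wind columns give identical AICs
  d2 <- d; d2$mean_wind_ms <- d2$max_wind_ms
  cmp2 <- compare_wind_covariates(d2)
  expect_lt(abs(cmp2$aic_max - cmp2$aic_mean), 1e-6)

  # symmetric case: distances regenerated from mean wind select mean
  set.seed(99)
  truth <- ref_truth()
  li <- log(d$iwl_cm2_per_g + 1); lw <- log(d$mean_wind_ms + 1)
  n_sp <- length(unique(d$species))
  b <- rnorm(n_sp, 0, truth["sigma_species"])
  names(b) <- unique(d$species)
  d$distance_m <- exp(truth["beta0"] + truth["beta1"] * li +
                        truth["beta2"] * lw + truth["beta3"] * li * lw +
                        b[d$species] + rnorm(nrow(d), 0, truth["sigma_resid"]))
  expect_equal(compare_wind_covariates(d)$selected, "mean")
})

test_that("median distance predictions evaluate the back-transform", {
  p <- ref_truth()
  expect_equal(predict_median_distance(p, 0, 1.72),
               exp(0.517 - 0.036 * log(2.72)), tolerance = 1e-12)
  expect_equal(predict_median_distance(p, 0, 1.72), 1.618, tolerance = 1e-3)
  expect_equal(predict_median_distance(p, 44.60, 1.72), 6.83,
               tolerance = 1e-2)
  p0 <- model_parameters(0, 0, 0, 0, 0.1, 0.5)
  expect_equal(predict_median_distance(p0, 25, 7), 1)
  expect_error(predict_median_distance(p, -1, 1), ">= 0")

  # increasing in IWL whenever beta1 + beta3*log(wind+1) > 0
  for (w in c(0, 1.72, 10)) {
    med <- predict_median_distance(p, seq(0, 50, by = 5), w)
    expect_true(all(diff(med) > 0))
  }
})

test_that("fit serialises to JSON and back", {
  d <- toy_dataset(seed = 14)
  fit <- fit_lmm(build_design(d, "max"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$params$beta1, unname(fit$params["beta1"]))
  expect_equal(back$n_species, fit$n_species)
  expect_equal(unlist(back$fixed_cov), as.numeric(t(fit$fixed_cov)),
               tolerance = 1e-12, ignore_attr = TRUE)
})
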