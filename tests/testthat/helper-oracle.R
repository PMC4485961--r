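# Independent oracles and small-data helpers shared across tests.

# Dense-matrix (RE)ML log-likelihood of the Gaussian random-intercept model,
# evaluated directly from V = sigma_s^2 ZZ' + sigma_e^2 I. Deliberately
# naive (O(n^3)); independent of the package's profiled fit path.
dense_loglik <- function(y, X, group, sigma_s, sigma_e, method = "REML") {
  n <- length(y)
  p <- ncol(X)
  Z <- stats::model.matrix(~ 0 + factor(group))
  V <- sigma_s^2 * tcrossprod(Z) + diag(sigma_e^2, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (method == "REML") {
    ldA <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
    -0.5 * ((n - p) * log(2 * pi) + ldV + ldA + quad)
  } else {
    -0.5 * (n * log(2 * pi) + ldV + quad)
  }
}

# Brute-force maximizer of the dense criterion over (sigma_s, sigma_e):
# coarse grid then Nelder-Mead polish. The package's profiled fit must agree.
brute_force_fit <- function(y, X, group, method = "REML") {
  obj <- function(par) {
    -dense_loglik(y, X, group, abs(par[1]), abs(par[2]), method)
  }
  grid_s <- seq(0, 0.8, by = 0.08)
  grid_e <- seq(0.2, 1.2, by = 0.08)
  vals <- outer(grid_s, grid_e,
                Vectorize(function(s, e) obj(c(s, e))))
  idx <- arrayInd(which.min(vals), dim(vals))
  start <- c(grid_s[idx[1]], grid_e[idx[2]])
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 3000))
  Z <- stats::model.matrix(~ 0 + factor(group))
  sigma_s <- abs(opt$par[1]); sigma_e <- abs(opt$par[2])
  V <- sigma_s^2 * tcrossprod(Z) + diag(sigma_e^2, length(y))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(sigma_species = sigma_s, sigma_resid = sigma_e,
       beta = as.numeric(beta), criterion = -opt$value)
}

# Reference (published-style) generating parameters used throughout tests.
ref_truth <- function() {
  model_parameters(0.517, 0.186, -0.036, 0.191, 0.154, 0.558)
}

# Small synthetic release dataset built directly (bypasses the full
# morphology generator for speed): IWL uniform on [0, 45], max wind gamma.
toy_dataset <- function(n_species = 8, n_per = 15, truth = ref_truth(),
                        seed = 1L) {
  set.seed(seed)
  n <- n_species * n_per
  species <- rep(sprintf("sp%02d", seq_len(n_species)), each = n_per)
  iwl <- stats::runif(n, 0, 45)
  wmax <- stats::rgamma(n, shape = 1.2, scale = 1.72 / 1.2)
  wmean <- wmax * stats::runif(n, 0.3, 1)
  b <- stats::rnorm(n_species, 0, truth["sigma_species"])
  li <- log(iwl + 1); lw <- log(wmax + 1)
  mu <- truth["beta0"] + truth["beta1"] * li + truth["beta2"] * lw +
    truth["beta3"] * li * lw
  d <- exp(mu + b[rep(seq_len(n_species), each = n_per)] +
             stats::rnorm(n, 0, truth["sigma_resid"]))
  data.frame(fruit_id = sprintf("f%04d", seq_len(n)), species = species,
             iwl_cm2_per_g = iwl, max_wind_ms = wmax, mean_wind_ms = wmean,
             distance_m = as.numeric(d), stringsAsFactors = FALSE)
}

# Minimal bootstrap_draws object from a numeric vector, for testing the
# interval and p-value operations against hand-computable cases.
draws_object <- function(x, parameter = "beta1", point = stats::median(x)) {
  m <- matrix(rep(x, 6), ncol = 6,
              dimnames = list(NULL, c("beta0", "beta1", "beta2", "beta3",
                                      "sigma_species", "sigma_resid")))
  structure(list(draws = m, B = length(x), refit_failures = 0L,
                 base_seed = 0L,
                 point = stats::setNames(rep(point, 6), colnames(m))),
            class = "bootstrap_draws")
}
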