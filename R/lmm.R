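# Random-intercept linear mixed model of log dispersal distance.
#
# Model: log(d) = b0 + b1*log(IWL+1) + b2*log(U+1) + b3*log(IWL+1)*log(U+1)
#                 + b_species + eps,
# b_species ~ N(0, sigma_species^2), eps ~ N(0, sigma_resid^2).
#
# The fit profiles the (RE)ML criterion over the variance ratio
# lambda = sigma_species^2 / sigma_resid^2. For fixed lambda the marginal
# correlation matrix is Lambda = I + lambda * Z Z' whose inverse is block
# diagonal with blocks I - (lambda / (1 + lambda*n_j)) * 1 1' per species j;
# GLS estimates of beta and the profiled sigma_resid^2 are then closed form,
# and a one-dimensional bounded search over log(lambda) completes the fit
# (with the boundary lambda = 0 checked explicitly).

#' Build the response, fixed-effect design and grouping
#'
#' Response is `log(distance)`; fixed-effect columns are the intercept,
#' `log(IWL + 1)`, `log(wind + 1)` and the product of the two logged terms
#' (the +1 offsets accommodate zero IWL for wingless fruit and calm releases).
#'
#' @param dataset Data.frame with columns `species`, `iwl_cm2_per_g`,
#'   `distance_m` and the wind column selected by `wind_choice`
#'   (`max_wind_ms` or `mean_wind_ms`).
#' @param wind_choice `"max"` (default) or `"mean"`.
#' @return A list with `y` (response vector), `X` (n x 4 design matrix with
#'   columns `(Intercept), log_iwl1, log_wind1, log_iwl1:log_wind1`),
#'   `group` (factor of species) and `wind_choice`.
#' @export
build_design <- function(dataset, wind_choice = c("max", "mean")) {
  wind_choice <- match.arg(wind_choice)
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  wind_col <- paste0(wind_choice, "_wind_ms")
  need <- c("species", "iwl_cm2_per_g", "distance_m", wind_col)
  if (!all(need %in% names(dataset))) {
    stop("dataset is missing columns: ",
         paste(setdiff(need, names(dataset)), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(dataset$distance_m)) || any(dataset$distance_m <= 0)) {
    stop("all distances must be finite and > 0", call. = FALSE)
  }
  li <- log(dataset$iwl_cm2_per_g + 1)
  lw <- log(dataset[[wind_col]] + 1)
  X <- cbind(`(Intercept)` = 1, log_iwl1 = li, log_wind1 = lw,
             `log_iwl1:log_wind1` = li * lw)
  list(y = log(dataset$distance_m), X = X,
       group = factor(dataset$species), wind_choice = wind_choice)
}

# Precompute the sufficient statistics of a design that do not depend on the
# response, so bootstrap refits of the same design are cheap.
.lmm_design_struct <- function(X, group) {
  group <- as.factor(group)
  gi <- as.integer(group)
  list(X = X, group = group, gi = gi,
       n = nrow(X), p = ncol(X), q = nlevels(group),
       nj = as.numeric(tabulate(gi, nlevels(group))),
       XtX = crossprod(X),
       S = rowsum(X, gi))            # q x p per-group column sums of X
}

# Profiled criterion at variance ratio lambda for response statistics
# (Xty, yty, t = per-group sums of y). Returns criterion, beta, sigma2.
.lmm_profile_eval <- function(st, lambda, Xty, yty, t, method) {
  cj <- lambda / (1 + lambda * st$nj)
  A <- st$XtX - crossprod(st$S, st$S * cj)             # X' Lambda^-1 X
  bvec <- Xty - crossprod(st$S, cj * t)[, 1]           # X' Lambda^-1 y
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, backsolve(ch, bvec, transpose = TRUE))
  rWr <- max(yty - sum(cj * t^2) - sum(bvec * beta), 1e-300)
  logdet_lambda <- sum(log1p(lambda * st$nj))
  if (method == "REML") {
    df <- st$n - st$p
    sigma2 <- rWr / df
    crit <- -0.5 * (df * (log(2 * pi * sigma2) + 1) + logdet_lambda +
                      2 * sum(log(diag(ch))))
  } else {
    sigma2 <- rWr / st$n
    crit <- -0.5 * (st$n * (log(2 * pi * sigma2) + 1) + logdet_lambda)
  }
  list(crit = crit, beta = as.numeric(beta), sigma2 = sigma2, chol_A = ch)
}

# Core fit for a prebuilt design structure and response vector.
.lmm_fit_core <- function(st, y, method = c("REML", "ML")) {
  method <- match.arg(method)
  Xty <- crossprod(st$X, y)[, 1]
  yty <- sum(y * y)
  t <- rowsum(y, st$gi)[, 1]
  obj <- function(u) {
    ev <- .lmm_profile_eval(st, exp(u), Xty, yty, t, method)
    if (is.null(ev)) -Inf else ev$crit
  }
  opt <- stats::optimize(obj, interval = c(-12, 12), maximum = TRUE,
                         tol = 1e-10)
  at0 <- .lmm_profile_eval(st, 0, Xty, yty, t, method)
  if (is.null(at0)) stop("fixed-effect design is rank deficient", call. = FALSE)
  if (at0$crit >= opt$objective) {
    lambda <- 0
    ev <- at0
    crit <- at0$crit
  } else {
    lambda <- exp(opt$maximum)
    ev <- .lmm_profile_eval(st, lambda, Xty, yty, t, method)
    crit <- ev$crit
  }
  sigma_resid <- sqrt(ev$sigma2)
  sigma_species <- sqrt(lambda * ev$sigma2)
  fixed_cov <- ev$sigma2 * chol2inv(ev$chol_A)
  dimnames(fixed_cov) <- list(colnames(st$X), colnames(st$X))
  list(beta = stats::setNames(ev$beta, colnames(st$X)),
       sigma_species = sigma_species, sigma_resid = sigma_resid,
       lambda = lambda, criterion = crit, fixed_cov = fixed_cov,
       method = method)
}

# ML log-likelihood at the fitted parameters (for AIC) given a core fit.
.lmm_ml_loglik <- function(st, y) {
  .lmm_fit_core(st, y, method = "ML")$criterion
}

#' Fit the random-intercept dispersal model
#'
#' Maximises the REML (default) or ML criterion by profiling: closed-form GLS
#' for the fixed effects and residual variance at each value of the variance
#' ratio, with a bounded one-dimensional search over its logarithm and an
#' explicit check of the zero-variance boundary.
#'
#' @param design Output of [build_design()], or a dataset (in which case
#'   `wind_choice` is forwarded to [build_design()]).
#' @param method `"REML"` (default, for parameter reporting) or `"ML"` (for
#'   AIC comparison of models with different fixed effects).
#' @param wind_choice Used only when `design` is a dataset.
#' @return An object of class `dispersal_lmm`: `params`
#'   ([model_parameters()]), `fixed_cov` (4 x 4), `reml_criterion`,
#'   `loglik_ml`, `aic_ml` (`-2*loglik_ml + 2*6`), `n_obs`, `n_species`,
#'   `converged`, `method`, `design`.
#' @export
fit_lmm <- function(design, method = c("REML", "ML"),
                    wind_choice = c("max", "mean")) {
  method <- match.arg(method)
  if (is.data.frame(design)) {
    design <- build_design(design, match.arg(wind_choice))
  }
  if (length(design$y) < 2) stop("need at least 2 observations", call. = FALSE)
  st <- .lmm_design_struct(design$X, design$group)
  if (qr(design$X)$rank < ncol(design$X)) {
    stop("fixed-effect design is rank deficient", call. = FALSE)
  }
  core <- .lmm_fit_core(st, design$y, method)
  loglik_ml <- if (method == "ML") core$criterion else .lmm_ml_loglik(st, design$y)
  params <- model_parameters(core$beta[1], core$beta[2], core$beta[3],
                             core$beta[4], core$sigma_species,
                             core$sigma_resid)
  structure(list(
    params = params,
    fixed_cov = core$fixed_cov,
    reml_criterion = if (method == "REML") core$criterion else
      .lmm_fit_core(st, design$y, "REML")$criterion,
    loglik_ml = loglik_ml,
    aic_ml = -2 * loglik_ml + 2 * 6,
    n_obs = st$n, n_species = st$q,
    converged = TRUE, method = method,
    design = design, .struct = st
  ), class = "dispersal_lmm")
}

#' @export
print.dispersal_lmm <- function(x, ...) {
  cat("Random-intercept dispersal model (", x$method, " fit)\n", sep = "")
  cat("  n =", x$n_obs, "releases,", x$n_species, "species\n")
  est <- x$params[1:4]
  se <- sqrt(diag(x$fixed_cov))
  tab <- data.frame(Estimate = as.numeric(est), `Std.Error` = se,
                    row.names = colnames(x$design$X), check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("  sigma_species = %.4f   sigma_resid = %.4f\n",
              x$params["sigma_species"], x$params["sigma_resid"]))
  cat(sprintf("  REML criterion = %.3f   AIC (ML) = %.2f\n",
              x$reml_criterion, x$aic_ml))
  invisible(x)
}

#' Decompose total random variance into per-component shares
#'
#' Each component's share is its variance over the summed variance of all
#' random terms plus the residual. Components whose share is below the
#' `droppable_below` threshold are flagged: in model reduction, random terms
#' explaining a vanishing share of total variance are removed.
#'
#' @param fit A `dispersal_lmm` fit, or a named numeric vector of standard
#'   deviations (one element per random term plus a `sigma_resid`-style
#'   residual entry).
#' @param droppable_below Share threshold for the droppable flag
#'   (default 0.001, i.e. 0.1% of total variance).
#' @return A data.frame with columns `component`, `sd`, `variance`, `share`,
#'   `droppable`; shares sum to one.
#' @export
variance_decomposition <- function(fit, droppable_below = 0.001) {
  sds <- if (inherits(fit, "dispersal_lmm")) {
    if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
    c(species = unname(fit$params["sigma_species"]),
      residual = unname(fit$params["sigma_resid"]))
  } else {
    if (!is.numeric(fit) || is.null(names(fit))) {
      stop("fit must be a dispersal_lmm or a named numeric vector of SDs",
           call. = FALSE)
    }
    fit
  }
  v <- sds^2
  share <- v / sum(v)
  out <- data.frame(component = names(sds), sd = as.numeric(sds),
                    variance = as.numeric(v), share = as.numeric(share),
                    stringsAsFactors = FALSE)
  out$droppable <- out$share < droppable_below & out$component != "residual"
  out
}

#' Compare maximum- vs mean-wind covariates by AIC
#'
#' Fits the dispersal model twice by ML, once with the maximum and once with
#' the mean wind speed per release, and selects the covariate with the lower
#' AIC. ML (not REML) is used because the two models differ in their fixed
#' effects.
#'
#' @param dataset A release dataset containing both `max_wind_ms` and
#'   `mean_wind_ms`.
#' @return A list with `aic_max`, `aic_mean`, `delta_aic`
#'   (`aic_mean - aic_max`) and `selected` (`"max"` or `"mean"`).
#' @export
compare_wind_covariates <- function(dataset) {
  if (!all(c("max_wind_ms", "mean_wind_ms") %in% names(dataset))) {
    stop("dataset must contain max_wind_ms and mean_wind_ms", call. = FALSE)
  }
  f_max <- fit_lmm(build_design(dataset, "max"), method = "ML")
  f_mean <- fit_lmm(build_design(dataset, "mean"), method = "ML")
  list(aic_max = f_max$aic_ml, aic_mean = f_mean$aic_ml,
       delta_aic = f_mean$aic_ml - f_max$aic_ml,
       selected = if (f_max$aic_ml <= f_mean$aic_ml) "max" else "mean")
}

#' Median predicted dispersal distance
#'
#' Back-transforms the linear predictor: because the model is log-normal with
#' a zero-median random effect, `exp(mu)` is the median (not the mean) of the
#' marginal distance distribution.
#'
#' @param params [model_parameters()] (or a `dispersal_lmm` fit).
#' @param iwl Inverse wing loading, cm^2/g (>= 0; vectorised).
#' @param wind Wind speed, m/s (>= 0; vectorised).
#' @return Median distance in metres.
#' @examples
#' p <- model_parameters(0.517, 0.186, -0.036, 0.191, 0.154, 0.558)
#' predict_median_distance(p, iwl = 44.6, wind = 1.72) # ~ 6.83 m
#' @export
predict_median_distance <- function(params, iwl, wind) {
  if (inherits(params, "dispersal_lmm")) params <- params$params
  if (any(iwl < 0) || any(wind < 0)) {
    stop("iwl and wind must be >= 0", call. = FALSE)
  }
  li <- log(iwl + 1)
  lw <- log(wind + 1)
  as.numeric(exp(params["beta0"] + params["beta1"] * li +
                   params["beta2"] * lw + params["beta3"] * li * lw))
}

#' Write a fitted model to JSON
#'
#' @param fit A `dispersal_lmm`.
#' @param path Output path (`fit.json`).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    params = as.list(unclass(fit$params)),
    fixed_cov = unname(fit$fixed_cov),
    reml_criterion = fit$reml_criterion,
    loglik_ml = fit$loglik_ml,
    aic_ml = fit$aic_ml,
    n_obs = fit$n_obs,
    n_species = fit$n_species,
    converged = fit$converged,
    method = fit$method
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
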