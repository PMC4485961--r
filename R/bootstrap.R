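# Parametric bootstrap for the dispersal mixed model.
#
# New responses are simulated from the fitted model (fresh species intercepts
# and residuals around X beta-hat), the model is refit, and the B resampled
# parameter vectors give percentile confidence intervals and approximate
# two-sided p-values from tail counts.

#' Simulate a response vector from a fitted model
#'
#' Draws fresh species intercepts `~ N(0, sigma_species^2)` and residuals
#' `~ N(0, sigma_resid^2)` and returns `X beta + Z b* + eps*` on the
#' fitted design.
#'
#' @param fit A converged `dispersal_lmm`.
#' @param rng_seed Integer seed.
#' @return Numeric response vector of length `n_obs` (log-distance scale).
#' @export
simulate_response <- function(fit, rng_seed = 1L) {
  if (!inherits(fit, "dispersal_lmm") || !isTRUE(fit$converged)) {
    stop("fit must be a converged dispersal_lmm", call. = FALSE)
  }
  set.seed(as.integer(rng_seed))
  st <- fit$.struct
  mu <- as.numeric(st$X %*% fit$params[1:4])
  b <- stats::rnorm(st$q, 0, fit$params["sigma_species"])
  eps <- stats::rnorm(st$n, 0, fit$params["sigma_resid"])
  mu + b[st$gi] + eps
}

#' Parametric bootstrap of the dispersal model
#'
#' Runs `B` independent simulate-then-refit cycles. Each replicate uses a seed
#' derived deterministically from `base_seed`, so the full draw table is
#' reproducible. Replicates whose refit fails are counted and dropped.
#'
#' @param fit A converged `dispersal_lmm`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param base_seed Integer seed for the whole bootstrap.
#' @return An object of class `bootstrap_draws`: `draws` (retained x 6 matrix
#'   with columns `beta0..beta3, sigma_species, sigma_resid`), `B`,
#'   `refit_failures`, `base_seed`, `point` (the original parameter vector).
#' @export
bootstrap_lmm <- function(fit, B = 1000, base_seed = 1L) {
  if (!inherits(fit, "dispersal_lmm")) {
    stop("fit must be a dispersal_lmm", call. = FALSE)
  }
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  st <- fit$.struct
  base_seed <- as.integer(base_seed)
  draws <- matrix(NA_real_, B, 6,
                  dimnames = list(NULL, c("beta0", "beta1", "beta2", "beta3",
                                          "sigma_species", "sigma_resid")))
  ok <- logical(B)
  for (i in seq_len(B)) {
    y_star <- simulate_response(fit, rng_seed = (base_seed + 104729L * i) %%
                                  2147483647L)
    core <- tryCatch(.lmm_fit_core(st, y_star, fit$method),
                     error = function(e) NULL)
    if (!is.null(core)) {
      draws[i, ] <- c(core$beta, core$sigma_species, core$sigma_resid)
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("all bootstrap refits failed", call. = FALSE)
  structure(list(draws = draws[ok, , drop = FALSE], B = B,
                 refit_failures = sum(!ok), base_seed = base_seed,
                 point = fit$params),
            class = "bootstrap_draws")
}

#' @export
print.bootstrap_draws <- function(x, ...) {
  cat("Parametric bootstrap:", nrow(x$draws), "retained of", x$B,
      "replicates (", x$refit_failures, "refit failures )\n")
  print(round(t(apply(x$draws, 2, stats::quantile,
                      probs = c(0.025, 0.5, 0.975), type = 7)), 4))
  invisible(x)
}

#' Percentile confidence interval from bootstrap draws
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` of the
#' retained draws, with type-7 interpolation.
#'
#' @param boot A `bootstrap_draws` object.
#' @param parameter Column name (e.g. `"beta1"`).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A list with `parameter`, `point`, `lower`, `upper`, `level`,
#'   `degenerate` (TRUE when all draws coincide).
#' @export
percentile_interval <- function(boot, parameter, level = 0.95) {
  if (!inherits(boot, "bootstrap_draws")) {
    stop("boot must be a bootstrap_draws", call. = FALSE)
  }
  x <- boot$draws[, parameter]
  if (length(x) < 2) {
    stop("need at least 2 retained draws for an interval", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  qs <- stats::quantile(x, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 7, names = FALSE)
  list(parameter = parameter,
       point = unname(boot$point[parameter]),
       lower = qs[1], upper = qs[2], level = level,
       degenerate = qs[1] == qs[2])
}

#' Approximate two-sided bootstrap p-value
#'
#' Tail-count p-value: twice the smaller of the fractions of draws at or
#' below zero and at or above zero, floored at `1/B_retained` (a bootstrap
#' can never certify a p-value below the resolution of its draw count) and
#' capped at 1.
#'
#' @param boot A `bootstrap_draws` object.
#' @param parameter Column name.
#' @return p-value in `(0, 1]`.
#' @export
approx_p_value <- function(boot, parameter) {
  if (!inherits(boot, "bootstrap_draws")) {
    stop("boot must be a bootstrap_draws", call. = FALSE)
  }
  x <- boot$draws[, parameter]
  b <- length(x)
  p <- 2 * min(sum(x <= 0), sum(x >= 0)) / b
  min(max(p, 1 / b), 1)
}

#' Summarise a bootstrap into intervals and p-values, optionally to JSON
#'
#' @param boot A `bootstrap_draws` object.
#' @param level Confidence level (default 0.95).
#' @param path Optional path: when given, the draw table, intervals and
#'   p-values are written as JSON.
#' @return A data.frame with one row per fixed effect and variance parameter:
#'   `parameter`, `point`, `lower`, `upper`, `approx_p` (`NA` for the two
#'   variance parameters, which are not tested against zero this way).
#' @export
summarise_bootstrap <- function(boot, level = 0.95, path = NULL) {
  pars <- colnames(boot$draws)
  rows <- lapply(pars, function(p) {
    ci <- percentile_interval(boot, p, level)
    data.frame(parameter = p, point = ci$point, lower = ci$lower,
               upper = ci$upper,
               approx_p = if (startsWith(p, "beta")) approx_p_value(boot, p)
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    jsonlite::write_json(list(
      B = boot$B, refit_failures = boot$refit_failures,
      base_seed = boot$base_seed, level = level,
      draws = as.data.frame(boot$draws), summary = out
    ), path, auto_unbox = TRUE, digits = NA)
  }
  out
}
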