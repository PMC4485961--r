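# Dispersal kernels.
#
# Under the fitted model, distance for a given (IWL, wind) condition is
# log-normal with location mu = b0 + b1*log(IWL+1) + b2*log(U+1) +
# b3*log(IWL+1)*log(U+1) and scale sigma_resid (plus the species
# random-effect variance when predicting for an unobserved species).
# Kernels can be evaluated in closed form, by Monte Carlo, and with
# pointwise 95% confidence bands across bootstrap parameter draws.

#' Specify a kernel evaluation request
#'
#' @param iwl Inverse wing loading, cm^2/g (>= 0).
#' @param wind Wind speed, m/s (>= 0).
#' @param include_species_effect Add the species random-effect variance to
#'   the log-scale spread (marginal prediction for an unobserved species)?
#'   Default `TRUE`; set `FALSE` for a conditional within-species kernel.
#' @param n_draws Monte-Carlo draw count (used by [kernel_monte_carlo()]).
#' @param distance_grid Strictly increasing positive distances (m) on which
#'   density and cdf are evaluated; `NULL` for the default 512-point
#'   geometric grid from 0.05 m to 1.5 x the 99.9% quantile.
#' @return A `kernel_request` list.
#' @export
kernel_request <- function(iwl, wind, include_species_effect = TRUE,
                           n_draws = 10000L, distance_grid = NULL) {
  if (iwl < 0 || wind < 0) stop("iwl and wind must be >= 0", call. = FALSE)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (!is.null(distance_grid)) {
    if (any(distance_grid <= 0) || is.unsorted(distance_grid, strictly = TRUE)) {
      stop("distance_grid must be strictly increasing and > 0", call. = FALSE)
    }
  }
  structure(list(iwl = iwl, wind = wind,
                 include_species_effect = isTRUE(include_species_effect),
                 n_draws = as.integer(n_draws),
                 distance_grid = distance_grid),
            class = "kernel_request")
}

# Log-normal location and scale implied by parameters and a request.
.kernel_mu_s <- function(params, request) {
  if (inherits(params, "dispersal_lmm")) params <- params$params
  li <- log(request$iwl + 1)
  lw <- log(request$wind + 1)
  mu <- unname(params["beta0"] + params["beta1"] * li +
                 params["beta2"] * lw + params["beta3"] * li * lw)
  s2 <- unname(params["sigma_resid"]^2 +
                 if (request$include_species_effect)
                   params["sigma_species"]^2 else 0)
  list(mu = mu, s = sqrt(s2))
}

.default_grid <- function(mu, s) {
  upper <- 1.5 * stats::qlnorm(0.999, mu, max(s, 1e-8))
  upper <- max(upper, 0.1)
  exp(seq(log(0.05), log(upper), length.out = 512))
}

#' Closed-form log-normal dispersal kernel
#'
#' @param params [model_parameters()] or a `dispersal_lmm` fit.
#' @param request A [kernel_request()].
#' @return A `dispersal_kernel`: `request`, `distance_m`, `density` (per m),
#'   `cdf`, `quantiles` (`q05, q50, q90, q95` in m), `mu`, `s`, and
#'   `type = "closed_form"`.
#' @examples
#' p <- model_parameters(0.517, 0.186, -0.036, 0.191, 0.154, 0.558)
#' k <- kernel_closed_form(p, kernel_request(44.6, 1.72,
#'                                           include_species_effect = FALSE))
#' k$quantiles[["q50"]] # ~ 6.83 m
#' @export
kernel_closed_form <- function(params, request) {
  if (!inherits(request, "kernel_request")) {
    stop("request must be a kernel_request", call. = FALSE)
  }
  ms <- .kernel_mu_s(params, request)
  grid <- request$distance_grid
  if (is.null(grid)) grid <- .default_grid(ms$mu, ms$s)
  if (ms$s > 0) {
    dens <- stats::dlnorm(grid, ms$mu, ms$s)
    cdf <- stats::plnorm(grid, ms$mu, ms$s)
    qs <- stats::qlnorm(c(0.05, 0.5, 0.9, 0.95), ms$mu, ms$s)
  } else {
    # degenerate point mass at exp(mu)
    dens <- rep(0, length(grid))
    cdf <- as.numeric(grid >= exp(ms$mu))
    qs <- rep(exp(ms$mu), 4)
  }
  structure(list(request = request, distance_m = grid, density = dens,
                 cdf = cdf,
                 quantiles = stats::setNames(qs, c("q05", "q50", "q90", "q95")),
                 mu = ms$mu, s = ms$s, type = "closed_form"),
            class = "dispersal_kernel")
}

#' Monte-Carlo dispersal kernel
#'
#' Draws a species effect (when requested) and a residual per simulated
#' fruit, exponentiates, and estimates density (histogram on the grid bins),
#' cdf and empirical type-7 quantiles. Converges to [kernel_closed_form()]
#' as `n_draws` grows.
#'
#' @param params [model_parameters()] or a `dispersal_lmm` fit.
#' @param request A [kernel_request()] with `n_draws >= 100`.
#' @param rng_seed Integer seed.
#' @return A `dispersal_kernel` with `type = "monte_carlo"` and the simulated
#'   `draws` attached.
#' @export
kernel_monte_carlo <- function(params, request, rng_seed = 1L) {
  if (!inherits(request, "kernel_request")) {
    stop("request must be a kernel_request", call. = FALSE)
  }
  if (request$n_draws < 100) {
    stop("n_draws must be >= 100 for density estimation", call. = FALSE)
  }
  if (inherits(params, "dispersal_lmm")) params <- params$params
  ms <- .kernel_mu_s(params, request)
  set.seed(as.integer(rng_seed))
  n <- request$n_draws
  b <- if (request$include_species_effect) {
    stats::rnorm(n, 0, params["sigma_species"])
  } else 0
  eps <- stats::rnorm(n, 0, params["sigma_resid"])
  draws <- exp(ms$mu + b + eps)
  grid <- request$distance_grid
  if (is.null(grid)) grid <- .default_grid(ms$mu, ms$s)
  cdf <- stats::ecdf(draws)(grid)
  # histogram density on grid-midpoint bins
  edges <- c(grid[1] - (grid[2] - grid[1]) / 2,
             (grid[-1] + grid[-length(grid)]) / 2,
             grid[length(grid)] + diff(grid[length(grid) - 1:0]) / 2)
  edges[1] <- max(edges[1], 0)
  bin <- findInterval(draws, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin[bin >= 1 & bin <= length(grid)], nbins = length(grid))
  dens <- counts / (n * diff(edges))
  qs <- stats::quantile(draws, c(0.05, 0.5, 0.9, 0.95), type = 7,
                        names = FALSE)
  structure(list(request = request, distance_m = grid, density = dens,
                 cdf = cdf,
                 quantiles = stats::setNames(qs, c("q05", "q50", "q90", "q95")),
                 mu = ms$mu, s = ms$s, type = "monte_carlo", draws = draws),
            class = "dispersal_kernel")
}

#' Bootstrap confidence bands around a dispersal kernel
#'
#' Evaluates the closed-form kernel at each bootstrap parameter draw and
#' takes pointwise 2.5% and 97.5% percentiles of density (and of each
#' quantile) across draws.
#'
#' @param boot A `bootstrap_draws` with at least 40 retained draws.
#' @param request A [kernel_request()].
#' @param params Optional point parameters (default: the bootstrap's original
#'   fit parameters) for the central kernel.
#' @return A `dispersal_kernel` with extra fields `band_lower`, `band_upper`
#'   (density envelope per grid point) and `quantile_bands` (2 x 4 matrix of
#'   2.5/97.5 percentiles of `q05, q50, q90, q95`).
#' @export
kernel_bands <- function(boot, request, params = NULL) {
  if (!inherits(boot, "bootstrap_draws")) {
    stop("boot must be a bootstrap_draws", call. = FALSE)
  }
  if (nrow(boot$draws) < 40) {
    stop("need at least 40 retained draws for 95% bands", call. = FALSE)
  }
  if (is.null(params)) params <- boot$point
  point <- kernel_closed_form(params, request)
  grid <- point$distance_m
  req_on_grid <- request
  req_on_grid$distance_grid <- grid
  per_draw <- apply(boot$draws, 1, function(row) {
    k <- kernel_closed_form(model_parameters(row[1], row[2], row[3], row[4],
                                             row[5], row[6]), req_on_grid)
    c(k$density, k$quantiles)
  })
  ng <- length(grid)
  dens_mat <- per_draw[seq_len(ng), , drop = FALSE]
  q_mat <- per_draw[ng + 1:4, , drop = FALSE]
  point$band_lower <- unname(apply(dens_mat, 1, stats::quantile, 0.025,
                                   type = 7, names = FALSE))
  point$band_upper <- unname(apply(dens_mat, 1, stats::quantile, 0.975,
                                   type = 7, names = FALSE))
  point$quantile_bands <- apply(q_mat, 1, stats::quantile, c(0.025, 0.975),
                                type = 7)
  colnames(point$quantile_bands) <- c("q05", "q50", "q90", "q95")
  point$type <- "bootstrap_bands"
  point
}

#' Kernel summary over an IWL x wind grid
#'
#' Closed-form kernel quantiles for every combination of the supplied IWL and
#' wind values (e.g. IWL 1..50 by wind 1..10 m/s).
#'
#' @param params [model_parameters()] or a `dispersal_lmm` fit.
#' @param iwl_values Vector of IWL values, cm^2/g.
#' @param wind_values Vector of wind speeds, m/s.
#' @param include_species_effect Passed to [kernel_request()].
#' @return A data.frame with columns `iwl, wind, q05, q50, q90, q95` (m),
#'   one row per grid cell.
#' @export
kernel_grid <- function(params, iwl_values = 1:50, wind_values = 1:10,
                        include_species_effect = TRUE) {
  if (length(iwl_values) == 0 || length(wind_values) == 0) {
    stop("iwl_values and wind_values must be non-empty", call. = FALSE)
  }
  cells <- expand.grid(iwl = iwl_values, wind = wind_values,
                       KEEP.OUT.ATTRS = FALSE)
  qs <- t(vapply(seq_len(nrow(cells)), function(i) {
    kernel_closed_form(params,
                       kernel_request(cells$iwl[i], cells$wind[i],
                                      include_species_effect))$quantiles
  }, numeric(4)))
  cbind(cells, as.data.frame(qs))
}

#' Per-species and pooled empirical distance summaries
#'
#' Order statistics (minimum, maximum, median, 90th percentile; type-7
#' quantiles) of observed dispersal distance per species, plus a pooled row
#' over all releases.
#'
#' @param dataset Release data.frame with columns `species` and `distance_m`.
#' @return A data.frame with columns `species, n, min, max, median, p90`;
#'   the final row (`species = "(pooled)"`) summarises all observations.
#' @export
empirical_summaries <- function(dataset) {
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  one <- function(x, label) {
    data.frame(species = label, n = length(x), min = min(x), max = max(x),
               median = stats::quantile(x, 0.5, type = 7, names = FALSE),
               p90 = stats::quantile(x, 0.9, type = 7, names = FALSE),
               stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(split(dataset$distance_m, dataset$species),
                               one, label = ""))
  per$species <- names(split(dataset$distance_m, dataset$species))
  rbind(per, one(dataset$distance_m, "(pooled)"))
}

#' Write kernel grid outputs to disk
#'
#' Writes one `kernel_iwl<i>_wind<w>.csv` (`distance_m,density,cdf`) per grid
#' cell plus `kernel_summary.csv` (`iwl,wind,q05,q50,q90,q95`).
#'
#' @param params [model_parameters()] or `dispersal_lmm` fit.
#' @param iwl_values,wind_values Grid values.
#' @param dir Output directory.
#' @param include_species_effect Passed through.
#' @return Path of the summary CSV, invisibly.
#' @export
write_kernel_grid <- function(params, iwl_values, wind_values, dir,
                              include_species_effect = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (iwl in iwl_values) {
    for (w in wind_values) {
      k <- kernel_closed_form(params,
                              kernel_request(iwl, w, include_species_effect))
      utils::write.csv(data.frame(distance_m = k$distance_m,
                                  density = k$density, cdf = k$cdf),
                       file.path(dir, sprintf("kernel_iwl%g_wind%g.csv",
                                              iwl, w)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  summ <- kernel_grid(params, iwl_values, wind_values, include_species_effect)
  path <- file.path(dir, "kernel_summary.csv")
  utils::write.csv(summ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
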