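# Ballistic comparison model.
#
# The classical ballistic model of wind dispersal: a fruit released from
# height H falls at its terminal velocity V_t and is carried laterally by a
# constant wind U, so horizontal distance d = U * H / V_t. For gyrating
# winged fruit, V_t scales linearly with the square root of wing loading
# (weight per wing area), V_t = a + b * sqrt(WL). When the regression
# coefficients (a, b) are not available directly they can be recovered from
# any two species with known sqrt(WL) and published ballistic distance.

#' Ballistic model parameters
#'
#' @param vt_intercept Intercept `a` of the terminal-velocity line, m/s.
#' @param vt_slope Slope `b`, m/s per (mdyn/cm^2)^(1/2).
#' @param release_height Release height `H`, m (> 0; default 30).
#' @param wind_speed Lateral wind speed `U`, m/s (>= 0; default 1.72).
#' @return A `ballistic_params` list.
#' @export
ballistic_params <- function(vt_intercept, vt_slope,
                             release_height = 30, wind_speed = 1.72) {
  if (!is.finite(release_height) || release_height <= 0) {
    stop("release_height must be > 0", call. = FALSE)
  }
  if (!is.finite(wind_speed) || wind_speed < 0) {
    stop("wind_speed must be >= 0", call. = FALSE)
  }
  structure(list(vt_intercept = vt_intercept, vt_slope = vt_slope,
                 release_height = release_height, wind_speed = wind_speed),
            class = "ballistic_params")
}

#' Terminal velocity from square-root wing loading
#'
#' `V_t = a + b * sqrt_wl`. Errors when the line predicts a non-positive
#' descent rate (out of the calibration's valid range).
#'
#' @param params A [ballistic_params()].
#' @param sqrt_wl Square-root wing loading, (mdyn/cm^2)^(1/2) (> 0;
#'   vectorised).
#' @return Terminal velocity in m/s.
#' @export
terminal_velocity <- function(params, sqrt_wl) {
  if (any(!is.finite(sqrt_wl)) || any(sqrt_wl <= 0)) {
    stop("sqrt_wl must be finite and > 0", call. = FALSE)
  }
  vt <- params$vt_intercept + params$vt_slope * sqrt_wl
  if (any(vt <= 0)) {
    stop("calibrated terminal velocity is non-positive at the requested ",
         "sqrt wing loading (outside calibration range)", call. = FALSE)
  }
  vt
}

#' Ballistic dispersal distance
#'
#' `d = U * H / V_t`: fall duration `H / V_t` times constant lateral wind.
#'
#' @param params A [ballistic_params()].
#' @param vt Terminal velocity, m/s (> 0; vectorised).
#' @return Distance in m.
#' @export
ballistic_distance <- function(params, vt) {
  if (any(!is.finite(vt)) || any(vt <= 0)) {
    stop("vt must be finite and > 0", call. = FALSE)
  }
  params$wind_speed * params$release_height / vt
}

#' Calibrate the terminal-velocity line from published distances
#'
#' Each anchor row gives a species' square-root wing loading and its
#' published ballistic distance at known (U, H); the implied terminal
#' velocity is `U * H / d`. With two anchors the line is solved exactly, with
#' more it is fit by least squares. Calibration diagnostics (maximum absolute
#' distance residual over the anchors) are stored.
#'
#' @param anchors Data.frame with columns `sqrt_wl` and `distance` (two or
#'   more rows with distinct `sqrt_wl`).
#' @param wind_speed `U` in m/s.
#' @param release_height `H` in m.
#' @return A [ballistic_params()] with an extra `calibration` element
#'   (`n_anchors`, `max_abs_residual_m`).
#' @export
calibrate_from_anchors <- function(anchors, wind_speed = 1.72,
                                   release_height = 30) {
  if (nrow(anchors) < 2) stop("need at least 2 anchors", call. = FALSE)
  if (length(unique(anchors$sqrt_wl)) < 2) {
    stop("anchors must have distinct sqrt_wl values", call. = FALSE)
  }
  vt <- wind_speed * release_height / anchors$distance
  if (nrow(anchors) == 2) {
    b <- diff(vt) / diff(anchors$sqrt_wl)
    a <- vt[1] - b * anchors$sqrt_wl[1]
  } else {
    co <- stats::coef(stats::lm(vt ~ sqrt_wl, data = cbind(anchors, vt = vt)))
    a <- unname(co[1]); b <- unname(co[2])
  }
  params <- ballistic_params(a, b, release_height, wind_speed)
  pred <- ballistic_distance(params, terminal_velocity(params, anchors$sqrt_wl))
  params$calibration <- list(n_anchors = nrow(anchors),
                             max_abs_residual_m = max(abs(pred - anchors$distance)))
  params
}

#' Side-by-side comparison of mixed-model and ballistic predictions
#'
#' For each species emits the median distance from the dispersal mixed model
#' (a marginal prediction at the species' mean IWL), the ballistic distance
#' via the terminal-velocity line, and their ratio. The ballistic column is
#' `NA` for wingless species, whose wing loading diverges.
#'
#' @param params_lmm [model_parameters()] or a `dispersal_lmm` fit.
#' @param ballistic A [ballistic_params()] (typically from
#'   [calibrate_from_anchors()]).
#' @param species_rows Data.frame with columns `species`, `mean_iwl` and
#'   optionally `sqrt_wl` (published per-fruit-averaged values; when absent
#'   or `NA`, the closed-form transform of `mean_iwl` is used).
#' @return A data.frame `species, mean_iwl, sqrt_wl, lmm_median_m,
#'   ballistic_m, ratio_ballistic_over_lmm`.
#' @export
comparison_table <- function(params_lmm, ballistic, species_rows) {
  if (!all(c("species", "mean_iwl") %in% names(species_rows))) {
    stop("species_rows needs columns species and mean_iwl", call. = FALSE)
  }
  swl <- if ("sqrt_wl" %in% names(species_rows)) species_rows$sqrt_wl
         else rep(NA_real_, nrow(species_rows))
  fallback <- is.na(swl) & species_rows$mean_iwl > 0
  swl[fallback] <-
    iwl_to_sqrt_wing_loading(species_rows$mean_iwl[fallback])$sqrt_wing_loading
  lmm_med <- predict_median_distance(params_lmm, species_rows$mean_iwl,
                                     ballistic$wind_speed)
  bal <- rep(NA_real_, nrow(species_rows))
  winged <- species_rows$mean_iwl > 0 & !is.na(swl) & swl > 0
  if (any(winged)) {
    bal[winged] <- ballistic_distance(
      ballistic, terminal_velocity(ballistic, swl[winged]))
  }
  data.frame(species = species_rows$species,
             mean_iwl = species_rows$mean_iwl,
             sqrt_wl = ifelse(species_rows$mean_iwl > 0, swl, NA_real_),
             lmm_median_m = lmm_med,
             ballistic_m = bal,
             ratio_ballistic_over_lmm = bal / lmm_med,
             stringsAsFactors = FALSE)
}
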