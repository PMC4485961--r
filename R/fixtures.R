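# Packaged reference tables and the default generator configuration.
#
# Three small CSVs ship with the package: per-species fruit morphology and
# empirical dispersal summaries for the 13 dipterocarp species of the 30-m
# tower release study; the mixed-model parameter estimates with bootstrap
# intervals and approximate p-values; and the per-species predicted-distance
# comparison (mixed-model median vs ballistic model) including published
# square-root wing-loading values. They drive the demo pipeline, the default
# synthetic generator, and the ballistic calibration.

.FIXTURE_MD5 <- c(
  species_morphology.csv = "3fc3eb82e520f200a4fcb62539a28998",
  lmm_estimates.csv = "89de1818541f6f3816260eeb17a49bf5",
  predicted_distances.csv = "b6fec41c530d73bfff209a0c0d925eb0"
)

#' Load the packaged reference tables
#'
#' Reads the three packaged CSVs (species morphology and dispersal summaries;
#' mixed-model estimates; predicted-distance comparison), verifying their
#' checksums.
#'
#' @return A list with data.frames `species` (13 rows), `estimates` (6 rows:
#'   four fixed effects and two SDs) and `predicted` (13 rows), plus scalars
#'   `release_height_m` (30) and `mean_max_wind_ms` (1.72).
#' @export
load_fixtures <- function() {
  read_checked <- function(fname) {
    path <- system.file("extdata", fname, package = "gyrokernels",
                        mustWork = TRUE)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(.FIXTURE_MD5[fname]))) {
      stop("packaged fixture ", fname, " failed its checksum (",
           md5, ")", call. = FALSE)
    }
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  list(species = read_checked("species_morphology.csv"),
       estimates = read_checked("lmm_estimates.csv"),
       predicted = read_checked("predicted_distances.csv"),
       release_height_m = 30,
       mean_max_wind_ms = 1.72)
}

#' Mixed-model parameters from the packaged estimates table
#'
#' @return A [model_parameters()] vector (beta0 = 0.517, beta1 = 0.186,
#'   beta2 = -0.036, beta3 = 0.191, sigma_species = 0.154,
#'   sigma_resid = 0.558).
#' @export
reference_parameters <- function() {
  est <- load_fixtures()$estimates
  g <- function(p) est$estimate[est$parameter == p]
  model_parameters(g("beta0"), g("beta1"), g("beta2"), g("beta3"),
                   g("sigma_species"), g("sigma_resid"))
}

#' Default synthetic-experiment configuration
#'
#' Builds a [generator_config()] emulating the tower release study: the 13
#' species of the packaged morphology table with their fruit counts, per-fruit
#' IWL spread reconstructed from the tabulated standard errors
#' (`sd = SE * sqrt(n)`), mass coefficient of variation likewise, maximum
#' wind speeds with mean 1.72 m/s truncated at 10.5 m/s, and the packaged
#' mixed-model estimates as generating truth.
#'
#' @param rng_seed Integer seed.
#' @param wind_shape Gamma shape of the maximum-wind distribution
#'   (default 1.2, right-skewed).
#' @return A [generator_config()].
#' @export
default_generator_config <- function(rng_seed = 1L, wind_shape = 1.2) {
  fx <- load_fixtures()
  sp <- fx$species
  profiles <- lapply(seq_len(nrow(sp)), function(i) {
    n <- sp$n_fruit[i]
    mass_sd <- sp$se_mass_g[i] * sqrt(n)
    species_profile(
      name = sp$species[i],
      genus_rule = sp$genus_rule[i],
      mean_iwl = sp$mean_iwl_cm2_per_g[i],
      iwl_sd = sp$se_iwl_cm2_per_g[i] * sqrt(n),
      mean_mass = sp$mean_mass_g[i],
      mass_cv = mass_sd / sp$mean_mass_g[i],
      n_fruit = n
    )
  })
  generator_config(profiles, truth = reference_parameters(),
                   wind_mean_max = fx$mean_max_wind_ms, wind_max_cap = 10.5,
                   wind_shape = wind_shape, rng_seed = rng_seed)
}

#' Default ballistic calibration from the packaged comparison table
#'
#' Calibrates the terminal-velocity line from the two extreme-wing-loading
#' anchor species (Shorea seminis and Shorea argentifolia) of the packaged
#' predicted-distance table.
#'
#' @param wind_speed,release_height Conditions of the published comparison
#'   (defaults 1.72 m/s and 30 m).
#' @param anchor_species Character vector of two or more species used as
#'   calibration anchors.
#' @return A [ballistic_params()] from [calibrate_from_anchors()].
#' @export
default_ballistic_calibration <- function(wind_speed = 1.72,
                                          release_height = 30,
                                          anchor_species = c("Shorea seminis",
                                                             "Shorea argentifolia")) {
  pred <- load_fixtures()$predicted
  rows <- pred[pred$species %in% anchor_species, ]
  if (nrow(rows) < 2) stop("unknown anchor species", call. = FALSE)
  calibrate_from_anchors(
    data.frame(sqrt_wl = rows$sqrt_wl, distance = rows$ballistic_m),
    wind_speed = wind_speed, release_height = release_height)
}
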