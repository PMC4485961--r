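# Synthetic release-experiment generator.
#
# Emulates a canopy-tower release study: per-species fruit morphology with
# realistic per-fruit spread, right-skewed maximum wind speeds, and dispersal
# distances drawn from the log-normal random-intercept model the analysis
# assumes. Everything is reproducible from an integer seed, so the downstream
# fitting, bootstrap and kernel stages are testable without field data.

#' Define a species profile for the generator
#'
#' @param name Species label.
#' @param genus_rule Wing-area rule: `"two_winged"`, `"shorea_five_winged"`
#'   or `"wingless"`.
#' @param mean_iwl Mean inverse wing loading, cm^2/g (0 for wingless).
#' @param iwl_sd Per-fruit standard deviation of IWL, cm^2/g. Published
#'   species tables typically report standard errors of the mean; convert
#'   with `SE * sqrt(n)` before passing.
#' @param mean_mass Median fruit mass, g.
#' @param mass_cv Coefficient of variation of fruit mass (dimensionless).
#' @param n_fruit Number of fruits released for this species.
#' @return A `species_profile` list.
#' @export
species_profile <- function(name, genus_rule, mean_iwl, iwl_sd,
                            mean_mass, mass_cv, n_fruit) {
  genus_rule <- match.arg(genus_rule, .GENUS_RULES)
  num <- c(mean_iwl = mean_iwl, iwl_sd = iwl_sd, mean_mass = mean_mass,
           mass_cv = mass_cv, n_fruit = n_fruit)
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("invalid species profile '", name,
         "': parameters must be finite and non-negative", call. = FALSE)
  }
  if (mean_mass <= 0) stop("mean_mass must be > 0", call. = FALSE)
  if (n_fruit < 1) stop("n_fruit must be >= 1", call. = FALSE)
  if (genus_rule == "wingless" && (mean_iwl != 0 || iwl_sd != 0)) {
    stop("wingless profiles must have mean_iwl = 0 and iwl_sd = 0",
         call. = FALSE)
  }
  structure(list(name = name, genus_rule = genus_rule, mean_iwl = mean_iwl,
                 iwl_sd = iwl_sd, mean_mass = mean_mass, mass_cv = mass_cv,
                 n_fruit = as.integer(n_fruit)),
            class = "species_profile")
}

#' Model parameters of the dispersal mixed model
#'
#' Fixed effects are on the natural-log metre scale:
#' `log(distance) = beta0 + beta1*log(IWL + 1) + beta2*log(U + 1) +
#' beta3*log(IWL + 1)*log(U + 1) + b_species + eps`,
#' with `b_species ~ N(0, sigma_species^2)` and `eps ~ N(0, sigma_resid^2)`.
#'
#' @param beta0,beta1,beta2,beta3 Fixed-effect coefficients.
#' @param sigma_species Species random-intercept SD (>= 0).
#' @param sigma_resid Residual SD (> 0 for a stochastic model; 0 allowed for
#'   noise-free deterministic generation).
#' @return A named numeric vector of class `model_parameters`.
#' @export
model_parameters <- function(beta0, beta1, beta2, beta3,
                             sigma_species, sigma_resid) {
  p <- c(beta0 = unname(beta0), beta1 = unname(beta1), beta2 = unname(beta2),
         beta3 = unname(beta3), sigma_species = unname(sigma_species),
         sigma_resid = unname(sigma_resid))
  if (any(!is.finite(p))) stop("model parameters must be finite", call. = FALSE)
  if (sigma_species < 0 || sigma_resid < 0) {
    stop("variance parameters must be >= 0", call. = FALSE)
  }
  structure(p, class = "model_parameters")
}

#' Configuration for the release-experiment generator
#'
#' @param species_profiles List of [species_profile()] objects.
#' @param wind_mean_max Mean of the per-release maximum wind speed, m/s.
#' @param wind_max_cap Upper truncation of maximum wind speed, m/s.
#' @param wind_shape Gamma shape of the maximum-wind distribution; small
#'   values give a heavy right tail.
#' @param truth [model_parameters()] generating the distances.
#' @param rng_seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(species_profiles, truth,
                             wind_mean_max = 1.72, wind_max_cap = 10.5,
                             wind_shape = 1.2, rng_seed = 1L) {
  if (length(species_profiles) == 0) {
    stop("species_profiles must be non-empty", call. = FALSE)
  }
  if (!all(vapply(species_profiles, inherits, logical(1), "species_profile"))) {
    stop("species_profiles must be a list of species_profile objects",
         call. = FALSE)
  }
  if (!inherits(truth, "model_parameters")) {
    stop("truth must be a model_parameters object", call. = FALSE)
  }
  if (wind_mean_max <= 0 || wind_shape <= 0) {
    stop("wind_mean_max and wind_shape must be > 0", call. = FALSE)
  }
  if (wind_max_cap <= wind_mean_max) {
    stop("wind_max_cap must exceed wind_mean_max", call. = FALSE)
  }
  structure(list(species_profiles = species_profiles, truth = truth,
                 wind_mean_max = wind_mean_max, wind_max_cap = wind_max_cap,
                 wind_shape = wind_shape, rng_seed = as.integer(rng_seed)),
            class = "generator_config")
}

# Back-solve rectangular wing dimensions so the genus rule returns `area`
# exactly: a fixed aspect ratio (width = length/4) and, for the Shorea rule,
# a 55/45 split between longest and shortest long wing.
.wing_dims_for_area <- function(genus_rule, area) {
  if (genus_rule == "wingless" || area == 0) {
    return(list(lengths = numeric(0), widths = numeric(0)))
  }
  rect <- function(a) list(L = sqrt(2 * a), W = sqrt(a / 2))
  if (genus_rule == "two_winged") {
    a <- area / 2
    r <- rect(a)
    list(lengths = c(r$L, r$L), widths = c(r$W, r$W))
  } else { # shorea_five_winged: (a1 + a2) * 1.5 = area
    a1 <- (area / 1.5) * 0.55
    a2 <- (area / 1.5) * 0.45
    r1 <- rect(a1); r2 <- rect(a2)
    list(lengths = c(r1$L, r2$L), widths = c(r1$W, r2$W))
  }
}

#' Generate per-fruit morphology for one species
#'
#' Per-fruit IWL is drawn from a normal truncated at zero (negative draws are
#' rejected and redrawn) with mean `mean_iwl` and SD `iwl_sd`; mass is
#' log-normal with median `mean_mass` and coefficient of variation `mass_cv`.
#' Wing dimensions are back-solved so that [compute_wing_area()] applied to
#' them reproduces the drawn IWL exactly.
#'
#' @param profile A [species_profile()].
#' @param rng_seed Integer seed.
#' @return A data.frame with columns `fruit_id, species, genus_rule,
#'   wing_lengths_cm, wing_widths_cm, mass_g, wing_area_cm2, iwl_cm2_per_g`.
#' @export
generate_fruit <- function(profile, rng_seed = 1L) {
  if (!inherits(profile, "species_profile")) {
    stop("profile must be a species_profile", call. = FALSE)
  }
  set.seed(as.integer(rng_seed))
  n <- profile$n_fruit
  if (profile$iwl_sd > 0) {
    iwl <- stats::rnorm(n, profile$mean_iwl, profile$iwl_sd)
    bad <- which(iwl < 0)
    while (length(bad) > 0) {
      iwl[bad] <- stats::rnorm(length(bad), profile$mean_iwl, profile$iwl_sd)
      bad <- bad[iwl[bad] < 0]
    }
  } else {
    iwl <- rep(profile$mean_iwl, n)
  }
  sdlog <- sqrt(log(1 + profile$mass_cv^2))
  mass <- stats::rlnorm(n, meanlog = log(profile$mean_mass), sdlog = sdlog)
  area <- iwl * mass
  dims <- lapply(seq_len(n), function(i) {
    .wing_dims_for_area(profile$genus_rule, area[i])
  })
  fmt <- function(x) paste(formatC(x, digits = 17, format = "g"), collapse = ";")
  data.frame(
    fruit_id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "_", profile$name),
                       seq_len(n)),
    species = profile$name,
    genus_rule = profile$genus_rule,
    wing_lengths_cm = vapply(dims, function(d) fmt(d$lengths), character(1)),
    wing_widths_cm = vapply(dims, function(d) fmt(d$widths), character(1)),
    mass_g = mass,
    wing_area_cm2 = area,
    iwl_cm2_per_g = iwl,
    stringsAsFactors = FALSE
  )
}

#' Generate per-release wind summaries
#'
#' Maximum wind speed per release is gamma distributed (shape `wind_shape`,
#' scaled to mean `wind_mean_max`) and truncated at `wind_max_cap` by
#' redrawing; mean wind speed is the maximum times an independent uniform
#' fraction on (0.3, 1), so `mean_wind <= max_wind` always.
#'
#' @param n Number of releases.
#' @param wind_mean_max Target mean of maximum wind speed, m/s.
#' @param wind_shape Gamma shape (> 0); small values are right-skewed.
#' @param wind_max_cap Truncation cap, m/s (> `wind_mean_max`).
#' @param rng_seed Integer seed.
#' @return A data.frame with columns `max_wind_ms`, `mean_wind_ms`.
#' @export
generate_winds <- function(n, wind_mean_max = 1.72, wind_shape = 1.2,
                           wind_max_cap = 10.5, rng_seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (wind_max_cap <= wind_mean_max) {
    stop("wind_max_cap must exceed wind_mean_max", call. = FALSE)
  }
  if (wind_mean_max <= 0 || wind_shape <= 0) {
    stop("wind_mean_max and wind_shape must be > 0", call. = FALSE)
  }
  set.seed(as.integer(rng_seed))
  scale <- wind_mean_max / wind_shape
  mx <- stats::rgamma(n, shape = wind_shape, scale = scale)
  bad <- which(mx > wind_max_cap | mx <= 0)
  while (length(bad) > 0) {
    mx[bad] <- stats::rgamma(length(bad), shape = wind_shape, scale = scale)
    bad <- bad[mx[bad] > wind_max_cap | mx[bad] <= 0]
  }
  frac <- stats::runif(n, 0.3, 1.0)
  data.frame(max_wind_ms = mx, mean_wind_ms = mx * frac)
}

#' Generate a full synthetic release experiment
#'
#' For each species, draws fruit morphology and per-release winds, then
#' distances from the log-normal random-intercept model in `config$truth`:
#' one species intercept `b ~ N(0, sigma_species^2)` per species, one residual
#' per fruit. Identical `(config)` (including `rng_seed`) gives identical
#' output.
#'
#' @param config A [generator_config()].
#' @return A list with `dataset` (data.frame with columns `fruit_id, species,
#'   genus, mass_g, wing_area_cm2, iwl_cm2_per_g, max_wind_ms, mean_wind_ms,
#'   distance_m`) and `truth` (the generating [model_parameters()]).
#' @export
generate_releases <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("config must be a generator_config", call. = FALSE)
  }
  profiles <- config$species_profiles
  tr <- config$truth
  base <- as.integer(config$rng_seed)
  # distinct sub-seeds per stage/species, kept within 32-bit integer range
  sub_seed <- function(k) (base + 7919L * k) %% 2147483647L
  fruit <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    generate_fruit(profiles[[i]], rng_seed = sub_seed(i))
  }))
  n <- nrow(fruit)
  winds <- generate_winds(n, config$wind_mean_max, config$wind_shape,
                          config$wind_max_cap,
                          rng_seed = sub_seed(length(profiles) + 1L))
  set.seed(sub_seed(length(profiles) + 2L))
  b_species <- stats::rnorm(length(profiles), 0, tr["sigma_species"])
  names(b_species) <- vapply(profiles, `[[`, character(1), "name")
  eps <- stats::rnorm(n, 0, tr["sigma_resid"])
  li <- log(fruit$iwl_cm2_per_g + 1)
  lw <- log(winds$max_wind_ms + 1)
  mu <- tr["beta0"] + tr["beta1"] * li + tr["beta2"] * lw + tr["beta3"] * li * lw
  distance <- exp(mu + b_species[fruit$species] + eps)
  dataset <- data.frame(
    fruit_id = fruit$fruit_id,
    species = fruit$species,
    genus = fruit$genus_rule,
    mass_g = fruit$mass_g,
    wing_area_cm2 = fruit$wing_area_cm2,
    iwl_cm2_per_g = fruit$iwl_cm2_per_g,
    max_wind_ms = winds$max_wind_ms,
    mean_wind_ms = winds$mean_wind_ms,
    distance_m = as.numeric(distance),
    stringsAsFactors = FALSE
  )
  list(dataset = dataset, truth = tr)
}

#' Write a release dataset and its generating truth to disk
#'
#' Writes `releases.csv` (schema of [generate_releases()]) and `truth.json`
#' into `dir`. UTF-8, '.' decimal separator.
#'
#' @param sim Output of [generate_releases()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_releases <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "releases.csv")
  js <- file.path(dir, "truth.json")
  utils::write.csv(sim$dataset, csv, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(as.list(unclass(sim$truth)), js,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(releases = csv, truth = js))
}

#' Read a release dataset written by [write_releases()]
#'
#' @param path Path to `releases.csv`.
#' @return A data.frame in the [generate_releases()] dataset schema.
#' @export
read_releases_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fruit_id", "species", "iwl_cm2_per_g", "max_wind_ms",
            "mean_wind_ms", "distance_m")
  if (!all(need %in% names(d))) {
    stop("releases CSV is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  d
}
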