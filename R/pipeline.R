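# End-to-end pipeline: simulate -> fit -> bootstrap -> kernels -> ballistic.
#
# Every stochastic stage takes an explicit seed and every artifact is a CSV
# or JSON file, so a run is fully reproducible: identical configuration and
# seeds give byte-identical outputs, recorded as MD5 digests in the manifest.

.PIPELINE_DEFAULTS <- function() list(
  stages = c("simulate", "fit", "bootstrap", "kernels", "ballistic"),
  out_dir = ".",
  seed_simulate = 1L,
  seed_bootstrap = 2L,
  wind_choice = "max",
  method = "REML",
  B = 1000L,
  kernel_iwl = 1:50,
  kernel_wind = 1:10,
  include_species_effect = TRUE,
  ballistic_height = 30,
  ballistic_wind = 1.72,
  anchor_species = c("Shorea seminis", "Shorea argentifolia"),
  generator = NULL   # a generator_config; NULL = default_generator_config()
)

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected by name; missing keys take their defaults.
#'
#' @param config Named list of options (see [run_pipeline()] for the keys).
#' @return A complete configuration list.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- .PIPELINE_DEFAULTS()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, config)
  bad <- setdiff(out$stages, .PIPELINE_DEFAULTS()$stages)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Run the dispersal-modelling pipeline
#'
#' Executes the enabled stages in order: `simulate` writes `releases.csv` and
#' `truth.json`; `fit` writes `fit.json`; `bootstrap` writes `boot.json`;
#' `kernels` writes `kernel_summary.csv` (and per-cell kernel CSVs when the
#' grid is small); `ballistic` writes `comparison.csv`. A `manifest.json`
#' records the configuration, seeds and an MD5 digest of every artifact.
#'
#' Configuration keys: `stages` (subset of the five names above), `out_dir`,
#' `seed_simulate`, `seed_bootstrap`, `wind_choice` ("max"/"mean"),
#' `method` ("REML"/"ML"), `B`, `kernel_iwl`, `kernel_wind`,
#' `include_species_effect`, `ballistic_height`, `ballistic_wind`,
#' `anchor_species`, `generator` (a [generator_config()]; default the
#' packaged 13-species design).
#'
#' @param config Named list, validated by [pipeline_config()].
#' @param quiet Suppress per-stage messages?
#' @return The manifest list, invisibly. Also written as `manifest.json`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[gyrokernels] ", ...)
  artifacts <- character(0)
  manifest <- list(config = cfg[setdiff(names(cfg), "generator")],
                   stages_run = character(0))
  fail <- function(stage, e) {
    writeLines(paste0("pipeline failed in stage: ", stage),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  sim <- fit <- boot <- NULL

  if ("simulate" %in% cfg$stages) {
    tryCatch({
      say("simulate: generating release experiment (seed ", cfg$seed_simulate, ")")
      gen <- cfg$generator
      if (is.null(gen)) gen <- default_generator_config(cfg$seed_simulate)
      else gen$rng_seed <- as.integer(cfg$seed_simulate)
      sim <- generate_releases(gen)
      artifacts <- c(artifacts, write_releases(sim, cfg$out_dir))
      manifest$stages_run <- c(manifest$stages_run, "simulate")
    }, error = function(e) fail("simulate", e))
  }

  if ("fit" %in% cfg$stages) {
    tryCatch({
      if (is.null(sim)) {
        sim <- list(dataset =
                      read_releases_csv(file.path(cfg$out_dir, "releases.csv")))
      }
      say("fit: ", cfg$method, " fit with ", cfg$wind_choice, " wind")
      fit <- fit_lmm(build_design(sim$dataset, cfg$wind_choice),
                     method = cfg$method)
      p <- file.path(cfg$out_dir, "fit.json")
      write_fit_json(fit, p)
      artifacts <- c(artifacts, fit = p)
      manifest$stages_run <- c(manifest$stages_run, "fit")
    }, error = function(e) fail("fit", e))
  }

  if ("bootstrap" %in% cfg$stages) {
    tryCatch({
      if (is.null(fit)) stop("bootstrap requires the fit stage")
      say("bootstrap: B = ", cfg$B, " (seed ", cfg$seed_bootstrap, ")")
      boot <- bootstrap_lmm(fit, B = cfg$B, base_seed = cfg$seed_bootstrap)
      p <- file.path(cfg$out_dir, "boot.json")
      summarise_bootstrap(boot, path = p)
      artifacts <- c(artifacts, boot = p)
      manifest$stages_run <- c(manifest$stages_run, "bootstrap")
    }, error = function(e) fail("bootstrap", e))
  }

  if ("kernels" %in% cfg$stages) {
    tryCatch({
      params <- if (!is.null(fit)) fit$params else reference_parameters()
      say("kernels: ", length(cfg$kernel_iwl), " x ", length(cfg$kernel_wind),
          " IWL x wind grid")
      kdir <- file.path(cfg$out_dir, "kernels")
      if (length(cfg$kernel_iwl) * length(cfg$kernel_wind) <= 100) {
        artifacts <- c(artifacts, kernel_summary =
                         write_kernel_grid(params, cfg$kernel_iwl,
                                           cfg$kernel_wind, kdir,
                                           cfg$include_species_effect))
      } else {
        dir.create(kdir, showWarnings = FALSE)
        summ <- kernel_grid(params, cfg$kernel_iwl, cfg$kernel_wind,
                            cfg$include_species_effect)
        p <- file.path(kdir, "kernel_summary.csv")
        utils::write.csv(summ, p, row.names = FALSE, quote = FALSE)
        artifacts <- c(artifacts, kernel_summary = p)
      }
      manifest$stages_run <- c(manifest$stages_run, "kernels")
    }, error = function(e) fail("kernels", e))
  }

  if ("ballistic" %in% cfg$stages) {
    tryCatch({
      say("ballistic: calibration + comparison table")
      bp <- default_ballistic_calibration(cfg$ballistic_wind,
                                          cfg$ballistic_height,
                                          cfg$anchor_species)
      params <- if (!is.null(fit)) fit$params else reference_parameters()
      pred <- load_fixtures()$predicted
      cmp <- comparison_table(params, bp,
                              data.frame(species = pred$species,
                                         mean_iwl = pred$mean_iwl,
                                         sqrt_wl = pred$sqrt_wl))
      p <- file.path(cfg$out_dir, "comparison.csv")
      utils::write.csv(cmp, p, row.names = FALSE, quote = FALSE)
      artifacts <- c(artifacts, comparison = p)
      manifest$stages_run <- c(manifest$stages_run, "ballistic")
    }, error = function(e) fail("ballistic", e))
  }

  manifest$artifacts <- lapply(stats::setNames(artifacts, basename(artifacts)),
                               function(p) list(path = p,
                                                md5 = unname(tools::md5sum(p))))
  manifest$r_version <- as.character(getRversion())
  manifest$package_version <-
    as.character(utils::packageVersion("gyrokernels"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
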