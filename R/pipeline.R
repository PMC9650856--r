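# End-to-end orchestration: raw inputs -> steps -> strata -> covariates ->
# moderators -> candidate fits -> AICc selection -> coefficient / RSS
# outputs, with a machine-readable run manifest. Each stage is an exported
# function; run_pipeline() chains them with one config.

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions throughout the package: 4-h
#' steps with a 30-min tolerance, 9 available steps per used step, a 200-m
#' chain-rule threshold, dry period January-June, and a VIF screen at 4.
#'
#' @param fixes path to the fixes CSV (see [read_fixes()]).
#' @param landscape path to a landscape directory of ESRI ASCII rasters:
#'   `ndvi_YYYYMMDD.asc`, `temp_YYYYMMDD.asc`, `elevation.asc`.
#' @param out output directory.
#' @param interval_hours,tolerance_mins resampling parameters.
#' @param n_available available steps per stratum.
#' @param group_threshold chain-rule distance in meters.
#' @param dry_months months forming the dry period; the wet period is the
#'   complement.
#' @param baseline_start,baseline_end aNDVI baseline window (defaults: the
#'   4 calendar years before the last NDVI composite's year).
#' @param tiers candidate models to fit.
#' @param vif_threshold collinearity warning level.
#' @param min_strata minimum strata for a period to be fitted.
#' @param seed master seed.
#' @param column_map passed to [read_fixes()].
#' @return a `issa_pipeline_config` list.
#' @export
pipeline_config <- function(fixes, landscape, out,
                            interval_hours = 4, tolerance_mins = 30,
                            n_available = 9, group_threshold = 200,
                            dry_months = 1:6,
                            baseline_start = NULL, baseline_end = NULL,
                            tiers = c("M1", "M2", "M3", "M4"),
                            vif_threshold = 4, min_strata = 50,
                            seed = 1L, column_map = character()) {
  dry_months <- as.integer(dry_months)
  if (length(dry_months) == 0 || !all(dry_months %in% 1:12) ||
      length(dry_months) == 12 || anyDuplicated(dry_months))
    stop_config("dry_months must be a strict, duplicate-free subset of 1:12; ",
                "the wet period is its complement")
  structure(as.list(environment()), class = "issa_pipeline_config")
}

#' Read a landscape directory into a covariate stack
#'
#' @param dir directory of `ndvi_YYYYMMDD.asc`, `temp_YYYYMMDD.asc` and
#'   `elevation.asc` rasters.
#' @param baseline_start,baseline_end aNDVI baseline window; default is the
#'   4 calendar years preceding the final composite's year.
#' @return list: `stack` (a `issa_stack`), `ndvi` (the raw NDVI series).
#' @export
read_landscape_dir <- function(dir, baseline_start = NULL, baseline_end = NULL) {
  if (!dir.exists(dir)) stop_config("landscape directory not found: ", dir)
  read_series <- function(prefix) {
    files <- sort(list.files(dir, paste0("^", prefix, "_\\d{8}\\.asc$"),
                             full.names = TRUE))
    if (length(files) == 0) stop_config("no ", prefix, "_YYYYMMDD.asc rasters in ", dir)
    dates <- as.Date(sub(paste0(".*", prefix, "_(\\d{8})\\.asc$"), "\\1", files),
                     format = "%Y%m%d")
    grid_series(dates, lapply(files, grid_read_ascii))
  }
  ndvi <- read_series("ndvi")
  temperature <- read_series("temp")
  elev_path <- file.path(dir, "elevation.asc")
  if (!file.exists(elev_path)) stop_config("missing elevation.asc in ", dir)
  elevation <- grid_read_ascii(elev_path)
  last_year <- as.integer(format(max(ndvi$dates), "%Y"))
  if (is.null(baseline_start)) baseline_start <- as.Date(paste0(last_year - 4, "-01-01"))
  if (is.null(baseline_end)) baseline_end <- as.Date(paste0(last_year - 1, "-12-31"))
  andvi <- compute_andvi(ndvi, baseline_start, baseline_end)
  dndvi <- compute_dndvi(ndvi)
  list(stack = landscape_stack(andvi = andvi, dndvi = dndvi,
                               elevation = elevation, temperature = temperature),
       ndvi = ndvi)
}

#' Run the full analysis pipeline
#'
#' Stages: read fixes, resample to the analysis interval, build steps,
#' assemble the landscape stack, then per period: fit the movement kernel
#' on that period's steps, sample available steps into strata, extract
#' covariates, attach moderators, fit the candidate models, screen the
#' largest design with VIF, select by AICc, and write coefficient tables,
#' the model comparison, RSS curves of the best model, and a run manifest.
#'
#' @param config a [pipeline_config()].
#' @return list of per-period results (`fits`, `comparison`, `best_tier`,
#'   `strata`) plus the manifest, invisibly; all tables are also written
#'   under `config$out`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "issa_pipeline_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  message("[tracks] reading fixes")
  fx <- read_fixes(config$fixes, config$column_map)
  bursts <- resample_to_interval(fx, config$interval_hours, config$tolerance_mins)
  steps <- build_steps(bursts, dry_months = config$dry_months)
  write_steps(steps, file.path(config$out, "steps.csv"))
  message("[tracks] ", nrow(fx), " fixes -> ", nrow(steps), " steps")

  message("[landscape] reading rasters")
  land <- read_landscape_dir(config$landscape, config$baseline_start,
                             config$baseline_end)
  grp <- group_sizes(bursts, threshold = config$group_threshold,
                     bin_hours = config$interval_hours)
  release <- tapply(fx$release_date, fx$animal_id, min)
  release <- as_utc(as.POSIXct(release, origin = "1970-01-01", tz = "UTC"))

  counts <- list(fixes = nrow(fx), steps = nrow(steps))
  results <- list()
  all_strata <- list()
  for (period in intersect(c("dry", "wet"), unique(as.character(steps$period)))) {
    psteps <- steps[as.character(steps$period) == period, , drop = FALSE]
    usable <- sum(!is.na(psteps$ta))
    if (usable < config$min_strata) {
      message("[", period, "] only ", usable, " usable steps; period skipped")
      next
    }
    message("[", period, "] kernel fit on ", nrow(psteps), " steps")
    gf <- fit_gamma(psteps$sl)
    vf <- fit_vonmises(psteps$ta[!is.na(psteps$ta)])
    write_kernel(gf, vf, file.path(config$out, paste0("kernel_", period, ".json")),
                 period = period)
    strata <- build_strata(psteps, gf, vf, n_available = config$n_available,
                           seed = substream_seed(config$seed, paste0("strata_", period)))
    strata$stratum_id <- paste0(period, "_", strata$stratum_id)
    strata <- extract_covariates(strata, land$stack)
    strata <- attach_moderators(strata, grp, release,
                                bin_hours = config$interval_hours)
    all_strata[[period]] <- strata
    message("[", period, "] ", length(unique(strata$stratum_id)), " strata")

    fits <- lapply(stats::setNames(config$tiers, config$tiers), function(tier)
      fit_issf(build_design(strata, period = period, tier = tier,
                            warn_inestimable = FALSE)))
    vifs <- suppressWarnings(vif(build_design(strata, period = period,
                                              tier = config$tiers[length(config$tiers)],
                                              warn_inestimable = FALSE)))
    if (any(vifs >= config$vif_threshold))
      message("[", period, "] VIF >= ", config$vif_threshold, " for: ",
              paste(names(vifs)[vifs >= config$vif_threshold], collapse = ", "))
    cmp <- select_model(fits)
    best <- cmp$tier[1]
    for (tier in names(fits))
      utils::write.csv(rss_table(fits[[tier]]),
                       file.path(config$out, paste0("coefficients_", period, "_", tier, ".csv")),
                       row.names = FALSE)
    utils::write.csv(as.data.frame(cmp),
                     file.path(config$out, paste0("aicc_", period, ".csv")),
                     row.names = FALSE)
    curves <- do.call(rbind, lapply(issa_env_covariates, function(cv) {
      if (!cv %in% names(coef(fits[[best]]))) return(NULL)
      log_rss_curve(fits[[best]], cv)
    }))
    utils::write.csv(curves, file.path(config$out, paste0("curves_", period, ".csv")),
                     row.names = FALSE)
    counts[[paste0("strata_", period)]] <- length(unique(strata$stratum_id))
    counts[[paste0("rows_", period)]] <- nrow(strata)
    results[[period]] <- list(fits = fits, comparison = cmp, best_tier = best,
                              vif = vifs, strata = strata)
  }
  manifest <- list(seed = config$seed,
                   interval_hours = config$interval_hours,
                   n_available = config$n_available,
                   group_threshold = config$group_threshold,
                   dry_months = config$dry_months,
                   counts = counts,
                   best = lapply(results, `[[`, "best_tier"))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
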