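# Synthetic data with known truth: seasonally dynamic landscapes and
# multi-animal trajectories driven by a known step-selection rule, so that
# every pipeline stage (and the estimator itself) can be tested end to end
# without field data.
#
# All randomness flows from one master seed through named substreams
# (landscape, tracks, strata, ...) so stages are reproducible in isolation.

#' Configuration for a simulated landscape
#'
#' @param nrow,ncol grid dimensions in cells (default 200 x 200).
#' @param cellsize cell size in meters (default 500, the analysis resolution).
#' @param years calendar years simulated; NDVI composites are produced every
#'   16 days (23 per year). At least 5 years so a 4-year anomaly baseline
#'   precedes the study year.
#' @param ndvi_base,ndvi_amplitude,ndvi_phase_doy mean NDVI level, seasonal
#'   amplitude and day-of-year phase of the greenness cycle.
#' @param ndvi_noise_sd SD of the per-composite spatially smooth NDVI noise.
#' @param anomaly_sd SD of the greening/browning anomaly field planted in
#'   `anomaly_year` (what aNDVI should recover).
#' @param anomaly_year year receiving the planted anomaly (default: last).
#' @param corr_range_cells spatial correlation length of the NDVI random
#'   fields, in cells (> 1).
#' @param elev_mean,elev_sd,elev_range_cells elevation field parameters.
#' @param temp_mean,temp_amplitude,temp_phase_doy,temp_lapse,temp_noise_sd
#'   temperature cycle: mean (deg C), seasonal amplitude, phase, per-meter
#'   elevation lapse, and smooth per-composite noise SD.
#' @param seed integer seed for the landscape substream.
#' @return a `issa_sim_landscape_config` list.
#' @export
sim_landscape_config <- function(nrow = 200, ncol = 200, cellsize = 500,
                                 years = 2016:2020,
                                 ndvi_base = 0.25, ndvi_amplitude = 0.15,
                                 ndvi_phase_doy = 153, ndvi_noise_sd = 0.04,
                                 anomaly_sd = 0.08, anomaly_year = max(years),
                                 corr_range_cells = 8,
                                 elev_mean = 300, elev_sd = 60, elev_range_cells = 15,
                                 temp_mean = 30, temp_amplitude = 8,
                                 temp_phase_doy = 120, temp_lapse = -0.01,
                                 temp_noise_sd = 1.5, seed = 1L) {
  if (corr_range_cells <= 1) stop_config("correlation length must exceed one cell")
  if (length(years) < 5) stop_config("simulate at least 5 years so a 4-year anomaly baseline exists")
  structure(as.list(environment()), class = "issa_sim_landscape_config")
}

# Smooth Gaussian random field (mean 0, sd 1) by FFT convolution of white
# noise with a Gaussian kernel on the torus.
gauss_field <- function(nr, nc, range_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  di <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dj <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  k <- exp(-outer(di^2, dj^2, `+`) / (2 * range_cells^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

sim_composite_dates <- function(years) {
  as.Date(unlist(lapply(years, function(y)
    as.character(as.Date(paste0(y, "-01-01")) + seq(0, by = 16, length.out = 23)))))
}

#' Simulate a seasonally dynamic landscape
#'
#' Produces a 16-day NDVI composite series (smooth spatial base + seasonal
#' cycle + smooth noise + a planted anomaly field in the study year), a
#' smooth elevation field with its TRI, and a temperature composite series
#' (seasonal cycle + elevation lapse + smooth noise). Derived aNDVI (slot
#' baseline over all years before the anomaly year) and dNDVI are computed
#' with the package's own covariate operations.
#'
#' @param config a [sim_landscape_config()].
#' @return list of class `issa_sim_landscape`: `ndvi` (`issa_series`),
#'   `stack` (`issa_stack`), `anomaly` (the planted anomaly `issa_grid`),
#'   `config`.
#' @export
simulate_landscape <- function(config = sim_landscape_config()) {
  cfg <- config
  set.seed(substream_seed(cfg$seed, "landscape"))
  nr <- cfg$nrow; nc <- cfg$ncol
  base <- cfg$ndvi_base + 0.08 * gauss_field(nr, nc, cfg$corr_range_cells)
  amp <- cfg$ndvi_amplitude * (0.7 + 0.3 * stats::pnorm(gauss_field(nr, nc, cfg$corr_range_cells)))
  anomaly <- cfg$anomaly_sd * gauss_field(nr, nc, cfg$corr_range_cells)
  elev_vals <- cfg$elev_mean + cfg$elev_sd * gauss_field(nr, nc, cfg$elev_range_cells)
  elevation <- grid_create(elev_vals, 0, 0, cfg$cellsize)

  dates <- sim_composite_dates(cfg$years)
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  season <- sin(2 * pi * (doy - cfg$ndvi_phase_doy) / 365.25 + pi / 2)
  tseason <- sin(2 * pi * (doy - cfg$temp_phase_doy) / 365.25 + pi / 2)

  ndvi_grids <- vector("list", length(dates))
  temp_grids <- vector("list", length(dates))
  elev_dev <- elev_vals - mean(elev_vals)
  for (i in seq_along(dates)) {
    v <- base + amp * season[i] + cfg$ndvi_noise_sd * gauss_field(nr, nc, cfg$corr_range_cells)
    if (yr[i] == cfg$anomaly_year) v <- v + anomaly
    ndvi_grids[[i]] <- grid_create(pmin(pmax(v, -0.2), 1), 0, 0, cfg$cellsize)
    tv <- cfg$temp_mean + cfg$temp_amplitude * tseason[i] + cfg$temp_lapse * elev_dev +
      cfg$temp_noise_sd * gauss_field(nr, nc, cfg$corr_range_cells)
    temp_grids[[i]] <- grid_create(tv, 0, 0, cfg$cellsize)
  }
  ndvi <- grid_series(dates, ndvi_grids)
  temperature <- grid_series(dates, temp_grids)
  baseline_years <- setdiff(cfg$years, cfg$anomaly_year)
  andvi <- compute_andvi(ndvi,
                         baseline_start = as.Date(paste0(min(baseline_years), "-01-01")),
                         baseline_end = as.Date(paste0(max(baseline_years), "-12-31")))
  dndvi <- compute_dndvi(ndvi)
  stack <- landscape_stack(andvi = andvi, dndvi = dndvi, elevation = elevation,
                           temperature = temperature)
  structure(list(ndvi = ndvi, stack = stack,
                 anomaly = grid_create(anomaly, 0, 0, cfg$cellsize),
                 config = cfg),
            class = "issa_sim_landscape")
}

#' Known truth for a simulated step-selection dataset
#'
#' @param beta_env named selection coefficients on the standardized
#'   environmental covariates (`andvi`, `dndvi`, `elev`, `tri`, `temp`).
#' @param beta_exp named experience-interaction coefficients (same names).
#' @param beta_grp named group-size-interaction coefficients (same names).
#' @param gamma_shape,gamma_scale true step-length kernel (meters).
#' @param vm_kappa true turning-angle concentration.
#' @param group_attraction strength of the quadratic pull toward the group
#'   centroid that keeps multi-animal groups cohesive (0 disables it;
#'   singleton groups are never attracted).
#' @param attraction_scale distance (meters) at which the attraction penalty
#'   reaches `group_attraction` log-odds units.
#' @return a `issa_sim_truth` list (scaling constants are filled in by
#'   [simulate_tracks()]).
#' @export
sim_truth <- function(beta_env = c(andvi = 0.5, dndvi = -0.3, elev = 0.25, tri = -0.4),
                      beta_exp = numeric(0), beta_grp = numeric(0),
                      gamma_shape = 1.8, gamma_scale = 450, vm_kappa = 0.8,
                      group_attraction = 2, attraction_scale = 200) {
  env_names <- issa_env_covariates
  stopifnot(all(names(beta_env) %in% env_names),
            all(names(beta_exp) %in% env_names),
            all(names(beta_grp) %in% env_names),
            group_attraction >= 0, attraction_scale > 0)
  structure(list(beta_env = beta_env, beta_exp = beta_exp, beta_grp = beta_grp,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 vm_kappa = vm_kappa,
                 group_attraction = group_attraction,
                 attraction_scale = attraction_scale, scaling = NULL),
            class = "issa_sim_truth")
}

# Marginal standardization constants of the landscape layers over the
# simulation window, plus the (deterministic) experience / group-size
# schedules; these are the scales on which the true coefficients live.
truth_scaling <- function(land, times, release_by_animal, group_size_by_animal,
                          animals) {
  stack <- land$stack
  win <- range(as.Date(times))
  pick <- function(series) {
    i <- which(series$dates >= win[1] - 16 & series$dates <= win[2])
    if (length(i) == 0) i <- length(series$dates)
    unlist(lapply(series$grids[i], function(g) as.vector(g$values)))
  }
  vals <- list(andvi = pick(stack$andvi), dndvi = pick(stack$dndvi),
               temp = pick(stack$temperature),
               elev = as.vector(stack$elevation$values),
               tri = as.vector(stack$tri$values))
  center <- vapply(vals, mean, numeric(1))
  scale <- vapply(vals, stats::sd, numeric(1))
  expd <- as.vector(outer(as.numeric(times), as.numeric(release_by_animal[animals]),
                          function(t, r) (t - r) / 86400))
  center["experience"] <- mean(expd); scale["experience"] <- stats::sd(expd)
  gs <- rep(group_size_by_animal[animals], each = length(times))
  center["group_size"] <- mean(gs)
  scale["group_size"] <- if (stats::sd(gs) > 0) stats::sd(gs) else 1
  list(center = center, scale = scale)
}

reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  v <- (v - lo) %% (2 * w)
  v <- ifelse(v > w, 2 * w - v, v)
  v + lo
}

#' Simulate multi-animal tracks driven by a known step-selection rule
#'
#' Every animal takes 4-hourly steps: `n_candidates` candidate steps are
#' drawn from the true gamma / von Mises kernel, and one is chosen with
#' probability proportional to `exp(u)`, where `u` adds the environmental
#' coefficients and the experience / group-size interaction terms on the
#' standardized covariates at the candidate end point. Animals in a
#' multi-animal group additionally feel a quadratic attraction toward their
#' group's current centroid (`-group_attraction * (d / attraction_scale)^2`),
#' which keeps groups cohesive enough for chain-rule detection while every
#' member still makes its own habitat choices. Positions update
#' synchronously within each 4-h bin. Steps that would leave the landscape
#' are reflected at the boundary.
#'
#' @param land a `issa_sim_landscape`.
#' @param truth a [sim_truth()].
#' @param groups list of character vectors of animal ids; each vector is one
#'   cohesive group (singletons allowed).
#' @param n_steps steps per animal.
#' @param start time (POSIXct UTC) of the first fix.
#' @param release_dates named POSIXct vector, release date per animal.
#' @param n_candidates candidate steps per move (default 50; deliberately
#'   more than the 9 available steps used at analysis, to reduce simulation
#'   bias).
#' @param seed integer seed for the tracks substream.
#' @return list of class `issa_sim_tracks`: `fixes` (a `issa_fixes` table),
#'   `truth` (with `scaling` filled in), `groups`, `release_dates`.
#' @export
simulate_tracks <- function(land, truth, groups, n_steps = 300,
                            start = as.POSIXct("2020-02-01 00:00:00", tz = "UTC"),
                            release_dates = NULL, n_candidates = 50, seed = 1L) {
  stopifnot(inherits(land, "issa_sim_landscape"), inherits(truth, "issa_sim_truth"))
  stack <- land$stack
  g0 <- stack$elevation
  xr <- c(g0$xmin + g0$cellsize, grid_xmax(g0) - g0$cellsize)
  yr <- c(g0$ymin + g0$cellsize, grid_ymax(g0) - g0$cellsize)
  animals <- unname(unlist(groups))
  if (anyDuplicated(animals)) stop_config("an animal appears in more than one group")
  if (is.null(release_dates)) {
    release_dates <- rep(as_utc(start) - 30 * 86400, length(animals))
    names(release_dates) <- animals
  }
  gsize <- rep(lengths(groups), lengths(groups))
  names(gsize) <- animals
  times <- as_utc(start) + (0:n_steps) * 4 * 3600
  scal <- truth_scaling(land, times, release_dates, gsize, animals)
  truth$scaling <- scal

  env_all <- issa_env_covariates
  b_env <- b_exp <- b_grp <- stats::setNames(rep(0, length(env_all)), env_all)
  b_env[names(truth$beta_env)] <- truth$beta_env
  b_exp[names(truth$beta_exp)] <- truth$beta_exp
  b_grp[names(truth$beta_grp)] <- truth$beta_grp

  # composite index per step time for the dynamic layers
  ia <- series_index_at(stack$andvi, times)
  id <- series_index_at(stack$dndvi, times)
  it <- series_index_at(stack$temperature, times)
  if (any(ia == 0) || any(id == 0) || any(it == 0))
    stop_data("simulation window precedes the first derived composite")

  set.seed(substream_seed(seed, "tracks"))
  K <- as.integer(n_candidates)
  n_anim <- length(animals)
  group_of <- rep(seq_along(groups), lengths(groups))
  names(group_of) <- animals
  zg_a <- (gsize[animals] - scal$center["group_size"]) / scal$scale["group_size"]
  rel_num <- as.numeric(release_dates[animals])
  att <- truth$group_attraction
  d0 <- truth$attraction_scale

  # group start points; members begin within 100 m of their group's point
  gx <- stats::runif(length(groups), xr[1] + 0.25 * diff(xr), xr[2] - 0.25 * diff(xr))
  gy <- stats::runif(length(groups), yr[1] + 0.25 * diff(yr), yr[2] - 0.25 * diff(yr))
  px <- matrix(NA_real_, n_steps + 1, n_anim, dimnames = list(NULL, animals))
  py <- matrix(NA_real_, n_steps + 1, n_anim, dimnames = list(NULL, animals))
  px[1, ] <- gx[group_of] + stats::runif(n_anim, -100, 100)
  py[1, ] <- gy[group_of] + stats::runif(n_anim, -100, 100)
  heading <- stats::runif(n_anim, -pi, pi)

  zq <- function(vals, layer) (vals - scal$center[layer]) / scal$scale[layer]
  for (s in seq_len(n_steps)) {
    cgx <- tapply(px[s, ], group_of, mean)
    cgy <- tapply(py[s, ], group_of, mean)
    ze_s <- ((as.numeric(times[s]) - rel_num) / 86400 - scal$center["experience"]) /
      scal$scale["experience"]
    for (a in seq_len(n_anim)) {
      sl <- stats::rgamma(K, shape = truth$gamma_shape, scale = truth$gamma_scale)
      ta <- rvonmises(K, mu = 0, kappa = truth$vm_kappa)
      hh <- wrap_angle(heading[a] + ta)
      cx <- reflect_into(px[s, a] + sl * cos(hh), xr[1], xr[2])
      cy <- reflect_into(py[s, a] + sl * sin(hh), yr[1], yr[2])
      zc <- rbind(
        andvi = zq(grid_extract(stack$andvi$grids[[ia[s + 1]]], cx, cy), "andvi"),
        dndvi = zq(grid_extract(stack$dndvi$grids[[id[s + 1]]], cx, cy), "dndvi"),
        elev = zq(grid_extract(stack$elevation, cx, cy), "elev"),
        tri = zq(grid_extract(stack$tri, cx, cy), "tri"),
        temp = zq(grid_extract(stack$temperature$grids[[it[s + 1]]], cx, cy), "temp"))
      u <- drop((b_env + ze_s[a] * b_exp + zg_a[a] * b_grp) %*% zc)
      g <- group_of[a]
      if (att > 0 && lengths(groups)[g] > 1) {
        d2 <- (cx - cgx[g])^2 + (cy - cgy[g])^2
        u <- u - att * d2 / d0^2
      }
      pr <- exp(u - max(u))
      j <- sample.int(K, 1, prob = pr)
      # heading update uses the realized displacement (reflection may bend it)
      heading[a] <- atan2(cy[j] - py[s, a], cx[j] - px[s, a])
      px[s + 1, a] <- cx[j]; py[s + 1, a] <- cy[j]
    }
  }
  out <- lapply(seq_len(n_anim), function(a)
    data.frame(animal_id = animals[a],
               timestamp = times,
               x = px[, a], y = py[, a],
               release_date = unname(release_dates[animals[a]]),
               stringsAsFactors = FALSE))
  fx <- fixes(do.call(rbind, out))
  structure(list(fixes = fx, truth = truth, groups = groups,
                 release_dates = release_dates,
                 group_size = gsize, n_candidates = K, seed = seed),
            class = "issa_sim_tracks")
}

sim_profiles <- list(
  tiny = list(n_animals = 2, n_steps = 50, nrow = 40, ncol = 40,
              group_sizes = c(1, 1)),
  recovery = list(n_animals = 15, n_steps = 300, nrow = 200, ncol = 200,
                  group_sizes = rep(1, 15)),
  grouped = list(n_animals = 12, n_steps = 200, nrow = 200, ncol = 200,
                 group_sizes = c(2, 4, 6)),
  moderated = list(n_animals = 32, n_steps = 300, nrow = 200, ncol = 200,
                   group_sizes = c(1, 1, 2, 2, 3, 4, 5, 6, 8))
)

#' Simulate a complete named dataset (landscape + tracks) in memory
#'
#' Profiles: `tiny` (2 animals x 50 steps, fast end-to-end checks),
#' `recovery` (15 independent animals x 300 steps, two release cohorts,
#' known environmental + experience-interaction coefficients; the
#' parameter-recovery oracle), `grouped` (12 animals in 3 cohesive groups of
#' 2/4/6, for chain-rule grouping checks) and `moderated` (12 animals in 6
#' groups of sizes 1-3 whose release cohorts are deliberately not aligned
#' with group size, so experience and group-size interactions are jointly
#' identifiable; used for model-selection experiments).
#'
#' @param profile one of `"tiny"`, `"recovery"`, `"grouped"`, `"moderated"`.
#' @param seed master seed.
#' @return list of class `issa_sim`: `land`, `tracks`, `profile`, `seed`.
#' @export
simulate_dataset <- function(profile = c("tiny", "recovery", "grouped", "moderated"),
                             seed = 1L) {
  profile <- match.arg(profile)
  p <- sim_profiles[[profile]]
  cfg <- sim_landscape_config(nrow = p$nrow, ncol = p$ncol,
                              seed = substream_seed(seed, "landscape"))
  land <- simulate_landscape(cfg)
  ids <- sprintf("oryx%02d", seq_len(p$n_animals))
  groups <- split(ids, rep(seq_along(p$group_sizes), p$group_sizes))
  start <- as.POSIXct("2020-02-01 00:00:00", tz = "UTC")
  # release cohorts: seasoned animals and recent releases (groups share a
  # release date so cohesive members carry one experience level)
  if (profile == "grouped") {
    rel <- as_utc(start) - rep(c(400, 200, 30) * 86400, times = p$group_sizes)
  } else if (profile == "moderated") {
    # release cohorts scattered over ~1.5 years, out of step with group size
    rel <- as_utc(start) - rep(c(500, 120, 300, 30, 420, 200, 60, 350, 150) * 86400,
                               times = p$group_sizes)
  } else {
    rel <- rep(as_utc(start) - c(400, 30) * 86400, length.out = p$n_animals)
  }
  names(rel) <- ids
  truth <- switch(profile,
    tiny = sim_truth(beta_env = c(andvi = 0.4, tri = -0.3)),
    recovery = sim_truth(beta_env = c(andvi = 0.5, dndvi = -0.3, elev = 0.25, tri = -0.4),
                         beta_exp = c(dndvi = -0.25, tri = 0.3)),
    grouped = sim_truth(beta_env = c(andvi = 0.4, elev = 0.2, tri = -0.3)),
    moderated = sim_truth(beta_env = c(andvi = 0.4, elev = 0.2, tri = -0.3),
                          beta_exp = c(tri = 0.25, dndvi = -0.2),
                          beta_grp = c(elev = -0.25, andvi = 0.2)))
  tracks <- simulate_tracks(land, truth, groups, n_steps = p$n_steps,
                            start = start, release_dates = rel,
                            seed = substream_seed(seed, "tracks"))
  structure(list(land = land, tracks = tracks, profile = profile, seed = seed),
            class = "issa_sim")
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits `fixes.csv`, a `landscape/` directory of dated ESRI ASCII rasters
#' (`ndvi_YYYYMMDD.asc`, `temp_YYYYMMDD.asc`, `elevation.asc`) and a
#' `truth.json` manifest of the (synthetic) generating parameters.
#'
#' @param profile see [simulate_dataset()].
#' @param dir output directory (created).
#' @param seed master seed.
#' @return the `issa_sim` object, invisibly; paths in attribute `paths`.
#' @export
make_fixture <- function(profile = c("tiny", "recovery", "grouped"),
                         dir = tempfile("issa_fixture_"), seed = 1L) {
  sim <- simulate_dataset(profile, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lsdir <- file.path(dir, "landscape")
  dir.create(lsdir, showWarnings = FALSE)
  fx <- sim$tracks$fixes
  utils::write.csv(data.frame(animal_id = fx$animal_id,
                              timestamp = format(fx$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                              x = fx$x, y = fx$y,
                              release_date = format(fx$release_date, "%Y-%m-%d", tz = "UTC")),
                   file.path(dir, "fixes.csv"), row.names = FALSE)
  nd <- sim$land$ndvi
  for (i in seq_along(nd$dates)) {
    stamp <- format(nd$dates[i], "%Y%m%d")
    grid_write_ascii(nd$grids[[i]], file.path(lsdir, paste0("ndvi_", stamp, ".asc")))
    grid_write_ascii(sim$land$stack$temperature$grids[[i]],
                     file.path(lsdir, paste0("temp_", stamp, ".asc")))
  }
  grid_write_ascii(sim$land$stack$elevation, file.path(lsdir, "elevation.asc"))
  tr <- sim$tracks$truth
  jsonlite::write_json(list(synthetic = TRUE, profile = profile, seed = seed,
                            beta_env = as.list(tr$beta_env),
                            beta_exp = as.list(tr$beta_exp),
                            beta_grp = as.list(tr$beta_grp),
                            gamma_shape = tr$gamma_shape,
                            gamma_scale = tr$gamma_scale,
                            vm_kappa = tr$vm_kappa,
                            scaling = tr$scaling,
                            release_dates = as.list(format(sim$tracks$release_dates,
                                                           "%Y-%m-%d", tz = "UTC"))),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  attr(sim, "paths") <- list(dir = dir, fixes = file.path(dir, "fixes.csv"),
                             landscape = lsdir, truth = file.path(dir, "truth.json"))
  invisible(sim)
}
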