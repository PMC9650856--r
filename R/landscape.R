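# Landscape covariates: NDVI-derived layers (16-day change and multi-year
# anomaly), terrain ruggedness, and extraction of all covariates at step
# endpoints. Time-indexed layers live in an `issa_series` (dates + grids
# sharing one geometry); the assembled covariate set is an `issa_stack`.

#' Construct a time-indexed grid series
#'
#' @param dates Date vector, strictly increasing (e.g. 16-day NDVI composite
#'   dates).
#' @param grids list of `issa_grid` objects, co-registered.
#' @return object of class `issa_series`.
#' @export
grid_series <- function(dates, grids) {
  dates <- as.Date(dates)
  if (length(dates) != length(grids)) stop_config("dates and grids differ in length")
  if (is.unsorted(dates, strictly = TRUE)) stop_config("series dates must be strictly increasing")
  for (g in grids) if (!grid_same_geometry(g, grids[[1]]))
    stop_data("series grids are not co-registered")
  structure(list(dates = dates, grids = grids), class = "issa_series")
}

#' @export
print.issa_series <- function(x, ...) {
  cat("<issa_series> ", length(x$dates), " composites, ",
      format(min(x$dates)), " .. ", format(max(x$dates)), "\n", sep = "")
  invisible(x)
}

# Index of the most recent composite at or before each timestamp (no
# look-ahead); 0 when the timestamp precedes the first composite.
series_index_at <- function(series, timestamps) {
  findInterval(as.numeric(as.Date(as_utc(timestamps))), as.numeric(series$dates))
}

#' 16-day NDVI change (dNDVI)
#'
#' Cellwise difference between each composite and its predecessor,
#' `NDVI_t - NDVI_(t-16)`: positive values indicate short-term greening,
#' negative values drying. The first composite has no predecessor and is
#' omitted.
#'
#' @param series an NDVI `issa_series` with >= 2 composites.
#' @return a `issa_series` of dNDVI grids starting at the second composite
#'   date.
#' @export
compute_dndvi <- function(series) {
  n <- length(series$dates)
  if (n < 2) stop_config("dNDVI needs at least 2 composites")
  grids <- vector("list", n - 1)
  for (i in 2:n) {
    a <- series$grids[[i]]; b <- series$grids[[i - 1]]
    if (!grid_same_geometry(a, b)) stop_data("misaligned NDVI composites")
    grids[[i - 1]] <- grid_create(a$values - b$values, a$xmin, a$ymin, a$cellsize)
  }
  grid_series(series$dates[-1], grids)
}

#' NDVI anomaly relative to a multi-year baseline (aNDVI)
#'
#' Cellwise difference between each composite and the baseline mean for its
#' position in the seasonal cycle: greenness relative to the longer-term
#' trend at that time of year. By default the baseline is computed per
#' composite slot (same composite-of-year across the baseline years), so a
#' normal seasonal cycle has anomaly ~0 year-round; `mode = "grand"` uses a
#' single all-composites baseline mean instead.
#'
#' @param series an NDVI `issa_series` spanning the baseline and study years.
#' @param baseline_start,baseline_end Dates bounding the baseline period
#'   (inclusive), e.g. a 4-year window.
#' @param mode `"slot"` (seasonal baseline, default) or `"grand"`.
#' @return a `issa_series` of anomaly grids for every composite in `series`.
#' @export
compute_andvi <- function(series, baseline_start, baseline_end,
                          mode = c("slot", "grand")) {
  mode <- match.arg(mode)
  baseline_start <- as.Date(baseline_start); baseline_end <- as.Date(baseline_end)
  in_base <- series$dates >= baseline_start & series$dates <= baseline_end
  if (!any(in_base)) stop_data("no composites inside the baseline window")
  g1 <- series$grids[[1]]
  # composite slot = rank of the composite within its calendar year
  yr <- as.integer(format(series$dates, "%Y"))
  slot <- stats::ave(seq_along(series$dates), yr, FUN = seq_along)

  if (mode == "grand") {
    acc <- Reduce(`+`, lapply(series$grids[in_base], function(g) g$values))
    base_mean <- list(acc / sum(in_base))
    slot_of <- rep(1L, length(series$dates))
  } else {
    slots <- sort(unique(slot))
    base_mean <- vector("list", max(slots))
    for (s in slots) {
      pick <- which(slot == s & in_base)
      if (length(pick) == 0)
        stop_data("baseline window contains no composite for seasonal slot ", s)
      base_mean[[s]] <- Reduce(`+`, lapply(series$grids[pick], function(g) g$values)) /
        length(pick)
    }
    slot_of <- slot
  }
  grids <- lapply(seq_along(series$dates), function(i) {
    g <- series$grids[[i]]
    grid_create(g$values - base_mean[[slot_of[i]]], g$xmin, g$ymin, g$cellsize)
  })
  grid_series(series$dates, grids)
}

#' Terrain ruggedness index (TRI)
#'
#' Riley's index: for each cell, the square root of the summed squared
#' elevation differences between the cell and its 8 neighbors. Border cells
#' use the neighbors that exist. Invariant to adding a constant elevation;
#' scales with |c| when elevation is scaled by c.
#'
#' @param elevation an elevation `issa_grid` (>= 3 x 3).
#' @return a `issa_grid` of TRI values on the same geometry.
#' @export
compute_tri <- function(elevation) {
  v <- elevation$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) stop_config("TRI needs a grid of at least 3 x 3 cells")
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- v
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    d2 <- (nb - v)^2
    d2[is.na(d2)] <- 0   # missing neighbor (border) contributes nothing
    acc <- acc + d2
  }
  out <- sqrt(acc)
  out[is.na(v)] <- NA_real_
  grid_create(out, elevation$xmin, elevation$ymin, elevation$cellsize)
}

#' Assemble a landscape covariate stack
#'
#' @param andvi,dndvi,temperature `issa_series` layers (NDVI anomaly, 16-day
#'   NDVI change, temperature).
#' @param elevation,tri static `issa_grid` layers; `tri` defaults to
#'   [compute_tri()] of the elevation grid.
#' @return object of class `issa_stack`.
#' @export
landscape_stack <- function(andvi, dndvi, elevation, temperature, tri = NULL) {
  if (is.null(tri)) tri <- compute_tri(elevation)
  geoms_ok <- grid_same_geometry(andvi$grids[[1]], elevation) &&
    grid_same_geometry(dndvi$grids[[1]], elevation) &&
    grid_same_geometry(temperature$grids[[1]], elevation) &&
    grid_same_geometry(tri, elevation)
  if (!geoms_ok) stop_data("stack layers are not co-registered")
  structure(list(andvi = andvi, dndvi = dndvi, elevation = elevation,
                 tri = tri, temperature = temperature),
            class = "issa_stack")
}

#' Extract covariates at step endpoints and drop incomplete strata
#'
#' For every stratum row the five covariates (aNDVI, dNDVI, elevation, TRI,
#' temperature) are read at the step end point; time-indexed layers use the
#' most recent composite at or before the step's end timestamp. A stratum in
#' which any row has any missing covariate (off-map point, no-data cell) is
#' dropped whole, preserving the 1 used : n available balance required by the
#' conditional likelihood.
#'
#' @param strata a `issa_strata` table ([build_strata()]).
#' @param stack a `issa_stack`.
#' @param method point extraction method, `"nearest"` (default; grids are at
#'   the analysis resolution) or `"bilinear"`.
#' @return the strata table with columns `andvi`, `dndvi`, `elev`, `tri`,
#'   `temp` appended; attribute `dropped_strata` counts whole strata removed
#'   for missing covariates.
#' @export
extract_covariates <- function(strata, stack, method = "nearest") {
  t_end <- strata$t2
  ia <- series_index_at(stack$andvi, t_end)
  id <- series_index_at(stack$dndvi, t_end)
  it <- series_index_at(stack$temperature, t_end)
  if (any(ia == 0) || any(id == 0) || any(it == 0))
    stop_data("step timestamps precede the first composite of a time-indexed layer")

  pull <- function(series, idx) {
    out <- rep(NA_real_, nrow(strata))
    for (i in unique(idx)) {
      sel <- idx == i
      out[sel] <- grid_extract(series$grids[[i]], strata$x2[sel], strata$y2[sel],
                               method = method)
    }
    out
  }
  strata$andvi <- pull(stack$andvi, ia)
  strata$dndvi <- pull(stack$dndvi, id)
  strata$temp <- pull(stack$temperature, it)
  strata$elev <- grid_extract(stack$elevation, strata$x2, strata$y2, method = method)
  strata$tri <- grid_extract(stack$tri, strata$x2, strata$y2, method = method)

  covs <- c("andvi", "dndvi", "elev", "tri", "temp")
  bad_row <- rowSums(is.na(as.matrix(strata[, covs]))) > 0
  bad_strata <- unique(strata$stratum_id[bad_row])
  if (length(bad_strata) > 0)
    message(length(bad_strata), " strata dropped for missing covariates")
  keep <- !strata$stratum_id %in% bad_strata
  out <- strata[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_available") <- attr(strata, "n_available")
  attr(out, "dropped_strata") <- length(bad_strata)
  class(out) <- c("issa_strata", "data.frame")
  out
}
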