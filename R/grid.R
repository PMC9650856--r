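# Minimal single-band raster container: a value matrix plus an affine
# transform (square cells, axis-aligned, row 1 = northernmost). Rows map to
# decreasing y, columns to increasing x; cell (r, c) has center
#   x = xmin + (c - 0.5) * cellsize,  y = ymax - (r - 0.5) * cellsize.

#' Construct a grid
#'
#' @param values numeric matrix (row 1 is the northern edge).
#' @param xmin,ymin projected coordinates (meters) of the lower-left corner.
#' @param cellsize cell edge length in meters (> 0).
#' @param nodata value marking missing cells (stored as NA internally).
#' @return object of class `issa_grid`.
#' @export
grid_create <- function(values, xmin = 0, ymin = 0, cellsize = 500, nodata = NA_real_) {
  values <- as.matrix(values)
  if (!is.numeric(cellsize) || cellsize <= 0) stop_config("cellsize must be > 0")
  if (!is.na(nodata)) values[values == nodata] <- NA_real_
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize,
                 nrow = nrow(values), ncol = ncol(values)),
            class = "issa_grid")
}

#' @export
print.issa_grid <- function(x, ...) {
  cat("<issa_grid> ", x$nrow, "x", x$ncol, " cells @ ", x$cellsize, " m, origin (",
      x$xmin, ", ", x$ymin, "), ", sum(is.na(x$values)), " no-data cells\n", sep = "")
  invisible(x)
}

grid_ymax <- function(g) g$ymin + g$nrow * g$cellsize
grid_xmax <- function(g) g$xmin + g$ncol * g$cellsize

grid_same_geometry <- function(a, b) {
  isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize, a$nrow, a$ncol),
                   c(b$xmin, b$ymin, b$cellsize, b$nrow, b$ncol)))
}

#' Extract grid values at points
#'
#' @param g a `issa_grid`.
#' @param x,y point coordinates in meters.
#' @param method `"nearest"` (cell containing the point; the default, used at
#'   the analysis resolution) or `"bilinear"` (4-neighbor weighted average of
#'   cell centers, no-data neighbors dropped with renormalized weights).
#' @return numeric vector; NA outside the grid extent or at no-data cells.
#' @export
grid_extract <- function(g, x, y, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (method == "nearest") {
    col <- floor((x - g$xmin) / g$cellsize) + 1
    row <- floor((grid_ymax(g) - y) / g$cellsize) + 1
    ok <- col >= 1 & col <= g$ncol & row >= 1 & row <= g$nrow & is.finite(x) & is.finite(y)
    out <- rep(NA_real_, length(x))
    out[ok] <- g$values[cbind(row[ok], col[ok])]
    out
  } else {
    vapply(seq_along(x), function(i) bilinear_at(g, x[i], y[i]), numeric(1))
  }
}

# Bilinear interpolation at one point from the 4 surrounding cell centers.
bilinear_at <- function(g, px, py) {
  if (!is.finite(px) || !is.finite(py)) return(NA_real_)
  # fractional cell-center coordinates
  fc <- (px - g$xmin) / g$cellsize - 0.5
  fr <- (grid_ymax(g) - py) / g$cellsize - 0.5
  c0 <- floor(fc); r0 <- floor(fr)
  wc <- fc - c0; wr <- fr - r0
  vals <- numeric(4); wts <- numeric(4); k <- 0L
  for (dr in 0:1) for (dc in 0:1) {
    r <- r0 + dr + 1; c <- c0 + dc + 1
    w <- (if (dr == 0) 1 - wr else wr) * (if (dc == 0) 1 - wc else wc)
    if (r >= 1 && r <= g$nrow && c >= 1 && c <= g$ncol && !is.na(g$values[r, c])) {
      k <- k + 1L
      vals[k] <- g$values[r, c]; wts[k] <- w
    }
  }
  if (k == 0L || sum(wts[1:k]) <= 0) return(NA_real_)
  sum(vals[1:k] * wts[1:k]) / sum(wts[1:k])
}

#' Resample a grid to a coarser or finer cell size by bilinear interpolation
#'
#' The target grid covers the same extent with square cells of `target_cell`
#' meters; each target cell takes the bilinear interpolation of the source at
#' its center (no-data source cells excluded with renormalized weights).
#'
#' @param g source `issa_grid`.
#' @param target_cell target cell size in meters (default 500, the analysis
#'   resolution).
#' @return a `issa_grid` at the target resolution.
#' @export
resample_bilinear <- function(g, target_cell = 500) {
  if (target_cell <= 0) stop_config("target cell size must be > 0")
  nr <- max(1L, round((grid_ymax(g) - g$ymin) / target_cell))
  nc <- max(1L, round((grid_xmax(g) - g$xmin) / target_cell))
  xs <- g$xmin + (seq_len(nc) - 0.5) * target_cell
  ys <- grid_ymax(g) - (seq_len(nr) - 0.5) * target_cell
  if (all(xs < g$xmin) || all(xs > grid_xmax(g)))
    stop_data("target extent disjoint from source grid")
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr))
    vals[r, ] <- vapply(xs, function(px) bilinear_at(g, px, ys[r]), numeric(1))
  grid_create(vals, xmin = g$xmin, ymin = grid_ymax(g) - nr * target_cell,
              cellsize = target_cell)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster with affine georeferencing in the header;
#' readable by standard GIS tooling.
#'
#' @param g a `issa_grid`.
#' @param path output path (conventionally `layer_YYYYMMDD.asc` for dated
#'   layers).
#' @param digits significant digits written.
#' @return `path`, invisibly.
#' @export
grid_write_ascii <- function(g, path, digits = 7) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", g$ncol),
               paste("nrows", g$nrow),
               paste("xllcorner", format(g$xmin, scientific = FALSE)),
               paste("yllcorner", format(g$ymin, scientific = FALSE)),
               paste("cellsize", format(g$cellsize, scientific = FALSE)),
               "NODATA_value -9999"), con)
  v <- g$values
  v[is.na(v)] <- -9999
  for (r in seq_len(g$nrow))
    writeLines(paste(signif(v[r, ], digits), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path path to a `.asc` file.
#' @return a `issa_grid`.
#' @export
grid_read_ascii <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  dat <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  grid_create(m, xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
              cellsize = val[["cellsize"]],
              nodata = if ("nodata_value" %in% key) val[["nodata_value"]] else NA_real_)
}
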