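# Track handling: raw GPS fixes -> regular bursts -> steps with movement
# attributes. Coordinates must already be projected in meters (e.g. UTM);
# geographic coordinates are rejected rather than reprojected.

#' Construct a fix table
#'
#' A fix table holds time-stamped animal locations plus the release date of
#' each animal (used downstream to compute post-release experience). This
#' constructor validates an in-memory data frame; use [read_fixes()] to load
#' one from disk.
#'
#' @param df data frame with columns `animal_id`, `timestamp` (POSIXct or
#'   ISO-8601 character, UTC), `x`, `y` (projected meters) and `release_date`.
#' @return a `issa_fixes` data frame sorted by animal then time, with
#'   duplicate (animal, timestamp) rows collapsed.
#' @export
fixes <- function(df) {
  required <- c("animal_id", "timestamp", "x", "y", "release_date")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_config("fix table is missing required column(s): ",
                paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, required]
  df$animal_id <- as.character(df$animal_id)

  if (!inherits(df$timestamp, "POSIXct")) {
    parsed <- parse_utc(as.character(df$timestamp))
    bad <- which(is.na(parsed) & !is.na(df$timestamp))
    if (length(bad) > 0)
      stop_data("unparseable timestamp in row(s): ",
                paste(utils::head(bad, 20), collapse = ", "),
                if (length(bad) > 20) " ..." else "")
    df$timestamp <- parsed
  }
  df$timestamp <- as_utc(df$timestamp)
  if (!inherits(df$release_date, "POSIXct")) {
    rel <- parse_utc(as.character(df$release_date))
    if (anyNA(rel[!is.na(df$release_date)]))
      stop_data("unparseable release_date value(s)")
    df$release_date <- as_utc(rel)
  }

  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop_config("x and y must be numeric projected coordinates in meters")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop_data("non-finite coordinates in fix table")
  # A projected study area spans kilometers; values inside lon/lat bounds for
  # every fix almost certainly mean unprojected geographic coordinates.
  if (all(abs(df$x) <= 360) && all(abs(df$y) <= 90))
    stop_config("coordinates look like longitude/latitude; ",
                "supply projected coordinates in meters (e.g. UTM)")

  ord <- order(df$animal_id, df$timestamp)
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[, c("animal_id", "timestamp")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (animal, timestamp) fix(es) dropped")
    df <- df[!dup, , drop = FALSE]
  }
  late <- tapply(seq_len(nrow(df)), df$animal_id, function(i) {
    any(df$release_date[i] > min(df$timestamp[i]))
  })
  if (any(unlist(late)))
    stop_data("release_date after first fix for animal(s): ",
              paste(names(late)[unlist(late)], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("issa_fixes", "data.frame")
  df
}

#' Read GPS fixes from a delimited text file
#'
#' @param path path to a CSV file.
#' @param column_map named character vector mapping the canonical names
#'   (`animal_id`, `timestamp`, `x`, `y`, `release_date`) to the column names
#'   used in the file. Entries may be omitted when the file already uses the
#'   canonical name.
#' @return a validated `issa_fixes` data frame (see [fixes()]).
#' @export
read_fixes <- function(path, column_map = character()) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (canon in names(column_map)) {
    src <- column_map[[canon]]
    if (!src %in% names(raw))
      stop_config("mapped column '", src, "' (for ", canon, ") not in file")
    names(raw)[names(raw) == src] <- canon
  }
  fixes(raw)
}

#' Resample fixes to a regular interval and split into bursts
#'
#' Mixed fix schedules (1/2/4 h collars) are reduced to a common interval by
#' greedy forward selection: starting from an anchor fix, the fix closest to
#' `anchor + interval` within `+/- tolerance` is retained and becomes the next
#' anchor. A gap longer than `interval + tolerance` closes the burst; bursts
#' with fewer than 3 fixes cannot yield a turning angle and are dropped.
#'
#' @param fx a `issa_fixes` table.
#' @param interval_hours target interval in hours (default 4).
#' @param tolerance_mins half-width of the acceptance window in minutes
#'   (default 30, i.e. 12.5% of a 4-h interval).
#' @return a `issa_bursts` data frame: the retained fixes plus a `burst_id`
#'   column; attribute `dropped_bursts` counts bursts discarded for being
#'   too short.
#' @export
resample_to_interval <- function(fx, interval_hours = 4, tolerance_mins = 30) {
  if (!is.numeric(interval_hours) || interval_hours <= 0)
    stop_config("interval must be positive")
  if (tolerance_mins < 0) stop_config("tolerance must be non-negative")
  stopifnot(inherits(fx, "issa_fixes"))
  interval <- interval_hours * 3600
  tol <- tolerance_mins * 60

  pieces <- list()
  dropped <- 0L
  for (id in unique(fx$animal_id)) {
    sub <- fx[fx$animal_id == id, , drop = FALSE]
    tt <- as.numeric(sub$timestamp)
    n <- length(tt)
    keep <- integer(0)
    burst <- integer(0)
    b <- 1L
    i <- 1L
    keep <- c(keep, i); burst <- c(burst, b)
    while (TRUE) {
      target <- tt[i] + interval
      cand <- which(tt > tt[i] & abs(tt - target) <= tol)
      if (length(cand) > 0) {
        j <- cand[which.min(abs(tt[cand] - target))]
        keep <- c(keep, j); burst <- c(burst, b)
        i <- j
      } else {
        nxt <- which(tt > tt[i])
        if (length(nxt) == 0) break
        b <- b + 1L
        i <- nxt[1]
        keep <- c(keep, i); burst <- c(burst, b)
      }
    }
    out <- sub[keep, , drop = FALSE]
    out$burst_id <- paste0(id, "_", burst)
    sizes <- table(out$burst_id)
    short <- names(sizes)[sizes < 3]
    dropped <- dropped + length(short)
    out <- out[!out$burst_id %in% short, , drop = FALSE]
    pieces[[id]] <- out
  }
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  if (dropped > 0)
    message(dropped, " burst(s) shorter than 3 fixes dropped")
  attr(res, "dropped_bursts") <- dropped
  attr(res, "interval_hours") <- interval_hours
  attr(res, "tolerance_mins") <- tolerance_mins
  class(res) <- c("issa_bursts", "data.frame")
  res
}

#' Classify a timestamp into the dry or wet period
#'
#' The study year is split by calendar month: January-June is the dry period
#' (virtually no precipitation, senescent vegetation) and July-December the
#' wet period (most precipitation, peak vegetation growth).
#'
#' @param timestamp POSIXct vector (UTC).
#' @param dry_months integer months defining the dry period (default 1:6).
#' @return factor with levels `dry`, `wet`.
#' @export
assign_period <- function(timestamp, dry_months = 1:6) {
  m <- as.integer(format(as_utc(timestamp), "%m", tz = "UTC"))
  factor(ifelse(m %in% dry_months, "dry", "wet"), levels = c("dry", "wet"))
}

#' Build steps from resampled bursts
#'
#' One step per consecutive fix pair within a burst. Step length is the
#' Euclidean displacement (floored at 1 m, below GPS error, so that log step
#' length is finite for stationary fixes); absolute heading comes from
#' `atan2` of the displacement; the turning angle is the wrapped difference
#' of successive headings and is undefined (NA) for the first step of each
#' burst. The period label is taken from the step's start timestamp (a step
#' is an action initiated at its start).
#'
#' @param bursts a `issa_bursts` table from [resample_to_interval()].
#' @param dry_months passed to [assign_period()].
#' @return a `issa_steps` data frame with columns `animal_id`, `burst_id`,
#'   `t1`, `t2`, `x1`, `y1`, `x2`, `y2`, `sl`, `log_sl`, `heading`, `ta`,
#'   `prev_heading`, `period`.
#' @export
build_steps <- function(bursts, dry_months = 1:6) {
  stopifnot(inherits(bursts, "data.frame"))
  if (!"burst_id" %in% names(bursts))
    stop_config("bursts must carry a burst_id column; run resample_to_interval() first")
  pieces <- lapply(split(seq_len(nrow(bursts)), bursts$burst_id), function(idx) {
    sub <- bursts[idx, , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) return(NULL)
    dx <- diff(sub$x); dy <- diff(sub$y)
    sl <- pmax(sqrt(dx^2 + dy^2), 1)
    heading <- atan2(dy, dx)
    ta <- c(NA_real_, wrap_angle(diff(heading)))
    data.frame(animal_id = sub$animal_id[-n],
               burst_id = sub$burst_id[-n],
               t1 = sub$timestamp[-n], t2 = sub$timestamp[-1],
               x1 = sub$x[-n], y1 = sub$y[-n],
               x2 = sub$x[-1], y2 = sub$y[-1],
               sl = sl, log_sl = log(sl),
               heading = heading, ta = ta,
               prev_heading = c(NA_real_, heading[-(n - 1)]),
               stringsAsFactors = FALSE)
  })
  steps <- do.call(rbind, pieces)
  rownames(steps) <- NULL
  steps$period <- assign_period(steps$t1, dry_months)
  class(steps) <- c("issa_steps", "data.frame")
  steps
}

#' Write a step table to CSV
#'
#' Column order: animal_id, t_start, t_end, x1, y1, x2, y2, sl, heading, ta,
#' period, burst_id.
#'
#' @param steps a `issa_steps` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_steps <- function(steps, path) {
  out <- data.frame(animal_id = steps$animal_id,
                    t_start = format(steps$t1, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    t_end = format(steps$t2, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    x1 = steps$x1, y1 = steps$y1, x2 = steps$x2, y2 = steps$y2,
                    sl = steps$sl, heading = steps$heading, ta = steps$ta,
                    period = as.character(steps$period),
                    burst_id = steps$burst_id)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
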