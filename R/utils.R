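# Internal helpers shared across modules.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @keywords internal
#' @noRd
wrap_angle <- function(x) {
  out <- ((x + pi) %% (2 * pi)) - pi
  # %% maps exact multiples to -pi; the convention here is (-pi, pi]
  out[out <= -pi] <- pi
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("issa_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("issa_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Derive a deterministic sub-seed for a named random substream
#'
#' All randomness in the package flows from one integer seed; each stage
#' (landscape, kernel, selection, grouping, ...) draws from its own substream
#' so stages can be re-run or tested in isolation without perturbing others.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return an integer seed, stable across platforms, in [0, 2^31).
#' @keywords internal
#' @noRd
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Element-wise ISO-8601-ish timestamp parsing in UTC. as.POSIXct with
# tryFormats picks one format for the whole vector, which silently truncates
# mixed inputs (e.g. a midnight fix written without its time-of-day), so
# each format is applied per element and NAs filled progressively.
parse_utc <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
              "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out) & !is.na(x) & nzchar(x))
    if (length(idx) == 0) break
    p <- as.POSIXct(strptime(x[idx], f, tz = "UTC"), tz = "UTC")
    ok <- !is.na(p)
    out[idx[ok]] <- p[ok]
  }
  out
}

# POSIXct constructor pinned to UTC; all timestamps in the package are UTC.
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}
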