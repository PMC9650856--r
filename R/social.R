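# Social moderators: chain-rule group size per 4-h time bin, and
# post-release experience in days.

#' Detect social groups in one time bin by the chain rule
#'
#' Two animals belong to the same group if they are within `threshold`
#' meters of each other, directly or through a chain of intermediate
#' animals: groups are the connected components of the proximity graph.
#' Implemented as single-linkage clustering cut at the threshold distance,
#' which yields exactly those components. A lone animal is its own group of
#' size 1 ("alone" means group size 1, not 0).
#'
#' @param positions data frame with one row per animal observed in the bin:
#'   columns `animal_id`, `x`, `y`.
#' @param threshold chain distance in meters (default 200).
#' @return data frame `animal_id`, `group_id`, `group_size`.
#' @export
detect_groups <- function(positions, threshold = 200) {
  stopifnot(all(c("animal_id", "x", "y") %in% names(positions)))
  if (anyDuplicated(positions$animal_id))
    stop_data("more than one position per animal in a bin")
  n <- nrow(positions)
  if (n == 0) return(data.frame(animal_id = character(0), group_id = integer(0),
                                group_size = integer(0)))
  if (n == 1) {
    return(data.frame(animal_id = positions$animal_id, group_id = 1L,
                      group_size = 1L, stringsAsFactors = FALSE))
  }
  d <- stats::dist(positions[, c("x", "y")])
  memb <- stats::cutree(stats::hclust(d, method = "single"), h = threshold)
  sizes <- table(memb)
  data.frame(animal_id = positions$animal_id,
             group_id = as.integer(memb),
             group_size = as.integer(sizes[as.character(memb)]),
             stringsAsFactors = FALSE)
}

#' Chain-rule group sizes for every time bin of a resampled fix table
#'
#' Each animal's resampled fix in a bin is its position for that bin; animals
#' without a fix in a bin are absent from that bin's proximity graph.
#'
#' @param bursts a `issa_bursts` (or `issa_fixes`) table.
#' @param threshold chain distance in meters (default 200).
#' @param bin_hours width of the time bin in hours (default 4, the analysis
#'   cadence).
#' @return data frame `bin_start` (POSIXct), `animal_id`, `group_id`,
#'   `group_size`.
#' @export
group_sizes <- function(bursts, threshold = 200, bin_hours = 4) {
  tt <- as.numeric(bursts$timestamp)
  bin <- floor(tt / (bin_hours * 3600))
  pieces <- lapply(split(seq_len(nrow(bursts)), bin), function(idx) {
    sub <- bursts[idx, , drop = FALSE]
    # one position per animal per bin: keep the first fix
    sub <- sub[!duplicated(sub$animal_id), , drop = FALSE]
    g <- detect_groups(sub[, c("animal_id", "x", "y")], threshold = threshold)
    g$bin_start <- as_utc(min(sub$timestamp))
    attr(g$bin_start, "tzone") <- "UTC"
    g$bin <- bin[idx[1]]
    g
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("bin", "bin_start", "animal_id", "group_id", "group_size")]
}

#' Post-release experience in days
#'
#' @param timestamp POSIXct fix times.
#' @param release_date POSIXct release date(s), recycled.
#' @return fractional days since release (>= 0).
#' @export
experience_days <- function(timestamp, release_date) {
  d <- as.numeric(as_utc(timestamp)) - as.numeric(as_utc(release_date))
  if (any(d < 0)) stop_data("fix timestamp precedes release date")
  d / 86400
}

#' Attach group-size and experience moderators to strata
#'
#' Both moderators are constant within a stratum: they are evaluated at the
#' stratum's start fix (the decision point) and replicated to the used and
#' all available rows.
#'
#' @param strata a `issa_strata` table.
#' @param groups output of [group_sizes()] for the same fixes.
#' @param release_dates named vector/list: POSIXct release date per
#'   animal_id.
#' @param bin_hours bin width used when building `groups`.
#' @return strata with `group_size` and `experience` columns appended.
#' @export
attach_moderators <- function(strata, groups, release_dates, bin_hours = 4) {
  bin <- floor(as.numeric(strata$t1) / (bin_hours * 3600))
  key <- paste(bin, strata$animal_id)
  gkey <- paste(groups$bin, groups$animal_id)
  m <- match(key, gkey)
  if (anyNA(m)) {
    miss <- unique(strata$stratum_id[is.na(m)])
    stop_data("no group record for ", length(miss), " strata (first: ",
              paste(utils::head(miss, 5), collapse = ", "), ")")
  }
  strata$group_size <- groups$group_size[m]
  rel <- as_utc(do.call(c, as.list(release_dates[strata$animal_id])))
  strata$experience <- experience_days(strata$t1, rel)
  strata
}
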