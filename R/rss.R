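# Relative selection strength: exponentiated coefficients and log-RSS
# prediction curves over a covariate's standardized range, with delta-method
# confidence bands and -1/0/+1 SD moderator levels.

#' Relative selection strength of a coefficient
#'
#' `RSS = exp(beta)`: the ratio of selection probabilities between two
#' locations differing by one (standardized) unit of the covariate, all else
#' equal. Strictly increasing in beta, with `rss(-b) = 1/rss(b)` and
#' `rss(0) = 1` (no selection).
#'
#' @param beta coefficient(s).
#' @return numeric vector of RSS values.
#' @export
rss_from_coefficient <- function(beta) {
  if (any(!is.finite(beta))) stop_data("RSS needs finite coefficients")
  exp(beta)
}

#' Categorize standardized moderator values into -1 / 0 / +1 SD levels
#'
#' Values at least one SD below the mean are the low category (`"-1"`),
#' values within one SD of the mean the median category (`"0"`), and values
#' at least one SD above the mean the high category (`"+1"`).
#'
#' @param z standardized moderator values.
#' @return factor with levels `-1`, `0`, `+1`.
#' @export
moderator_categories <- function(z) {
  lab <- ifelse(z <= -1, "-1", ifelse(z >= 1, "+1", "0"))
  factor(lab, levels = c("-1", "0", "+1"))
}

# Find the fitted-term names attached to a base covariate.
rss_terms <- function(fit, covariate, moderator = NULL) {
  cn <- names(fit$coef)
  quad <- paste0(covariate, "_sq")
  int <- if (!is.null(moderator)) paste0(covariate, ":", moderator) else NULL
  if (!covariate %in% cn)
    stop_config("covariate '", covariate, "' is not in the fitted roster")
  if (!is.null(int) && !int %in% cn)
    stop_config("interaction '", int, "' is not in the fitted roster")
  list(lin = covariate,
       quad = if (quad %in% cn) quad else NULL,
       int = int)
}

#' Log-RSS prediction curve for one covariate
#'
#' Computes `log-RSS(x; x_ref) = b_lin (x - x_ref) + b_quad (x^2 - x_ref^2)
#' + m b_int (x - x_ref)` on a grid of standardized covariate values, where
#' `m` is the moderator level in SD units (0 when no moderator is given).
#' The pointwise variance comes from the delta method on the robust
#' covariance of the involved coefficients, and the confidence band is
#' symmetric on the log scale. At `x = x_ref` the RSS is exactly 1 with a
#' zero-width band.
#'
#' @param fit a `issa_fit`.
#' @param covariate base covariate name (e.g. `"andvi"`, or a movement term
#'   such as `"sl"`).
#' @param x numeric grid of standardized covariate values.
#' @param x_ref reference value (default 0, the period mean, where the curve
#'   crosses RSS = 1).
#' @param moderator optional moderator name (`"experience"`/`"group_size"`).
#' @param level moderator level in SD units, typically -1, 0 or +1.
#' @param conf confidence level for the band (default 0.95).
#' @return data frame of class `issa_rss_curve`: `covariate`, `x`,
#'   `moderator_level`, `log_rss`, `rss`, `lo`, `hi`.
#' @export
log_rss_curve <- function(fit, covariate, x = seq(-2, 2, length.out = 101),
                          x_ref = 0, moderator = NULL, level = 0, conf = 0.95) {
  tm <- rss_terms(fit, covariate, moderator)
  terms <- c(tm$lin, tm$quad, tm$int)
  b <- fit$coef[terms]
  V <- vcov(fit, "robust")[terms, terms, drop = FALSE]
  # gradient of log-RSS wrt the involved coefficients, per grid point
  G <- cbind(x - x_ref,
             if (!is.null(tm$quad)) x^2 - x_ref^2,
             if (!is.null(tm$int)) level * (x - x_ref))
  lr <- drop(G %*% b)
  se <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(covariate = covariate, x = x,
                    moderator_level = if (is.null(moderator)) NA_real_ else level,
                    log_rss = lr, rss = exp(lr),
                    lo = exp(lr - zq * se), hi = exp(lr + zq * se),
                    stringsAsFactors = FALSE)
  class(out) <- c("issa_rss_curve", "data.frame")
  out
}

#' Plot an RSS curve
#'
#' Base-graphics rendering: RSS against the standardized covariate with the
#' confidence band shaded and the no-selection line (RSS = 1) dotted.
#'
#' @param x a `issa_rss_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.issa_rss_curve <- function(x, ...) {
  graphics::plot(x$x, x$rss, type = "n", xlab = x$covariate[1],
                 ylab = "Relative selection strength",
                 ylim = range(c(x$lo, x$hi)), ...)
  graphics::polygon(c(x$x, rev(x$x)), c(x$lo, rev(x$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$x, x$rss, lwd = 2, col = "steelblue4")
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Coefficient/RSS table for a fitted model
#'
#' One row per fitted term: coefficient, robust SE, RSS, p-value and the
#' significance flag, in a layout suitable for reporting.
#'
#' @param fit a `issa_fit`.
#' @return data frame `term`, `coefficient`, `rss`, `se`, `p`, `significant`,
#'   `period`, `tier`.
#' @export
rss_table <- function(fit) {
  s <- summary(fit)
  data.frame(term = s$term, coefficient = s$coefficient, rss = s$rss,
             se = s$se, p = s$p, significant = s$significant,
             period = fit$period %||% NA_character_,
             tier = fit$tier %||% NA_character_,
             stringsAsFactors = FALSE)
}
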