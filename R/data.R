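#' Reference coefficient table for the oryx reintroduction iSSF
#'
#' Published population-level coefficient estimates, robust standard errors
#' and relative selection strengths from the final dry- and wet-period
#' integrated step-selection functions for scimitar-horned oryx reintroduced
#' into central Chad (two release cohorts, 32 GPS-collared animals, 4-h
#' steps, 9 available steps per used step). Terms follow the package's
#' design-column naming ([design_roster()]): movement terms `sl`/`log_sl`,
#' environmental mains, `_sq` quadratics, and `base:moderator` interactions.
#' Useful as a structural reference for the expected output of
#' [rss_table()] and for checking the RSS = exp(coefficient) identity; the
#' underlying movement data are not redistributable, so these estimates
#' cannot be recomputed here.
#'
#' @return data frame with columns `term`, `period`, `coefficient`, `rss`,
#'   `se`, `significant`.
#' @export
reference_coefficients <- function() {
  path <- system.file("extdata", "oryx_issf_reference.csv", package = "issa",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
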