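# Design construction for the four candidate models: standardization,
# quadratic terms, moderator interactions, and the VIF collinearity screen.
#
# Candidate tiers per period:
#   M1  environmental covariates only
#   M2  environmental + experience interactions
#   M3  environmental + group-size interactions
#   M4  environmental + experience + group-size interactions
# All tiers carry the movement correction terms (step length, log step
# length). Temperature enters with a quadratic and with moderator
# interactions in the dry period only (its wet-period effect is close to
# linear and weak); this is configurable.

issa_env_covariates <- c("andvi", "dndvi", "elev", "tri", "temp")
issa_moderators <- c("experience", "group_size")

#' Center and standardize covariate columns
#'
#' Each column is transformed to `(x - mean) / sd` (sample SD, n-1), with the
#' constants stored so that raw-scale values and the -1/0/+1 SD moderator
#' categories can be recovered. Pass `center`/`scale` to standardize with
#' fixed constants (e.g. from a fitted model, or from known landscape
#' marginals in simulation studies).
#'
#' @param df data frame holding the columns.
#' @param cols character vector of column names to standardize.
#' @param center,scale optional named numeric vectors of fixed constants.
#' @return list with `values` (data frame of standardized columns), `center`,
#'   `scale`.
#' @export
standardize_covariates <- function(df, cols, center = NULL, scale = NULL) {
  out <- df[, cols, drop = FALSE]
  ctr <- numeric(0); scl <- numeric(0)
  for (cl in cols) {
    x <- as.numeric(out[[cl]])
    if (any(!is.finite(x))) stop_data("non-finite values in covariate '", cl, "'")
    m <- if (!is.null(center) && cl %in% names(center)) center[[cl]] else mean(x)
    s <- if (!is.null(scale) && cl %in% names(scale)) scale[[cl]] else stats::sd(x)
    if (!is.finite(s) || s <= 0)
      stop_data("zero-variance covariate column: '", cl, "'")
    out[[cl]] <- (x - m) / s
    ctr[cl] <- m; scl[cl] <- s
  }
  list(values = out, center = ctr, scale = scl)
}

#' Column roster for one candidate model
#'
#' @param period `"dry"` or `"wet"`.
#' @param tier `"M1"`..`"M4"`.
#' @param temp_dry_only keep temperature's quadratic and interactions out of
#'   the wet-period models (default TRUE).
#' @return character vector of design column names; interactions are named
#'   `base:moderator`, quadratics `base_sq`.
#' @export
design_roster <- function(period = c("dry", "wet"), tier = c("M1", "M2", "M3", "M4"),
                          temp_dry_only = TRUE) {
  period <- match.arg(period); tier <- match.arg(tier)
  temp_in <- period == "dry" || !temp_dry_only
  move <- c("sl", "log_sl")
  quads <- c("andvi_sq", "dndvi_sq", if (temp_in) "temp_sq")
  targets <- c(move, "andvi", "dndvi", "elev", "tri", if (temp_in) "temp")
  mods <- switch(tier, M1 = character(0), M2 = "experience",
                 M3 = "group_size", M4 = c("experience", "group_size"))
  ints <- if (length(mods) == 0) character(0)
    else as.vector(t(outer(targets, mods, function(a, b) paste0(a, ":", b))))
  c(move, issa_env_covariates, quads, ints)
}

#' Build the design for one candidate model
#'
#' Base covariates (movement terms, environmental covariates, moderators)
#' are standardized over all rows of the period's strata; quadratics and
#' interactions are products of the standardized bases and are not
#' re-standardized, so moderator levels stay interpretable in SD units.
#' Moderator main effects are constant within strata and therefore carry no
#' information in the conditional likelihood; they are excluded from the
#' estimable design (with a warning) unless `keep_inestimable = TRUE`.
#'
#' @param strata a `issa_strata` table with covariates ([extract_covariates()])
#'   and moderators ([attach_moderators()]) attached.
#' @param period `"dry"` or `"wet"`; strata of the other period are dropped.
#' @param tier candidate model `"M1"`..`"M4"`.
#' @param center,scale optional fixed standardization constants (named by
#'   base covariate).
#' @param temp_dry_only see [design_roster()].
#' @param keep_inestimable include stratum-constant moderator main effects
#'   anyway (for transparency; expect near-zero, huge-SE estimates).
#' @param warn_inestimable emit the exclusion warning (default TRUE).
#' @return object of class `issa_design`: design matrix `X`, response `case`,
#'   `stratum`, `cluster`, the column manifest, and the standardization
#'   constants.
#' @export
build_design <- function(strata, period = c("dry", "wet"), tier = c("M1", "M2", "M3", "M4"),
                         center = NULL, scale = NULL, temp_dry_only = TRUE,
                         keep_inestimable = FALSE, warn_inestimable = TRUE) {
  period <- match.arg(period); tier <- match.arg(tier)
  need <- c("stratum_id", "case", "animal_id", "sl", "log_sl",
            issa_env_covariates)
  missing <- setdiff(need, names(strata))
  if (length(missing) > 0)
    stop_config("strata lack required column(s): ", paste(missing, collapse = ", "))
  mods_used <- switch(tier, M1 = character(0), M2 = "experience",
                      M3 = "group_size", M4 = issa_moderators)
  if (length(mods_used) > 0 && !all(mods_used %in% names(strata)))
    stop_config("tier ", tier, " needs moderator column(s): ",
                paste(setdiff(mods_used, names(strata)), collapse = ", "),
                "; run attach_moderators() first")
  if ("period" %in% names(strata))
    strata <- strata[as.character(strata$period) == period, , drop = FALSE]
  if (nrow(strata) == 0) stop_data("no strata in period '", period, "'")

  bases <- c("sl", "log_sl", issa_env_covariates, mods_used)
  std <- standardize_covariates(strata, bases, center = center, scale = scale)
  z <- std$values

  roster <- design_roster(period, tier, temp_dry_only)
  X <- matrix(NA_real_, nrow(strata), length(roster),
              dimnames = list(NULL, roster))
  for (cl in roster) {
    if (cl %in% bases) {
      X[, cl] <- z[[cl]]
    } else if (grepl("_sq$", cl)) {
      X[, cl] <- z[[sub("_sq$", "", cl)]]^2
    } else {
      parts <- strsplit(cl, ":", fixed = TRUE)[[1]]
      X[, cl] <- z[[parts[1]]] * z[[parts[2]]]
    }
  }
  if (length(mods_used) > 0) {
    if (keep_inestimable) {
      Xm <- sapply(mods_used, function(m) z[[m]])
      colnames(Xm) <- mods_used
      X <- cbind(X, Xm)
      roster <- c(roster, mods_used)
    } else if (warn_inestimable) {
      warning("moderator main effect(s) ", paste(mods_used, collapse = ", "),
              " are constant within strata and were excluded from the ",
              "estimable design (use keep_inestimable = TRUE to force them in)",
              call. = FALSE)
    }
  }
  structure(list(X = X, case = as.integer(strata$case),
                 stratum = as.character(strata$stratum_id),
                 cluster = as.character(strata$animal_id),
                 columns = roster,
                 center = std$center, scale = std$scale,
                 period = period, tier = tier,
                 n_available = attr(strata, "n_available")),
            class = "issa_design")
}

#' @export
print.issa_design <- function(x, ...) {
  cat("<issa_design> ", x$period, "/", x$tier, ": ", nrow(x$X), " rows, ",
      length(unique(x$stratum)), " strata, ", ncol(x$X), " columns\n", sep = "")
  cat("  columns: ", paste(x$columns, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each design column on all the
#' others (with intercept). Values of 4 or more trigger a collinearity
#' warning; perfectly collinear columns report `Inf`.
#'
#' @param x a `issa_design` or a numeric matrix with >= 2 columns.
#' @param warn_at warning threshold (default 4).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x, warn_at = 4) {
  X <- if (inherits(x, "issa_design")) x$X else as.matrix(x)
  if (ncol(X) < 2) stop_config("VIF needs at least 2 columns")
  out <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Zj, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(!is.finite(out) | out >= warn_at))
    warning("collinear design columns (VIF >= ", warn_at, "): ",
            paste(names(out)[!is.finite(out) | out >= warn_at], collapse = ", "),
            call. = FALSE)
  out
}
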