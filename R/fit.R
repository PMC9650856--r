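# Conditional logistic (stratified partial-likelihood) estimation with
# cluster-robust variance: the estimation core of the package.
#
# For strata s with rows j, linear predictors eta = X beta, and exactly one
# used row per stratum, the log partial likelihood is
#   l(beta) = sum_s [ eta_case(s) - log sum_j exp(eta_sj) ].
# Newton-Raphson with the analytic gradient and Hessian; the robust
# (sandwich) covariance aggregates per-stratum scores by cluster (animal):
#   V_robust = A^-1 B A^-1,  A = observed information,
#   B = sum_c (sum_{s in c} u_s)(sum_{s in c} u_s)'.

#' Fit an integrated step-selection function
#'
#' `fit_issf()` is a generic: give it either a design built by
#' [build_design()], or a formula plus a data frame of strata rows.
#'
#' @param x a `issa_design`, or a formula such as
#'   `case ~ sl + log_sl + andvi` (no intercept is ever included; the
#'   conditional likelihood absorbs it).
#' @param ... passed on to methods / the Newton optimizer: `tol` (gradient
#'   max-norm convergence tolerance, default 1e-8), `max_iter` (default 50).
#' @return object of class `issa_fit`; see Details.
#' @details The returned object carries `coef`, `vcov_naive` (inverse
#'   observed information), `vcov_robust` (cluster sandwich), `loglik`,
#'   `loglik_null` (at beta = 0; equal to `-sum(log stratum size)`),
#'   `k`, `n_strata`, `n_clusters`, convergence diagnostics, and the
#'   standardization constants when fitted from a `issa_design`.
#' @export
fit_issf <- function(x, ...) UseMethod("fit_issf")

#' @rdname fit_issf
#' @export
fit_issf.issa_design <- function(x, ...) {
  fit <- clogit_newton(x$X, x$case, x$stratum, x$cluster, ...)
  fit$period <- x$period
  fit$tier <- x$tier
  fit$center <- x$center
  fit$scale <- x$scale
  fit
}

#' @rdname fit_issf
#' @param data data frame containing the model variables plus `stratum` /
#'   `cluster` columns (formula method).
#' @param stratum,cluster column names in `data` identifying the stratum and
#'   the cluster (formula method; defaults `"stratum_id"`, `"animal_id"`).
#' @export
fit_issf.formula <- function(x, data, stratum = "stratum_id",
                             cluster = "animal_id", ...) {
  mf <- stats::model.frame(x, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(x, data = mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  clogit_newton(X, as.integer(y), as.character(data[[stratum]]),
                as.character(data[[cluster]]), ...)
}

clogit_newton <- function(X, case, stratum, cluster, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  sf <- factor(stratum, levels = unique(stratum))
  si <- as.integer(sf)
  ns <- nlevels(sf)
  counts <- tabulate(si, ns)
  case_per <- tapply(case, si, sum)
  if (any(case_per != 1))
    stop_data("every stratum must contain exactly one used (case = 1) row")
  const <- apply(X, 2, function(cl) all(tapply(cl, si, function(v) max(v) - min(v)) < 1e-12))
  if (any(const))
    stop_data("stratum-constant column(s) carry no information in the ",
              "conditional likelihood: ", paste(colnames(X)[const], collapse = ", "))

  case_rows <- which(case == 1)
  case_rows <- case_rows[order(si[case_rows])]   # row of the case in stratum order
  cl_of_stratum <- cluster[case_rows]

  loglik_at <- function(beta) {
    eta <- drop(X %*% beta)
    smax_s <- as.numeric(tapply(eta, si, max))
    denom_s <- as.numeric(rowsum(exp(eta - smax_s[si]), si))
    list(eta = eta, smax = smax_s[si], denom = denom_s,
         ll = sum(eta[case_rows]) - sum(log(denom_s) + smax_s))
  }

  beta <- rep(0, p)
  st <- loglik_at(beta)
  ll0 <- -sum(log(counts))       # l(0): uniform weights within each stratum
  ll <- st$ll
  iter <- 0L; converged <- FALSE; gnorm <- NA_real_
  repeat {
    w <- exp(st$eta - st$smax) / st$denom[si]     # softmax weights within stratum
    M <- rowsum(X * w, si)                        # per-stratum weighted means
    U_s <- X[case_rows, , drop = FALSE] - M       # per-stratum scores
    U <- colSums(U_s)
    gnorm <- max(abs(U))
    if (gnorm < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    H <- crossprod(X, X * w) - crossprod(M)       # observed information
    step <- tryCatch(solve(H, U), error = function(e)
      stop_data("singular information matrix; check the design for collinearity"))
    if (max(abs(step)) > 25 || any(!is.finite(step)))
      stop_data("divergent Newton step: a column may perfectly separate ",
                "used from available rows (separation)")
    # step-halving if the likelihood would decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      stc <- loglik_at(cand)
      if (stc$ll >= ll - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- cand; st <- stc; ll <- stc$ll
    iter <- iter + 1L
  }
  if (!converged)
    stop_data("conditional logistic fit did not converge in ", max_iter,
              " iterations (gradient max-norm ", format(gnorm), ")")
  # a huge coefficient with a flat gradient is separation, not convergence:
  # the likelihood is monotone in that direction and exp() drowns the score
  if (max(abs(beta)) > 15)
    stop_data("coefficient diverged beyond exp(15); a column (nearly) ",
              "perfectly separates used from available rows (separation)")
  w <- exp(st$eta - st$smax) / st$denom[si]
  M <- rowsum(X * w, si)
  U_s <- X[case_rows, , drop = FALSE] - M
  H <- crossprod(X, X * w) - crossprod(M)
  A_inv <- solve(H)
  cf <- factor(cl_of_stratum)
  S <- rowsum(U_s, cf)                            # per-cluster score sums
  G <- nlevels(cf)
  # CR1 small-sample multiplier: the plain outer-product B underestimates
  # the score variance when clusters are few (here, tens of animals)
  B <- crossprod(S) * if (G > 1) G / (G - 1) else 1
  V_rob <- A_inv %*% B %*% A_inv
  names(beta) <- colnames(X)
  dimnames(A_inv) <- dimnames(V_rob) <- list(colnames(X), colnames(X))

  structure(list(coef = beta,
                 vcov_naive = A_inv,
                 vcov_robust = V_rob,
                 loglik = ll, loglik_null = ll0,
                 k = p, n_strata = ns, n_rows = nrow(X),
                 n_clusters = nlevels(cf),
                 converged = converged, iterations = iter,
                 gradient_norm = gnorm,
                 stratum_signature = c(ns, nrow(X), sum(si * seq_along(si)) %% 2^31)),
            class = "issa_fit")
}

#' @export
print.issa_fit <- function(x, ...) {
  cat("Integrated step-selection fit",
      if (!is.null(x$period)) paste0(" (", x$period, "/", x$tier, ")"), "\n", sep = "")
  cat("  strata: ", x$n_strata, "  clusters: ", x$n_clusters,
      "  coefficients: ", x$k, "\n", sep = "")
  cat("  log partial likelihood: ", format(x$loglik), "  AICc: ",
      format(AICc(x)), "\n", sep = "")
  print(round(x$coef, 6))
  invisible(x)
}

#' @export
coef.issa_fit <- function(object, ...) object$coef

#' @export
vcov.issa_fit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$vcov_robust else object$vcov_naive
}

#' @export
logLik.issa_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_strata,
            class = "logLik")
}

#' @export
nobs.issa_fit <- function(object, ...) object$n_strata

#' Summarize a step-selection fit
#'
#' Coefficients with robust standard errors, relative selection strengths
#' (`RSS = exp(beta)`), normal-reference two-sided p-values, and a
#' significance flag at p < 0.05.
#'
#' @param object a `issa_fit`.
#' @param type which covariance feeds the SEs (default robust).
#' @param ... unused.
#' @return data frame with one row per coefficient, class `summary.issa_fit`.
#' @export
summary.issa_fit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  se <- sqrt(diag(vcov(object, type)))
  z <- object$coef / se
  pv <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(term = names(object$coef),
                    coefficient = unname(object$coef),
                    rss = exp(unname(object$coef)),
                    se = unname(se), z = unname(z), p = unname(pv),
                    significant = unname(pv < 0.05),
                    stringsAsFactors = FALSE)
  attr(out, "loglik") <- object$loglik
  attr(out, "aicc") <- AICc(object)
  attr(out, "se_type") <- type
  class(out) <- c("summary.issa_fit", "data.frame")
  out
}

#' @export
print.summary.issa_fit <- function(x, ...) {
  cat("Coefficients (", attr(x, "se_type"), " SEs); logLik ",
      format(attr(x, "loglik")), ", AICc ", format(attr(x, "aicc")), "\n", sep = "")
  df <- as.data.frame(x)
  df$coefficient <- round(df$coefficient, 6)
  df$rss <- round(df$rss, 6)
  df$se <- round(df$se, 6)
  df$z <- round(df$z, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 l + 2k + 2k(k+1)/(n - k - 1)` with `n` the number of strata
#' (the independent contributions to the conditional likelihood).
#'
#' @param fit a `issa_fit`, or anything with `loglik`/`k`/`n_strata` supplied
#'   via the explicit arguments.
#' @param loglik,k,n override/raw inputs for the closed form.
#' @return numeric AICc value.
#' @export
AICc <- function(fit = NULL, loglik = fit$loglik, k = fit$k, n = fit$n_strata) {
  if (n <= k + 1) stop_data("AICc undefined: n (", n, ") <= k + 1 (", k + 1, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' All candidates must be fitted on the identical strata set; ties in AICc
#' break toward the smaller model.
#'
#' @param fits named list of `issa_fit` objects (e.g. M1..M4).
#' @return data frame `tier`, `k`, `logLik`, `AICc`, `deltaAICc`, `rank`,
#'   class `issa_model_comparison`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2)
  sigs <- lapply(fits, `[[`, "stratum_signature")
  if (!all(vapply(sigs, function(s) isTRUE(all.equal(s, sigs[[1]])), logical(1))))
    stop_data("candidates were fitted on different strata; AICc not comparable")
  tiers <- names(fits) %||% paste0("M", seq_along(fits))
  tab <- data.frame(tier = tiers,
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    logLik = vapply(fits, `[[`, numeric(1), "loglik"),
                    AICc = vapply(fits, AICc, numeric(1)),
                    stringsAsFactors = FALSE)
  tab$deltaAICc <- tab$AICc - min(tab$AICc)
  ord <- order(tab$AICc, tab$k)
  tab$rank <- match(seq_len(nrow(tab)), ord)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  class(tab) <- c("issa_model_comparison", "data.frame")
  tab
}

#' @export
print.issa_model_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$logLik <- round(df$logLik, 2)
  df$AICc <- round(df$AICc, 2)
  df$deltaAICc <- round(df$deltaAICc, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
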