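# Movement kernel: gamma step lengths, von Mises turning angles, and the
# sampling of available steps that forms the matched strata of the
# conditional likelihood.

#' Fit a gamma distribution to observed step lengths
#'
#' Maximum likelihood via the profile score for the shape parameter:
#' `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))`, solved by
#' monotone root-finding, with `scale = mean(x) / shape`. The method-of-moments
#' estimate brackets the search.
#'
#' @param lengths positive step lengths in meters (>= 30 values).
#' @return object of class `issa_gamma` with elements `shape`, `scale`,
#'   `loglik`, `n`.
#' @export
fit_gamma <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop_data("step lengths must be positive and finite")
  if (length(lengths) < 30)
    stop_data("need at least 30 step lengths to fit the kernel")
  if (stats::var(lengths) == 0)
    stop_data("degenerate step lengths: all values identical")
  m <- mean(lengths)
  s <- log(m) - mean(log(lengths))   # > 0 unless degenerate
  if (s <= 0) stop_data("degenerate step lengths: zero dispersion on log scale")
  score <- function(k) log(k) - digamma(k) - s
  # Minka's closed-form start; bracket it generously for uniroot.
  k0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  root <- stats::uniroot(score, lower = k0 / 100, upper = k0 * 100,
                         extendInt = "downX", tol = 1e-10)
  shape <- root$root
  scale <- m / shape
  ll <- sum(stats::dgamma(lengths, shape = shape, scale = scale, log = TRUE))
  structure(list(shape = shape, scale = scale, loglik = ll,
                 n = length(lengths)),
            class = "issa_gamma")
}

#' Fit a von Mises distribution to observed turning angles
#'
#' The mean direction is the circular mean; the concentration solves
#' `A1(kappa) = Rbar` where `A1 = I1/I0` is the ratio of modified Bessel
#' functions and `Rbar` the mean resultant length, by monotone root-finding
#' on exponentially scaled Bessel ratios (stable for large kappa). A
#' resultant length of (numerically) zero gives `kappa = 0`, the uniform
#' circular distribution.
#'
#' @param angles turning angles in radians, wrapped to (-pi, pi] (>= 30 values).
#' @return object of class `issa_vonmises` with elements `mu`, `kappa`,
#'   `rbar`, `n`.
#' @export
fit_vonmises <- function(angles) {
  angles <- as.numeric(angles)
  angles <- angles[is.finite(angles)]
  if (length(angles) < 30)
    stop_data("need at least 30 finite turning angles to fit the kernel")
  C <- mean(cos(angles)); S <- mean(sin(angles))
  rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  kappa <- a1inv(rbar)
  structure(list(mu = mu, kappa = kappa, rbar = rbar, n = length(angles)),
            class = "issa_vonmises")
}

# Bessel ratio A1(kappa) = I1(kappa)/I0(kappa); scaled form cancels overflow.
a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Inverse of A1 by bisection-backed root finding. A1 is strictly increasing
# from 0 (kappa = 0) to 1 (kappa -> Inf).
a1inv <- function(rbar, tol = 1e-10) {
  if (rbar < 1e-12) return(0)
  if (rbar >= 1 - 1e-12) stop_data("resultant length numerically 1; angles degenerate")
  # Banerjee et al. approximation as a starting bracket
  k0 <- rbar * (2 - rbar^2) / (1 - rbar^2)
  lo <- k0 / 10; hi <- k0 * 10 + 1
  while (a1(lo) > rbar) lo <- lo / 10
  while (a1(hi) < rbar) hi <- hi * 10
  stats::uniroot(function(k) a1(k) - rbar, lower = lo, upper = hi, tol = tol)$root
}

#' Draw von Mises random angles
#'
#' Best & Fisher (1979) acceptance-rejection sampler; falls back to the
#' uniform circular distribution when `kappa` is (numerically) zero.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_angle(out + mu)
}

#' Sample available steps and assemble matched strata
#'
#' For each usable observed step (one with a defined previous heading),
#' `n_available` alternative steps are generated by drawing lengths from the
#' fitted gamma and turning angles from the fitted von Mises kernel; each
#' alternative shares the observed step's origin and start time, and its
#' absolute heading is the previous observed heading plus the sampled turn.
#' The observed step is the single `case = 1` row of its stratum.
#'
#' @param steps a `issa_steps` table ([build_steps()]).
#' @param gamma_fit `issa_gamma` kernel parameters.
#' @param vm_fit `issa_vonmises` kernel parameters.
#' @param n_available alternatives per used step (default 9, giving strata
#'   of 10 rows).
#' @param seed integer seed; sampling order is animal-then-time so results
#'   are reproducible under subsetting.
#' @return a `issa_strata` data frame with columns `stratum_id`, `case`,
#'   `animal_id`, `t1`, `t2`, `x1`, `y1`, `x2`, `y2`, `sl`, `log_sl`, `ta`,
#'   `period`.
#' @export
build_strata <- function(steps, gamma_fit, vm_fit, n_available = 9, seed = 1L) {
  if (!is.numeric(n_available) || n_available < 1)
    stop_config("n_available must be >= 1")
  stopifnot(inherits(gamma_fit, "issa_gamma"), inherits(vm_fit, "issa_vonmises"))
  usable <- steps[!is.na(steps$ta), , drop = FALSE]
  usable <- usable[order(usable$animal_id, usable$t1), , drop = FALSE]
  n <- nrow(usable)
  if (n == 0) stop_data("no usable steps (none has a previous heading)")
  set.seed(as.integer(seed))
  k <- as.integer(n_available)
  sl_a <- matrix(stats::rgamma(n * k, shape = gamma_fit$shape, scale = gamma_fit$scale),
                 nrow = n, ncol = k, byrow = TRUE)
  ta_a <- matrix(rvonmises(n * k, mu = vm_fit$mu, kappa = vm_fit$kappa),
                 nrow = n, ncol = k, byrow = TRUE)
  sl_a <- pmax(sl_a, 1)   # same 1 m floor as observed steps

  rows_per <- k + 1L
  idx <- rep(seq_len(n), each = rows_per)
  case <- rep(c(1L, rep(0L, k)), times = n)
  sl <- numeric(n * rows_per); ta <- numeric(n * rows_per)
  sl[case == 1] <- usable$sl
  ta[case == 1] <- usable$ta
  sl[case == 0] <- as.vector(t(sl_a))
  ta[case == 0] <- as.vector(t(ta_a))
  heading <- wrap_angle(usable$prev_heading[idx] + ta)
  x2 <- usable$x1[idx] + sl * cos(heading)
  y2 <- usable$y1[idx] + sl * sin(heading)
  # keep the observed endpoint exactly as recorded
  x2[case == 1] <- usable$x2
  y2[case == 1] <- usable$y2

  out <- data.frame(stratum_id = idx,
                    case = case,
                    animal_id = usable$animal_id[idx],
                    t1 = usable$t1[idx], t2 = usable$t2[idx],
                    x1 = usable$x1[idx], y1 = usable$y1[idx],
                    x2 = x2, y2 = y2,
                    sl = sl, log_sl = log(sl), ta = ta,
                    period = usable$period[idx],
                    stringsAsFactors = FALSE)
  attr(out, "n_available") <- k
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("issa_strata", "data.frame")
  out
}

#' Write fitted kernel parameters to JSON
#'
#' @param gamma_fit,vm_fit fitted kernel pieces.
#' @param path output path.
#' @param period optional period label recorded in the file.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(gamma_fit, vm_fit, path, period = NA_character_) {
  doc <- list(shape = gamma_fit$shape, scale = gamma_fit$scale,
              mu = vm_fit$mu, kappa = vm_fit$kappa,
              n_lengths = gamma_fit$n, n_angles = vm_fit$n,
              period = period)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
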