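# Independent reference implementations used as oracles; written plainly
# (explicit loops) so they share no code path with the package.

# Brute-force union-find over all pairs: reference partition for the
# chain-rule grouping.
uf_partition <- function(xy, threshold) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
        if (d <= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Two partitions (membership vectors) describe the same grouping?
same_partition <- function(a, b) {
  canon <- function(m) {
    key <- vapply(seq_along(m), function(i) min(which(m == m[i])), integer(1))
    key
  }
  identical(canon(a), canon(b))
}

# Exhaustive grid search of the conditional logistic partial likelihood
# for a 2-covariate problem; coarse pass then a fine exhaustive pass at
# 1e-3 resolution around the coarse optimum.
grid_search_clogit <- function(X, case, stratum) {
  ll <- function(b) {
    eta <- X %*% b
    tot <- 0
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      tot <- tot + eta[idx][case[idx] == 1] - log(sum(exp(eta[idx])))
    }
    tot
  }
  best <- c(0, 0); bestll <- -Inf
  for (b1 in seq(-3, 3, by = 0.05)) {
    for (b2 in seq(-3, 3, by = 0.05)) {
      v <- ll(c(b1, b2))
      if (v > bestll) { bestll <- v; best <- c(b1, b2) }
    }
  }
  for (b1 in seq(best[1] - 0.06, best[1] + 0.06, by = 0.001)) {
    for (b2 in seq(best[2] - 0.06, best[2] + 0.06, by = 0.001)) {
      v <- ll(c(b1, b2))
      if (v > bestll) { bestll <- v; best <- c(b1, b2) }
    }
  }
  list(beta = best, loglik = bestll)
}

# Bisection on the Bessel ratio I1/I0 to invert the mean resultant length.
bisect_kappa <- function(rbar, lo = 1e-8, hi = 1e4, iters = 200) {
  f <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE) - rbar
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Reference greedy resampler (scalar loop version).
ref_resample_times <- function(tt, interval, tol) {
  keep <- 1L
  bursts <- list()
  cur <- c(1L)
  i <- 1L
  while (TRUE) {
    target <- tt[i] + interval
    cand <- integer(0)
    for (j in seq_along(tt)) {
      if (tt[j] > tt[i] && abs(tt[j] - target) <= tol) cand <- c(cand, j)
    }
    if (length(cand) > 0) {
      dbest <- Inf; jbest <- NA_integer_
      for (j in cand) {
        if (abs(tt[j] - target) < dbest) { dbest <- abs(tt[j] - target); jbest <- j }
      }
      cur <- c(cur, jbest); i <- jbest
    } else {
      nxt <- which(tt > tt[i])
      bursts[[length(bursts) + 1]] <- cur
      if (length(nxt) == 0) break
      i <- nxt[1]; cur <- c(i)
    }
  }
  bursts[lengths(bursts) >= 3]
}

# Small helper: fix table around a projected UTM-like origin.
make_fix_df <- function(animal, times, x, y, release = "2016-08-15") {
  data.frame(animal_id = animal,
             timestamp = as.POSIXct(times, tz = "UTC"),
             x = 400000 + x, y = 1500000 + y,
             release_date = as.POSIXct(release, tz = "UTC"),
             stringsAsFactors = FALSE)
}

# Deterministic 3-step burst -> usable steps for strata construction tests.
toy_steps <- function(n = 20, seed = 1) {
  set.seed(seed)
  t0 <- as.POSIXct("2020-02-01 00:00:00", tz = "UTC")
  xs <- 400000 + cumsum(stats::runif(n + 2, -400, 400))
  ys <- 1500000 + cumsum(stats::runif(n + 2, -400, 400))
  fx <- fixes(data.frame(animal_id = "a1", timestamp = t0 + (0:(n + 1)) * 14400,
                         x = xs, y = ys, release_date = as.POSIXct("2019-01-01", tz = "UTC")))
  bursts <- resample_to_interval(fx)
  build_steps(bursts)
}
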