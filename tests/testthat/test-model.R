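# Strata data frame with known covariates for design/fit tests.
synth_strata <- function(ns = 40, rows = 10, seed = 1, moderators = TRUE) {
  set.seed(seed)
  n <- ns * rows
  out <- data.frame(stratum_id = rep(seq_len(ns), each = rows),
                    case = rep(c(1, rep(0, rows - 1)), ns),
                    animal_id = rep(sprintf("a%d", rep(1:5, length.out = ns)), each = rows),
                    sl = rgamma(n, 2, scale = 300),
                    log_sl = NA_real_,
                    andvi = rnorm(n, 0, 0.05), dndvi = rnorm(n, 0, 0.03),
                    elev = rnorm(n, 300, 40), tri = rexp(n, 1 / 5),
                    temp = rnorm(n, 30, 4),
                    period = factor("dry", levels = c("dry", "wet")))
  out$log_sl <- log(out$sl)
  if (moderators) {
    out$experience <- rep(rnorm(ns, 200, 120)[seq_len(ns)], each = rows)
    out$group_size <- rep(sample(1:8, ns, TRUE), each = rows)
  }
  class(out) <- c("issa_strata", "data.frame")
  attr(out, "n_available") <- rows - 1
  out
}

test_that("standardization centers and scales with sample SD", {
  df <- data.frame(a = c(1, 2, 3))
  s <- standardize_covariates(df, "a")
  expect_equal(s$values$a, c(-1, 0, 1))       # sample SD convention
  expect_equal(unname(s$center["a"]), 2)
  expect_equal(unname(s$scale["a"]), 1)

  # idempotent on an already standardized column
  s2 <- standardize_covariates(s$values, "a")
  expect_equal(s2$values$a, s$values$a, tolerance = 1e-12)

  set.seed(2)
  df3 <- data.frame(z = rnorm(500, 7, 3))
  s3 <- standardize_covariates(df3, "z")
  expect_equal(mean(s3$values$z), 0, tolerance = 1e-12)
  expect_equal(sd(s3$values$z), 1, tolerance = 1e-12)

  expect_error(standardize_covariates(data.frame(k = rep(4, 10)), "k"),
               "zero-variance.*k")
})

test_that("model rosters nest as M1 in M2/M3 and M4 as their union", {
  m1 <- design_roster("dry", "M1")
  expect_equal(m1, c("sl", "log_sl", "andvi", "dndvi", "elev", "tri", "temp",
                     "andvi_sq", "dndvi_sq", "temp_sq"))
  # wet models carry no temperature quadratic or interactions by default
  expect_false("temp_sq" %in% design_roster("wet", "M1"))
  expect_false(any(grepl("^temp:", design_roster("wet", "M4"))))
  for (period in c("dry", "wet")) {
    m1 <- design_roster(period, "M1"); m2 <- design_roster(period, "M2")
    m3 <- design_roster(period, "M3"); m4 <- design_roster(period, "M4")
    expect_true(all(m1 %in% m2) && all(m1 %in% m3))
    expect_setequal(m4, union(m2, m3))
  }
})

test_that("design columns are standardized bases, their squares and products", {
  st <- synth_strata(seed = 4)
  d <- suppressWarnings(build_design(st, "dry", "M4"))
  expect_equal(unname(colMeans(d$X[, c("sl", "andvi", "temp")])), rep(0, 3),
               tolerance = 1e-10)
  expect_equal(unname(apply(d$X[, c("sl", "andvi", "temp")], 2, sd)), rep(1, 3),
               tolerance = 1e-10)
  expect_equal(d$X[, "andvi_sq"], d$X[, "andvi"]^2)
  zexp <- (st$experience - d$center["experience"]) / d$scale["experience"]
  expect_equal(d$X[, "tri:experience"], d$X[, "tri"] * zexp, ignore_attr = TRUE)
})

test_that("stratum-constant moderator mains are excluded with a warning", {
  st <- synth_strata(seed = 5)
  expect_warning(d <- build_design(st, "dry", "M4"), "constant within strata")
  expect_false(any(c("experience", "group_size") %in% d$columns))
  dk <- build_design(st, "dry", "M4", keep_inestimable = TRUE)
  expect_true(all(c("experience", "group_size") %in% dk$columns))
  # and the fitter refuses stratum-constant columns outright
  expect_error(fit_issf(dk), "stratum-constant")
})

test_that("VIF matches leave-one-out regressions and flags collinearity", {
  x1 <- c(rep(1, 10), rep(-1, 10))
  x2 <- rep(c(1, -1), 10)          # orthogonal to x1
  expect_equal(unname(vif(cbind(x1, x2))), c(1, 1))
  expect_warning(v <- vif(cbind(x1, x1, x2)), "collinear")
  expect_true(any(!is.finite(v)))

  set.seed(6)
  z <- matrix(rnorm(300), 100, 3)
  z[, 3] <- 0.8 * z[, 1] + 0.3 * z[, 2] + 0.4 * rnorm(100)
  got <- suppressWarnings(vif(z))
  for (j in 1:3) {
    r2 <- summary(lm(z[, j] ~ z[, -j]))$r.squared
    expect_equal(unname(got[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("perfectly balanced strata give a zero coefficient", {
  # x_case - x_control sums to zero and score at 0 vanishes symmetrically
  df <- data.frame(stratum_id = rep(1:4, each = 2),
                   case = rep(c(1, 0), 4),
                   x = c(1, -1, -1, 1, 2, -2, -2, 2),
                   animal_id = "a")
  f <- fit_issf(case ~ x, data = df)
  expect_equal(unname(coef(f)), 0, tolerance = 1e-9)
})

test_that("Newton estimates agree with exhaustive grid search of the likelihood", {
  set.seed(91)
  ns <- 5; rows <- 10
  X <- cbind(x1 = rnorm(ns * rows), x2 = rnorm(ns * rows))
  stratum <- rep(seq_len(ns), each = rows)
  case <- rep(c(1, rep(0, rows - 1)), ns)
  X[case == 1, 1] <- X[case == 1, 1] + 0.8   # plant a signal
  df <- data.frame(stratum_id = stratum, case = case, X, animal_id = "a")
  fit <- fit_issf(case ~ x1 + x2, data = df)
  ref <- grid_search_clogit(X, case, stratum)
  expect_lt(max(abs(coef(fit) - ref$beta)), 1e-3)
  expect_gte(fit$loglik, ref$loglik - 1e-6)
  # null likelihood identity: l(0) = -N log(10)
  expect_identical(fit$loglik_null, -ns * log(10))
})

test_that("fit matches survival::clogit in coefficients and both covariances", {
  set.seed(42)
  ns <- 200; rows <- 10
  df <- data.frame(stratum_id = rep(seq_len(ns), each = rows),
                   case = rep(c(1, rep(0, rows - 1)), ns),
                   x1 = rnorm(ns * rows), x2 = rnorm(ns * rows),
                   animal_id = rep(sample(letters[1:8], ns, TRUE), each = rows))
  df$x1[df$case == 1] <- df$x1[df$case == 1] + 0.4
  library(survival)
  f <- fit_issf(case ~ x1 + x2, data = df)
  cf <- survival::clogit(case ~ x1 + x2 + strata(stratum_id) + cluster(animal_id),
                         data = df, method = "breslow")
  expect_equal(unname(coef(f)), unname(coef(cf)), tolerance = 1e-7)
  expect_equal(unname(vcov(f, "naive")), unname(cf$naive.var), tolerance = 1e-7)
  # survival reports the uncorrected sandwich; ours carries the CR1
  # small-sample multiplier G/(G-1) for the 8 animal clusters
  expect_equal(unname(vcov(f, "robust")), unname(vcov(cf)) * 8 / 7, tolerance = 1e-7)
  expect_equal(f$loglik, unname(cf$loglik[2]), tolerance = 1e-8)
})

test_that("the likelihood is invariant to within-stratum recentring", {
  set.seed(14)
  ns <- 50; rows <- 10
  X <- cbind(a = rnorm(ns * rows), b = rnorm(ns * rows))
  stratum <- rep(seq_len(ns), each = rows)
  case <- rep(c(1, rep(0, rows - 1)), ns)
  X[case == 1, "a"] <- X[case == 1, "a"] + 0.5
  df <- data.frame(stratum_id = stratum, case = case, X, animal_id = "a")
  f1 <- fit_issf(case ~ a + b, data = df)
  shift <- ave(rnorm(ns)[stratum], stratum)   # a stratum-level constant
  df2 <- df; df2$a <- df2$a + shift
  f2 <- fit_issf(case ~ a + b, data = df2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
})

test_that("separation is detected rather than silently diverging", {
  ns <- 20; rows <- 5
  x <- rep(0, ns * rows)
  case <- rep(c(1, rep(0, rows - 1)), ns)
  x[case == 1] <- 1    # perfectly predicts the used row
  df <- data.frame(stratum_id = rep(seq_len(ns), each = rows), case = case,
                   x = x + rnorm(ns * rows, 0, 1e-6), animal_id = "a")
  expect_error(fit_issf(case ~ x, data = df), "separat|converge")
})

test_that("robust and naive covariances agree when clusters are independent strata", {
  set.seed(8)
  ns <- 3000; rows <- 6
  X <- cbind(a = rnorm(ns * rows))
  stratum <- rep(seq_len(ns), each = rows)
  eta <- 0.5 * X[, "a"]
  case <- integer(ns * rows)
  for (s in seq_len(ns)) {
    idx <- which(stratum == s)
    p <- exp(eta[idx]); p <- p / sum(p)
    case[idx[sample.int(rows, 1, prob = p)]] <- 1
  }
  df <- data.frame(stratum_id = stratum, case = case, a = X[, "a"],
                   animal_id = as.character(stratum))  # one cluster per stratum
  f <- fit_issf(case ~ a, data = df)
  ratio <- vcov(f, "robust")[1, 1] / vcov(f, "naive")[1, 1]
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("AICc follows the closed form and its large-n limit", {
  expect_equal(AICc(loglik = -100, k = 2, n = 50), 204 + 12 / 47)
  expect_equal(AICc(loglik = -100, k = 2, n = 1e9), 204, tolerance = 1e-6)
  expect_error(AICc(loglik = -10, k = 5, n = 6), "undefined")
})

test_that("a pure-noise column moves AICc by the parameter penalty minus its gain", {
  set.seed(10)
  ns <- 300; rows <- 10
  df <- data.frame(stratum_id = rep(seq_len(ns), each = rows),
                   case = rep(c(1, rep(0, rows - 1)), ns),
                   x = rnorm(ns * rows), noise = rnorm(ns * rows),
                   animal_id = "a")
  df$x[df$case == 1] <- df$x[df$case == 1] + 0.3
  f1 <- fit_issf(case ~ x, data = df)
  f2 <- fit_issf(case ~ x + noise, data = df)
  dl <- f2$loglik - f1$loglik
  d_aicc <- AICc(f2) - AICc(f1)
  correction <- (2 * 2 * 3 / (ns - 3)) - (2 * 1 * 2 / (ns - 2))
  expect_equal(d_aicc, 2 - 2 * dl + correction, tolerance = 1e-10)
  expect_lt(dl, 3)   # a noise column buys almost nothing
})

test_that("model comparison ranks by AICc and requires identical strata", {
  set.seed(3)
  st <- synth_strata(ns = 60, seed = 3)
  # plant signal on andvi so tiers differ
  st$andvi[st$case == 1] <- st$andvi[st$case == 1] + 0.03
  fits <- lapply(c(M1 = "M1", M2 = "M2", M3 = "M3", M4 = "M4"), function(t)
    fit_issf(build_design(st, "dry", t, warn_inestimable = FALSE)))
  cmp <- select_model(fits)
  expect_s3_class(cmp, "issa_model_comparison")
  expect_equal(cmp$deltaAICc[1], 0)
  expect_equal(sort(cmp$rank), 1:4)
  expect_true(!is.unsorted(cmp$AICc))

  other <- synth_strata(ns = 50, seed = 9)
  f_other <- fit_issf(build_design(other, "dry", "M1"))
  expect_error(select_model(list(A = fits$M1, B = f_other)), "different strata")
})
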