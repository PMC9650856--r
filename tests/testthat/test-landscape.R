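rand_grid <- function(nr = 8, nc = 8, seed = 1, cellsize = 500) {
  set.seed(seed)
  grid_create(matrix(runif(nr * nc), nr, nc), 0, 0, cellsize)
}

rand_series <- function(dates, nr = 6, nc = 6, seed = 1) {
  set.seed(seed)
  grid_series(dates, lapply(seq_along(dates), function(i)
    grid_create(matrix(runif(nr * nc, 0, 0.6), nr, nc), 0, 0, 500)))
}

test_that("dNDVI is the cellwise 16-day difference", {
  d <- as.Date("2020-01-01") + c(0, 16)
  a <- grid_create(matrix(0.20, 3, 3), 0, 0, 500)
  b <- grid_create(matrix(0.30, 3, 3), 0, 0, 500)
  dn <- compute_dndvi(grid_series(d, list(a, b)))
  expect_equal(length(dn$dates), 1)
  expect_equal(dn$dates, d[2])
  expect_equal(unique(as.vector(dn$grids[[1]]$values)), 0.10)

  # identical consecutive composites -> all-zero grid
  dn0 <- compute_dndvi(grid_series(d, list(a, a)))
  expect_true(all(dn0$grids[[1]]$values == 0))

  # random composites match an explicit elementwise loop
  s <- rand_series(as.Date("2020-01-01") + c(0, 16, 32), seed = 42)
  dn2 <- compute_dndvi(s)
  for (k in 1:2) {
    ref <- matrix(NA_real_, 6, 6)
    for (r in 1:6) for (c in 1:6)
      ref[r, c] <- s$grids[[k + 1]]$values[r, c] - s$grids[[k]]$values[r, c]
    expect_equal(dn2$grids[[k]]$values, ref)
  }
  expect_error(compute_dndvi(grid_series(d[1], list(a))), "at least 2")
})

test_that("aNDVI is the anomaly against the seasonal-slot baseline", {
  # 3 years x 2 composites per year; constant series -> zero anomaly
  d <- as.Date(c("2016-01-01", "2016-07-01", "2017-01-01", "2017-07-01",
                 "2018-01-01", "2018-07-01"))
  gs <- lapply(c(0.2, 0.5, 0.2, 0.5, 0.2, 0.5), function(v)
    grid_create(matrix(v, 4, 4), 0, 0, 500))
  an <- compute_andvi(grid_series(d, gs), "2016-01-01", "2017-12-31")
  expect_true(all(abs(unlist(lapply(an$grids, `[[`, "values"))) < 1e-12))

  # current 0.25 against a slot baseline of 0.20 -> 0.05
  gs2 <- gs
  gs2[[5]] <- grid_create(matrix(0.25, 4, 4), 0, 0, 500)
  an2 <- compute_andvi(grid_series(d, gs2), "2016-01-01", "2017-12-31")
  expect_equal(unique(as.vector(an2$grids[[5]]$values)), 0.05)

  # planted offset in a non-baseline year is recovered exactly
  set.seed(8)
  offset <- matrix(rnorm(16, 0, 0.05), 4, 4)
  gs3 <- gs
  gs3[[6]] <- grid_create(gs[[6]]$values + offset, 0, 0, 500)
  an3 <- compute_andvi(grid_series(d, gs3), "2016-01-01", "2017-12-31")
  expect_equal(an3$grids[[6]]$values, offset)

  # grand-mean mode subtracts one overall baseline mean
  ang <- compute_andvi(grid_series(d, gs), "2016-01-01", "2017-12-31", mode = "grand")
  expect_equal(unique(round(as.vector(ang$grids[[1]]$values), 10)), 0.2 - 0.35)
})

test_that("TRI follows Riley's 8-neighbor root-sum-of-squares", {
  flat <- grid_create(matrix(7, 5, 5), 0, 0, 500)
  expect_true(all(compute_tri(flat)$values == 0))

  g <- grid_create(matrix(c(11, 11, 11, 11, 10, 11, 11, 11, 11), 3, 3), 0, 0, 500)
  expect_equal(compute_tri(g)$values[2, 2], sqrt(8))

  # random grid vs an explicit neighborhood loop (interior and border)
  e <- rand_grid(6, 7, seed = 5)
  tri <- compute_tri(e)
  ref <- matrix(0, 6, 7)
  for (r in 1:6) for (c in 1:7) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= 6 && cc >= 1 && cc <= 7)
        acc <- acc + (e$values[rr, cc] - e$values[r, c])^2
    }
    ref[r, c] <- sqrt(acc)
  }
  expect_equal(tri$values, ref)
  expect_error(compute_tri(grid_create(matrix(1, 2, 2), 0, 0, 500)), "3 x 3")
})

test_that("TRI is shift-invariant and absolutely homogeneous in elevation", {
  e <- rand_grid(7, 7, seed = 9)
  t0 <- compute_tri(e)
  shifted <- grid_create(e$values + 123.4, 0, 0, 500)
  scaled <- grid_create(e$values * -2.5, 0, 0, 500)
  expect_equal(compute_tri(shifted)$values, t0$values)
  expect_equal(compute_tri(scaled)$values, 2.5 * t0$values)
})

test_that("derived NDVI layers are linear in the input series", {
  d <- as.Date(c("2016-03-01", "2017-03-01", "2018-03-01"))  # one slot per year
  s <- rand_series(d, seed = 3)
  s2 <- grid_series(d, lapply(s$grids, function(g)
    grid_create(3 * g$values, 0, 0, 500)))
  dn1 <- compute_dndvi(s); dn2 <- compute_dndvi(s2)
  expect_equal(dn2$grids[[1]]$values, 3 * dn1$grids[[1]]$values)
  an1 <- compute_andvi(s, d[1], d[2]); an2 <- compute_andvi(s2, d[1], d[2])
  expect_equal(an2$grids[[3]]$values, 3 * an1$grids[[3]]$values)
})

test_that("bilinear sampling interpolates cell centers exactly", {
  g <- grid_create(matrix(5, 4, 4), 0, 0, 500)
  expect_equal(grid_extract(g, 777, 1234, method = "bilinear"), 5)

  # midpoint of 4 cells valued 0,0,1,1 -> 0.5
  m <- grid_create(matrix(c(0, 0, 1, 1), 2, 2), 0, 0, 500)  # columns 1: 0,0; 2: 1,1
  expect_equal(grid_extract(m, 500, 500, method = "bilinear"), 0.5)

  # random points match the explicit 4-neighbor weighted average
  g2 <- rand_grid(6, 6, seed = 21)
  set.seed(22)
  px <- runif(10, 300, 2700); py <- runif(10, 300, 2700)
  got <- grid_extract(g2, px, py, method = "bilinear")
  for (i in 1:10) {
    fc <- px[i] / 500 - 0.5; fr <- (3000 - py[i]) / 500 - 0.5
    c0 <- floor(fc); r0 <- floor(fr); wc <- fc - c0; wr <- fr - r0
    ref <- (1 - wr) * (1 - wc) * g2$values[r0 + 1, c0 + 1] +
           (1 - wr) * wc * g2$values[r0 + 1, c0 + 2] +
           wr * (1 - wc) * g2$values[r0 + 2, c0 + 1] +
           wr * wc * g2$values[r0 + 2, c0 + 2]
    expect_equal(got[i], ref)
  }
})

test_that("bilinear resampling preserves constants and honors geometry", {
  g <- grid_create(matrix(2.5, 10, 10), 0, 0, 250)
  out <- resample_bilinear(g, 500)
  expect_equal(out$cellsize, 500)
  expect_equal(dim(out$values), c(5, 5))
  expect_true(all(out$values == 2.5))

  # downsampling a random grid equals pointwise bilinear at target centers
  g2 <- rand_grid(8, 8, seed = 2, cellsize = 250)
  out2 <- resample_bilinear(g2, 400)
  xs <- (seq_len(out2$ncol) - 0.5) * 400
  ys <- 8 * 250 - (seq_len(out2$nrow) - 0.5) * 400
  for (r in seq_len(out2$nrow))
    expect_equal(out2$values[r, ], grid_extract(g2, xs, rep(ys[r], length(xs)),
                                                method = "bilinear"))
  expect_error(resample_bilinear(g, -5), "target cell")
})

test_that("no-data cells are excluded with renormalized weights", {
  v <- matrix(1, 2, 2); v[1, 1] <- NA
  g <- grid_create(v, 0, 0, 500)
  expect_equal(grid_extract(g, 500, 500, method = "bilinear"), 1)
  all_na <- grid_create(matrix(NA_real_, 2, 2), 0, 0, 500)
  expect_true(is.na(grid_extract(all_na, 500, 500, method = "bilinear")))
})

test_that("ESRI ASCII round trip preserves values and georeferencing", {
  g <- rand_grid(5, 7, seed = 31)
  g$values[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  grid_write_ascii(g, path)
  h <- grid_read_ascii(path)
  expect_equal(h$values, g$values, tolerance = 1e-6)
  expect_equal(h$cellsize, g$cellsize)
  expect_equal(h$xmin, g$xmin)
  expect_equal(h$nrow, 5)
})

# A compact landscape stack over two composite dates for extraction tests.
toy_stack <- function(nr = 10, nc = 10, seed = 17) {
  set.seed(seed)
  d <- as.Date(c("2020-01-01", "2020-01-17", "2020-02-02"))
  mk <- function() grid_create(matrix(runif(nr * nc, 0, 0.6), nr, nc), 0, 0, 500)
  ndvi <- grid_series(d, list(mk(), mk(), mk()))
  elev <- grid_create(matrix(runif(nr * nc, 200, 400), nr, nc), 0, 0, 500)
  temp <- grid_series(d, list(mk(), mk(), mk()))
  landscape_stack(andvi = compute_andvi(ndvi, d[1], d[3]),
                  dndvi = compute_dndvi(ndvi),
                  elevation = elev, temperature = temp)
}

fake_strata <- function(x2, y2, t2, n_per = 2) {
  n <- length(x2)
  out <- data.frame(stratum_id = rep(seq_len(n / n_per), each = n_per),
                    case = rep(c(1, rep(0, n_per - 1)), n / n_per),
                    animal_id = "a1",
                    t1 = t2 - 14400, t2 = t2,
                    x1 = x2, y1 = y2, x2 = x2, y2 = y2,
                    sl = 100, log_sl = log(100), ta = 0,
                    period = factor("dry", levels = c("dry", "wet")))
  class(out) <- c("issa_strata", "data.frame")
  attr(out, "n_available") <- n_per - 1
  out
}

test_that("covariates are read at endpoints from the right composite", {
  stk <- toy_stack()
  t2 <- as.POSIXct("2020-01-20 12:00:00", tz = "UTC")  # after the 2nd composite
  # endpoint at the center of cell (row 3, col 4)
  x <- (4 - 0.5) * 500; y <- 10 * 500 - (3 - 0.5) * 500
  st <- fake_strata(rep(x, 2), rep(y, 2), rep(t2, 2))
  got <- extract_covariates(st, stk)
  expect_equal(got$elev, rep(stk$elevation$values[3, 4], 2))
  expect_equal(got$tri, rep(stk$tri$values[3, 4], 2))
  i <- findInterval(as.numeric(as.Date(t2)), as.numeric(stk$andvi$dates))
  expect_equal(got$andvi, rep(stk$andvi$grids[[i]]$values[3, 4], 2))
  j <- findInterval(as.numeric(as.Date(t2)), as.numeric(stk$dndvi$dates))
  expect_equal(got$dndvi, rep(stk$dndvi$grids[[j]]$values[3, 4], 2))

  # random endpoints equal independent per-point lookups
  set.seed(4)
  px <- runif(20, 100, 4900); py <- runif(20, 100, 4900)
  st2 <- fake_strata(px, py, rep(t2, 20))
  got2 <- extract_covariates(st2, stk)
  for (k in seq_len(nrow(got2))) {
    r <- floor((5000 - got2$y2[k]) / 500) + 1
    c <- floor(got2$x2[k] / 500) + 1
    expect_equal(got2$elev[k], stk$elevation$values[r, c])
  }
})

test_that("a stratum with any off-map row is dropped whole", {
  stk <- toy_stack()
  t2 <- as.POSIXct("2020-01-20", tz = "UTC")
  x <- c(1000, 1000, 1000, 99999)   # last row off the grid
  st <- fake_strata(x, rep(1000, 4), rep(t2, 4))
  expect_message(got <- extract_covariates(st, stk), "1 strata dropped")
  expect_equal(unique(got$stratum_id), 1)
  expect_equal(attr(got, "dropped_strata"), 1)
})

test_that("timestamps before the first composite raise a coverage error", {
  stk <- toy_stack()
  st <- fake_strata(rep(1000, 2), rep(1000, 2),
                    rep(as.POSIXct("2019-12-01", tz = "UTC"), 2))
  expect_error(extract_covariates(st, stk), "precede")
})
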