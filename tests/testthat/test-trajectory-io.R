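# Ingestion: CSV round trips, calibration, spline resampling, velocities.

test_that("a wide CSV reads back identically, including explicit gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,c1_x,c1_y,c2_x,c2_y",
               "0.0,10,20,30,40",
               "0.2,11,21,,41",
               "0.4,12,22,32,42"), path)
  raw <- read_session(path)
  expect_named(raw$series, c("c1", "c2"))
  expect_equal(raw$series$c1$x, c(10, 11, 12))
  expect_equal(raw$series$c2$y, c(40, 41, 42))
  # the empty x cell is an explicit gap, never a zero
  expect_true(is.na(raw$series$c2$x[2]))
  expect_equal(raw$sample_interval, 0.2)
})

test_that("write_session %>% read_session reproduces random sessions", {
  for (seed in 1:10) {
    raw <- random_raw_session(n_agents = 3, n_samples = 12, seed = seed,
                              gap_prob = if (seed %% 2) 0 else 0.05)
    path <- withr::local_tempfile(fileext = ".csv")
    write_session(raw, path)
    back <- read_session(path)
    for (id in names(raw$series)) {
      expect_equal(back$series[[id]]$x, raw$series[[id]]$x, tolerance = 1e-9)
      expect_equal(back$series[[id]]$y, raw$series[[id]]$y, tolerance = 1e-9)
    }
  }
})

test_that("non-monotone time is rejected with a row reference", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,c1_x,c1_y", "0.0,1,1", "0.4,2,2", "0.2,3,3"), path)
  expect_error(read_session(path), "non-monotone time at row 3")
})

test_that("projective fit recovers identity, translation and random maps", {
  sq <- rbind(c(0, 0), c(100, 0), c(100, 80), c(0, 80))
  ident <- fit_projective_transform(sq, sq)
  expect_equal(ident$matrix / ident$matrix[3, 3], diag(3), tolerance = 1e-9)

  shifted <- sweep(sq, 2, c(35, -12), "+")
  tr <- fit_projective_transform(sq, shifted)
  expect_equal(tr$matrix / tr$matrix[3, 3],
               matrix(c(1, 0, 35, 0, 1, -12, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-9)

  # synthesize-then-recover: map 4 points through a known homography, refit
  set.seed(7)
  for (rep in 1:20) {
    H <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
    H[3, 3] <- 1
    floor_pts <- apply_calibration(sq, H)
    fit <- fit_projective_transform(sq, floor_pts)
    expect_equal(fit$matrix / fit$matrix[3, 3], H / H[3, 3], tolerance = 1e-6)
    # round trip: forward then inverse returns the pixel points
    back <- apply_calibration(apply_calibration(sq, fit), fit, inverse = TRUE)
    expect_equal(back, sq, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("collinear calibration points are rejected", {
  bad <- rbind(c(0, 0), c(50, 0), c(100, 0), c(0, 80))
  good <- rbind(c(0, 0), c(100, 0), c(100, 80), c(0, 80))
  expect_error(fit_projective_transform(bad, good), "collinear")
})

test_that("spline resampling is exact on polynomial paths and at raw times", {
  t_raw <- seq(0, 2, by = 0.2)
  # straight line at constant speed stays a straight line, equally spaced
  lin <- structure(list(sample_interval = 0.2, series = list(
    c1 = data.frame(time = t_raw, x = 100 * t_raw, y = 50 * t_raw))),
    class = "raw_digitization")
  tr <- resample_spline(lin, 0.05)
  expect_equal(tr$pos[, 1, 1], 100 * tr$time, tolerance = 1e-9)
  expect_equal(diff(tr$pos[, 1, 1]), rep(5, n_frames(tr) - 1), tolerance = 1e-9)

  # a cubic spline reproduces a parabola exactly on the fine grid
  par <- structure(list(sample_interval = 0.2, series = list(
    c1 = data.frame(time = t_raw, x = 30 * t_raw^2 - 10 * t_raw + 3,
                    y = -12 * t_raw^2 + 4))), class = "raw_digitization")
  tr <- resample_spline(par, 0.05)
  expect_equal(tr$pos[, 1, 1], 30 * tr$time^2 - 10 * tr$time + 3,
               tolerance = 1e-8)
  expect_equal(tr$pos[, 1, 2], -12 * tr$time^2 + 4, tolerance = 1e-8)

  # interpolant passes through raw samples at the raw times
  raw <- random_raw_session(2, 11, seed = 3)
  tr <- resample_spline(raw, 0.05)
  at_raw <- tr$time %in% raw$series$c1$time
  expect_equal(tr$pos[at_raw, "c1", 1],
               raw$series$c1$x[raw$series$c1$time %in% tr$time],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("sinusoidal path error stays below the spline error bound", {
  h <- 0.2
  f <- function(t) 100 * sin(pi * t)
  t_raw <- seq(0, 4, by = h)
  raw <- structure(list(sample_interval = h, series = list(
    c1 = data.frame(time = t_raw, x = f(t_raw), y = 0))),
    class = "raw_digitization")
  tr <- resample_spline(raw, 0.05)
  # interpolation theory: |err| <= 5/384 h^4 max|f''''|; check away from ends
  bound <- 5 / 384 * h^4 * 100 * pi^4
  interior <- tr$time >= h & tr$time <= max(t_raw) - h
  expect_lt(max(abs(tr$pos[interior, 1, 1] - f(tr$time[interior]))), bound)
})

test_that("sparse or gap-riddled individuals are excluded with a warning", {
  raw <- random_raw_session(2, 12, seed = 5)
  raw$series$c2$x[1:9] <- NA  # only 3 usable samples
  expect_warning(tr <- resample_spline(raw, 0.05), "fewer than 4")
  expect_equal(tr$ids, "c1")

  raw2 <- random_raw_session(2, 20, seed = 6)
  raw2$series$c2$x[1:4] <- NA  # 20% missing, above the 10% rule
  expect_warning(tr2 <- resample_spline(raw2, 0.05), "missing")
  expect_equal(tr2$ids, "c1")
})

test_that("velocities follow the declared backward-difference scheme", {
  T <- 41
  still <- traj_from_list(list(c1 = cbind(rep(100, T), rep(200, T))))
  expect_true(all(still$vel[-1, 1, ] == 0))
  expect_true(all(is.na(still$vel[1, 1, ])))

  uni <- traj_from_list(list(c1 = cbind(100 + 5 * (0:(T - 1)), rep(0, T))))
  expect_equal(unname(uni$vel[-1, 1, 1]), rep(100, T - 1))  # 5 cm / 0.05 s
  expect_equal(unname(uni$vel[-1, 1, 2]), rep(0, T - 1))

  # circular motion: discrete speed within 0.5 R w^2 dt of R w
  R <- 200; w <- 1.5; dt <- 0.05
  tt <- (0:100) * dt
  circ <- traj_from_list(list(c1 = cbind(R * cos(w * tt), R * sin(w * tt))),
                         dt = dt)
  speed <- sqrt(circ$vel[-1, 1, 1]^2 + circ$vel[-1, 1, 2]^2)
  expect_true(all(abs(speed - R * w) <= 0.5 * R * w^2 * dt))
})

test_that("time reversal negates the reversed velocity sequence", {
  tr <- random_walk_traj(2, 30, seed = 9)
  rev_tr <- traj_from_list(lapply(seq_along(tr$ids), function(k)
    tr$pos[rev(seq_len(n_frames(tr))), k, ]))
  T <- n_frames(tr)
  for (k in seq_along(tr$ids)) {
    expect_equal(rev_tr$vel[2:T, k, ], -tr$vel[T:2, k, ],
                 ignore_attr = TRUE)
  }
})
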