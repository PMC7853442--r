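# Movement indices against closed-form cases and brute-force double loops.

test_that("pairwise distance matches known geometry and the loop oracle", {
  T <- 5
  tr <- traj_from_list(list(c1 = cbind(rep(0, T), rep(0, T)),
                            c2 = cbind(rep(300, T), rep(400, T)),
                            c3 = cbind(rep(0, T), rep(0, T))))
  d <- pair_distance(tr)
  expect_equal(unname(d$values[, "c1", "c2"]), rep(500, T))  # 3-4-5
  expect_equal(unname(d$values[, "c1", "c3"]), rep(0, T))    # coincident
  expect_equal(d$values[, "c1", "c2"], d$values[, "c2", "c1"])
  expect_true(all(is.na(d$values[, "c1", "c1"])))

  rw <- random_walk_traj(5, 50, seed = 11)
  expect_equal(unname(pair_distance(rw)$values), oracle_distance(rw),
               tolerance = 1e-9)
})

test_that("heading angle hits the head-on / perpendicular / receding cases", {
  # one moving individual, three stationary partners placed around it
  T <- 3
  mover <- cbind(100 + 20 * (0:(T - 1)), rep(100, T))  # moving +x
  tr <- traj_from_list(list(
    m = mover,
    ahead = cbind(rep(900, T), rep(100, T)),
    side = cbind(100 + 20 * (0:(T - 1)), rep(400, T)),  # always straight above
    behind = cbind(rep(-500, T), rep(100, T))))
  a <- pair_angle(tr)
  expect_equal(unname(a$values[-1, "m", "ahead"]), rep(0, T - 1))
  expect_equal(unname(a$values[-1, "m", "side"]), rep(90, T - 1))
  expect_equal(unname(a$values[-1, "m", "behind"]), rep(180, T - 1))
  # stationary partners have no defined heading angle of their own
  expect_true(all(is.na(a$values[, "ahead", "m"])))
  # no velocity at the first frame
  expect_true(all(is.na(a$values[1, , ])))

  rw <- random_walk_traj(5, 50, seed = 12)
  expect_equal(unname(pair_angle(rw)$values), oracle_angle(rw),
               tolerance = 1e-9)
})

test_that("angle of i toward j plus angle under reversed velocity is 180", {
  rw <- random_walk_traj(4, 40, seed = 13)
  a <- pair_angle(rw)
  flipped <- rw
  flipped$vel <- -rw$vel
  b <- pair_angle(flipped)
  s <- a$values + b$values
  expect_equal(s[!is.na(s)], rep(180, sum(!is.na(s))), tolerance = 1e-9)
})

test_that("static group centre averages frames and individuals", {
  T <- 10
  tr <- traj_from_list(list(c1 = cbind(rep(0, T), rep(0, T)),
                            c2 = cbind(rep(100, T), rep(0, T))))
  expect_equal(static_group_center(tr), c(x = 50, y = 0))

  # a full circle's uniform samples average to its centre
  tt <- seq(0, 2 * pi, length.out = 201)[-201]
  circ <- traj_from_list(list(c1 = cbind(200 + 150 * cos(tt),
                                         300 + 150 * sin(tt))))
  expect_equal(static_group_center(circ), c(x = 200, y = 300),
               tolerance = 1e-9)

  rw <- random_walk_traj(3, 60, seed = 14)
  expect_equal(unname(static_group_center(rw)), unname(oracle_center(rw)),
               tolerance = 1e-9)
})

test_that("angular momentum is |sin| of the radial/velocity angle", {
  # straight movers arranged so that at frame 2 each sits exactly at
  # (600, 425): radial vector (100, 0) from the supplied centre (500, 425)
  T <- 4; dt <- 0.05
  mk <- function(vel) t(sapply(0:(T - 1), function(k)
    c(600, 425) + (k - 1) * dt * vel))
  tr <- traj_from_list(list(
    tangential = mk(c(0, 50)),    # velocity perpendicular to the radial
    radial = mk(c(70, 0)),        # velocity along the radial
    diagonal = mk(c(50, 50))),    # 45 degrees between them
    dt = dt)
  m <- angular_momentum(tr, center = c(500, 425))
  expect_equal(unname(m[2, "tangential"]), 1, tolerance = 1e-9)
  expect_equal(unname(m[2, "radial"]), 0, tolerance = 1e-9)
  expect_equal(unname(m[2, "diagonal"]), sqrt(2) / 2, tolerance = 1e-9)
  expect_true(all(is.na(m[1, ])))

  rw <- random_walk_traj(5, 50, seed = 15)
  ctr <- static_group_center(rw)
  expect_equal(unname(unclass(angular_momentum(rw))),
               oracle_momentum(rw, ctr), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("angular momentum is invariant to speed rescaling and rigid maps", {
  rw <- random_walk_traj(4, 40, seed = 16)
  m0 <- angular_momentum(rw)

  faster <- rw
  faster$vel <- rw$vel * 3.7
  expect_equal(unclass(angular_momentum(faster, attr(m0, "center"))),
               unclass(m0), ignore_attr = TRUE)

  # rotate + translate all positions; recompute centre and velocities
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- rw$pos
  for (k in seq_along(rw$ids)) {
    moved[, k, ] <- rw$pos[, k, ] %*% t(R)
    moved[, k, 1] <- moved[, k, 1] + 123
    moved[, k, 2] <- moved[, k, 2] - 77
  }
  tr2 <- compute_velocity(trajectory_set(moved, frame_interval = 0.05))
  expect_equal(unclass(angular_momentum(tr2)), unclass(m0),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("activity amount and group momentum reduce correctly", {
  T <- 41
  uni <- traj_from_list(list(c1 = cbind(5 * (0:(T - 1)), rep(0, T)),
                             c2 = cbind(rep(50, T), rep(60, T))))
  act <- activity_amount(uni)
  expect_equal(unname(act["c1"]), 100)
  expect_equal(unname(act["c2"]), 0)

  # piecewise speeds 50 then 150 over equal frame counts average to 100
  xs <- c(0, cumsum(c(rep(2.5, 20), rep(7.5, 20))))
  pw <- traj_from_list(list(c1 = cbind(xs, 0)))
  expect_equal(unname(activity_amount(pw)), 100)

  # group momentum: mean over valid individuals, masked when none valid
  m <- matrix(c(NA, 1, 1, NA, 0.5, 0, NA, NA, NA), nrow = 3, byrow = TRUE)
  colnames(m) <- c("a", "b", "c")
  gm <- group_angular_momentum(structure(m, class = c("momentum_series",
                                                      "matrix")))
  expect_equal(gm, c(1, 0.25, NA))

  rw <- random_walk_traj(4, 30, seed = 17)
  mm <- angular_momentum(rw)
  loop <- sapply(seq_len(nrow(mm)), function(t) {
    v <- mm[t, ][!is.na(mm[t, ])]
    if (length(v)) mean(v) else NA_real_
  })
  expect_equal(group_angular_momentum(mm), loop, tolerance = 1e-9)
})
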