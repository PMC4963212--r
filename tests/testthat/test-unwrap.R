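test_that("cylinders develop isometrically", {
  set.seed(5)
  n <- 800
  th <- runif(n, -3 * pi / 4, 3 * pi / 4)
  z <- runif(n, -2, 2)
  P <- cbind(cos(th), sin(th), z)
  ch <- unwrap(P, n_slices = 10)
  i <- sample.int(n, 300); j <- sample.int(n, 300)
  dtrue <- sqrt((z[i] - z[j])^2 + (th[i] - th[j])^2)
  dch <- sqrt(rowSums((ch$uv[i, ] - ch$uv[j, ])^2))
  keep <- dtrue > 1e-8
  expect_lt(max(abs(dch[keep] - dtrue[keep]) / dtrue[keep]), 1e-6)
  # pass 2 is the identity on the developable intermediate
  expect_lt(max(abs((ch$uv[, 1L] - mean(ch$uv[, 1L])) -
                      (z - mean(z)))), 1e-6)
})

test_that("flat data unwrap to a rigid motion of themselves", {
  set.seed(6)
  x <- runif(300, -2, 2); y <- runif(300, -2, 2)
  P <- cbind(x, y, 0.5 * y) # tilted plane
  ch <- unwrap(P, n_slices = 8)
  expect_lt(max(abs(dist(P) - dist(ch$uv))), 1e-9)
  expect_identical(ch$pass1$mode, "flat")
})

test_that("the arc coordinate is monotone around each slice", {
  set.seed(7)
  n <- 600
  th <- sort(runif(n, -2, 2))
  z <- runif(n, -1, 1)
  P <- cbind(cos(th), sin(th), z)
  ch <- unwrap(P, axis = "z", n_slices = 6)
  # within a thin band of the slicing coordinate, v must follow the
  # angular order
  band <- which(abs(z) < 0.05)
  expect_true(all(diff(ch$uv[band, 2L]) > -1e-9))
})

test_that("tracks never tear across the reference meridian", {
  sim <- simulate_preset("cylinder", "brownian", 20, 100, seed = 8)
  ch <- unwrap(sim$tracks, n_slices = 10)
  st <- steps(ch$tracks)
  perim <- 2 * pi # r = 1
  expect_lt(max(abs(st$dv)), perim / 2)
})

test_that("charts converge as the slab count grows", {
  sim <- simulate_preset("hemisphere", "brownian", 30, 120, seed = 9)
  ch16 <- unwrap(sim$tracks, n_slices = 16)
  ch24 <- unwrap(sim$tracks, n_slices = 24)
  # sup-norm difference small relative to the chart extent
  d <- max(abs(ch16$uv - ch24$uv))
  expect_lt(d, 0.02 * diff(range(ch16$uv[, 2L])))
})

test_that("new points map consistently through a fitted chart", {
  sim <- simulate_preset("hemisphere", "brownian", 20, 80, seed = 10)
  ch <- unwrap(sim$tracks, n_slices = 10)
  P <- as.matrix(as.data.frame(sim$tracks)[, c("x", "y", "z")])
  uv <- predict(ch, P[1:25, ])
  expect_equal(unname(uv), unname(ch$uv[1:25, ]), tolerance = 1e-10)
})

test_that("slice-coverage failures are reported, not silent", {
  set.seed(12)
  P3 <- cbind(circle_pts(40, r = 1) + rnorm(80, 0, 0.01),
              runif(40, 0, 1))
  expect_error(unwrap_pass(P3, axis = "z", n_slices = 10), "fewer slices")
})

test_that("hemisphere charts beat the xy projection on turning angles", {
  sim <- simulate_preset("hemisphere", "brownian", 30, 150, seed = 11)
  ch <- unwrap(sim$tracks, n_slices = 12)
  tru <- true_angle_distribution(walk_model(), "persistence")
  dev_u <- deviation_distance(persistence_angles(ch$tracks), tru)
  dev_xy <- deviation_distance(persistence_angles(project_xy(sim$tracks)),
                               tru)
  # the chart should track the truth at the sampling-noise level;
  # the xy projection carries the dome's rim compression on top
  expect_lt(dev_u, dev_xy + 0.01)
  turn <- sim$headings$turn_angle
  turn <- turn[!is.na(turn)]
  pa <- persistence_angles(ch$tracks)
  err <- min(sqrt(mean(wrap_angle(pa$angles - turn)^2)),
             sqrt(mean(wrap_angle(-pa$angles - turn)^2)))
  expect_lt(err, 0.3) # per-step fidelity (radians) at this density
})
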