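test_that("von Mises sampler matches its density", {
  for (k in c(0, 0.5, 2, 20)) {
    expect_equal(stats::integrate(dvonmises, -pi, pi, kappa = k)$value, 1,
                 tolerance = 1e-8)
  }
  set.seed(1)
  x <- rvonmises(2e5, mu = 0.5, kappa = 2)
  expect_equal(atan2(mean(sin(x)), mean(cos(x))), 0.5, tolerance = 0.01)
  expect_equal(sqrt(mean(cos(x))^2 + mean(sin(x))^2),
               besselI(2, 1) / besselI(2, 0), tolerance = 0.01)
  u <- rvonmises(5e4, 0, 0)
  expect_gt(suppressWarnings(
    stats::ks.test(u / (2 * pi) + 0.5, "punif"))$p.value, 0.01)
})

test_that("simulated walks stay on-surface with conserved step length", {
  s <- make_surface("sphere", r = 1)
  sim <- simulate_walk(s, walk_model(step_length = 0.02), 20, 100,
                       seed = 10)
  P <- as.matrix(as.data.frame(sim$tracks)[, c("x", "y", "z")])
  expect_lt(max(abs(surface_implicit(s, P))), 1e-8)
  st <- steps(sim$tracks)
  len <- sqrt(st$dx^2 + st$dy^2 + st$dz^2)
  # chord length within [0.99, 1] L for L well below the curvature radius
  expect_true(all(len <= 0.02 + 1e-12 & len >= 0.99 * 0.02))
  e <- make_surface("ellipsoid", a = 5, b = 1, c = 0.2, cap = pi / 3,
                    bounded = TRUE)
  sime <- simulate_walk(e, walk_model(step_length = 0.02), 10, 60,
                        seed = 11)
  Pe <- as.matrix(as.data.frame(sime$tracks)[, c("x", "y", "z")])
  expect_lt(max(abs(surface_implicit(e, Pe))), 1e-8)
})

test_that("identical seeds reproduce the simulation exactly", {
  s <- surface_preset("hemisphere")$surface
  m <- walk_model(bias = 1, persistence = 0.5, target = c(0, 0, 2),
                  step_length = 0.03)
  a <- simulate_walk(s, m, 5, 40, seed = 99)
  b <- simulate_walk(s, m, 5, 40, seed = 99)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$headings, b$headings)
})

test_that("Brownian headings are uniform on the full sphere", {
  s <- make_surface("sphere", r = 1)
  sim <- simulate_walk(s, walk_model(step_length = 0.02), 500, 200,
                       seed = 12)
  turn <- sim$headings$turn_angle
  turn <- turn[!is.na(turn)]
  expect_gte(length(turn), 9.9e4)
  expect_gt(suppressWarnings(
    stats::ks.test(turn / (2 * pi) + 0.5, "punif"))$p.value, 0.01)
})

test_that("Brownian plane walks give uniform bias and persistence", {
  pl <- make_surface("plane", wx = 2, wy = 2)
  sim <- simulate_walk(pl, walk_model(step_length = 0.03), 50, 200,
                       seed = 13)
  ts2 <- project_xy(sim$tracks)
  ba <- bias_angles(ts2, c(5, 3))
  pa <- persistence_angles(ts2)
  expect_gt(uniformity_test(ba)$p.value, 0.01)
  expect_gt(uniformity_test(pa)$p.value, 0.01)
})

test_that("strong persistence gives straight tracks", {
  pl <- make_surface("plane")
  sim <- simulate_walk(pl, walk_model(persistence = 5e4,
                                      step_length = 0.05), 3, 100,
                       seed = 14)
  D <- straightness_index(sim$tracks)
  expect_true(all(D > 0.999))
})

test_that("bias concentrates headings toward the target", {
  pl <- make_surface("plane", wx = 0.5, wy = 0.5)
  cv <- vapply(c(0.5, 1, 2, 4), function(k) {
    sim <- simulate_walk(pl, walk_model(bias = k, target = c(50, 0, 0),
                                        step_length = 0.02), 20, 150,
                         seed = 15)
    b <- sim$headings$bias_angle
    expect_equal(mean(b), 0, tolerance = 3 / sqrt(length(b)) /
                   sqrt(max(k, 1)) + 0.02)
    1 - sqrt(mean(cos(b))^2 + mean(sin(b))^2) # circular variance
  }, numeric(1))
  expect_true(all(diff(cv) < 0))
})

test_that("reflecting boundaries confine walks to the patch", {
  s <- make_surface("hemisphere_patch", r = 1, cap = pi / 3,
                    bounded = TRUE)
  sim <- simulate_walk(s, walk_model(step_length = 0.05), 20, 200,
                       seed = 16)
  P <- as.matrix(as.data.frame(sim$tracks)[, c("x", "y", "z")])
  expect_true(all(acos(pmin(1, P[, 3L])) <= pi / 3 + 1e-9))
})

test_that("true angle distributions integrate to one and match oracles", {
  bw <- diff(seq(-pi, pi, length.out = 37L))[1L]
  for (m in list(walk_model(), walk_model(bias = 1.5, target = c(9, 0, 0)),
                 walk_model(persistence = 2))) {
    for (w in c("bias", "persistence")) {
      td <- true_angle_distribution(m, w)
      expect_equal(sum(td$density) * bw, 1, tolerance = 1e-8)
    }
  }
  # Brownian: flat density 1 / (2 pi)
  td0 <- true_angle_distribution(walk_model(), "bias")
  expect_equal(td0$density, rep(1 / (2 * pi), 36L))
  # persistence-only model has a flat bias distribution by symmetry
  tdp <- true_angle_distribution(walk_model(persistence = 3), "bias")
  expect_equal(tdp$density, rep(1 / (2 * pi), 36L))
  # bias-only turning distribution: closed form against Monte Carlo
  mb <- walk_model(bias = 1.5, target = c(9, 0, 0))
  td <- true_angle_distribution(mb, "persistence")
  set.seed(17)
  d <- wrap_angle(rvonmises(1e6, 0, 1.5) - rvonmises(1e6, 0, 1.5))
  mc <- graphics::hist(d, breaks = td$breaks, plot = FALSE)$density
  expect_lt(sum(abs(mc - td$density)) * bw, 0.01)
  # bias-only model: bias distribution equals the sampling kernel
  tb <- true_angle_distribution(mb, "bias")
  expect_equal(tb$density_fun(0.4), dvonmises(0.4, 0, 1.5))
})

test_that("parameter errors are raised early", {
  expect_error(walk_model(bias = 1), "target")
  expect_error(simulate_walk(make_surface("plane"), walk_model(),
                             n_steps = 0), "n_steps")
  m <- walk_model(bias = 1, target = c(0, 0, 0))
  expect_error(simulate_walk(make_surface("plane"), m, 1, 5,
                             start = matrix(c(0, 0, 0), 1L)),
               "target coincides")
})
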