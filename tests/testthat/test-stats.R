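test_that("bias angles follow the counterclockwise sign convention", {
  ts <- tracks2d(c("a", "a", "a"), 0:2, c(0, 1, 1), c(0, 0, 1))
  # step (1,0) toward target (5,0): aligned, angle 0
  ba <- bias_angles(ts, c(5, 0))
  expect_equal(ba$angles[1L], 0)
  # step (0,1) with target east: +pi/2
  expect_equal(ba$angles[2L], pi / 2, tolerance = 1e-12)
  expect_error(bias_angles(ts, c(0, 0)), "target coincides")
})

test_that("persistence angles handle turns and degenerate steps", {
  straight <- tracks2d("a", 0:4, 0:4, rep(0, 5L))
  expect_equal(persistence_angles(straight)$angles, rep(0, 3L))
  # square spiral of right (clockwise) turns: every angle is -pi/2
  sq <- tracks2d("a", 0:4, c(0, 1, 1, 0, 0), c(0, 0, -1, -1, 0))
  expect_equal(persistence_angles(sq)$angles, rep(-pi / 2, 3L),
               tolerance = 1e-12)
  # stationary cell: the pair is excluded and counted
  stat <- tracks2d("a", 0:3, c(0, 1, 1, 2), c(0, 0, 0, 0))
  pa <- persistence_angles(stat)
  expect_equal(length(pa$angles), 0L)
  expect_equal(pa$n_excluded, 2L)
})

test_that("straightness index separates ballistic from diffusive", {
  straight <- tracks2d("a", 0:9, 0:9, rep(0, 10L))
  expect_equal(unname(straightness_index(straight)), 1)
  outback <- tracks2d("a", 0:2, c(0, 1, 0), c(0, 0, 0))
  expect_equal(unname(straightness_index(outback)), 0)
  expect_error(straightness_index(tracks2d("a", 0:1, c(0, 0), c(0, 0))),
               "zero path length")
  # Brownian E[D] decreases with track length ~ n^(-1/2)
  pl <- make_surface("plane", wx = 0.1, wy = 0.1)
  meanD <- vapply(c(25L, 100L, 400L), function(n) {
    sim <- simulate_walk(pl, walk_model(step_length = 0.05), 40, n,
                         seed = n)
    mean(straightness_index(sim$tracks))
  }, numeric(1))
  expect_true(all(diff(meanD) < 0))
  expect_equal(meanD[2L] / meanD[1L], 0.5, tolerance = 0.25)
})

test_that("persistent-walk concentration is recovered by the vM MLE", {
  pl <- make_surface("plane", wx = 0.5, wy = 0.5)
  sim <- simulate_walk(pl, walk_model(persistence = 2,
                                      step_length = 0.02), 50, 201,
                       seed = 20)
  pa <- persistence_angles(project_xy(sim$tracks))
  fit <- vm_kappa_mle(pa$angles)
  expect_equal(fit$kappa, 2, tolerance = 4 * fit$se / 2 + 0.02)
  expect_equal(mean(pa$angles), 0, tolerance = 0.05)
})

test_that("deviation distance behaves like a bounded metric", {
  set.seed(21)
  a <- angle_distribution(runif(500, -pi, pi))
  expect_equal(deviation_distance(a, a), 0)
  # two disjoint point masses have maximal total variation
  d1 <- angle_distribution(rep(0.01, 100L))
  d2 <- angle_distribution(rep(3, 100L))
  expect_equal(deviation_distance(d1, d2), 1)
  # symmetry and triangle inequality on random distributions
  b <- angle_distribution(rvonmises(500, 1, 2))
  c_ <- angle_distribution(rvonmises(500, -1, 0.5))
  expect_equal(deviation_distance(a, b), deviation_distance(b, a))
  expect_lte(deviation_distance(a, c_),
             deviation_distance(a, b) + deviation_distance(b, c_) + 1e-12)
  expect_error(deviation_distance(a, angle_distribution(a$angles,
                                                        n_bins = 18)),
               "binned differently")
})

test_that("uniform-vs-von-Mises deviation matches direct quadrature", {
  set.seed(22)
  # build the binned vM(kappa = 1) density by independent quadrature
  br <- seq(-pi, pi, length.out = 37L)
  q <- vapply(1:36, function(i)
    stats::integrate(function(x) dvonmises(x, 0, 1), br[i],
                     br[i + 1L])$value / diff(br)[1L], numeric(1))
  expected <- 0.5 * sum(abs(q - 1 / (2 * pi))) * diff(br)[1L]
  vm <- true_angle_distribution(walk_model(persistence = 1),
                                "persistence")
  unif <- true_angle_distribution(walk_model(), "persistence")
  expect_equal(deviation_distance(vm, unif), expected, tolerance = 1e-8)
})

test_that("angle distributions are normalized and rotation invariant", {
  sim <- simulate_preset("plane", "brownian", 10, 50, seed = 23)
  ts2 <- project_xy(sim$tracks)
  pa <- persistence_angles(ts2)
  bw <- diff(pa$breaks)[1L]
  expect_equal(sum(pa$density) * bw, 1, tolerance = 1e-12)
  # rigid rotation of the representation leaves all angles unchanged
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  Y <- cbind(ts2$u, ts2$v) %*% t(R)
  rot <- tracks2d(ts2$track_id, ts2$t, Y[, 1L], Y[, 2L])
  expect_equal(persistence_angles(rot)$angles, pa$angles,
               tolerance = 1e-10)
  tg <- c(2, 1)
  expect_equal(bias_angles(rot, drop(R %*% tg))$angles,
               bias_angles(ts2, tg)$angles, tolerance = 1e-10)
})

test_that("compare_methods ties all methods on flat data", {
  sim <- simulate_preset("plane", "brownian", 40, 120, seed = 24)
  cmp <- compare_methods(sim$tracks,
                         target3d = surface_preset("plane")$target,
                         truth = walk_model(),
                         methods = c("xy", "pca", "unwrap"))
  tab <- cmp$table
  for (w in c("bias", "persistence")) {
    devs <- tab$deviation[tab$which == w]
    expect_lt(max(devs) - min(devs), 1e-9) # identical charts up to rigid motion
    expect_equal(length(unique(tab$n_steps[tab$which == w])), 1L)
  }
})

test_that("track-level bootstrap CIs cover the point estimate", {
  sim <- simulate_preset("plane", "brownian", 25, 80, seed = 25)
  pa <- persistence_angles(project_xy(sim$tracks))
  tru <- true_angle_distribution(walk_model(), "persistence")
  ci <- deviation_ci(pa, tru, n_boot = 100, seed = 1)
  expect_lt(ci$lower, ci$upper)
  expect_gt(ci$lower, 0)
  expect_lt(abs(ci$estimate - median(ci$boot)), 0.05)
})
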