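test_that("surface constructors validate parameters", {
  expect_error(make_surface("sphere", r = -1), "positive")
  expect_error(make_surface("sphere", radius = 1), "unknown parameter")
  s <- make_surface("sphere", r = 2)
  expect_equal(surface_implicit(s, c(2, 0, 0)), 0)
  expect_equal(drop(surface_normal(s, c(0, 0, 2))), c(0, 0, 1))
})

test_that("a round ellipsoid is a sphere (operators agree pointwise)", {
  se <- make_surface("ellipsoid", a = 1, b = 1, c = 1)
  ss <- make_surface("sphere", r = 1)
  set.seed(3)
  P <- matrix(rnorm(60), ncol = 3L) * 1.4
  expect_equal(surface_implicit(se, P), surface_implicit(ss, P))
  expect_equal(project_to_surface(se, P), project_to_surface(ss, P),
               tolerance = 1e-9)
  expect_equal(surface_normal(se, project_to_surface(se, P)),
               surface_normal(ss, project_to_surface(ss, P)),
               tolerance = 1e-9)
})

test_that("ellipsoid projection finds the closest surface point", {
  s <- make_surface("ellipsoid", a = 5, b = 1, c = 0.2)
  set.seed(4)
  P <- cbind(runif(20, -6, 6), runif(20, -2, 2), runif(20, -1, 1))
  Q <- project_to_surface(s, P)
  expect_lt(max(abs(surface_implicit(s, Q))), 1e-10)
  # oracle: dense parameter search plus local refinement
  for (i in 1:5) {
    p <- P[i, ]
    f <- function(ang) {
      q <- c(5 * cos(ang[1L]) * cos(ang[2L]), cos(ang[1L]) * sin(ang[2L]),
             0.2 * sin(ang[1L]))
      sum((p - q)^2)
    }
    grid <- as.matrix(expand.grid(seq(-pi / 2, pi / 2, length.out = 60),
                                  seq(-pi, pi, length.out = 120)))
    best <- grid[which.min(apply(grid, 1L, f)), ]
    ref <- stats::optim(best, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-14))
    expect_equal(sum((p - Q[i, ])^2), ref$value, tolerance = 1e-5)
  }
})

test_that("tangent bases are orthonormal and right-handed", {
  for (s in list(make_surface("sphere"), make_surface("cylinder"),
                 make_surface("ellipsoid", a = 2, b = 1.2, c = 1))) {
    P <- project_to_surface(s, matrix(rnorm(30), ncol = 3L))
    B <- tangent_basis(s, P)
    expect_equal(rowSums(B$e1^2), rep(1, 10L))
    expect_equal(rowSums(B$e2^2), rep(1, 10L))
    expect_equal(rowSums(B$e1 * B$e2), rep(0, 10L), tolerance = 1e-12)
    expect_equal(rowSums(B$e1 * B$n), rep(0, 10L), tolerance = 1e-12)
    # e1 x e2 = n
    cr <- cbind(B$e1[, 2L] * B$e2[, 3L] - B$e1[, 3L] * B$e2[, 2L],
                B$e1[, 3L] * B$e2[, 1L] - B$e1[, 1L] * B$e2[, 3L],
                B$e1[, 1L] * B$e2[, 2L] - B$e1[, 2L] * B$e2[, 1L])
    expect_equal(cr, B$n, tolerance = 1e-12)
  }
})

test_that("tangent stepping is exact on flat directions", {
  pl <- make_surface("plane")
  p <- c(0.1, 0.2, 0)
  B <- tangent_basis(pl, p)
  q <- tangent_step(pl, p, heading = pi / 4, L = 0.5)
  expect_equal(q, p + 0.5 * (cos(pi / 4) * B$e1[1L, ] +
                               sin(pi / 4) * B$e2[1L, ]))
  expect_equal(sqrt(sum((q - p)^2)), 0.5)
  # cylinder, heading along the axis: stays on the same generator line
  cy <- make_surface("cylinder", r = 1, h = 4)
  p <- c(cos(0.3), sin(0.3), 0)
  B <- tangent_basis(cy, p)
  ax_heading <- atan2(B$e2[1L, 3L], B$e1[1L, 3L]) # direction of +z
  q <- tangent_step(cy, p, ax_heading, 0.7)
  expect_equal(q[1:2], p[1:2], tolerance = 1e-12)
  expect_equal(abs(q[3L] - p[3L]), 0.7, tolerance = 1e-12)
  expect_error(tangent_step(cy, c(2, 0, 0), 0, 0.1), "not on the surface")
})

test_that("small sphere steps track great circles", {
  s <- make_surface("sphere", r = 1)
  p <- c(1, 0, 0)
  B <- tangent_basis(s, p)
  L <- 0.01
  q <- tangent_step(s, p, 0, L)
  # closed-form great-circle step in the e1 direction
  ang <- L # arc angle for r = 1
  gc <- cos(ang) * p + sin(ang) * B$e1[1L, ]
  expect_lt(sqrt(sum((q - gc)^2)), 1e-5)
})

test_that("patch sampling stays on-surface and in-patch", {
  set.seed(9)
  s <- make_surface("hemisphere_patch", r = 1, cap = pi / 3)
  P <- sample_on_surface(s, 300)
  expect_lt(max(abs(surface_implicit(s, P))), 1e-12)
  expect_gte(min(P[, 3L]), cos(pi / 3) - 1e-12)
  e <- make_surface("ellipsoid", a = 2, b = 1, c = 0.5, cap = pi / 2)
  Pe <- sample_on_surface(e, 200)
  expect_lt(max(abs(surface_implicit(e, Pe))), 1e-12)
  expect_true(all(Pe[, 3L] > -1e-12))
})

test_that("closed-form geodesic distances match known cases", {
  s <- make_surface("sphere", r = 2)
  expect_equal(surface_distance(s, c(2, 0, 0), c(0, 2, 0)), 2 * pi / 2)
  cy <- make_surface("cylinder", r = 1, h = 4)
  d <- surface_distance(cy, c(1, 0, 0), c(cos(1), sin(1), 2))
  expect_equal(d, sqrt(1 + 4))
})
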