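test_that("neighbour graphs have symmetric monotone kernel weights", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  g <- build_graph(X, k = 2, bandwidth = 1)
  W <- as.matrix(g$W)
  expect_equal(W, t(W))
  expect_equal(range(W[upper.tri(W)]), rep(exp(-1), 2L))
  set.seed(1)
  Y <- flat_cloud(200)
  gy <- build_graph(Y, k = 10)
  i <- 17L
  nb <- which(as.matrix(gy$W)[i, ] > 0 & seq_len(200) != i)
  d <- sqrt(rowSums(sweep(Y[nb, ], 2L, Y[i, ])^2))
  w <- as.matrix(gy$W)[i, nb]
  expect_true(all(diff(w[order(d)]) <= 1e-12))
  # two far clusters cannot form one chart
  Z <- rbind(flat_cloud(50, seed = 2),
             sweep(flat_cloud(50, seed = 3), 2L, c(50, 0, 0), "+"))
  expect_error(build_graph(Z, k = 5), "disconnected.*50, 50")
})

test_that("the graph Laplacian annihilates constants and acts like the
           Laplace-Beltrami operator", {
  set.seed(2)
  X <- flat_cloud(3000)
  g <- build_graph(X, k = 100)
  L <- graph_laplacian(g)
  expect_lt(max(abs(L %*% rep(1, 3000))), 1e-10)
  Lf <- as.vector(L %*% X[, 1L]^2)
  interior <- X[, 1L] > 0.25 & X[, 1L] < 0.75 &
    X[, 2L] > 0.25 & X[, 2L] < 0.75
  # sign convention: L x^2 ~ -2 away from the boundary
  expect_equal(mean(Lf[interior]), -2, tolerance = 0.15)
})

test_that("Laplacian eigenfunction error on the circle shrinks with n", {
  # the kernel bandwidth must shrink more slowly than the sampling
  # spacing for pointwise consistency; the systematic error of the
  # estimator (median over points) then vanishes with n
  err <- vapply(c(200L, 800L, 3200L), function(n) {
    set.seed(n)
    th <- runif(n, 0, 2 * pi)
    X <- cbind(cos(th), sin(th), 0)
    eps <- 0.6 * n^(-1 / 5)
    k <- min(n - 1L, ceiling(n * 3 * eps / pi))
    g <- build_graph(X, k = k, bandwidth = eps)
    L <- graph_laplacian(g)
    f <- sin(th)
    keep <- abs(f) > 0.4
    # sin is an eigenfunction: -Lap sin = sin, our L estimates -Lap
    abs(median(as.vector(L %*% f)[keep] / f[keep]) - 1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3L], 0.05)
})

test_that("LLE embeds flat patches affinely and preserves
           neighbourhoods on developable ones", {
  set.seed(3)
  X <- flat_cloud(600, seed = 3)
  emb <- lle_embed(X, k = 10)
  fit <- stats::lm(emb$coords ~ X[, 1L] + X[, 2L])
  rel <- sum(stats::residuals(fit)^2) / sum(scale(emb$coords,
                                                  scale = FALSE)^2)
  expect_lt(rel, 0.01)
  # developable roll: neighbourhood preservation
  set.seed(4)
  t_ <- runif(700, 0, 3 * pi / 2)
  X2 <- cbind(cos(t_) * (1 + 0.3 * t_), sin(t_) * (1 + 0.3 * t_),
              runif(700, 0, 2))
  emb2 <- lle_embed(X2, k = 10, dim_check = FALSE)
  expect_gt(trustworthiness(X2, emb2$coords, k = 10), 0.95)
})

test_that("metric estimation undoes linear distortions of flat data", {
  set.seed(5)
  n <- 2000
  X <- flat_cloud(n, seed = 5)
  A <- matrix(c(1.4, 0.5, -0.3, 0.9), 2L)
  Y <- X[, 1:2] %*% t(A)
  gtrue <- solve(A %*% t(A))
  g <- build_graph(X, k = 30)
  L <- graph_laplacian(g)
  met <- estimate_metric(Y, L, calibrate = X)
  interior <- X[, 1L] > 0.15 & X[, 1L] < 0.85 &
    X[, 2L] > 0.15 & X[, 2L] < 0.85
  err <- vapply(which(interior), function(i) {
    G <- matrix(c(met$g[i, 1L], met$g[i, 2L], met$g[i, 2L],
                  met$g[i, 3L]), 2L)
    norm(G - gtrue, "F") / norm(gtrue, "F")
  }, numeric(1))
  expect_lt(median(err), 0.05)
  # pure scaling: g = s^-2 I
  met2 <- estimate_metric(3.5 * X[, 1:2], L, calibrate = X)
  expect_equal(median(met2$g[interior, 1L]) * 3.5^2, 1, tolerance = 0.05)
  expect_equal(median(met2$g[interior, 3L]) * 3.5^2, 1, tolerance = 0.05)
})

test_that("metric-corrected step lengths match the surface", {
  sim <- simulate_preset("hemisphere", "brownian", 30, 150, seed = 6)
  mm <- manifold_learn(sim$tracks)
  st <- steps(mm$tracks)
  gr <- curvetrack:::metric_rows(mm$metric, st$track_id, st$t_start)
  lens <- riemannian_norm(cbind(st$du, st$dv), gr)
  st3 <- steps(sim$tracks)
  l3 <- sqrt(st3$dx^2 + st3$dy^2 + st3$dz^2)
  expect_lt(median(abs(lens - l3) / l3), 0.1)
  # without the metric the embedding scale is arbitrary
  le <- sqrt(st$du^2 + st$dv^2)
  expect_gt(median(abs(le - l3) / l3), 0.25)
})

test_that("riemannian primitives reduce to Euclidean ones for g = I", {
  u <- c(1, 2); v <- c(-0.5, 1)
  gI <- diag(2)
  expect_equal(riemannian_inner(u, v, gI), sum(u * v))
  expect_equal(riemannian_angle(u, v, gI),
               atan2(u[1L] * v[2L] - u[2L] * v[1L], sum(u * v)))
  gD <- matrix(c(4, 0, 0, 1), 2L)
  expect_equal(riemannian_inner(c(1, 0), c(0, 1), gD), 0)
  expect_equal(riemannian_norm(c(1, 0), gD), 2)
  expect_equal(riemannian_norm(c(0, 1), gD), 1)
  expect_error(riemannian_angle(c(0, 0), v, gI), "zero-norm")
  # Cauchy-Schwarz under random PSD metrics
  set.seed(7)
  for (i in 1:25) {
    B <- matrix(rnorm(4), 2L); G <- crossprod(B) + 1e-6 * diag(2)
    a <- rnorm(2); b <- rnorm(2)
    expect_lte(abs(riemannian_inner(a, b, G)),
               riemannian_norm(a, G) * riemannian_norm(b, G) + 1e-12)
  }
})

test_that("angle statistics are invariant to affine reparameterization", {
  set.seed(8)
  n <- 1200
  X <- flat_cloud(n, seed = 8)
  ids <- rep(sprintf("t%02d", 1:24), each = 50L)
  tt <- rep(1:50, times = 24L)
  g <- build_graph(X, k = 30)
  L <- graph_laplacian(g)
  A <- matrix(c(0.8, 0.6, -0.4, 1.5), 2L)
  angles_under <- function(M) {
    Y <- X[, 1:2] %*% t(M)
    ts2 <- tracks2d(ids, tt, Y[, 1L], Y[, 2L])
    met <- estimate_metric(Y, L, track_id = ids, t = tt, calibrate = X)
    persistence_angles(ts2, metric = met)$angles
  }
  a1 <- angles_under(diag(2))
  a2 <- angles_under(A)
  flip <- if (det(A) < 0) -1 else 1
  expect_lt(median(abs(wrap_angle(a1 - flip * a2))), 0.03)
})

test_that("thin sparse clouds raise the dimensionality error", {
  sim <- simulate_preset("ellipsoid_thin", "brownian", 120, 6, seed = 1)
  expect_error(suppressWarnings(manifold_learn(sim$tracks)),
               "one-dimensional")
})
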