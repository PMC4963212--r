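# Shared fixtures, built in code.

# points on a circle / ellipse in a plane
circle_pts <- function(n, r = 1, cx = 0, cy = 0, from = 0, to = 2 * pi) {
  th <- seq(from, to, length.out = n + 1L)[seq_len(n)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipse_pts <- function(n, A, B, phi = 0, cx = 0, cy = 0,
                        from = 0, to = 2 * pi) {
  th <- seq(from, to, length.out = n + 1L)[seq_len(n)]
  x <- A * cos(th); y <- B * sin(th)
  cbind(cx + x * cos(phi) - y * sin(phi),
        cy + x * sin(phi) + y * cos(phi))
}

# a simple hand-written track set
toy_tracks <- function() {
  tracks3d(track_id = rep(c("a", "b"), c(3L, 4L)),
           t = c(0:2, 0:3),
           x = c(0, 1, 1, 0, 1, 2, 3),
           y = c(0, 0, 1, 0, 0, 0, 0),
           z = c(0, 0, 0, 1, 1, 1, 1))
}

# uniform random points on the unit square embedded in 3D
flat_cloud <- function(n, seed = 1) {
  set.seed(seed)
  cbind(runif(n), runif(n), 0)
}

# neighbourhood-preservation score (trustworthiness) of an embedding
trustworthiness <- function(X, Y, k = 10L) {
  n <- nrow(X)
  dx <- as.matrix(dist(X)); dy <- as.matrix(dist(Y))
  diag(dx) <- Inf; diag(dy) <- Inf
  acc <- 0
  for (i in seq_len(n)) {
    rx <- rank(dx[i, ])
    nn_y <- order(dy[i, ])[seq_len(k)]
    intruders <- nn_y[rx[nn_y] > k]
    acc <- acc + sum(rx[intruders] - k)
  }
  1 - 2 * acc / (n * k * (2 * n - 3 * k - 1))
}

# von Mises concentration MLE (solve A(kappa) = Rbar) and its rough SE
vm_kappa_mle <- function(a) {
  Rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  A <- function(k) besselI(k, 1, TRUE) / besselI(k, 0, TRUE)
  kap <- stats::uniroot(function(k) A(k) - Rbar, c(1e-6, 500))$root
  Ak <- A(kap)
  se <- 1 / sqrt(length(a) * (1 - Ak^2 - Ak / kap))
  list(kappa = kap, se = se)
}
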