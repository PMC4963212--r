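# Ellipse fitting and arc-length machinery used by the unwrapping method.

.curvetrack_env <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch, cached.
gauss_legendre <- function(n = 48L) {
  key <- paste0("gl", n)
  if (!is.null(.curvetrack_env[[key]])) return(.curvetrack_env[[key]])
  k <- seq_len(n - 1L)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- beta
  J[cbind(k + 1L, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  wts <- 2 * e$vectors[1L, ]^2
  ord <- order(nodes)
  out <- list(x = nodes[ord], w = wts[ord])
  .curvetrack_env[[key]] <- out
  out
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to planar points by the numerically stable
#' Halir–Flusser formulation of the direct (ellipse-specific) least-squares
#' conic fit: the quadratic constraint `4AC - B^2 = 1` guarantees an
#' ellipse rather than a general conic. Data are centered and scaled
#' internally for conditioning; the fit is deterministic.
#'
#' @param pts an n x 2 matrix of points, `n >= 5`, not all collinear.
#' @return An object of class `ellipse`: list with `center` (2-vector),
#'   `axes` (semi-axes, `A >= B > 0`), `phi` (orientation of the major
#'   axis, defined mod pi) and `residual` (RMS orthogonal distance of the
#'   points to the fitted ellipse).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' e <- fit_ellipse(cbind(1 + 2 * cos(th), 1 + 2 * sin(th)))
#' e$center; e$axes
#' @export
fit_ellipse <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2L)
  if (nrow(pts) < 5L) stop("need at least 5 points to fit an ellipse")
  ctr <- colMeans(pts)
  Z <- sweep(pts, 2L, ctr)
  sc <- sqrt(mean(Z^2))
  if (sc == 0) stop("degenerate configuration: all points coincide")
  sv <- svd(Z, nu = 0L)
  if (sv$d[2L] <= 1e-9 * sv$d[1L])
    stop("degenerate configuration: points are collinear")
  Z <- Z / sc
  x <- Z[, 1L]; y <- Z[, 2L]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1L, ] * evec[3L, ] - evec[2L, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("ellipse fit failed: no admissible conic (degenerate data)")
  a1 <- evec[, ok[1L]]
  coef <- c(a1, Tm %*% a1) # A B C D E F in scaled frame
  geo <- conic_to_ellipse(coef)
  if (is.null(geo)) stop("ellipse fit failed: conic is not a real ellipse")
  out <- structure(list(center = ctr + sc * geo$center,
                        axes = sc * geo$axes,
                        phi = geo$phi, residual = NA_real_),
                   class = "ellipse")
  ft <- ellipse_foot(out, pts)
  out$residual <- sqrt(mean(ft$dist^2))
  out
}

# conic (A,B,C,D,E,F) -> geometric parameters, or NULL if not an ellipse
conic_to_ellipse <- function(cf) {
  A <- cf[1L]; B <- cf[2L]; C <- cf[3L]; D <- cf[4L]; E <- cf[5L]; F <- cf[6L]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  if (Fc == 0) return(NULL)
  Q <- matrix(c(A, B / 2, B / 2, C), 2L) / (-Fc)
  e <- eigen(Q, symmetric = TRUE)
  if (any(e$values <= 0)) return(NULL)
  axes <- 1 / sqrt(e$values) # descending eigenvalues -> ascending axes
  v <- e$vectors[, which.min(e$values)] # major-axis direction
  list(center = c(cx, cy), axes = sort(axes, decreasing = TRUE),
       phi = atan2(v[2L], v[1L]) %% pi)
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf("<ellipse> center=(%.4g, %.4g) axes=(%.4g, %.4g) phi=%.4g rad\n",
              x$center[1L], x$center[2L], x$axes[1L], x$axes[2L], x$phi))
  invisible(x)
}

# Symmetric positive-definite shape matrix S with (p-c)' S (p-c) = 1.
ellipse_shape_matrix <- function(e) {
  R <- matrix(c(cos(e$phi), sin(e$phi), -sin(e$phi), cos(e$phi)), 2L)
  R %*% diag(1 / e$axes^2) %*% t(R)
}

# Inverse: (center, s11, s12, s22) rows -> (A, B, phi) rows, vectorized.
# A >= B; the returned frame (u1, u2) is right-handed (CCW parameter).
shape_to_axes <- function(s11, s12, s22) {
  tr <- s11 + s22
  dt <- s11 * s22 - s12^2
  disc <- sqrt(pmax(0, tr^2 - 4 * dt))
  l1 <- (tr + disc) / 2 # larger eigenvalue -> minor axis
  l2 <- (tr - disc) / 2
  # eigenvector for the smaller eigenvalue l2 (major axis direction)
  vx <- ifelse(abs(s12) > 1e-300, s12, l2 - s22)
  vy <- ifelse(abs(s12) > 1e-300, l2 - s11, s12)
  deg <- abs(vx) + abs(vy) < 1e-300 # circle: any direction
  vx[deg] <- 1; vy[deg] <- 0
  nrm <- sqrt(vx^2 + vy^2)
  list(A = 1 / sqrt(l2), B = 1 / sqrt(l1),
       ux = vx / nrm, uy = vy / nrm)
}

#' Nearest point on an ellipse
#'
#' Finds the foot point (orthogonal projection) of each query point on an
#' ellipse by safeguarded Newton iteration on the ellipse parameter,
#' tolerance 1e-10. Robust for points moderately off the ellipse, as
#' produced by tracking noise.
#'
#' @param e an [fit_ellipse()] object.
#' @param pts n x 2 matrix (or 2-vector) of query points.
#' @return list with `t` (foot parameter angles, CCW convention),
#'   `foot` (n x 2 foot points) and `dist` (unsigned distances).
#' @export
ellipse_foot <- function(e, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  n <- nrow(pts)
  r <- ellipse_foot_vec(pts[, 1L], pts[, 2L],
                        rep(e$center[1L], n), rep(e$center[2L], n),
                        rep(e$axes[1L], n), rep(e$axes[2L], n),
                        rep(cos(e$phi), n), rep(sin(e$phi), n))
  r
}

# Vectorized foot-point solver; one (point, ellipse) pair per row.
# (ux, uy) is the unit major-axis direction. Robust bracketed Newton on
# the standard one-parameter root problem (first-quadrant reduction), so
# it converges for arbitrarily placed query points.
ellipse_foot_vec <- function(px, py, cx, cy, A, B, ux, uy) {
  # coordinates in the ellipse frame (u1 major, u2 minor, right-handed)
  dx <- px - cx; dy <- py - cy
  X <- dx * ux + dy * uy
  Y <- -dx * uy + dy * ux
  if (any(X == 0 & Y == 0)) stop("point at ellipse center: foot undefined")
  u <- abs(X); v <- abs(Y)
  fx <- numeric(length(u)); fy <- numeric(length(u))
  # degenerate: on the major axis inside the evolute -> off-axis foot
  on_axis <- v == 0
  inside_ev <- on_axis & (u * A < A^2 - B^2)
  if (any(inside_ev)) {
    xx <- A[inside_ev]^2 * u[inside_ev] / (A[inside_ev]^2 - B[inside_ev]^2)
    fx[inside_ev] <- xx
    fy[inside_ev] <- B[inside_ev] *
      sqrt(pmax(0, 1 - (xx / A[inside_ev])^2))
  }
  vert <- on_axis & !inside_ev
  if (any(vert)) { fx[vert] <- A[vert]; fy[vert] <- 0 }
  g <- !on_axis
  if (any(g)) {
    Ag <- A[g]; Bg <- B[g]; ug <- u[g]; vg <- v[g]
    # solve (A u/(t+A^2))^2 + (B v/(t+B^2))^2 = 1, monotone decreasing in t
    lo <- -Bg^2 + Bg * vg
    hi <- -Bg^2 + sqrt((Ag * ug)^2 + (Bg * vg)^2)
    t <- (lo + hi) / 2
    for (it in 1:110) {
      ra <- Ag * ug / (t + Ag^2)
      rb <- Bg * vg / (t + Bg^2)
      Fv <- ra^2 + rb^2 - 1
      lo <- ifelse(Fv > 0, t, lo)
      hi <- ifelse(Fv > 0, hi, t)
      dF <- -2 * (ra^2 / (t + Ag^2) + rb^2 / (t + Bg^2))
      tn <- t - Fv / dF
      bad <- !is.finite(tn) | tn <= lo | tn >= hi
      tn[bad] <- (lo[bad] + hi[bad]) / 2
      if (max(abs(tn - t)) < 1e-15 * max(1, max(abs(t)))) { t <- tn; break }
      t <- tn
    }
    fx[g] <- Ag^2 * ug / (t + Ag^2)
    fy[g] <- Bg^2 * vg / (t + Bg^2)
  }
  fx <- fx * ifelse(X >= 0, 1, -1)
  fy <- fy * ifelse(Y >= 0, 1, -1)
  tpar <- atan2(fy / B, fx / A)
  foot_x <- cx + fx * ux - fy * uy
  foot_y <- cy + fx * uy + fy * ux
  list(t = tpar, foot = cbind(foot_x, foot_y),
       dist = sqrt((px - foot_x)^2 + (py - foot_y)^2))
}

# parameter angle at which the ray from the center in direction angle
# `ref_angle` (plane frame) crosses the ellipse
ellipse_ray_param <- function(ref_angle, A, B, ux, uy) {
  dx <- cos(ref_angle); dy <- sin(ref_angle)
  X <- dx * ux + dy * uy
  Y <- -dx * uy + dy * ux
  atan2(Y / B, X / A)
}

# arc length of q(t) between per-row parameter bounds, fixed-order
# Gauss-Legendre (exponentially convergent for this analytic integrand)
ellipse_arc_between <- function(t0, t1, A, B, n_nodes = 48L) {
  gl <- gauss_legendre(n_nodes)
  half <- (t1 - t0) / 2
  mid <- (t1 + t0) / 2
  acc <- 0
  for (j in seq_along(gl$x)) {
    tj <- mid + half * gl$x[j]
    acc <- acc + gl$w[j] * sqrt(A^2 * sin(tj)^2 + B^2 * cos(tj)^2)
  }
  acc * half
}

#' Signed arc coordinate on an ellipse
#'
#' Maps a point near an ellipse to its signed arc length along the ellipse,
#' measured from the reference meridian (the ray from the center at angle
#' `ref_angle`) to the point's foot, counterclockwise positive. The angular
#' difference is wrapped to `(-pi, pi]`, so data spanning less than the
#' full circumference unroll without tearing. Arc lengths are evaluated by
#' high-order Gauss–Legendre quadrature of the arc-length integrand.
#'
#' @param e an [fit_ellipse()] object.
#' @param pts n x 2 matrix (or 2-vector) of points.
#' @param ref_angle direction angle (radians, plane frame) of the
#'   reference meridian ray.
#' @return numeric vector of signed arc lengths.
#' @examples
#' e <- fit_ellipse(cbind(cos(1:8), sin(1:8)))
#' arc_coordinate(e, c(0, 1), ref_angle = 0) # quarter circle: pi/2
#' @export
arc_coordinate <- function(e, pts, ref_angle = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  ft <- ellipse_foot(e, pts)
  ux <- cos(e$phi); uy <- sin(e$phi)
  t0 <- ellipse_ray_param(ref_angle, e$axes[1L], e$axes[2L], ux, uy)
  dt <- wrap_pm_pi(ft$t - t0)
  ellipse_arc_between(rep(t0, nrow(pts)), t0 + dt,
                      rep(e$axes[1L], nrow(pts)), rep(e$axes[2L], nrow(pts)))
}

# wrap to (-pi, pi] (note: wrap_angle() uses [-pi, pi))
wrap_pm_pi <- function(a) {
  w <- wrap_angle(a)
  w[w == -pi] <- pi
  w
}

#' Full perimeter of an ellipse
#'
#' @param e an [fit_ellipse()] object.
#' @return the circumference, by quadrature.
#' @export
ellipse_perimeter <- function(e) {
  ellipse_arc_between(0, 2 * pi, e$axes[1L], e$axes[2L])
}

# Geometric (orthogonal-distance) ellipse refinement by damped
# Gauss-Newton over (cx, cy, A, B, phi), seeded by an algebraic fit.
# Direct conic fits are strongly biased on partial arcs (the typical slab
# of a convex surface); minimizing true point-to-ellipse distances removes
# that bias. Derivatives use the envelope theorem at the foot point.
fit_ellipse_geometric <- function(pts, init, max_iter = 60L) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  th0 <- c(init$center, init$axes, init$phi)
  if (th0[3L] == th0[4L]) th0[3L] <- th0[3L] * (1 + 1e-6)
  resid_jac <- function(th) {
    cx <- th[1L]; cy <- th[2L]; A <- th[3L]; B <- th[4L]; phi <- th[5L]
    ux <- cos(phi); uy <- sin(phi)
    ft <- ellipse_foot_vec(pts[, 1L], pts[, 2L], rep(cx, n), rep(cy, n),
                           rep(A, n), rep(B, n), rep(ux, n), rep(uy, n))
    dx <- pts[, 1L] - ft$foot[, 1L]; dy <- pts[, 2L] - ft$foot[, 2L]
    d <- sqrt(dx^2 + dy^2)
    # signed: positive outside
    X <- (pts[, 1L] - cx) * ux + (pts[, 2L] - cy) * uy
    Y <- -(pts[, 1L] - cx) * uy + (pts[, 2L] - cy) * ux
    sgn <- sign((X / A)^2 + (Y / B)^2 - 1)
    sgn[sgn == 0] <- 1
    nh <- cbind(dx, dy) / pmax(d, 1e-300) * sgn
    r <- d * sgn
    ct <- cos(ft$t); st <- sin(ft$t)
    qx <- ft$foot[, 1L] - cx; qy <- ft$foot[, 2L] - cy
    J <- cbind(-nh[, 1L], -nh[, 2L],
               -(nh[, 1L] * ux + nh[, 2L] * uy) * ct,
               -(-nh[, 1L] * uy + nh[, 2L] * ux) * st,
               -(nh[, 1L] * (-qy) + nh[, 2L] * qx))
    list(r = r, J = J)
  }
  th <- th0
  rj <- resid_jac(th)
  best <- sum(rj$r^2)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    H <- crossprod(rj$J)
    g <- crossprod(rj$J, rj$r)
    step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12)),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- th - as.vector(step %*% g)
    if (cand[3L] <= 0 || cand[4L] <= 0) { lambda <- lambda * 10; next }
    if (cand[3L] < cand[4L]) { # keep A >= B
      cand[3:4] <- cand[c(4L, 3L)]
      cand[5L] <- cand[5L] + pi / 2
    }
    rj2 <- resid_jac(cand)
    ss <- sum(rj2$r^2)
    if (is.finite(ss) && ss < best) {
      if (best - ss < 1e-14 * (best + 1e-300)) { th <- cand; best <- ss; break }
      th <- cand; best <- ss; rj <- rj2
      lambda <- max(lambda / 5, 1e-10)
    } else {
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
  }
  structure(list(center = th[1:2], axes = th[3:4], phi = th[5L] %% pi,
                 residual = sqrt(best / n)),
            class = "ellipse")
}

# Best available slab fit: direct conic and circle seeds, geometric
# refinement, lowest orthogonal-distance residual wins.
fit_slice <- function(pts, scale_hint = NULL) {
  cands <- list()
  e1 <- tryCatch(fit_ellipse(pts), error = function(e) NULL)
  c1 <- tryCatch(fit_circle(pts), error = function(e) NULL)
  seed <- NULL
  if (!is.null(c1)) { cands$circle <- c1; seed <- c1 }
  if (!is.null(e1)) {
    cands$conic <- e1
    if (is.null(seed) || e1$residual < seed$residual) seed <- e1
  }
  if (is.null(seed)) stop("slice fit failed: degenerate configuration")
  g <- tryCatch(fit_ellipse_geometric(pts, seed), error = function(e) NULL)
  if (!is.null(g)) cands$geometric <- g
  # reject implausible fits (huge or needle-like ellipses from short arcs)
  sc <- if (is.null(scale_hint)) sqrt(mean(scale(pts, scale = FALSE)^2))
        else scale_hint
  ok <- vapply(cands, function(e)
    is.finite(e$residual) && e$axes[1L] <= 50 * sc &&
      e$axes[1L] / e$axes[2L] <= 50, logical(1))
  cands <- cands[ok]
  if (!length(cands)) stop("slice fit failed: no plausible model")
  res <- vapply(cands, function(e) e$residual, numeric(1))
  out <- cands[[which.min(res)]]
  out$model <- names(cands)[which.min(res)]
  out
}

# Algebraic (Kasa) circle fit; linear least squares. Used as a robust
# fallback for slices whose angular coverage is too small for a stable
# ellipse fit.
fit_circle <- function(pts) {
  pts <- as.matrix(pts)
  A <- cbind(2 * pts[, 1L], 2 * pts[, 2L], 1)
  b <- pts[, 1L]^2 + pts[, 2L]^2
  sol <- qr.solve(A, b)
  r2 <- sol[3L] + sol[1L]^2 + sol[2L]^2
  if (!is.finite(r2) || r2 <= 0) stop("circle fit failed")
  structure(list(center = c(sol[1L], sol[2L]),
                 axes = c(sqrt(r2), sqrt(r2)), phi = 0,
                 residual = sqrt(mean((sqrt(rowSums(sweep(pts, 2L,
                   sol[1:2])^2)) - sqrt(r2))^2))),
            class = "ellipse")
}
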