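#' Parametric surfaces
#'
#' Constructs a parametric convex surface on which random walks can be
#' simulated. Every surface provides an implicit function `F(p)` vanishing
#' on the surface, an outward unit normal, an orthogonal projection of
#' near-surface points back onto the surface, and an orthonormal
#' tangent-plane basis at any on-surface point.
#'
#' Supported kinds and their parameters:
#' \describe{
#'   \item{`plane`}{the plane `z = 0`; `wx`, `wy` half-widths of the patch
#'     used by [sample_on_surface()] (default 1).}
#'   \item{`sphere`}{`r` radius (default 1); `cap` polar half-angle (radians,
#'     default `pi` = full sphere) bounding the sampling patch about `+z`.}
#'   \item{`hemisphere_patch`}{sphere of radius `r` restricted (for
#'     sampling) to the polar cap of half-angle `cap` (default `pi/2`).}
#'   \item{`ellipsoid`}{semi-axes `a`, `b`, `c` (x, y, z); `cap` polar
#'     half-angle of the sampling patch on the parameter sphere (default
#'     `pi`).}
#'   \item{`cylinder`}{circular cylinder about the z axis; `r` radius, `h`
#'     height, `theta_half` half-width (radians) of the angular sampling
#'     patch about azimuth 0 (default `pi` = full circumference).}
#' }
#'
#' @param kind one of `"plane"`, `"sphere"`, `"hemisphere_patch"`,
#'   `"ellipsoid"`, `"cylinder"`.
#' @param ... kind-specific parameters, see Details.
#' @param center 3-vector translation of the surface (default origin).
#' @param bounded if `TRUE`, the sampling patch is treated as a bounded
#'   domain with reflecting edges by [simulate_walk()] (default `TRUE` for
#'   `hemisphere_patch`, otherwise `FALSE`).
#' @return An object of class `surface`.
#' @examples
#' s <- make_surface("sphere", r = 2)
#' p <- project_to_surface(s, c(3, 0, 0.5))
#' abs(surface_implicit(s, p)) < 1e-12
#' @export
make_surface <- function(kind = c("plane", "sphere", "hemisphere_patch",
                                  "ellipsoid", "cylinder"),
                         ..., center = c(0, 0, 0),
                         bounded = identical(kind, "hemisphere_patch")) {
  kind <- match.arg(kind)
  p <- list(...)
  defaults <- switch(kind,
    plane = list(wx = 1, wy = 1),
    sphere = list(r = 1, cap = pi),
    hemisphere_patch = list(r = 1, cap = pi / 2),
    ellipsoid = list(a = 1, b = 1, c = 1, cap = pi),
    cylinder = list(r = 1, h = 2, theta_half = pi)
  )
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, p)
  for (nm in setdiff(names(p), c("cap", "theta_half")))
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("surface parameter '", nm, "' must be positive")
  stopifnot(length(center) == 3L, all(is.finite(center)))
  structure(list(kind = kind, params = p, center = as.numeric(center),
                 bounded = isTRUE(bounded)),
            class = "surface")
}

# fold a coordinate back into [lo, hi] (single reflection suffices for
# steps much shorter than the domain)
reflect1 <- function(x, lo, hi) {
  x <- ifelse(x > hi, 2 * hi - x, x)
  ifelse(x < lo, 2 * lo - x, x)
}

# Reflect points at the edges of the sampling patch (used by the walk
# simulator when the surface is bounded). Points inside are untouched.
reflect_into_patch <- function(s, p) {
  P <- sweep(as_point_matrix(p), 2L, s$center)
  pr <- s$params
  P <- switch(s$kind,
    plane = cbind(reflect1(P[, 1L], -pr$wx, pr$wx),
                  reflect1(P[, 2L], -pr$wy, pr$wy), P[, 3L]),
    cylinder = {
      z <- reflect1(P[, 3L], -pr$h / 2, pr$h / 2)
      th <- atan2(P[, 2L], P[, 1L])
      if (pr$theta_half < pi)
        th <- reflect1(th, -pr$theta_half, pr$theta_half)
      rr <- sqrt(P[, 1L]^2 + P[, 2L]^2)
      cbind(rr * cos(th), rr * sin(th), z)
    },
    sphere = , hemisphere_patch = {
      if (pr$cap >= pi) P else {
        rr <- sqrt(rowSums(P^2))
        pol <- acos(pmin(1, pmax(-1, P[, 3L] / rr)))
        newpol <- reflect1(pol, 0, pr$cap)
        az <- atan2(P[, 2L], P[, 1L])
        cbind(rr * sin(newpol) * cos(az), rr * sin(newpol) * sin(az),
              rr * cos(newpol))
      }
    },
    ellipsoid = {
      if (pr$cap >= pi) P else {
        ax <- surface_axes(s)
        U <- sweep(P, 2L, ax, "/")
        un <- sqrt(rowSums(U^2))
        U <- U / un
        pol <- acos(pmin(1, pmax(-1, U[, 3L])))
        newpol <- reflect1(pol, 0, pr$cap)
        az <- atan2(U[, 2L], U[, 1L])
        V <- cbind(sin(newpol) * cos(az), sin(newpol) * sin(az),
                   cos(newpol)) * un
        sweep(V, 2L, ax, "*")
      }
    })
  project_to_surface(s, sweep(P, 2L, s$center, "+"))
}

#' @export
print.surface <- function(x, ...) {
  cat("<surface:", x$kind, "> ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  stopifnot(ncol(p) == 3L)
  p
}

# semi-axes as a length-3 vector (spheres are round ellipsoids)
surface_axes <- function(s) {
  with(s$params, switch(s$kind,
    sphere = , hemisphere_patch = c(r, r, r),
    ellipsoid = c(a, b, c),
    NULL))
}

#' Implicit surface function
#'
#' Evaluates a smooth function that is zero exactly on the surface,
#' negative inside and positive outside (for the plane, it is the signed
#' height). Used to verify the on-surface invariant of simulated walks.
#'
#' @param s a [make_surface()] object.
#' @param p a 3-vector or an n x 3 matrix of points.
#' @return numeric vector of implicit-function values.
#' @export
surface_implicit <- function(s, p) {
  P <- sweep(as_point_matrix(p), 2L, s$center)
  ax <- surface_axes(s)
  switch(s$kind,
    plane = P[, 3L],
    cylinder = (P[, 1L]^2 + P[, 2L]^2) / s$params$r^2 - 1,
    # sphere/ellipsoid
    (P[, 1L] / ax[1L])^2 + (P[, 2L] / ax[2L])^2 + (P[, 3L] / ax[3L])^2 - 1
  )
}

#' Outward unit normal
#'
#' @inheritParams surface_implicit
#' @return an n x 3 matrix of unit normals.
#' @export
surface_normal <- function(s, p) {
  P <- sweep(as_point_matrix(p), 2L, s$center)
  n <- switch(s$kind,
    plane = cbind(0 * P[, 1L], 0, 1),
    cylinder = cbind(P[, 1L], P[, 2L], 0),
    sweep(P, 2L, surface_axes(s)^2, "/")
  )
  n / sqrt(rowSums(n^2))
}

#' Project points onto a surface
#'
#' Orthogonal (closest-point) projection. For planes, spheres and cylinders
#' the projection is closed form; for ellipsoids the closest point is found
#' by solving the standard one-parameter root problem
#' `sum(a_i^2 y_i^2 / (a_i^2 + t)^2) = 1` with vectorized Newton iteration
#' (fallback to bracketed root search), accurate to `|F| < 1e-12`.
#'
#' @inheritParams surface_implicit
#' @return an n x 3 matrix (or 3-vector, matching the input shape) of
#'   on-surface points.
#' @export
project_to_surface <- function(s, p) {
  vec_in <- is.null(dim(p))
  P <- sweep(as_point_matrix(p), 2L, s$center)
  Q <- switch(s$kind,
    plane = cbind(P[, 1:2, drop = FALSE], 0),
    cylinder = {
      rho <- sqrt(P[, 1L]^2 + P[, 2L]^2)
      if (any(rho == 0)) stop("cannot project a point on the cylinder axis")
      f <- s$params$r / rho
      cbind(P[, 1L] * f, P[, 2L] * f, P[, 3L])
    },
    sphere = , hemisphere_patch = {
      nr <- sqrt(rowSums(P^2))
      if (any(nr == 0)) stop("cannot project the sphere center")
      P * (s$params$r / nr)
    },
    ellipsoid = project_ellipsoid(P, surface_axes(s))
  )
  Q <- sweep(Q, 2L, s$center, "+")
  if (vec_in) drop(Q) else Q
}

# Closest point on an axis-aligned ellipsoid, centered coordinates.
project_ellipsoid <- function(Y, ax) {
  a2 <- ax^2
  f <- function(t) { # n-vector of sum a^2 y^2/(a^2+t)^2
    v <- 0
    for (j in 1:3) v <- v + a2[j] * Y[, j]^2 / (a2[j] + t)^2
    v
  }
  fp <- function(t) {
    v <- 0
    for (j in 1:3) v <- v - 2 * a2[j] * Y[, j]^2 / (a2[j] + t)^3
    v
  }
  t <- rep(0, nrow(Y))
  for (it in 1:60) {
    r <- f(t) - 1
    if (all(abs(r) < 1e-14)) break
    step <- r / fp(t)
    tn <- t - step
    # keep iterates above the pole at -min(a^2)
    tn <- pmax(tn, -min(a2) * 0.999999 + 1e-300)
    t <- tn
  }
  bad <- abs(f(t) - 1) > 1e-10
  if (any(bad)) { # rare: fall back to bracketed root per point
    for (i in which(bad)) {
      yi <- Y[i, , drop = FALSE]
      g <- function(tt) {
        sum(a2 * yi[1, ]^2 / (a2 + tt)^2) - 1
      }
      lo <- -min(a2[yi[1, ] != 0]) * (1 - 1e-9)
      t[i] <- stats::uniroot(g, lower = lo, upper = max(a2) * 10,
                             extendInt = "downX", tol = 1e-15)$root
    }
  }
  Q <- Y
  for (j in 1:3) Q[, j] <- a2[j] * Y[, j] / (a2[j] + t)
  Q
}

row_cross <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

#' Tangent-plane basis
#'
#' Deterministic orthonormal basis `(e1, e2)` of the tangent plane at each
#' on-surface point, right-handed with the outward normal
#' (`e1 x e2 = n`). The basis is built from a fixed auxiliary axis so that
#' it varies smoothly except near the poles of that axis.
#'
#' @inheritParams surface_implicit
#' @return list with n x 3 matrices `e1`, `e2`, `n`.
#' @export
tangent_basis <- function(s, p) {
  P <- as_point_matrix(p)
  n <- surface_normal(s, P)
  a <- matrix(rep(c(0, 0, 1), each = nrow(P)), ncol = 3L)
  flip <- abs(n[, 3L]) > 0.9
  a[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3L)
  e1 <- row_cross(a, n)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- row_cross(n, e1)
  list(e1 = e1, e2 = e2, n = n)
}

#' Take one tangent-plane step on a surface
#'
#' Projected-Euler stepping: move distance `L` from `p` along the
#' direction at angle `heading` in the local tangent basis, then project
#' orthogonally back onto the surface. Exact on planes and along
#' cylinder generators; `O(L^2 x curvature)` geodesic error elsewhere.
#'
#' @param s a [make_surface()] object.
#' @param p on-surface point (3-vector) or n x 3 matrix.
#' @param heading angle(s) in the tangent basis of [tangent_basis()].
#' @param L step length.
#' @param tol maximum allowed implicit-function value at `p`.
#' @return stepped on-surface point(s), same shape as `p`.
#' @export
tangent_step <- function(s, p, heading, L, tol = 1e-6) {
  vec_in <- is.null(dim(p))
  P <- as_point_matrix(p)
  if (any(abs(surface_implicit(s, P)) > tol))
    stop("point is not on the surface (|F| > tol)")
  B <- tangent_basis(s, P)
  Q <- project_to_surface(s, P + L * (B$e1 * cos(heading) +
                                        B$e2 * sin(heading)))
  if (vec_in) drop(Q) else Q
}

#' Uniform samples on a surface patch
#'
#' Draws points uniformly with respect to surface area from the sampling
#' patch encoded in the surface parameters (see [make_surface()]).
#' Ellipsoids use rejection sampling from the area measure through the
#' parameter-sphere map.
#'
#' @param s a [make_surface()] object.
#' @param n number of points.
#' @return an n x 3 matrix of on-surface points.
#' @export
sample_on_surface <- function(s, n) {
  pr <- s$params
  P <- switch(s$kind,
    plane = cbind(stats::runif(n, -pr$wx, pr$wx),
                  stats::runif(n, -pr$wy, pr$wy), 0),
    cylinder = {
      th <- stats::runif(n, -pr$theta_half, pr$theta_half)
      cbind(pr$r * cos(th), pr$r * sin(th),
            stats::runif(n, -pr$h / 2, pr$h / 2))
    },
    sphere = , hemisphere_patch = pr$r * sphere_cap_samples(n, pr$cap),
    ellipsoid = ellipsoid_samples(n, surface_axes(s), pr$cap)
  )
  sweep(P, 2L, s$center, "+")
}

# uniform on the unit-sphere cap of polar half-angle cap about +z
sphere_cap_samples <- function(n, cap) {
  z <- stats::runif(n, cos(cap), 1)
  th <- stats::runif(n, 0, 2 * pi)
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(th), rho * sin(th), z)
}

# area-weighted rejection through the parameter sphere
ellipsoid_samples <- function(n, ax, cap) {
  out <- matrix(NA_real_, 0L, 3L)
  # area scale factor dA_ell/dA_sph = abc * |(u1/a, u2/b, u3/c)|
  wmax <- prod(ax) / min(ax)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    U <- sphere_cap_samples(m, cap)
    w <- prod(ax) * sqrt((U[, 1L] / ax[1L])^2 + (U[, 2L] / ax[2L])^2 +
                           (U[, 3L] / ax[3L])^2)
    keep <- stats::runif(m) < w / wmax
    out <- rbind(out, sweep(U[keep, , drop = FALSE], 2L, ax, "*"))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Intrinsic surface distance
#'
#' Geodesic distance between on-surface points, available in closed form
#' for planes (Euclidean), spheres (great circle) and cylinders (developed
#' plane). Used as ground truth in validation; not defined for general
#' ellipsoids.
#'
#' @param s a [make_surface()] object of kind plane, sphere,
#'   hemisphere_patch or cylinder.
#' @param p,q 3-vectors or matching n x 3 matrices of on-surface points.
#' @return numeric vector of geodesic distances.
#' @export
surface_distance <- function(s, p, q) {
  P <- sweep(as_point_matrix(p), 2L, s$center)
  Q <- sweep(as_point_matrix(q), 2L, s$center)
  switch(s$kind,
    plane = sqrt(rowSums((P - Q)^2)),
    sphere = , hemisphere_patch = {
      r <- s$params$r
      cosg <- pmin(1, pmax(-1, rowSums(P * Q) / r^2))
      r * acos(cosg)
    },
    cylinder = {
      r <- s$params$r
      a1 <- atan2(P[, 2L], P[, 1L]); a2 <- atan2(Q[, 2L], Q[, 1L])
      da <- (a2 - a1 + pi) %% (2 * pi) - pi
      sqrt((r * da)^2 + (Q[, 3L] - P[, 3L])^2)
    },
    stop("no closed-form geodesic distance for kind ", s$kind)
  )
}
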