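# Two-pass surface unwrapping: slice-wise ellipse fitting + unrolling.

# right-handed frame (b1, b2, a) for a given slicing axis
axis_frame <- function(axis) {
  if (is.character(axis)) {
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                   stop("axis must be 'x', 'y', 'z' or a 3-vector"))
  }
  a <- axis / sqrt(sum(axis^2))
  h <- if (abs(a[3L]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  b1 <- c(h[2L] * a[3L] - h[3L] * a[2L],
          h[3L] * a[1L] - h[1L] * a[3L],
          h[1L] * a[2L] - h[2L] * a[1L])
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(a[2L] * b1[3L] - a[3L] * b1[2L],
          a[3L] * b1[1L] - a[1L] * b1[3L],
          a[1L] * b1[2L] - a[2L] * b1[1L])
  list(a = a, b1 = b1, b2 = b2)
}

# equal-count slab assignment along a coordinate
slab_assign <- function(s, n_slices) {
  if (n_slices < 3) stop("need at least 3 slices")
  br <- unique(stats::quantile(s, probs = seq(0, 1, length.out =
                                                n_slices + 1L)))
  idx <- findInterval(s, br, rightmost.closed = TRUE, all.inside = TRUE)
  list(idx = idx, n = length(br) - 1L)
}

#' First unwrapping pass: slice, fit ellipses, unroll
#'
#' Slices the point cloud into equal-count slabs along the slicing axis,
#' fits an ellipse to each slab's in-plane points (direct least squares,
#' with an algebraic circle fallback for slabs whose short angular
#' coverage makes the ellipse fit unstable), and replaces each point's
#' in-plane position by its signed arc length along the ellipse
#' interpolated at the point's axis coordinate. Ellipse centers and shape
#' matrices are interpolated linearly between slab midplanes so the map is
#' continuous along the axis; the reference meridian is the direction of
#' the first slab's data centroid, shared by all slabs, so adjacent slices
#' unroll without 2-pi offsets. Slabs in which the data are exactly
#' collinear (data on a plane parallel to the axis) switch the whole pass
#' to an exact line development.
#'
#' @param P n x 3 matrix of points.
#' @param axis `"x"`, `"y"`, `"z"` or a unit 3-vector.
#' @param n_slices number of slabs (>= 3); every slab must keep at least 5
#'   points.
#' @return An object of class `unwrap_pass`: per-point `s` (axis
#'   coordinate), `v` (arc coordinate), `rho` (distance from the slice
#'   center, the pass-2 profile height), `residual` (point-to-ellipse
#'   distance, a per-point quality metric), plus the fitted slab sequence
#'   (`report`) and everything needed to map new points.
#' @export
unwrap_pass <- function(P, axis = "z", n_slices = 12L) {
  P <- as_point_matrix(P)
  fr <- axis_frame(axis)
  s <- as.vector(P %*% fr$a)
  W <- cbind(P %*% fr$b1, P %*% fr$b2)
  sl <- slab_assign(s, n_slices)
  counts <- tabulate(sl$idx, sl$n)
  if (any(counts < 5L))
    stop("slab ", which.min(counts), " has ", min(counts),
         " points (< 5): use fewer slices")
  scale_w <- sqrt(mean(scale(W, scale = FALSE)^2))
  smid <- numeric(sl$n)
  cen <- matrix(NA_real_, sl$n, 2L)
  shp <- matrix(NA_real_, sl$n, 3L) # s11 s12 s22
  mode <- character(sl$n)
  resid <- numeric(sl$n)
  for (j in seq_len(sl$n)) {
    Wj <- W[sl$idx == j, , drop = FALSE]
    smid[j] <- mean(s[sl$idx == j])
    cj <- colMeans(Wj)
    sv <- svd(sweep(Wj, 2L, cj), nu = 0L)
    if (sv$d[2L] <= 1e-8 * max(sv$d[1L], 1e-300)) {
      mode[j] <- "line"
      next
    }
    e <- tryCatch(fit_slice(Wj, scale_hint = scale_w),
                  error = function(err) NULL)
    if (is.null(e))
      stop("slab ", j, ": slice fit degenerate; adjust n_slices or axis")
    mode[j] <- e$model
    cen[j, ] <- e$center
    S <- ellipse_shape_matrix(e)
    shp[j, ] <- c(S[1L, 1L], S[1L, 2L], S[2L, 2L])
    resid[j] <- e$residual
  }
  if (all(mode == "line")) {
    # flat (developable-in-plane) case: exact line development
    cen_line <- rowsum(W, sl$idx) / counts
    R <- W - cen_line[sl$idx, , drop = FALSE]
    dvec <- svd(R, nu = 0L)$v[, 1L]
    if (dvec[which.max(abs(dvec))] < 0) dvec <- -dvec
    v <- as.vector(W %*% dvec)
    rho <- as.vector(W %*% c(-dvec[2L], dvec[1L]))
    ps <- list(frame = fr, mode = "line", dvec = dvec,
               s = s, v = v, rho = rho, residual = rep(0, nrow(P)),
               report = data.frame(slab = seq_len(sl$n), s_mid = smid,
                                   n = counts, mode = mode,
                                   residual = 0))
    class(ps) <- "unwrap_pass"
    return(ps)
  }
  if (any(mode == "line"))
    stop("mixed degenerate and curved slabs; adjust n_slices or axis")
  fam <- fit_slice_family(s, W, smid, cen, shp, resid, counts)
  # reference meridian at the pooled data centroid's angular position
  # (centers the chart on the data, minimizing the worst-case shear)
  off <- cbind(W[, 1L] - (fam$c0[1L] + fam$c1[1L] * s),
               W[, 2L] - (fam$c0[2L] + fam$c1[2L] * s))
  d1 <- colMeans(off / pmax(sqrt(rowSums(off^2)), 1e-300))
  if (sqrt(sum(d1^2)) < 1e-6) d1 <- c(1, 0)
  ref_angle <- atan2(d1[2L], d1[1L])
  uv <- eval_pass1(fam, ref_angle, s, W)
  ps <- list(frame = fr, mode = "ellipse", family = fam,
             ref_angle = ref_angle,
             s = s, v = uv$v, rho = uv$rho, residual = uv$residual,
             report = data.frame(slab = seq_len(sl$n), s_mid = smid,
                                 n = counts, mode = mode,
                                 residual = resid))
  class(ps) <- "unwrap_pass"
  ps
}

# ---- smooth slice-ellipse family --------------------------------------
#
# Independent per-slab fits hug their own data but their parameters are
# noisy (the partial-arc fit is ill-conditioned), and parameter noise
# between adjacent slabs shears the chart. The slice sequence of any
# smooth convex surface is itself smooth, and for every quadric it has
# the exact form
#     (w - c(s))' M (w - c(s)) = k(s)
# with slice centers c(s) LINEAR in the axis coordinate, a CONSTANT
# normalized shape matrix M and a smooth positive size profile k(s)
# (quadratic for quadrics). We therefore refine the slab anchors into
# this family by minimizing the Sampson (gradient-weighted algebraic)
# distance over all points jointly, then re-estimate k(s) by a smoothing
# spline so that non-quadric convex profiles are followed as well.

fit_slice_family <- function(s, W, smid, cen, shp, resid, counts) {
  scale_w <- sqrt(mean(scale(W, scale = FALSE)^2))
  wj <- counts / (resid^2 + (0.01 * scale_w)^2)
  ok <- is.finite(wj) & wj > 0
  # per-slab normalized shapes and sizes: S = M / k, det(M) = 1
  detS <- shp[, 1L] * shp[, 3L] - shp[, 2L]^2
  kj <- 1 / sqrt(pmax(detS, 1e-300))
  Nj <- shp * kj # det-1 shape components per slab
  wn <- wj[ok] / sum(wj[ok])
  M0 <- colSums(Nj[ok, , drop = FALSE] * wn)
  dM0 <- M0[1L] * M0[3L] - M0[2L]^2
  M0 <- M0 / sqrt(max(dM0, 1e-300))
  # M = R(psi) diag(exp(gam), exp(-gam)) R(psi)' ; recover (gam, psi)
  ax0 <- shape_to_axes(M0[1L], M0[2L], M0[3L])
  gam0 <- -log(ax0$A) # A = exp(-gam) for the larger semi-axis of M^{-1}
  psi0 <- atan2(ax0$uy, ax0$ux)
  cfit <- lapply(1:2, function(j)
    stats::lm.wfit(cbind(1, smid[ok]), cen[ok, j], wj[ok])$coefficients)
  kfit <- stats::lm.wfit(cbind(1, smid[ok], smid[ok]^2), kj[ok],
                         wj[ok])$coefficients
  kfit[!is.finite(kfit)] <- 0
  theta <- c(cfit[[1L]], cfit[[2L]], gam0, psi0, kfit)
  # conservative second start: the best-fitting single slab, centered
  # constant along s (robust when the assembled start is contaminated by
  # a poor edge-slab fit)
  jb <- which.min(resid)
  axb <- shape_to_axes(Nj[jb, 1L], Nj[jb, 2L], Nj[jb, 3L])
  theta2 <- c(cen[jb, 1L], cen[jb, 2L], 0, 0, -log(axb$A),
              atan2(axb$uy, axb$ux), kfit)
  sampson <- function(th) {
    cx <- th[1L] + th[3L] * s; cy <- th[2L] + th[4L] * s
    eg <- exp(th[5L]); cp <- cos(th[6L]); sp <- sin(th[6L])
    m11 <- eg * cp^2 + sp^2 / eg
    m12 <- (eg - 1 / eg) * cp * sp
    m22 <- eg * sp^2 + cp^2 / eg
    k <- th[7L] + th[8L] * s + th[9L] * s^2
    if (any(k <= 0)) return(1e10 * (1 + sum(pmax(0, -k))))
    D1 <- W[, 1L] - cx; D2 <- W[, 2L] - cy
    Q <- m11 * D1^2 + 2 * m12 * D1 * D2 + m22 * D2^2
    gx <- 2 * (m11 * D1 + m12 * D2); gy <- 2 * (m12 * D1 + m22 * D2)
    sum(((Q - k) / sqrt(pmax(gx^2 + gy^2, 1e-300)))^2)
  }
  # anisotropy of M is box-bounded: unbounded eccentricity is a spurious
  # Sampson minimum (the ellipse degenerates into a line pair)
  span <- diff(range(s)); mid <- mean(range(s))
  lower <- c(rep(-Inf, 4L), -3.5, -Inf, rep(-Inf, 3L))
  upper <- c(rep(Inf, 4L), 3.5, Inf, rep(Inf, 3L))
  run_opt <- function(th0) tryCatch(
    stats::optim(th0, sampson, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 400, factr = 1e4)),
    error = function(e) list(par = th0, value = sampson(th0)))
  cands_th <- list(run_opt(theta), run_opt(theta2),
                   list(par = theta, value = sampson(theta)))
  vals <- vapply(cands_th, function(o)
    if (is.finite(o$value)) o$value else Inf, numeric(1))
  th <- cands_th[[which.min(vals)]]$par
  opt <- list(value = min(vals))
  eg <- exp(th[5L]); cp <- cos(th[6L]); sp <- sin(th[6L])
  M <- c(eg * cp^2 + sp^2 / eg, (eg - 1 / eg) * cp * sp,
         eg * sp^2 + cp^2 / eg)
  c0 <- th[1:2]; c1 <- th[3:4]
  # flexible size profile: smooth the per-point quadratic form values
  D1 <- W[, 1L] - (c0[1L] + c1[1L] * s)
  D2 <- W[, 2L] - (c0[2L] + c1[2L] * s)
  Qi <- M[1L] * D1^2 + 2 * M[2L] * D1 * D2 + M[3L] * D2^2
  ksp <- tryCatch(stats::smooth.spline(s, Qi), error = function(e) NULL)
  # extrapolation beyond the data's axis range is clamped to a fraction
  # of the smallest fitted slice size, so mapping an off-patch point
  # (e.g. an attractant beyond the rim) stays stable
  kobs <- if (!is.null(ksp)) stats::predict(ksp, range(s))$y else
    th[7L] + th[8L] * range(s) + th[9L] * range(s)^2
  kmin <- max(0.25 * min(kobs), 1e-6 * stats::median(Qi))
  kq <- th[7:9]
  list(c0 = c0, c1 = c1, M = M, ksp = ksp, kq = kq, kmin = kmin,
       sampson_rms = sqrt(opt$value / nrow(W)))
}

family_k <- function(fam, s) {
  k <- if (!is.null(fam$ksp)) stats::predict(fam$ksp, s)$y
       else fam$kq[1L] + fam$kq[2L] * s + fam$kq[3L] * s^2
  pmax(k, fam$kmin)
}

# ellipse of the family at axis coordinate(s) s
slice_family_at <- function(fam, s) {
  k <- family_k(fam, s)
  list(c = c(fam$c0[1L] + fam$c1[1L] * s, fam$c0[2L] + fam$c1[2L] * s),
       s11 = fam$M[1L] / k, s12 = fam$M[2L] / k, s22 = fam$M[3L] / k)
}

# per-point arc coordinate on the family ellipse at the point's s
eval_pass1 <- function(fam, ref_angle, s, W) {
  cx <- fam$c0[1L] + fam$c1[1L] * s
  cy <- fam$c0[2L] + fam$c1[2L] * s
  k <- family_k(fam, s)
  ax <- shape_to_axes(fam$M[1L] / k, fam$M[2L] / k, fam$M[3L] / k)
  ft <- ellipse_foot_vec(W[, 1L], W[, 2L], cx, cy, ax$A, ax$B, ax$ux, ax$uy)
  t0 <- ellipse_ray_param(ref_angle, ax$A, ax$B, ax$ux, ax$uy)
  dt <- wrap_pm_pi(ft$t - t0)
  v <- ellipse_arc_between(t0, t0 + dt, ax$A, ax$B)
  list(v = v, rho = sqrt((W[, 1L] - cx)^2 + (W[, 2L] - cy)^2),
       residual = ft$dist)
}

# map new points through a fitted pass
predict_pass1 <- function(ps, P) {
  P <- as_point_matrix(P)
  s <- as.vector(P %*% ps$frame$a)
  W <- cbind(P %*% ps$frame$b1, P %*% ps$frame$b2)
  if (ps$mode == "line") {
    list(s = s, v = as.vector(W %*% ps$dvec),
         rho = as.vector(W %*% c(-ps$dvec[2L], ps$dvec[1L])))
  } else {
    uv <- eval_pass1(ps$family, ps$ref_angle, s, W)
    list(s = s, v = uv$v, rho = uv$rho)
  }
}

# --- pass 2: flatten the orthogonal profile -------------------------------

# arc-length function u(s) of a profile rho(s) given on a dense grid;
# linear continuation beyond the grid with the boundary slopes
profile_arcfun <- function(grid, drho) {
  ds <- diff(grid)
  speed <- sqrt(1 + drho^2)
  u <- c(0, cumsum((speed[-1L] + speed[-length(speed)]) / 2 * ds))
  lo <- grid[1L]; hi <- grid[length(grid)]
  ulo <- 0; uhi <- u[length(u)]
  slo <- speed[1L]; shi <- speed[length(speed)]
  f <- stats::approxfun(grid, u)
  function(s) {
    out <- f(pmin(pmax(s, lo), hi))
    out[s < lo] <- ulo + (s[s < lo] - lo) * slo
    out[s > hi] <- uhi + (s[s > hi] - hi) * shi
    out
  }
}

# fit one slab's profile rho(s) and return its arc-length function,
# anchored at the common reference coordinate s0 so that arc functions of
# different slabs agree there (they are blended later). The profile
# derivative is only trusted over the slab's own s-coverage and continued
# linearly outside it.
fit_profile_slab <- function(s, rho, grid, s0) {
  scale_r <- max(stats::sd(rho), 1e-300)
  if (length(unique(round(s, 12))) >= 8L &&
      stats::sd(rho) > 1e-9 * (abs(mean(rho)) + 1)) {
    sp <- stats::smooth.spline(s, rho)
    gcl <- pmin(pmax(grid, min(s)), max(s))
    drho <- stats::predict(sp, gcl, deriv = 1L)$y
  } else if (length(unique(s)) >= 2L && scale_r > 0) {
    slope <- stats::coef(stats::lm(rho ~ s))[2L]
    if (!is.finite(slope)) slope <- 0
    drho <- rep(slope, length(grid))
  } else {
    drho <- rep(0, length(grid))
  }
  f <- profile_arcfun(grid, drho)
  off <- f(s0)
  function(s) f(s) - off
}

#' Unwrap 3D tracks onto a flat chart
#'
#' The full two-pass unwrapping. Pass 1 ([unwrap_pass()]) maps the data
#' onto a cylindrical-like intermediate, flat along the unrolled arc
#' coordinate `v`. Pass 2 repeats the flattening in the orthogonal
#' dimension: the data are sliced along `v`, the orthogonal profile (the
#' slice-center distance `rho` as a function of the axis coordinate) is
#' fitted with a smoothing spline per slab, and the axis coordinate is
#' replaced by arc length along that profile. Arc-length functions are
#' interpolated linearly between slab mid-`v` values so the chart is
#' continuous; on developable data (cylinders, planes) pass 2 reduces to
#' the identity and the chart is an exact isometric development.
#'
#' @param ts a [tracks3d()] object (or an n x 3 point matrix).
#' @param axis slicing axis for pass 1: `"auto"` (coordinate axis of
#'   greatest data extent, the default), `"auto_residual"` (try all three,
#'   keep the smallest total fit residual), `"x"`, `"y"`, `"z"`, or a unit
#'   3-vector.
#' @param n_slices slabs for pass 1.
#' @param n_slices2 slabs for pass 2 (default: same).
#' @return An object of class `unwrap_chart` with elements `tracks` (a
#'   [tracks2d()], `method_tag = "unwrap"`, coordinates `u` = flattened
#'   axis arc, `v` = circumferential arc), `pass1`, `report` (per-slab
#'   ellipse parameters and residuals) and `residual` (per-point distance
#'   to the fitted surface model). Use [predict.unwrap_chart()] to map
#'   additional points (e.g. an attractant position) through the same
#'   chart.
#' @examples
#' s <- make_surface("cylinder", r = 1, h = 4, theta_half = 2)
#' sim <- simulate_walk(s, walk_model(step_length = 0.05), 5, 60, seed = 2)
#' ch <- unwrap(sim$tracks, n_slices = 8)
#' ch$tracks
#' @export
unwrap <- function(ts, axis = "auto", n_slices = 12L, n_slices2 = n_slices) {
  if (inherits(ts, "tracks3d")) {
    P <- coord_matrix(ts)
    ids <- ts$track_id; tt <- ts$t
  } else {
    P <- as_point_matrix(ts)
    ids <- rep("p", nrow(P)); tt <- seq_len(nrow(P))
  }
  # globally flat data develop exactly: rotate onto the principal plane
  ctr <- colMeans(P)
  svP <- svd(sweep(P, 2L, ctr), nu = 0L)
  if (svP$d[3L] <= 1e-9 * svP$d[1L]) {
    V <- svP$v[, 1:2, drop = FALSE]
    for (jj in 1:2) if (V[which.max(abs(V[, jj])), jj] < 0)
      V[, jj] <- -V[, jj]
    UV <- sweep(P, 2L, ctr) %*% V
    tr <- if (inherits(ts, "tracks3d"))
      tracks2d(ids, tt, UV[, 1L], UV[, 2L], method_tag = "unwrap",
               dt = attr(ts, "dt"))
    else NULL
    return(structure(list(tracks = tr, uv = cbind(u = UV[, 1L],
                                                  v = UV[, 2L]),
                          pass1 = list(mode = "flat", center = ctr, V = V),
                          pass2 = NULL, axis = "flat",
                          report = data.frame(slab = integer(0)),
                          residual = rep(0, nrow(P))),
                     class = "unwrap_chart"))
  }
  if (identical(axis, "auto")) {
    ext <- apply(P, 2L, function(v) diff(range(v)))
    axis <- c("x", "y", "z")[which.max(ext)]
    p1 <- unwrap_pass(P, axis, n_slices)
  } else if (identical(axis, "auto_residual")) {
    cand <- lapply(c("x", "y", "z"), function(a)
      tryCatch(unwrap_pass(P, a, n_slices), error = function(e) NULL))
    tot <- vapply(cand, function(p)
      if (is.null(p)) Inf else sum(p$residual), numeric(1))
    if (all(!is.finite(tot))) stop("no axis admits a valid slicing")
    axis <- c("x", "y", "z")[which.min(tot)]
    p1 <- cand[[which.min(tot)]]
  } else {
    p1 <- unwrap_pass(P, axis, n_slices)
  }
  p2 <- fit_pass2(p1$s, p1$v, p1$rho, n_slices2)
  u <- eval_pass2(p2, p1$s, p1$v)
  tr <- if (inherits(ts, "tracks3d"))
    tracks2d(ids, tt, u, p1$v, method_tag = "unwrap", dt = attr(ts, "dt"))
  else NULL
  structure(list(tracks = tr, uv = cbind(u = u, v = p1$v),
                 pass1 = p1, pass2 = p2, axis = axis,
                 report = p1$report, residual = p1$residual),
            class = "unwrap_chart")
}

fit_pass2 <- function(s, v, rho, n_slices2) {
  sl <- slab_assign(v, n_slices2)
  grid <- seq(min(s), max(s), length.out = 1025L)
  vmid <- as.vector(rowsum(v, sl$idx) / tabulate(sl$idx, sl$n))
  s0 <- stats::median(s)
  arcs <- lapply(seq_len(sl$n), function(j) {
    i <- sl$idx == j
    fit_profile_slab(s[i], rho[i], grid, s0)
  })
  ord <- order(vmid)
  list(vmid = vmid[ord], arcs = arcs[ord], n = sl$n)
}

# blend slab arc-length functions smoothly in v (Gaussian kernel over
# slab mid-positions; hard interval blending would kink the chart at
# every slab boundary and leave angle artifacts)
eval_pass2 <- function(p2, s, v) {
  if (p2$n == 1L) return(p2$arcs[[1L]](s))
  vm <- p2$vmid
  h <- stats::median(diff(vm))
  U <- matrix(unlist(lapply(p2$arcs, function(f) f(s))), nrow = length(s))
  Wt <- matrix(unlist(lapply(vm, function(m) exp(-((v - m) / h)^2))),
               nrow = length(v))
  rowSums(U * Wt) / rowSums(Wt)
}

#' @export
print.unwrap_chart <- function(x, ...) {
  cat(sprintf("<unwrap_chart> axis=%s, %d pass-1 slabs (%s), %d pass-2 slabs\n",
              x$axis, nrow(x$report),
              paste(unique(x$report$mode), collapse = "/"), x$pass2$n))
  cat(sprintf("  median |point - surface| residual: %.3g\n",
              stats::median(x$residual)))
  invisible(x)
}

#' @export
summary.unwrap_chart <- function(object, ...) {
  print(object)
  print(object$report)
  invisible(object$report)
}

#' Map new points through a fitted unwrap chart
#'
#' @param object an [unwrap()] chart.
#' @param newdata 3-vector or n x 3 matrix of points.
#' @param ... unused.
#' @return n x 2 matrix of chart coordinates `(u, v)`.
#' @export
predict.unwrap_chart <- function(object, newdata, ...) {
  P <- as_point_matrix(newdata)
  if (identical(object$pass1$mode, "flat")) {
    UV <- sweep(P, 2L, object$pass1$center) %*% object$pass1$V
    return(cbind(u = UV[, 1L], v = UV[, 2L]))
  }
  p1 <- predict_pass1(object$pass1, P)
  u <- eval_pass2(object$pass2, p1$s, p1$v)
  cbind(u = u, v = p1$v)
}

#' @export
plot.unwrap_chart <- function(x, ...) {
  if (!is.null(x$tracks)) plot(x$tracks, main = "unwrapped tracks", ...)
  else plot(x$uv[, 1L], x$uv[, 2L], pch = 16, cex = 0.4, asp = 1,
            xlab = "u", ylab = "v", ...)
  invisible(x)
}
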