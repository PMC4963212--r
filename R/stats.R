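#' Binned circular angle distribution
#'
#' Container for a set of per-step angles in `[-pi, pi)` together with an
#' equal-width histogram normalized to a density (integral 1). Raw angles
#' are always retained alongside the bins so that alternative distances
#' and bootstraps over tracks remain possible.
#'
#' @param angles numeric vector of angles (wrapped internally).
#' @param n_bins number of equal bins over `[-pi, pi)`, at least 8
#'   (default 36, i.e. 10 degrees).
#' @param track_id optional per-angle track identifiers (enables
#'   track-level bootstrap).
#' @param n_excluded count of steps excluded upstream (zero-length steps).
#' @param provenance named list tagging how the angles were obtained
#'   (method, which, surface/model tags).
#' @return An object of class `angle_distribution` with elements `angles`,
#'   `breaks`, `density`, `track_id`, `n_excluded`, `provenance`.
#' @export
angle_distribution <- function(angles, n_bins = 36, track_id = NULL,
                               n_excluded = 0L, provenance = list()) {
  if (n_bins < 8) stop("use at least 8 bins")
  angles <- wrap_angle(as.numeric(angles))
  angles <- angles[is.finite(angles)]
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  h <- if (length(angles))
    graphics::hist(angles, breaks = breaks, plot = FALSE)$density
  else rep(NA_real_, n_bins)
  structure(list(angles = angles, breaks = breaks, density = h,
                 track_id = track_id, n_excluded = as.integer(n_excluded),
                 provenance = provenance),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("<angle_distribution%s> %s angles, %d bins%s\n",
              if (length(pv)) paste0(": ", paste(unlist(pv[c("method",
                "which")]), collapse = "/")) else "",
              if (is.null(x$angles)) "analytic (no raw)" else
                format(length(x$angles)),
              length(x$density),
              if (x$n_excluded > 0)
                sprintf(" (%d zero-length steps excluded)", x$n_excluded)
              else ""))
  invisible(x)
}

#' @export
plot.angle_distribution <- function(x, ...) {
  mids <- (x$breaks[-1L] + x$breaks[-length(x$breaks)]) / 2
  graphics::plot(mids, x$density, type = "h", lwd = 3,
                 xlab = "angle (rad)", ylab = "density", ...)
  graphics::abline(h = 1 / (2 * pi), lty = 3)
  invisible(x)
}

# signed angle from w to d (CCW positive), optionally under per-row
# 2x2 metrics given as columns g11,g12,g22
signed_angle <- function(w, d, g = NULL) {
  if (is.null(g)) {
    atan2(w[, 1L] * d[, 2L] - w[, 2L] * d[, 1L], rowSums(w * d))
  } else {
    dot <- g[, 1L] * w[, 1L] * d[, 1L] +
      g[, 2L] * (w[, 1L] * d[, 2L] + w[, 2L] * d[, 1L]) +
      g[, 3L] * w[, 2L] * d[, 2L]
    cr <- sqrt(pmax(0, g[, 1L] * g[, 3L] - g[, 2L]^2)) *
      (w[, 1L] * d[, 2L] - w[, 2L] * d[, 1L])
    atan2(cr, dot)
  }
}

# fetch per-row metric components (g11,g12,g22) for given (track_id, t)
metric_rows <- function(metric, track_id, t) {
  if (is.null(metric)) return(NULL)
  i <- match(paste(track_id, t, sep = "\r"), metric$key)
  if (anyNA(i)) stop("metric field does not cover all requested points")
  cbind(metric$g[i, 1L], metric$g[i, 2L], metric$g[i, 3L])
}

#' Bias angles of a 2D track set
#'
#' For every step, the signed angle between the step displacement and the
#' direction from the step origin toward the attractant (target),
#' counterclockwise positive. With a metric field, inner products, norms
#' and orientation use the metric tensor at the step origin, which removes
#' the distortion of non-isometric 2D charts. Zero-length steps have no
#' direction and are excluded (counted in `n_excluded`).
#'
#' @param ts2d a [tracks2d()] object.
#' @param target2d attractant position in the same 2D chart.
#' @param metric optional [metric_field()] covering the track points.
#' @param n_bins histogram bins.
#' @return An [angle_distribution()].
#' @export
bias_angles <- function(ts2d, target2d, metric = NULL, n_bins = 36) {
  stopifnot(inherits(ts2d, "tracks2d"), length(target2d) == 2L)
  st <- steps(ts2d)
  d <- cbind(st$du, st$dv)
  w <- cbind(target2d[1L] - st$u, target2d[2L] - st$v)
  if (any(rowSums(w^2) == 0))
    stop("target coincides with a step origin")
  ok <- rowSums(d^2) > 0
  g <- metric_rows(metric, st$track_id, st$t_start)
  a <- signed_angle(w[ok, , drop = FALSE], d[ok, , drop = FALSE],
                    if (is.null(g)) NULL else g[ok, , drop = FALSE])
  angle_distribution(a, n_bins = n_bins, track_id = st$track_id[ok],
                     n_excluded = sum(!ok),
                     provenance = list(method = attr(ts2d, "method_tag"),
                                       which = "bias"))
}

#' Persistence (turning) angles of a 2D track set
#'
#' For every pair of consecutive steps within a track, the signed angle
#' from the first to the second displacement. With a metric field the
#' angle is evaluated with the metric tensor at the shared point. Pairs
#' containing a zero-length step are excluded and counted.
#'
#' @inheritParams bias_angles
#' @return An [angle_distribution()].
#' @export
persistence_angles <- function(ts2d, metric = NULL, n_bins = 36) {
  stopifnot(inherits(ts2d, "tracks2d"))
  st <- steps(ts2d)
  n <- nrow(st)
  if (n < 2L) return(angle_distribution(numeric(0), n_bins = n_bins))
  consec <- st$track_id[-n] == st$track_id[-1L] &
    st$t_start[-1L] == st$t_start[-n] + 1L
  i <- which(consec)
  d1 <- cbind(st$du[i], st$dv[i])
  d2 <- cbind(st$du[i + 1L], st$dv[i + 1L])
  ok <- rowSums(d1^2) > 0 & rowSums(d2^2) > 0
  # metric at the shared point = origin of the second step
  g <- metric_rows(metric, st$track_id[i + 1L], st$t_start[i + 1L])
  a <- signed_angle(d1[ok, , drop = FALSE], d2[ok, , drop = FALSE],
                    if (is.null(g)) NULL else g[ok, , drop = FALSE])
  angle_distribution(a, n_bins = n_bins, track_id = st$track_id[i][ok],
                     n_excluded = sum(!ok),
                     provenance = list(method = attr(ts2d, "method_tag"),
                                       which = "persistence"))
}

#' Straightness index
#'
#' `D = net displacement / total path length` per track: 1 for ballistic
#' (straight) motion, approaching 0 for diffusive motion as tracks grow.
#'
#' @param ts a track set (2D or 3D).
#' @return named numeric vector, one `D` in `[0, 1]` per track.
#' @export
straightness_index <- function(ts) {
  stopifnot(inherits(ts, "tracks"))
  cn <- coord_names(ts)
  df <- as.data.frame(ts)
  ids <- unique(df$track_id)
  out <- vapply(ids, function(id) {
    X <- as.matrix(df[df$track_id == id, cn, drop = FALSE])
    if (nrow(X) < 2L) stop("track '", id, "' has fewer than 2 points")
    seg <- diff(X)
    tot <- sum(sqrt(rowSums(seg^2)))
    if (tot == 0) stop("track '", id, "' has zero path length")
    sqrt(sum((X[nrow(X), ] - X[1L, ])^2)) / tot
  }, numeric(1))
  names(out) <- ids
  out
}

#' Deviation distance between angle distributions
#'
#' Scalar distance between a computed angle distribution and a reference
#' (typically the true distribution of the generating walk model). The
#' default is the total-variation distance between the binned densities,
#' `0.5 * sum |p_i - q_i| * binwidth`, which lies in `[0, 1]`; an L2
#' distance on densities and a Kolmogorov–Smirnov statistic on the raw
#' angles are selectable.
#'
#' @param d,truth [angle_distribution()] objects on identical bins.
#' @param method `"tv"` (default), `"l2"` or `"ks"`.
#' @return non-negative scalar.
#' @export
deviation_distance <- function(d, truth, method = c("tv", "l2", "ks")) {
  method <- match.arg(method)
  stopifnot(inherits(d, "angle_distribution"),
            inherits(truth, "angle_distribution"))
  if (length(d$breaks) != length(truth$breaks) ||
      max(abs(d$breaks - truth$breaks)) > 1e-12)
    stop("distributions are binned differently")
  bw <- diff(d$breaks)[1L]
  switch(method,
    tv = 0.5 * sum(abs(d$density - truth$density)) * bw,
    l2 = sqrt(sum((d$density - truth$density)^2) * bw),
    ks = {
      if (is.null(d$angles) || is.null(truth$angles))
        stop("KS distance needs raw angles on both sides")
      as.numeric(suppressWarnings(
        stats::ks.test(d$angles, truth$angles)$statistic))
    })
}

#' Bootstrap confidence interval for a deviation distance
#'
#' Resamples whole tracks with replacement and recomputes the deviation
#' distance, giving a CI that respects within-track correlation.
#'
#' @param d an [angle_distribution()] carrying raw angles and `track_id`.
#' @param truth reference [angle_distribution()] on the same bins.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed optional seed.
#' @return list with `estimate`, `lower`, `upper`, `boot` (replicates).
#' @export
deviation_ci <- function(d, truth, n_boot = 200, conf = 0.95, seed = NULL) {
  if (is.null(d$angles) || is.null(d$track_id))
    stop("need raw angles with track ids for the bootstrap")
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(d$track_id)
  by_id <- split(d$angles, d$track_id)[ids]
  n_bins <- length(d$density)
  boot <- vapply(seq_len(n_boot), function(b) {
    a <- unlist(by_id[sample.int(length(ids), replace = TRUE)],
                use.names = FALSE)
    db <- angle_distribution(a, n_bins = n_bins)
    deviation_distance(db, truth)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(estimate = deviation_distance(d, truth),
       lower = unname(stats::quantile(boot, alpha)),
       upper = unname(stats::quantile(boot, 1 - alpha)),
       boot = boot)
}

#' Chi-square goodness of fit against the uniform circle
#'
#' Convenience wrapper testing whether binned angles are consistent with
#' the uniform circular distribution.
#'
#' @param d an [angle_distribution()] with raw angles.
#' @return the `htest` object from [stats::chisq.test()].
#' @export
uniformity_test <- function(d) {
  counts <- graphics::hist(d$angles, breaks = d$breaks, plot = FALSE)$counts
  stats::chisq.test(counts)
}
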