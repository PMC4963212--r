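#' Random-walk model on a surface
#'
#' Specifies a (possibly biased, possibly persistent) random walk. Step
#' headings in the local tangent plane are drawn from a von Mises kernel
#' centered on the tangent-projected direction toward `target`
#' (concentration `bias`) and/or on the transported previous heading
#' (concentration `persistence`); when both are active the kernels combine
#' multiplicatively, which is again von Mises with resultant parameters.
#' `bias = persistence = 0` gives the Brownian (uniform-heading) walk; the
#' four sign patterns of the two strengths give the four classic
#' random-walk classes (unbiased/biased x non-persistent/persistent).
#'
#' @param bias concentration (`>= 0`) of attraction toward `target`.
#' @param persistence concentration (`>= 0`) of alignment with the
#'   previous step.
#' @param target 3-vector attractant position; required iff `bias > 0`.
#' @param step_length surface distance per step (`> 0`).
#' @return An object of class `walk_model`.
#' @export
walk_model <- function(bias = 0, persistence = 0, target = NULL,
                       step_length = 0.03) {
  stopifnot(bias >= 0, persistence >= 0, step_length > 0)
  if (bias > 0 && is.null(target))
    stop("a target position is required when bias > 0")
  if (!is.null(target)) stopifnot(length(target) == 3L, all(is.finite(target)))
  structure(list(bias = bias, persistence = persistence,
                 target = if (is.null(target)) NULL else as.numeric(target),
                 step_length = step_length),
            class = "walk_model")
}

#' @export
print.walk_model <- function(x, ...) {
  cat(sprintf("<walk_model> bias=%g persistence=%g step_length=%g%s\n",
              x$bias, x$persistence, x$step_length,
              if (is.null(x$target)) "" else
                paste0(" target=(", paste(signif(x$target, 4),
                                          collapse = ", "), ")")))
  invisible(x)
}

#' Simulate random walks on a surface
#'
#' Walkers take steps of length `step_length` along a heading drawn in the
#' local tangent plane, followed by orthogonal projection back onto the
#' surface (projected-Euler stepping: exact on planes and along cylinder
#' generators, O(L^2) geodesic error elsewhere). The previous heading is
#' parallel-transported between steps by projecting the previous 3D step
#' direction onto the new tangent plane and renormalizing.
#'
#' @param s a [make_surface()] object.
#' @param m a [walk_model()].
#' @param n_tracks number of walkers.
#' @param n_steps steps per walker (`>= 1`).
#' @param seed optional integer seed for reproducibility.
#' @param start optional n_tracks x 3 matrix of on-surface start points;
#'   by default starts are sampled uniformly from the sampling patch of
#'   `start_surface`.
#' @param start_surface surface whose sampling patch supplies the start
#'   points (defaults to `s` itself); must share the geometry of `s`.
#' @return An object of class `sim_walk`: a list with
#'   \item{tracks}{a [tracks3d()] of the walker positions,}
#'   \item{headings}{per-step ground truth: heading angle in the local
#'     tangent basis, intrinsic bias angle (`NA` without a target) and
#'     intrinsic turning angle (`NA` for first steps),}
#'   \item{surface, model, seed}{provenance.}
#' @examples
#' s <- make_surface("sphere", r = 1, cap = pi / 3)
#' sim <- simulate_walk(s, walk_model(), n_tracks = 3, n_steps = 20, seed = 1)
#' pts <- as.matrix(as.data.frame(sim$tracks)[, c("x", "y", "z")])
#' max(abs(surface_implicit(s, pts)))
#' @export
simulate_walk <- function(s, m, n_tracks = 10, n_steps = 100, seed = NULL,
                          start = NULL, start_surface = s) {
  stopifnot(inherits(s, "surface"), inherits(m, "walk_model"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (n_tracks < 1) stop("n_tracks must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  P <- if (is.null(start)) sample_on_surface(start_surface, n_tracks)
       else project_to_surface(s, as_point_matrix(start))
  if (m$bias > 0) {
    d0 <- sweep(-P, 2L, m$target, "+")
    if (any(rowSums(d0^2) == 0))
      stop("target coincides with a start point")
  }
  L <- m$step_length
  nt <- n_tracks
  pos <- array(NA_real_, c(nt, n_steps + 1L, 3L))
  pos[, 1L, ] <- P
  heading <- bias_a <- turn_a <- matrix(NA_real_, nt, n_steps)
  prev_dir <- NULL
  for (k in seq_len(n_steps)) {
    B <- tangent_basis(s, P)
    Rx <- rep(0, nt); Ry <- rep(0, nt)
    phi_b <- rep(NA_real_, nt)
    if (!is.null(m$target)) {
      Tv <- sweep(-P, 2L, m$target, "+")
      phi_b <- atan2(rowSums(Tv * B$e2), rowSums(Tv * B$e1))
      Rx <- Rx + m$bias * cos(phi_b); Ry <- Ry + m$bias * sin(phi_b)
    }
    phi_p <- rep(NA_real_, nt)
    if (!is.null(prev_dir)) {
      p1 <- rowSums(prev_dir * B$e1); p2 <- rowSums(prev_dir * B$e2)
      phi_p <- atan2(p2, p1)
      Rx <- Rx + m$persistence * cos(phi_p)
      Ry <- Ry + m$persistence * sin(phi_p)
    }
    kap <- sqrt(Rx^2 + Ry^2)
    mu <- ifelse(kap > 0, atan2(Ry, Rx), 0)
    th <- rvonmises(nt, mu, kap)
    dirs <- B$e1 * cos(th) + B$e2 * sin(th)
    Pn <- project_to_surface(s, P + L * dirs)
    if (s$bounded) Pn <- reflect_into_patch(s, Pn)
    heading[, k] <- th
    bias_a[, k] <- wrap_angle(th - phi_b)
    turn_a[, k] <- wrap_angle(th - phi_p)
    d <- Pn - P
    prev_dir <- d / sqrt(rowSums(d^2))
    P <- Pn
    pos[, k + 1L, ] <- P
  }
  ids <- sprintf("w%03d", seq_len(nt))
  tr <- tracks3d(rep(ids, each = n_steps + 1L),
                 rep(0:n_steps, times = nt),
                 as.vector(t(pos[, , 1L])),
                 as.vector(t(pos[, , 2L])),
                 as.vector(t(pos[, , 3L])))
  hd <- data.frame(track_id = rep(ids, each = n_steps),
                   t_start = rep(0:(n_steps - 1L), times = nt),
                   heading = as.vector(t(heading)),
                   bias_angle = as.vector(t(bias_a)),
                   turn_angle = as.vector(t(turn_a)),
                   stringsAsFactors = FALSE)
  structure(list(tracks = tr, headings = hd, surface = s, model = m,
                 seed = seed),
            class = "sim_walk")
}

#' @export
print.sim_walk <- function(x, ...) {
  cat(sprintf("<sim_walk> %d tracks x %d steps on %s (bias=%g, persistence=%g)\n",
              length(unique(x$tracks$track_id)),
              sum(!is.na(x$headings$heading)) /
                length(unique(x$tracks$track_id)),
              x$surface$kind, x$model$bias, x$model$persistence))
  invisible(x)
}

#' True angle distributions of a walk model
#'
#' The expected bias / persistence (turning) angle distribution implied by
#' the walk kernels, on a flat geometry. Uniform when the relevant
#' concentration is 0; von Mises for a single active kernel; for the
#' bias-only turning distribution the closed-form difference density of two
#' independent von Mises headings,
#' `f(d) = I0(2 k cos(d/2)) / (2 pi I0(k)^2)`; and a large-n Monte Carlo
#' estimate of the stationary heading chain when both kernels are active
#' (the only case without a closed form).
#'
#' @param m a [walk_model()].
#' @param which `"bias"` or `"persistence"`.
#' @param n_bins number of histogram bins (default 36).
#' @param mc_n Monte Carlo sample size for the biased-persistent case.
#' @param seed seed for the Monte Carlo branch.
#' @return An [angle_distribution()] with a `density_fun` attribute where
#'   the density is analytic.
#' @export
true_angle_distribution <- function(m, which = c("bias", "persistence"),
                                    n_bins = 36, mc_n = 1e6, seed = 1) {
  stopifnot(inherits(m, "walk_model"))
  which <- match.arg(which)
  kb <- m$bias; kp <- m$persistence
  prov <- list(method = "true", which = which, model = c(bias = kb,
               persistence = kp))
  dens_fun <- NULL
  if (which == "bias") {
    if (kb == 0) dens_fun <- function(a) rep(1 / (2 * pi), length(a))
    else if (kp == 0) dens_fun <- function(a) dvonmises(a, 0, kb)
  } else {
    if (kp == 0 && kb == 0) dens_fun <- function(a) rep(1 / (2 * pi), length(a))
    else if (kb == 0) dens_fun <- function(a) dvonmises(a, 0, kp)
    else if (kp == 0) dens_fun <- function(a) {
      # difference of two iid vM(0, kb) headings
      besselI(2 * kb * abs(cos(a / 2)), 0, expon.scaled = TRUE) *
        exp(2 * kb * (abs(cos(a / 2)) - 1)) /
        (2 * pi * besselI(kb, 0, expon.scaled = TRUE)^2)
    }
  }
  if (!is.null(dens_fun))
    return(analytic_angle_distribution(dens_fun, n_bins, prov))
  # biased-persistent: stationary heading chain toward a fixed target at 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
         globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_chain <- 2000L
  burn <- 100L
  T_tot <- ceiling(mc_n / n_chain) + burn
  th <- rvonmises(n_chain, 0, kb)
  vals <- vector("list", T_tot)
  for (t in seq_len(T_tot)) {
    Rx <- kb + kp * cos(th); Ry <- kp * sin(th)
    mu <- atan2(Ry, Rx); kap <- sqrt(Rx^2 + Ry^2)
    th_new <- rvonmises(n_chain, mu, kap)
    vals[[t]] <- if (which == "bias") th_new else wrap_angle(th_new - th)
    th <- th_new
  }
  a <- unlist(vals[-seq_len(burn)], use.names = FALSE)
  angle_distribution(a, n_bins = n_bins, provenance = prov)
}

# bin an analytic circular density exactly (per-bin average via quadrature)
analytic_angle_distribution <- function(dens_fun, n_bins, prov) {
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  dens <- vapply(seq_len(n_bins), function(i)
    stats::integrate(dens_fun, breaks[i], breaks[i + 1L],
                     rel.tol = 1e-10)$value / diff(breaks[i:(i + 1L)]),
    numeric(1))
  structure(list(angles = NULL, breaks = breaks, density = dens,
                 n_excluded = 0L, provenance = prov,
                 density_fun = dens_fun),
            class = "angle_distribution")
}
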