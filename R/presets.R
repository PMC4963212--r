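#' Validation presets: surfaces and walk models
#'
#' The validation grid pairs six geometries of increasing difficulty with
#' three random-walk classes. Geometries (all unit-scale):
#' \describe{
#'   \item{`plane`}{flat square patch, the zero-curvature control.}
#'   \item{`cylinder`}{radius-1 circular cylinder (zero Gaussian
#'     curvature): unwrapping is an exact isometry here.}
#'   \item{`hemisphere`}{spherical dome, polar half-angle 60 degrees,
#'     reflecting rim.}
#'   \item{`sphere`}{near-complete spherical cap (80 degrees), the
#'     strongest uniform curvature.}
#'   \item{`ellipsoid_mild`}{ellipsoid with semi-axes (2, 1.2, 1), top
#'     patch.}
#'   \item{`ellipsoid_thin`}{thinly stretched ellipsoid with semi-axes
#'     (5, 1, 0.2), the known failure regime of plain manifold learning.}
#' }
#' Patches are bounded with reflecting edges so that tracks remain on a
#' single-chart portion of each surface, as cells confined to a tissue
#' region are. The attractant (`target`) sits just outside the patch rim,
#' like a wound adjacent to the imaged field.
#'
#' @param name preset name, see Details.
#' @return A list with elements `surface` (a [make_surface()] object used
#'   both for walking and for start sampling), `target` (3-vector
#'   attractant position), and `step_length` (default surface distance per
#'   step).
#' @seealso [simulate_preset()], [walk_presets()]
#' @export
surface_preset <- function(name = c("plane", "cylinder", "hemisphere",
                                    "sphere", "ellipsoid_mild",
                                    "ellipsoid_thin")) {
  name <- match.arg(name)
  switch(name,
    plane = list(
      surface = make_surface("plane", wx = 0.9, wy = 0.9, bounded = TRUE),
      target = c(1.4, 0, 0), step_length = 0.04),
    cylinder = list(
      surface = make_surface("cylinder", r = 1, h = 2.2, theta_half = 0.75,
                             bounded = TRUE),
      target = c(cos(1.15), sin(1.15), 0.8), step_length = 0.04),
    hemisphere = list(
      surface = make_surface("hemisphere_patch", r = 1, cap = pi / 3,
                             bounded = TRUE),
      target = c(sin(1.22), 0, cos(1.22)), step_length = 0.04),
    sphere = list(
      surface = make_surface("hemisphere_patch", r = 1, cap = 4 * pi / 9,
                             bounded = TRUE),
      target = c(sin(1.75), 0, cos(1.75)), step_length = 0.03),
    ellipsoid_mild = list(
      surface = make_surface("ellipsoid", a = 2, b = 1.2, c = 1,
                             cap = pi / 3, bounded = TRUE),
      target = c(2 * sin(1.4), 0, cos(1.4)), step_length = 0.04),
    ellipsoid_thin = list(
      surface = make_surface("ellipsoid", a = 5, b = 1, c = 0.2,
                             cap = pi / 3, bounded = TRUE),
      target = c(5 * sin(1.4), 0, 0.2 * cos(1.4)), step_length = 0.04)
  )
}

#' @rdname surface_preset
#' @param model walk class: `"brownian"` (no bias, no persistence),
#'   `"biased"` (bias 2 toward the preset target) or
#'   `"biased_persistent"` (bias 2, persistence 1).
#' @param preset a [surface_preset()] result (supplies target and step
#'   length).
#' @export
walk_presets <- function(model = c("brownian", "biased",
                                   "biased_persistent"), preset) {
  model <- match.arg(model)
  switch(model,
    brownian = walk_model(0, 0, step_length = preset$step_length),
    biased = walk_model(2, 0, target = preset$target,
                        step_length = preset$step_length),
    biased_persistent = walk_model(2, 1, target = preset$target,
                                   step_length = preset$step_length))
}

#' Simulate a preset surface / walk-model combination
#'
#' One-call access to the validation grid cells: builds the preset surface
#' and walk model and runs [simulate_walk()].
#'
#' @inheritParams surface_preset
#' @inheritParams walk_presets
#' @param n_tracks,n_steps,seed passed to [simulate_walk()].
#' @return A `sim_walk` object whose `preset` element records the preset
#'   name and target.
#' @examples
#' sim <- simulate_preset("cylinder", "brownian", n_tracks = 5,
#'                        n_steps = 50, seed = 1)
#' sim$preset$name
#' @export
simulate_preset <- function(name, model = "brownian", n_tracks = 50,
                            n_steps = 200, seed = NULL) {
  pr <- surface_preset(name)
  m <- walk_presets(model, pr)
  sim <- simulate_walk(pr$surface, m, n_tracks = n_tracks,
                       n_steps = n_steps, seed = seed)
  sim$preset <- list(name = name, model = model, target = pr$target)
  sim
}
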