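#' 3D track sets
#'
#' A `tracks3d` object holds a collection of time-ordered 3D trajectories,
#' the common export shape of cell/particle tracking tools (one row per
#' observed position). Time is a frame index with uniform spacing; `dt` is
#' the optional physical time per frame and only affects velocity units,
#' never angles.
#'
#' @param track_id vector of track identifiers (coerced to character).
#' @param t integer frame indices, strictly increasing within each track.
#' @param x,y,z numeric spatial coordinates (microns or arbitrary length
#'   units); must be finite.
#' @param dt optional scalar time per frame.
#'
#' @return A data frame of class `tracks3d` with columns
#'   `track_id, t, x, y, z`, sorted by `(track_id, t)`, carrying `dt` as an
#'   attribute.
#' @seealso [tracks2d()], [read_tracks()], [steps()]
#' @export
tracks3d <- function(track_id, t, x, y, z, dt = NULL) {
  df <- data.frame(
    track_id = as.character(track_id),
    t = as.integer(t),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  new_tracks(df, coords = c("x", "y", "z"), class = "tracks3d", dt = dt)
}

#' 2D track sets
#'
#' Same data model as [tracks3d()] with planar coordinates `(u, v)` and a
#' `method_tag` recording which transformation produced the representation
#' (`"xy"`, `"pca"`, `"unwrap"` or `"manifold"`).
#'
#' @inheritParams tracks3d
#' @param u,v numeric planar coordinates.
#' @param method_tag character scalar naming the producing transformation.
#' @return A data frame of class `tracks2d` with columns `track_id, t, u, v`.
#' @export
tracks2d <- function(track_id, t, u, v, method_tag = "xy", dt = NULL) {
  df <- data.frame(
    track_id = as.character(track_id),
    t = as.integer(t),
    u = as.numeric(u), v = as.numeric(v),
    stringsAsFactors = FALSE
  )
  ts <- new_tracks(df, coords = c("u", "v"), class = "tracks2d", dt = dt)
  attr(ts, "method_tag") <- method_tag
  ts
}

# Shared constructor/validator: sorts canonically, checks invariants.
new_tracks <- function(df, coords, class, dt = NULL) {
  for (cc in coords) {
    if (any(!is.finite(df[[cc]])))
      stop("non-finite values in coordinate '", cc, "'")
  }
  if (any(is.na(df$t))) stop("non-integer or missing frame indices")
  ord <- order(df$track_id, df$t)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$track_id, df$t, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (track_id, t) pair: (", d$track_id, ", ", d$t, ")")
  }
  structure(df, class = c(class, "tracks", "data.frame"), dt = dt)
}

#' @export
print.tracks3d <- function(x, ...) {
  cat(sprintf("<tracks3d> %d points, %d tracks\n",
              nrow(x), length(unique(x$track_id))))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
print.tracks2d <- function(x, ...) {
  cat(sprintf("<tracks2d:%s> %d points, %d tracks\n",
              attr(x, "method_tag") %||% "?",
              nrow(x), length(unique(x$track_id))))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
summary.tracks <- function(object, ...) {
  len <- table(object$track_id)
  st <- steps(object)
  cat(sprintf("%d tracks, %d points, %d steps\n",
              length(len), nrow(object), nrow(st)))
  cat("track lengths: ", paste(range(len), collapse = "-"),
      " (median ", stats::median(len), ")\n", sep = "")
  invisible(list(n_tracks = length(len), n_points = nrow(object),
                 n_steps = nrow(st), lengths = as.integer(len)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

coord_names <- function(ts) {
  if (inherits(ts, "tracks3d")) c("x", "y", "z") else c("u", "v")
}

coord_matrix <- function(ts) {
  as.matrix(as.data.frame(ts)[, coord_names(ts), drop = FALSE])
}

#' Read tracks from CSV
#'
#' Reads a plain comma-separated table of tracked positions. Column names
#' are configurable to accommodate the headers of common exporters
#' (TrackMate, Imaris, ...). Rows with non-finite coordinates are dropped
#' with a message reporting how many.
#'
#' @param path path to a CSV file with a header line.
#' @param columns named character vector mapping the canonical names
#'   `track_id, t, x, y, z` to the file's column headers.
#' @param dt optional time per frame.
#' @return A [tracks3d()] object.
#' @export
read_tracks <- function(path,
                        columns = c(track_id = "track_id", t = "t",
                                    x = "x", y = "y", z = "z"),
                        dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input: ", path)
  need <- c("track_id", "t", "x", "y", "z")
  for (nm in need) {
    col <- columns[[nm]] %||% nm
    if (!col %in% names(df))
      stop("missing required column '", col, "' (maps to ", nm, ")")
  }
  g <- function(nm) df[[columns[[nm]] %||% nm]]
  xyz <- cbind(as.numeric(g("x")), as.numeric(g("y")), as.numeric(g("z")))
  ok <- rowSums(!is.finite(xyz)) == 0L
  if (any(!ok))
    message(sum(!ok), " row(s) with non-finite coordinates dropped")
  if (!any(ok)) stop("no usable rows in ", path)
  tracks3d(g("track_id")[ok], g("t")[ok],
           xyz[ok, 1L], xyz[ok, 2L], xyz[ok, 3L], dt = dt)
}

#' Write tracks to CSV
#'
#' Writes a track set as CSV with a header, rows ordered by `(track_id, t)`.
#' For 2D sets the producing method is recorded in a leading `#` comment
#' line. Coordinates are printed at full precision so that
#' `read_tracks(write_tracks(ts))` round-trips bit-identically.
#'
#' @param ts a [tracks3d()] or [tracks2d()] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "tracks"))
  if (nrow(ts) == 0L) stop("refusing to write an empty track set")
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(ts, "tracks2d"))
    writeLines(sprintf("# method_tag: %s", attr(ts, "method_tag") %||% "?"),
               con)
  df <- as.data.frame(ts)
  for (cc in coord_names(ts)) df[[cc]] <- sprintf("%.17g", df[[cc]])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Decompose tracks into step vectors
#'
#' Forms one displacement (motion) vector per pair of consecutive frames
#' within each track; a track of length n yields n - 1 steps. By default a
#' gap in the frame numbering produces no step; gaps of up to `gap` missing
#' frames can optionally be bridged, treating the displacement across the
#' gap as a single step.
#'
#' @param ts a track set (2D or 3D).
#' @param gap maximum number of missing frames to bridge (default 0, i.e.
#'   only consecutive frames form steps).
#' @return A data frame with one row per step: `track_id`, `t_start`,
#'   origin coordinates and displacement components (`dx,dy,dz` or `du,dv`).
#' @export
steps <- function(ts, gap = 0) {
  stopifnot(inherits(ts, "tracks"))
  cn <- coord_names(ts)
  df <- as.data.frame(ts)
  n <- nrow(df)
  if (n < 2L) return(empty_steps(cn))
  same <- df$track_id[-n] == df$track_id[-1L]
  dtv <- df$t[-1L] - df$t[-n]
  take <- same & dtv >= 1L & dtv <= (gap + 1L)
  if (!any(take)) return(empty_steps(cn))
  i <- which(take)
  out <- data.frame(track_id = df$track_id[i], t_start = df$t[i],
                    stringsAsFactors = FALSE)
  for (cc in cn) out[[cc]] <- df[[cc]][i]
  for (cc in cn) out[[paste0("d", cc)]] <- df[[cc]][i + 1L] - df[[cc]][i]
  out
}

empty_steps <- function(cn) {
  out <- data.frame(track_id = character(0), t_start = integer(0))
  for (cc in cn) out[[cc]] <- numeric(0)
  for (cc in cn) out[[paste0("d", cc)]] <- numeric(0)
  out
}

step_disp <- function(st) {
  dn <- grep("^d", names(st), value = TRUE)
  as.matrix(st[, dn, drop = FALSE])
}

#' Project tracks onto the xy plane
#'
#' The naive baseline: the z coordinate is simply ignored. On curved
#' surfaces this compresses steps wherever the surface tilts away from the
#' image plane, distorting angle and length statistics.
#'
#' @param ts a [tracks3d()] object.
#' @return A [tracks2d()] object with `method_tag = "xy"`.
#' @export
project_xy <- function(ts) {
  stopifnot(inherits(ts, "tracks3d"))
  tracks2d(ts$track_id, ts$t, ts$x, ts$y,
           method_tag = "xy", dt = attr(ts, "dt"))
}

#' Project tracks onto the top two principal axes
#'
#' Pools all points of all tracks, centers them, and projects onto the two
#' leading principal components. Exact for flat data; on curved surfaces it
#' is a (generally worse) linear baseline. The sign of each axis is fixed
#' so that its largest-magnitude loading is positive, making the result
#' deterministic.
#'
#' @param ts a [tracks3d()] object with at least 3 non-collinear points.
#' @return A [tracks2d()] object with `method_tag = "pca"`.
#' @export
project_pca <- function(ts) {
  stopifnot(inherits(ts, "tracks3d"))
  X <- coord_matrix(ts)
  if (nrow(X) < 3L) stop("need at least 3 points for PCA projection")
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 0L, nv = 3L)
  if (sv$d[2L] <= 1e-12 * sv$d[1L])
    stop("degenerate covariance: points are collinear (rank < 2)")
  V <- sv$v[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  Y <- Xc %*% V
  out <- tracks2d(ts$track_id, ts$t, Y[, 1L], Y[, 2L],
                  method_tag = "pca", dt = attr(ts, "dt"))
  attr(out, "projection") <- list(center = colMeans(X), V = V)
  out
}

#' @export
plot.tracks <- function(x, ...) {
  cn <- coord_names(x)[1:2]
  df <- as.data.frame(x)
  ids <- unique(df$track_id)
  cols <- grDevices::hcl.colors(max(3L, length(ids)), "Dark 3")
  plot(df[[cn[1L]]], df[[cn[2L]]], type = "n",
       xlab = cn[1L], ylab = cn[2L], asp = 1, ...)
  for (i in seq_along(ids)) {
    d <- df[df$track_id == ids[i], ]
    graphics::lines(d[[cn[1L]]], d[[cn[2L]]], col = cols[i])
  }
  invisible(x)
}
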