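# Riemannian (metric) manifold learning: LLE embedding + metric tensor
# estimation from a density-renormalized graph Laplacian.

# Block-wise brute-force k-nearest neighbours (no kd-tree dependency;
# point counts here are ~1e4, for which blocked dense distances are fast
# and memory-bounded).
knn_search <- function(X, k, block = 512L) {
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of points")
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(X^2)
  for (from in seq(1L, n, by = block)) {
    to <- min(from + block - 1L, n)
    D2 <- outer(sq[from:to], sq, "+") - 2 * (X[from:to, , drop = FALSE] %*% t(X))
    D2[cbind(seq_len(to - from + 1L), from:to)] <- Inf
    for (i in seq_len(to - from + 1L)) {
      o <- order(D2[i, ])[seq_len(k)]
      idx[from + i - 1L, ] <- o
      dst[from + i - 1L, ] <- sqrt(pmax(0, D2[i, o]))
    }
  }
  list(idx = idx, dist = dst)
}

#' Default kernel bandwidth
#'
#' The median distance to the `k_ref`-th nearest neighbour, the scale
#' below which the sampled surface is treated as flat.
#'
#' @param points3d n x 3 point matrix.
#' @param k_ref reference neighbour rank (default 10).
#' @return bandwidth (length scale) `epsilon`.
#' @export
default_bandwidth <- function(points3d, k_ref = 10L) {
  nn <- knn_search(as_point_matrix(points3d), k_ref)
  stats::median(nn$dist[, k_ref])
}

#' Neighbourhood graph with heat-kernel weights
#'
#' Builds the symmetric k-nearest-neighbour graph (union of directed
#' k-NN relations) with Gaussian heat-kernel weights
#' `w_ij = exp(-|x_i - x_j|^2 / eps^2)` and unit self-weights. The graph
#' must be connected: disconnection signals that `k` or the bandwidth is
#' too small for the sampling density.
#'
#' @param points3d n x 3 matrix of points.
#' @param k number of neighbours (default 30; large enough that the
#'   truncated kernel retains essentially all its mass).
#' @param bandwidth kernel length scale `eps`; default
#'   [default_bandwidth()].
#' @return An object of class `neighbor_graph`: sparse symmetric weight
#'   matrix `W` (with unit diagonal), `bandwidth`, `k`, and the kNN
#'   structure.
#' @export
build_graph <- function(points3d, k = 30L, bandwidth = NULL) {
  X <- as_point_matrix(points3d)
  n <- nrow(X)
  if (n < k + 1L) stop("need at least k + 1 points")
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(X)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  nn <- knn_search(X, k)
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nn$idx))
  w <- exp(-(as.vector(t(nn$dist)) / bandwidth)^2)
  W <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  W <- pmax_sparse(W, Matrix::t(W)) # symmetric union of directed kNN
  Matrix::diag(W) <- 1
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("neighbour graph is disconnected (component sizes: ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "),
         "); increase k or the bandwidth, or supply denser data")
  structure(list(W = W, bandwidth = bandwidth, k = k, knn = nn, n = n),
            class = "neighbor_graph")
}

# elementwise max of two sparse matrices with the same pattern union
pmax_sparse <- function(A, B) {
  S <- (A + B + abs(A - B)) / 2
  Matrix::drop0(S)
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, k=%d, bandwidth=%.4g, %d edges\n",
              x$n, x$k, x$bandwidth,
              (Matrix::nnzero(x$W) - x$n) / 2L))
  invisible(x)
}

#' Density-renormalized graph Laplacian
#'
#' The random-walk graph Laplacian with density renormalization
#' (alpha = 1): the kernel is first divided by the product of node
#' degrees, removing the sampling-density bias, then row-normalized. The
#' returned operator is
#' `L = (4 / eps^2) (I - P)`,
#' which converges to minus the Laplace–Beltrami operator of the
#' underlying surface regardless of how unevenly the tracks sample it
#' (sign convention: `L x^2 ~ -2` on flat regions; `L` annihilates
#' constants exactly).
#'
#' @param g a [build_graph()] object.
#' @return sparse matrix operator acting on per-point scalar vectors.
#' @export
graph_laplacian <- function(g) {
  stopifnot(inherits(g, "neighbor_graph"))
  W <- g$W
  q <- Matrix::rowSums(W)
  Wt <- Matrix::Diagonal(x = 1 / q) %*% W %*% Matrix::Diagonal(x = 1 / q)
  d <- Matrix::rowSums(Wt)
  P <- Matrix::Diagonal(x = 1 / d) %*% Wt
  (4 / g$bandwidth^2) * (Matrix::Diagonal(g$n) - P)
}

# smallest-eigenvalue eigenpairs of a symmetric PSD sparse matrix by
# shift-invert Lanczos (sparse Cholesky + ARPACK via igraph)
smallest_eigenvectors <- function(M, nev, tol = 1e-10) {
  n <- nrow(M)
  if (n <= 400L) {
    e <- eigen(as.matrix(M), symmetric = TRUE)
    ord <- order(e$values)
    return(list(values = e$values[ord[seq_len(nev)]],
                vectors = e$vectors[, ord[seq_len(nev)], drop = FALSE]))
  }
  shift <- 1e-10 * mean(Matrix::diag(M))
  Ms <- methods::as(M + shift * Matrix::Diagonal(n), "CsparseMatrix")
  ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Ms),
                                     "CsparseMatrix"), LDL = FALSE)
  f <- function(x, extra) as.vector(Matrix::solve(ch, x))
  ar <- igraph::arpack(f, sym = TRUE,
                       options = list(n = n, nev = nev,
                                      ncv = max(4L * nev + 1L, 20L),
                                      which = "LM", maxiter = 3000L))
  lam <- 1 / ar$values - shift
  ord <- order(lam)
  list(values = lam[ord], vectors = ar$vectors[, ord, drop = FALSE])
}

#' Locally linear embedding into the plane
#'
#' Standard LLE: each point is reconstructed from its k nearest
#' neighbours with regularized least-squares weights; the embedding is
#' given by the bottom non-trivial eigenvectors of `(I - W)'(I - W)`.
#' Deterministic: eigenvectors are ordered by eigenvalue and signed so
#' that their largest-magnitude loading is positive.
#'
#' The embedding is checked for effective dimensionality: on very thin
#' (quasi-1D) clouds with sparse sampling, the second embedding
#' coordinate degenerates into a function of the first (a harmonic along
#' the dominant dimension) instead of an independent direction — the
#' known failure mode of manifold learning on thinly stretched
#' ellipsoids. This is detected by regressing the second coordinate
#' smoothly on the first and raising a dimensionality error when it
#' explains almost all variance.
#'
#' @param points3d n x 3 matrix of points.
#' @param k neighbours for the reconstruction weights (default 12).
#' @param reg regularization for the local Gram matrices, relative to
#'   their trace.
#' @param dim_check if `TRUE` (default) raise the dimensionality error.
#' @return An `embedding2d` object: `coords` (n x 2), `k`, `method`.
#' @export
lle_embed <- function(points3d, k = 12L, reg = 1e-3, dim_check = TRUE) {
  X <- as_point_matrix(points3d)
  n <- nrow(X)
  if (k < 3L) stop("k must be at least 3")
  if (n < 5L * k) stop("too few points for a stable embedding (need >= 5k)")
  nn <- knn_search(X, k)
  i_all <- rep(seq_len(n), each = k)
  j_all <- as.vector(t(nn$idx))
  # a disconnected neighbourhood graph inflates the null space of the
  # LLE problem (one affine family per component): the embedding is then
  # degenerate, which the metric rank check downstream diagnoses
  gconn <- igraph::graph_from_edgelist(cbind(i_all, j_all),
                                       directed = FALSE)
  comp <- igraph::components(gconn)
  if (comp$no > 1L)
    warning("LLE neighbour graph is disconnected (component sizes: ",
            paste(sort(comp$csize, decreasing = TRUE), collapse = ", "),
            "); the embedding is unreliable at this sampling density")
  w_all <- numeric(n * k)
  for (i in seq_len(n)) {
    Z <- sweep(X[nn$idx[i, ], , drop = FALSE], 2L, X[i, ])
    G <- Z %*% t(Z)
    G <- G + diag(k) * (reg * sum(diag(G)) / k + 1e-12)
    w <- solve(G, rep(1, k))
    w_all[((i - 1L) * k + 1L):(i * k)] <- w / sum(w)
  }
  Wm <- Matrix::sparseMatrix(i = i_all, j = j_all, x = w_all,
                             dims = c(n, n))
  IW <- Matrix::Diagonal(n) - Wm
  M <- Matrix::crossprod(IW)
  ev <- smallest_eigenvectors(M, 3L)
  Y <- ev$vectors[, 2:3, drop = FALSE] * sqrt(n)
  for (jj in 1:2) {
    imax <- which.max(abs(Y[, jj]))
    if (Y[imax, jj] < 0) Y[, jj] <- -Y[, jj]
  }
  if (dim_check) {
    r2 <- dimensionality_r2(Y)
    if (r2 > 0.999)
      stop("embedding is effectively one-dimensional (R^2 = ",
           signif(r2, 4), "): the second coordinate is a function of ",
           "the first. The data are too sparse to resolve the second ",
           "dimension (thin-surface failure mode); add data or reduce k.")
  }
  structure(list(coords = Y, k = k, method = "lle",
                 eigenvalues = ev$values),
            class = "embedding2d")
}

# R^2 of a smooth regression of the second embedding coordinate on the
# first; near 1 means the embedding collapsed to a curve.
dimensionality_r2 <- function(Y) {
  o <- order(Y[, 1L])
  fit <- tryCatch(stats::smooth.spline(Y[o, 1L], Y[o, 2L], df = 10),
                  error = function(e) NULL)
  if (is.null(fit)) return(0)
  pred <- stats::predict(fit, Y[, 1L])$y
  1 - stats::var(Y[, 2L] - pred) / stats::var(Y[, 2L])
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d:%s> %d points, k=%d\n", x$method,
              nrow(x$coords), x$k))
  invisible(x)
}

#' Per-point metric field of a 2D embedding
#'
#' Estimates the position-dependent 2x2 metric tensor `g(i)` that the
#' embedding pulls back from the data surface. The dual (co-)metric is
#' obtained by applying the Laplace–Beltrami estimator to products of the
#' embedding coordinate functions,
#' `h^kl = -1/2 ( L(f_k f_l) - f_k L f_l - f_l L f_k )`,
#' (with the positive-semidefinite sign convention of
#' [graph_laplacian()]), symmetrized, and inverted pointwise with an
#' eigenvalue floor; `g` is the pseudo-inverse of `h`. Lengths and angles
#' measured with `g` are those of the underlying surface, independently
#' of how the embedding stretches or shears.
#'
#' @param e an `embedding2d` (or any n x 2 coordinate matrix).
#' @param L operator from [graph_laplacian()] over the same points.
#' @param track_id,t optional point keys (track id and frame) enabling
#'   metric lookup by step in [bias_angles()] / [persistence_angles()].
#' @param boundary optional logical vector flagging boundary points
#'   (estimated from neighbourhood asymmetry by [manifold_learn()]).
#' @param floor_rel relative eigenvalue floor for the pseudo-inverse.
#' @param calibrate optional n x 3 matrix of the original 3D points. The
#'   same estimator applied to the 3D coordinate functions must return a
#'   co-metric of trace 2 (the manifold dimension); the per-point factor
#'   that enforces this calibrates away the second-moment deficit of the
#'   truncated kernel (and most boundary deficit). Strongly recommended.
#' @param smooth_passes number of neighbourhood-averaging passes applied
#'   to the co-metric field before inversion. The pointwise estimator is
#'   noisy (it is a local weighted covariance); since the true field is
#'   smooth, local averaging trades negligible bias for a large variance
#'   reduction.
#' @return A `metric_field` object: `g` (n x 3 matrix of g11, g12, g22),
#'   `h` (same layout), `rank` (per-point rank used), `key`, `boundary`.
#' @export
estimate_metric <- function(e, L, track_id = NULL, t = NULL,
                            boundary = NULL, floor_rel = 1e-8,
                            calibrate = NULL, smooth_passes = 2L) {
  Y <- if (inherits(e, "embedding2d")) e$coords else as.matrix(e)
  stopifnot(ncol(Y) == 2L, nrow(Y) == nrow(L))
  f1 <- Y[, 1L]; f2 <- Y[, 2L]
  co_h <- function(fa, fb) {
    -0.5 * (as.vector(L %*% (fa * fb)) - fa * as.vector(L %*% fb) -
              fb * as.vector(L %*% fa))
  }
  h11 <- co_h(f1, f1); h22 <- co_h(f2, f2); h12 <- co_h(f1, f2)
  if (!is.null(calibrate)) {
    X3 <- as_point_matrix(calibrate)
    stopifnot(nrow(X3) == nrow(Y))
    tr3 <- co_h(X3[, 1L], X3[, 1L]) + co_h(X3[, 2L], X3[, 2L]) +
      co_h(X3[, 3L], X3[, 3L])
    fac <- 2 / pmax(tr3, 1e-12 * stats::median(abs(tr3)))
    h11 <- h11 * fac; h22 <- h22 * fac; h12 <- h12 * fac
  }
  if (smooth_passes > 0L) {
    A <- methods::as(methods::as(L != 0, "dMatrix"), "CsparseMatrix")
    A <- A / Matrix::rowSums(A)
    for (pass in seq_len(smooth_passes)) {
      h11 <- as.vector(A %*% h11)
      h22 <- as.vector(A %*% h22)
      h12 <- as.vector(A %*% h12)
    }
  }
  n <- length(f1)
  # vectorized 2x2 spectral pseudo-inverse with eigenvalue floor
  tr <- h11 + h22
  dt <- h11 * h22 - h12^2
  disc <- sqrt(pmax(0, tr^2 - 4 * dt))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  floor_i <- floor_rel * pmax(abs(tr), 1e-300)
  # eigenvector for l1: (h12, l1 - h11), fallback to axis for diagonal h
  vx <- ifelse(abs(h12) > 1e-300, h12, ifelse(h11 >= h22, 1, 0))
  vy <- ifelse(abs(h12) > 1e-300, l1 - h11, ifelse(h11 >= h22, 0, 1))
  nv <- sqrt(vx^2 + vy^2); vx <- vx / nv; vy <- vy / nv
  k1 <- ifelse(l1 > floor_i, 1 / l1, 0)
  k2 <- ifelse(l2 > floor_i, 1 / l2, 0)
  rk <- as.integer((l1 > floor_i) + (l2 > floor_i))
  g <- cbind(k1 * vx^2 + k2 * vy^2,
             (k1 - k2) * vx * vy,
             k1 * vy^2 + k2 * vx^2)
  colnames(g) <- NULL
  neg_frac <- mean(l2 < -0.05 * pmax(l1, 1e-300))
  if (neg_frac > 0.05)
    warning(sprintf(paste0("co-metric indefinite at %.1f%% of points; ",
                           "the bandwidth is likely unsuitable"),
                    100 * neg_frac))
  key <- if (!is.null(track_id)) paste(track_id, t, sep = "\r") else NULL
  structure(list(g = g, h = cbind(h11, h12, h22), rank = rk,
                 rank_ratio = l2 / pmax(l1, 1e-300), key = key,
                 boundary = boundary),
            class = "metric_field")
}

#' @export
print.metric_field <- function(x, ...) {
  cat(sprintf("<metric_field> %d points, full rank at %.1f%%%s\n",
              nrow(x$g), 100 * mean(x$rank == 2L),
              if (!is.null(x$boundary))
                sprintf(", %.1f%% boundary", 100 * mean(x$boundary))
              else ""))
  invisible(x)
}

#' Metric inner products, norms and angles
#'
#' `riemannian_inner(u, v, g) = u' g v`; the angle is signed, with the
#' orientation form `sqrt(det g) (u1 v2 - u2 v1)` as the sine component,
#' so it reduces to the usual counterclockwise Euclidean angle for
#' `g = I`.
#'
#' @param u,v 2-vectors (or n x 2 matrices).
#' @param g 2x2 symmetric PSD matrix, or a vector `(g11, g12, g22)`, or
#'   an n x 3 matrix of such rows.
#' @return numeric vector.
#' @export
riemannian_inner <- function(u, v, g) {
  u <- two_col(u); v <- two_col(v); g <- g_rows(g, nrow(u))
  g[, 1L] * u[, 1L] * v[, 1L] +
    g[, 2L] * (u[, 1L] * v[, 2L] + u[, 2L] * v[, 1L]) +
    g[, 3L] * u[, 2L] * v[, 2L]
}

#' @rdname riemannian_inner
#' @export
riemannian_norm <- function(u, g) sqrt(pmax(0, riemannian_inner(u, u, g)))

#' @rdname riemannian_inner
#' @export
riemannian_angle <- function(u, v, g) {
  u <- two_col(u); v <- two_col(v); gr <- g_rows(g, nrow(u))
  nu <- riemannian_norm(u, gr); nv <- riemannian_norm(v, gr)
  if (any(nu == 0 | nv == 0)) stop("angle undefined for zero-norm vector")
  signed_angle(u, v, gr)
}

two_col <- function(u) if (is.null(dim(u))) matrix(u, ncol = 2L) else
  as.matrix(u)

g_rows <- function(g, n) {
  if (is.matrix(g) && all(dim(g) == c(2L, 2L)))
    g <- c(g[1L, 1L], g[1L, 2L], g[2L, 2L])
  if (is.null(dim(g))) g <- matrix(g, n, 3L, byrow = TRUE)
  stopifnot(ncol(g) == 3L)
  g
}

#' Metric manifold learning of a track set
#'
#' The full pipeline of the second reconstruction method: embed all track
#' points (plus optional extra points such as the attractant position)
#' with locally linear embedding, build the density-renormalized graph
#' Laplacian, and estimate the per-point metric field. The returned
#' tracks carry `method_tag = "manifold"`; downstream angle statistics
#' use the metric at each step's origin (pass `$metric`), or none for the
#' "Euclidean manifold learning" baseline that the metric method is
#' compared against.
#'
#' @param ts a [tracks3d()] object.
#' @param k_embed neighbours for LLE.
#' @param k_graph neighbours for the Laplacian graph.
#' @param bandwidth kernel bandwidth (default [default_bandwidth()]).
#' @param extra_points optional m x 3 matrix of additional points mapped
#'   through the same embedding (appended to the cloud).
#' @param dim_check passed to [lle_embed()].
#' @return An object of class `manifold_map`: `tracks` ([tracks2d()]),
#'   `metric` ([estimate_metric()] field over the track points),
#'   `embedding`, `graph`, `extra_uv` (chart coordinates of
#'   `extra_points`), `boundary` (logical per track point).
#' @examples
#' sim <- simulate_preset("plane", "brownian", 10, 60, seed = 3)
#' mm <- manifold_learn(sim$tracks)
#' mm$tracks
#' @export
manifold_learn <- function(ts, k_embed = 12L, k_graph = 30L,
                           bandwidth = NULL, extra_points = NULL,
                           dim_check = TRUE) {
  stopifnot(inherits(ts, "tracks3d"))
  P <- coord_matrix(ts)
  n <- nrow(P)
  X <- if (is.null(extra_points)) P else rbind(P, as_point_matrix(extra_points))
  # connectivity is gated by the wider Laplacian graph: data that cannot
  # form one connected chart stop here with the component sizes
  gr <- build_graph(X, k = k_graph, bandwidth = bandwidth)
  emb <- lle_embed(X, k = k_embed, dim_check = dim_check)
  L <- graph_laplacian(gr)
  # boundary points: neighbourhood centroid displaced by more than half
  # the rms neighbour distance (interior neighbourhoods are balanced)
  ctr_off <- vapply(seq_len(nrow(X)), function(i) {
    nb <- emb$coords[gr$knn$idx[i, ], , drop = FALSE]
    off <- colMeans(nb) - emb$coords[i, ]
    sqrt(sum(off^2)) / sqrt(mean(rowSums(sweep(nb, 2L,
      emb$coords[i, ])^2)))
  }, numeric(1))
  boundary <- ctr_off > 0.5
  met <- estimate_metric(emb, L, track_id = ts$track_id, t = ts$t,
                         boundary = boundary[seq_len(n)], calibrate = X)
  # collapsed embeddings (the thin-surface failure mode) show up as a
  # rank-1 co-metric: the two coordinate functions have parallel
  # gradients almost everywhere
  if (dim_check && stats::median(met$rank_ratio) < 1e-3)
    stop("embedding is effectively one-dimensional: the estimated ",
         "co-metric is rank-deficient at most points (median eigenvalue ",
         "ratio ", signif(stats::median(met$rank_ratio), 2), "). The ",
         "data are too sparse to resolve the second dimension of a thin ",
         "surface; add tracks or steps.")
  met$g <- met$g[seq_len(n), , drop = FALSE]
  met$h <- met$h[seq_len(n), , drop = FALSE]
  met$rank <- met$rank[seq_len(n)]
  met$rank_ratio <- met$rank_ratio[seq_len(n)]
  tr <- tracks2d(ts$track_id, ts$t, emb$coords[seq_len(n), 1L],
                 emb$coords[seq_len(n), 2L], method_tag = "manifold",
                 dt = attr(ts, "dt"))
  extra_uv <- if (is.null(extra_points)) NULL else
    emb$coords[-seq_len(n), , drop = FALSE]
  structure(list(tracks = tr, metric = met, embedding = emb, graph = gr,
                 laplacian = L, extra_uv = extra_uv,
                 boundary = boundary[seq_len(n)]),
            class = "manifold_map")
}

#' @export
print.manifold_map <- function(x, ...) {
  cat(sprintf("<manifold_map> %d points, k_embed=%d, bandwidth=%.4g\n",
              nrow(x$tracks), x$embedding$k, x$graph$bandwidth))
  print(x$metric)
  invisible(x)
}

#' @export
plot.manifold_map <- function(x, ...) {
  plot(x$tracks, main = "metric manifold embedding", ...)
  invisible(x)
}
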