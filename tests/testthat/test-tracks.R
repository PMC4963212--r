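test_that("csv round trip is the identity on the data model", {
  sim <- simulate_preset("cylinder", "brownian", 4, 30, seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, p)
  back <- read_tracks(p)
  expect_identical(back$track_id, sim$tracks$track_id)
  expect_identical(back$t, sim$tracks$t)
  # full-precision printing round-trips bit-identically
  expect_identical(back$x, sim$tracks$x)
  expect_identical(back$y, sim$tracks$y)
  expect_identical(back$z, sim$tracks$z)
})

test_that("reader validates input and reports dropped rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,t,x,y,z", "a,0,0,0,0", "a,0,1,1,1"), p)
  expect_error(read_tracks(p), "duplicate.*\\(a, 0\\)")
  writeLines(c("track_id,t,x,y", "a,0,0,0"), p)
  expect_error(read_tracks(p), "missing required column 'z'")
  writeLines("track_id,t,x,y,z", p)
  expect_error(read_tracks(p), "empty")
  writeLines(c("id,frame,posx,posy,posz", "a,0,0,0,0", "a,1,1,NA,0",
               "a,2,2,0,0"), p)
  expect_message(
    ts <- read_tracks(p, columns = c(track_id = "id", t = "frame",
                                     x = "posx", y = "posy", z = "posz")),
    "1 row")
  expect_equal(nrow(ts), 2L)
  expect_error(write_tracks(ts[0, ], p), "empty")
})

test_that("2D sets carry their producing method through csv", {
  ts <- tracks2d(c("a", "a"), 0:1, c(0, 1), c(0, 2), method_tag = "unwrap")
  p <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, p)
  expect_match(readLines(p, n = 1L), "method_tag: unwrap")
  expect_equal(length(strsplit(readLines(p)[2L], ",")[[1L]]), 4L)
})

test_that("step decomposition follows the frame-gap rule", {
  ts <- toy_tracks()
  st <- steps(ts)
  # n tracks of length L give sum(L - 1) steps
  expect_equal(nrow(st), (3L - 1L) + (4L - 1L))
  expect_equal(st$dx[st$track_id == "a"], c(1, 0))
  expect_equal(st$dy[st$track_id == "a"], c(0, 1))
  # a gap produces no step unless bridging is requested
  g <- tracks3d(rep("a", 3L), c(0L, 1L, 3L), c(0, 1, 5), 0, 0)
  expect_equal(nrow(steps(g)), 1L)
  expect_equal(steps(g)$dx, 1)
  st2 <- steps(g, gap = 1)
  expect_equal(nrow(st2), 2L)
  expect_equal(st2$dx, c(1, 4))
})

test_that("steps are invariant under input row permutation", {
  sim <- simulate_preset("plane", "brownian", 3, 20, seed = 5)
  df <- as.data.frame(sim$tracks)
  set.seed(1)
  shuf <- df[sample.int(nrow(df)), ]
  ts2 <- tracks3d(shuf$track_id, shuf$t, shuf$x, shuf$y, shuf$z)
  expect_equal(steps(ts2), steps(sim$tracks))
})

test_that("projections are linear: they commute with steps", {
  sim <- simulate_preset("hemisphere", "brownian", 3, 25, seed = 4)
  st3 <- steps(sim$tracks)
  for (f in list(project_xy, project_pca)) {
    ts2 <- f(sim$tracks)
    st2 <- steps(ts2)
    expect_equal(nrow(st2), nrow(st3)) # step count conserved
    if (identical(f, project_xy)) {
      expect_equal(st2$du, st3$dx)
      expect_equal(st2$dv, st3$dy)
    }
  }
})

test_that("xy projection drops z; pca recovers flat geometry", {
  ts <- toy_tracks()
  pxy <- project_xy(ts)
  expect_equal(as.numeric(as.data.frame(pxy)[1L, c("u", "v")]), c(0, 0))
  expect_equal(pxy$u, ts$x)
  expect_equal(pxy$v, ts$y)
  # tilted plane: pairwise distances preserved by pca
  set.seed(2)
  x <- runif(40, -1, 1); y <- runif(40, -1, 1)
  tp <- tracks3d("a", seq_len(40L), x, y, 0.7 * x - 0.3 * y)
  pc <- project_pca(tp)
  d3 <- dist(cbind(x, y, 0.7 * x - 0.3 * y))
  d2 <- dist(cbind(pc$u, pc$v))
  expect_lt(max(abs(d3 - d2)), 1e-10)
  # already-2D data: identity up to rotation/reflection
  fl <- tracks3d("a", seq_len(40L), x, y, 0)
  pf <- project_pca(fl)
  expect_lt(max(abs(dist(cbind(x, y)) - dist(cbind(pf$u, pf$v)))), 1e-10)
  # collinear data has no 2D projection
  co <- tracks3d("a", 1:5, 1:5, 2 * (1:5), 3 * (1:5))
  expect_error(project_pca(co), "collinear")
})

test_that("track validation rejects malformed input", {
  expect_error(tracks3d("a", c(0, 0), c(1, 2), 0, 0), "duplicate")
  expect_error(tracks3d("a", 0:1, c(1, NA), 0, 0), "non-finite")
})
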