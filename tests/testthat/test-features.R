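# independent batch recomputation of the DMA/DMH recursions
batch_maps <- function(patches, tau, delta) {
  H <- nrow(patches[[1]]); W <- ncol(patches[[1]])
  dma <- matrix(0, H, W); dmh <- matrix(0, H, W)
  for (t in seq_along(patches)) {
    p <- patches[[t]]
    for (i in 1:H) for (j in 1:W) {
      if (p[i, j] > 0) {
        dma[i, j] <- if (dma[i, j] == 0) p[i, j] else min(dma[i, j], p[i, j])
      }
      if (t > 1) {
        moved <- abs(p[i, j] - patches[[t - 1]][i, j]) > delta
        dmh[i, j] <- if (moved) tau else max(dmh[i, j] - 1, 0)
      }
    }
  }
  list(dma = dma, dmh = dmh)
}

run_maps <- function(patches, tau = 30, delta = 0.01) {
  maps <- action_maps(nrow(patches[[1]]), ncol(patches[[1]]),
                      tau = tau, delta = delta)
  prev <- NULL
  for (p in patches) {
    maps <- update_dma(maps, p)
    if (!is.null(prev)) maps <- update_dmh(maps, p, prev)
    prev <- p
  }
  maps
}

test_that("silhouette normalization centres the blob and is translation invariant", {
  frame <- matrix(0, 180, 320)
  frame[60:109, 100:129] <- 2.2                    # 50 x 30 blob
  mask <- frame > 0
  patch <- normalize_silhouette(frame, mask)
  expect_equal(dim(patch), c(176, 256))
  w <- which(patch > 0, arr.ind = TRUE)
  expect_lt(abs(mean(w[, 1]) - 88.5), 1.5)
  expect_lt(abs(mean(w[, 2]) - 128.5), 1.5)

  frame2 <- matrix(0, 180, 320)
  frame2[20:69, 200:229] <- 2.2                    # same blob elsewhere
  expect_equal(normalize_silhouette(frame2, frame2 > 0), patch)

  # canvas-sized blob is copied unscaled
  full <- matrix(1.5, 176, 256)
  expect_equal(normalize_silhouette(full, full > 0), full)
  expect_error(normalize_silhouette(frame, matrix(FALSE, 180, 320)),
               "empty blob")
})

test_that("oversized blobs are isotropically downscaled to fit", {
  frame <- matrix(0, 400, 400)
  frame[1:300, 1:100] <- 3
  patch <- normalize_silhouette(frame, frame > 0)
  w <- which(patch > 0, arr.ind = TRUE)
  h_px <- diff(range(w[, 1])) + 1
  w_px <- diff(range(w[, 2])) + 1
  expect_lte(h_px, 176)
  expect_equal(h_px / w_px, 3, tolerance = 0.05)
})

test_that("the appearance template keeps the running depth minimum", {
  maps <- action_maps(4, 4, tau = 10, delta = 0.01)
  p1 <- matrix(2.0, 4, 4)
  maps <- update_dma(maps, p1)
  expect_equal(maps$dma, p1)                       # first branch from zero
  p2 <- matrix(1.5, 4, 4); p2[1, 1] <- 2.5
  maps <- update_dma(maps, p2)
  expect_equal(maps$dma[2, 2], 1.5)                # min branch
  expect_equal(maps$dma[1, 1], 2.0)
  # padding pixels leave the template unchanged
  p3 <- matrix(0, 4, 4)
  expect_equal(update_dma(maps, p3)$dma, maps$dma)
  # idempotence under identical patches
  expect_equal(update_dma(update_dma(maps, p2), p2)$dma,
               update_dma(maps, p2)$dma)
})

test_that("the history template resets on motion and decays otherwise", {
  maps <- action_maps(3, 3, tau = 30, delta = 0.01)
  still <- matrix(2, 3, 3)
  moved <- still; moved[2, 2] <- 2.02              # 0.02 > delta
  maps <- update_dmh(maps, moved, still)
  expect_equal(maps$dmh[2, 2], 30)
  expect_equal(maps$dmh[1, 1], 0)
  maps <- update_dmh(maps, moved, moved)           # static frame
  expect_equal(maps$dmh[2, 2], 29)
})

test_that("incremental DMA/DMH equals batch recomputation on random sequences", {
  set.seed(21)
  for (rep in 1:25) {
    patches <- lapply(1:10, function(t) {
      p <- matrix(runif(256, 1, 3), 16, 16)
      p[runif(256) < 0.3] <- 0
      p
    })
    inc <- run_maps(patches, tau = 7, delta = 0.05)
    ref <- batch_maps(patches, tau = 7, delta = 0.05)
    expect_equal(inc$dma, ref$dma)
    expect_equal(inc$dmh, ref$dmh)
    expect_true(all(inc$dmh >= 0 & inc$dmh <= 7))
  }
})

test_that("the HOG descriptor has the documented layout and flat-field zero", {
  desc <- hog_descriptor(matrix(rnorm(176 * 256), 176, 256))
  expect_length(desc, 1584)
  expect_length(fuse_features(desc, desc), 3168)
  expect_equal(hog_descriptor(matrix(4, 176, 256)), rep(0, 1584))
  expect_error(hog_descriptor(matrix(0, 100, 100)), "cell")
})

test_that("a vertical step edge concentrates energy in the horizontal-gradient bin", {
  m <- cbind(matrix(1, 32, 32), matrix(3, 32, 32))
  desc <- hog_descriptor(m, cell = 16, bins = 9)
  cells <- matrix(desc, nrow = 9)                  # bins x (2 x 4 cells)
  # edge runs between cell columns 2 and 3; gradient is purely horizontal,
  # an unsigned orientation of 0 -> first bin
  energy <- colSums(cells)
  edge_cells <- c(2, 3, 6, 7)                      # row-major cell ids
  expect_true(all(energy[edge_cells] > 0))
  expect_equal(colSums(cells[2:9, , drop = FALSE])[edge_cells], rep(0, 4))
})

test_that("HOG matches an independent per-cell histogram oracle", {
  set.seed(22)
  m <- matrix(runif(32 * 48, 0, 3), 32, 48)
  desc <- hog_descriptor(m, cell = 16, bins = 9)

  H <- 32; W <- 48; bins <- 9
  ref <- numeric((H / 16) * (W / 16) * bins)
  for (i in 1:H) for (j in 1:W) {
    gx <- (m[i, min(j + 1, W)] - m[i, max(j - 1, 1)]) / 2
    gy <- (m[min(i + 1, H), j] - m[max(i - 1, 1), j]) / 2
    mag <- sqrt(gx^2 + gy^2)
    ang <- atan2(gy, gx) %% pi
    b <- min(floor(ang / (pi / bins)), bins - 1)
    cell <- ((i - 1) %/% 16) * (W / 16) + (j - 1) %/% 16
    slot <- cell * bins + b + 1
    ref[slot] <- ref[slot] + mag
  }
  refm <- matrix(ref, nrow = bins)
  refm <- sweep(refm, 2, sqrt(colSums(refm^2) + 1e-12), `/`)
  expect_equal(desc, as.vector(refm), tolerance = 1e-6)
})

test_that("feature fusion keeps the DMA half first", {
  a <- runif(1584); b <- runif(1584)
  fused <- fuse_features(a, b)
  expect_identical(fused[1:1584], a)
  expect_identical(fused[1585:3168], b)
  expect_equal(fuse_features(rep(0, 10), rep(0, 10)), rep(0, 20))
  expect_error(fuse_features(a, b[-1]), "lengths differ")
})

test_that("pinhole back-projection follows the linear model", {
  K <- camera_intrinsics(focal_length = 160, baseline = 0.05,
                         cx = 160.5, cy = 90.5)
  expect_equal(unname(pixel_to_camera(160.5, 90.5, 2, K)[1, 1:2]), c(0, 0))
  expect_equal(unname(pixel_to_camera(160.5 + 160, 90.5, 2, K)[1, "X"]), 2)
  p1 <- pixel_to_camera(200, 120, 1.5, K)
  p2 <- pixel_to_camera(200, 120, 3.0, K)
  expect_equal(2 * p1[1, 1:2], p2[1, 1:2])
  expect_error(pixel_to_camera(10, 10, 0, K), "positive")
})

test_that("plane fitting is exact on exact data and rejects degenerate input", {
  K <- camera_intrinsics()
  set.seed(23)
  x <- runif(50, 1, 320); y <- runif(50, 1, 180)
  plane <- fit_floor_plane(x, y, rep(2, 50), K)     # all points on Z = 2
  expect_equal(unname(plane[1:4]), c(0, 0, 1, -2), tolerance = 1e-9)

  # three non-collinear points interpolate exactly
  p3 <- fit_floor_plane(c(10, 300, 150), c(20, 40, 170), c(2, 3, 4), K)
  pts <- pixel_to_camera(c(10, 300, 150), c(20, 40, 170), c(2, 3, 4), K)
  expect_equal(unname(centroid_floor_distance(pts, p3)), rep(0, 3),
               tolerance = 1e-9)

  expect_error(fit_floor_plane(c(1, 2), c(1, 2), c(1, 1), K), "3 floor points")
  expect_error(fit_floor_plane(c(100, 100, 100), c(20, 20, 20), c(2, 2, 2), K),
               "collinear")
})

test_that("plane parameters recover from noisy samples of a tilted plane", {
  K <- camera_intrinsics()
  n_true <- c(0, cos(25 * pi / 180), sin(25 * pi / 180))
  d_true <- -2.1
  set.seed(24)
  x <- runif(500, 1, 320); y <- runif(500, 120, 180)
  # depth solving n . P + d = 0 for points along each pixel ray
  Z <- -d_true / (n_true[1] * (x - K$cx) / K$focal_length +
                  n_true[2] * (y - K$cy) / K$focal_length + n_true[3])
  plane <- fit_floor_plane(x, y, Z + rnorm(500, 0, 0.01), K)
  ang <- acos(pmin(abs(sum(plane[1:3] * n_true)), 1)) * 180 / pi
  expect_lt(ang, 1)
  expect_lt(abs(abs(plane[4]) - abs(d_true)), 0.02)
})

test_that("point-plane distance matches the closed formula with sign", {
  plane <- structure(c(0, 0, 1, 0), class = "floor_plane")
  expect_equal(centroid_floor_distance(c(0.3, -0.2, 1.5), plane), 1.5)

  set.seed(25)
  for (k in 1:30) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    if (n[3] < 0) n <- -n
    d <- runif(1, -3, 3)
    p <- rnorm(3) * 2
    plane <- structure(c(n, d), class = "floor_plane")
    raw <- (sum(n * p) + d) / sqrt(sum(n^2))
    expected <- raw * (if (d < 0) -1 else 1)
    expect_equal(centroid_floor_distance(p, plane), expected)
    expect_equal(abs(centroid_floor_distance(p, plane)),
                 abs(sum(n * p) + d) / sqrt(sum(n^2)))
  }
})
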