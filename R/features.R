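#' Normalize a person silhouette to a fixed canvas
#'
#' Crops the blob's bounding box out of the depth frame (non-blob pixels
#' zeroed), downscales isotropically only when the box exceeds the canvas,
#' and pastes it so the blob centroid sits at the canvas centre (clamped so
#' the crop stays inside).  The result is translation invariant: the same
#' blob anywhere in the frame yields the same patch.
#'
#' @param frame Depth matrix.
#' @param blob_mask Logical matrix or integer pixel indices of the blob.
#' @param canvas `c(height, width)` of the output patch (default 176x256).
#' @return Numeric matrix of the canvas size; non-person pixels are 0.
#' @export
normalize_silhouette <- function(frame, blob_mask, canvas = c(176, 256)) {
  idx <- if (is.logical(blob_mask)) which(blob_mask) else as.integer(blob_mask)
  if (length(idx) == 0) stop("empty blob")
  H <- nrow(frame)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  rr <- range(rows); cr <- range(cols)
  crop <- matrix(0, rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L)
  crop[cbind(rows - rr[1] + 1L, cols - cr[1] + 1L)] <- frame[idx]
  # isotropic downscale (nearest neighbour) only when too large
  sc <- min(1, canvas[1] / nrow(crop), canvas[2] / ncol(crop))
  if (sc < 1) {
    nr <- max(1L, floor(nrow(crop) * sc))
    nc <- max(1L, floor(ncol(crop) * sc))
    crop <- crop[ceiling(seq_len(nr) / sc - 1e-9),
                 ceiling(seq_len(nc) / sc - 1e-9), drop = FALSE]
  }
  # paste so the blob centroid lands at the canvas centre
  w <- crop > 0
  if (!any(w)) w[] <- TRUE
  cen_r <- mean(((which(w) - 1L) %% nrow(crop)) + 1L)
  cen_c <- mean(((which(w) - 1L) %/% nrow(crop)) + 1L)
  off_r <- round((canvas[1] + 1) / 2 - cen_r)
  off_c <- round((canvas[2] + 1) / 2 - cen_c)
  off_r <- min(max(off_r, 0L), canvas[1] - nrow(crop))
  off_c <- min(max(off_c, 0L), canvas[2] - ncol(crop))
  patch <- matrix(0, canvas[1], canvas[2])
  patch[off_r + seq_len(nrow(crop)), off_c + seq_len(ncol(crop))] <- crop
  patch
}

#' Action representation maps
#'
#' Container for the depth motion appearance (DMA) and depth motion history
#' (DMH) templates accumulated over a recognition window.  The DMA is the
#' pixel-wise running minimum of depth over the window (the envelope of the
#' motion volume); the DMH is a decaying time stamp, reset to `tau` when a
#' pixel's depth changes by more than `delta` between consecutive frames
#' and decremented towards 0 otherwise.
#'
#' @param height,width Template size in pixels.
#' @param tau History time window in frames.
#' @param delta Depth-change threshold in metres.
#' @return An object of class `action_maps` with zero-initialized `dma` and
#'   `dmh`.
#' @export
action_maps <- function(height = 176, width = 256, tau = 30, delta = 0.01) {
  stopifnot(tau >= 1, delta > 0)
  structure(list(dma = matrix(0, height, width),
                 dmh = matrix(0, height, width),
                 tau = tau, delta = delta, t = 0L),
            class = "action_maps")
}

#' Update the depth motion appearance template
#'
#' Per pixel: the first observed depth is kept, later frames take the
#' minimum of the stored and incoming depth.  Zero pixels of the incoming
#' patch (silhouette padding, not a nearer surface) leave the template
#' unchanged.
#'
#' @param maps An [action_maps()] object.
#' @param patch Normalized silhouette patch of the current frame.
#' @return The updated `action_maps`.
#' @export
update_dma <- function(maps, patch) {
  stopifnot(inherits(maps, "action_maps"),
            identical(dim(maps$dma), dim(patch)))
  dma <- maps$dma
  fresh <- dma == 0 & patch > 0
  both <- dma > 0 & patch > 0
  dma[fresh] <- patch[fresh]
  dma[both] <- pmin(dma[both], patch[both])
  maps$dma <- dma
  maps$t <- maps$t + 1L
  maps
}

#' Update the depth motion history template
#'
#' Per pixel: the history is reset to `tau` when the absolute depth change
#' between the consecutive patches exceeds `delta`, and decays by one frame
#' (floored at 0) otherwise.  Values therefore always lie in `[0, tau]`.
#'
#' @param maps An [action_maps()] object.
#' @param patch_t,patch_prev Normalized silhouette patches of the current
#'   and previous frame.
#' @return The updated `action_maps`.
#' @export
update_dmh <- function(maps, patch_t, patch_prev) {
  stopifnot(inherits(maps, "action_maps"),
            identical(dim(maps$dmh), dim(patch_t)),
            identical(dim(patch_t), dim(patch_prev)))
  moved <- abs(patch_t - patch_prev) > maps$delta
  maps$dmh <- ifelse(moved, maps$tau, pmax(maps$dmh - 1, 0))
  maps
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Gradients by centred differences (edge-replicated borders), unsigned
#' orientations over `[0, 180)` degrees binned into `bins` directions,
#' magnitude-weighted per-cell histograms over non-overlapping
#' `cell x cell` blocks, each cell L2-normalized on its own (1x1-cell
#' blocks) with a small epsilon guard.  A 176x256 input with 16-px cells
#' and 9 bins yields 11 x 16 x 9 = 1584 values, cells scanned row-major,
#' bins contiguous per cell.
#'
#' @param map_grid Numeric matrix whose dimensions are multiples of `cell`.
#' @param cell Cell size in pixels.
#' @param bins Number of orientation bins.
#' @param eps Normalization guard.
#' @return Numeric descriptor of length `(rows/cell) * (cols/cell) * bins`.
#' @export
hog_descriptor <- function(map_grid, cell = 16, bins = 9, eps = 1e-6) {
  H <- nrow(map_grid); W <- ncol(map_grid)
  if (H %% cell != 0 || W %% cell != 0)
    stop(sprintf("input %dx%d is not a multiple of the %d-px cell", H, W, cell))
  gx <- (shift_matrix(map_grid, 0, 1) - shift_matrix(map_grid, 0, -1)) / 2
  gy <- (shift_matrix(map_grid, 1, 0) - shift_matrix(map_grid, -1, 0)) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ang / (pi / bins)), bins - 1)
  n_cr <- H / cell; n_cc <- W / cell
  cell_r <- (matrix(seq_len(H), H, W) - 1L) %/% cell        # 0-based
  cell_c <- (matrix(seq_len(W), H, W, byrow = TRUE) - 1L) %/% cell
  cell_id <- cell_r * n_cc + cell_c                          # row-major cells
  slot <- cell_id * bins + bin + 1
  desc <- numeric(n_cr * n_cc * bins)
  acc <- rowsum(as.vector(mag), as.vector(slot))
  desc[as.integer(rownames(acc))] <- acc
  m <- matrix(desc, nrow = bins)                             # bins x cells
  norms <- sqrt(colSums(m^2) + eps^2)
  as.vector(sweep(m, 2, norms, `/`))
}

#' Fuse the two map descriptors
#'
#' Concatenates the DMA descriptor followed by the DMH descriptor into the
#' final feature vector (1584 + 1584 = 3168 with the default layout).
#'
#' @param hog_dma,hog_dmh Equal-length HOG descriptors.
#' @return Numeric vector of twice the input length.
#' @export
fuse_features <- function(hog_dma, hog_dmh) {
  if (length(hog_dma) != length(hog_dmh))
    stop("descriptor lengths differ")
  c(hog_dma, hog_dmh)
}

#' Feature vector of a whole short sequence
#'
#' Batch helper: accumulates DMA/DMH over a list of silhouette patches and
#' returns the fused HOG descriptor, exactly as the incremental updates
#' would.
#'
#' @param patches List of normalized silhouette patches.
#' @param config A [pipeline_config()].
#' @return Fused feature vector.
#' @export
sequence_feature <- function(patches, config = pipeline_config()) {
  stopifnot(length(patches) >= 1)
  maps <- action_maps(config$canvas[1], config$canvas[2],
                      tau = config$tau, delta = config$delta)
  prev <- NULL
  for (p in patches) {
    maps <- update_dma(maps, p)
    if (!is.null(prev)) maps <- update_dmh(maps, p, prev)
    prev <- p
  }
  fuse_features(
    hog_descriptor(maps$dma, config$hog_cell, config$hog_bins),
    hog_descriptor(maps$dmh, config$hog_cell, config$hog_bins))
}

#' Back-project a pixel into camera coordinates
#'
#' Pinhole model: `X = Z * (x - cx) / f`, `Y = Z * (y - cy) / f`.
#'
#' @param x,y Pixel coordinates (column, row), vectorized.
#' @param Z Depth along the optical axis in metres.
#' @param intrinsics A [camera_intrinsics()].
#' @return An `n x 3` matrix of `(X, Y, Z)` camera coordinates.
#' @export
pixel_to_camera <- function(x, y, Z, intrinsics = camera_intrinsics()) {
  if (any(Z <= 0)) stop("depth must be positive")
  cbind(X = Z * (x - intrinsics$cx) / intrinsics$focal_length,
        Y = Z * (y - intrinsics$cy) / intrinsics$focal_length,
        Z = Z)
}

#' Fit the floor plane by total least squares
#'
#' Back-projects the floor pixels into camera coordinates and fits the
#' plane `a X + b Y + c Z + d = 0` minimizing orthogonal distances (the
#' smallest-eigenvalue direction of the point covariance).  Coefficients
#' are unit-normalized with `c >= 0`.
#'
#' @param x,y Floor pixel coordinates (column, row).
#' @param depth Their depths in metres.
#' @param intrinsics A [camera_intrinsics()].
#' @return An object of class `floor_plane`: numeric `c(a, b, c, d)`.
#' @export
fit_floor_plane <- function(x, y, depth, intrinsics = camera_intrinsics()) {
  pts <- pixel_to_camera(x, y, depth, intrinsics)
  if (nrow(pts) < 3) stop("need at least 3 floor points")
  ctr <- colMeans(pts)
  cov <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  eig <- eigen(cov, symmetric = TRUE)
  if (eig$values[2] < 1e-12 * max(eig$values[1], 1))
    stop("floor points are collinear")
  n <- eig$vectors[, 3]
  d <- -sum(n * ctr)
  coef <- c(n, d)
  if (n[3] < 0 || (n[3] == 0 && (n[2] < 0 || (n[2] == 0 && n[1] < 0))))
    coef <- -coef
  structure(coef, class = "floor_plane")
}

#' @export
print.floor_plane <- function(x, ...) {
  cat(sprintf("<floor_plane> %.4f X + %.4f Y + %.4f Z + %.4f = 0\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}

#' Signed distance from a point to the floor plane
#'
#' Point-plane distance `(a X + b Y + c Z + d) / sqrt(a^2 + b^2 + c^2)`,
#' oriented so that points on the camera's side of the floor — above it —
#' are positive (the camera sits at the origin of camera coordinates).
#'
#' @param point Numeric `c(X, Y, Z)` (or an `n x 3` matrix) in camera
#'   coordinates.
#' @param plane A [fit_floor_plane()] result or any numeric `c(a, b, c, d)`.
#' @return Signed distance(s) in metres.
#' @export
centroid_floor_distance <- function(point, plane) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  val <- (p %*% plane[1:3] + plane[4]) / sqrt(sum(plane[1:3]^2))
  orient <- if (plane[4] < 0) -1 else 1   # sign at the camera origin
  drop(val * orient)
}
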