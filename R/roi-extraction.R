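#' Convert a depth frame to an integer disparity map
#'
#' Disparity is inversely proportional to depth:
#' `disparity = focal_length * baseline / depth`, rounded to integer levels
#' and clipped to `[0, n_levels - 1]`.  Hole pixels map to `NA` and are
#' excluded from all disparity histograms.
#'
#' @param frame Depth matrix in metres (0 = hole).
#' @param intrinsics A [camera_intrinsics()]; `baseline` here may be the
#'   pipeline's virtual stereo baseline.
#' @param n_levels Number of disparity levels.
#' @return Integer matrix of disparity levels with attribute `n_levels`.
#' @export
depth_to_disparity <- function(frame, intrinsics = camera_intrinsics(),
                               n_levels = 128) {
  stopifnot(is.matrix(frame), n_levels > 1)
  d <- matrix(NA_integer_, nrow(frame), ncol(frame))
  valid <- is.finite(frame) & frame > 0
  d[valid] <- as.integer(pmin(pmax(round(
    intrinsics$focal_length * intrinsics$baseline / frame[valid]), 0),
    n_levels - 1))
  attr(d, "n_levels") <- as.integer(n_levels)
  d
}

#' Build U- and V-disparity histogram maps
#'
#' The V-disparity map counts, for every image row, how many pixels carry
#' each disparity level (height = image height, width = `n_levels`); the
#' U-disparity map does the same per image column (height = `n_levels`,
#' width = image width).  Flat horizontal surfaces (the floor) collapse to
#' a slanted line in V-disparity; flat vertical surfaces (a curtain)
#' collapse to a line in U-disparity.
#'
#' @param dmap Disparity map from [depth_to_disparity()].
#' @return List with integer count matrices `v_map` and `u_map`.
#' @export
build_uv_disparity <- function(dmap) {
  n_levels <- attr(dmap, "n_levels")
  stopifnot(!is.null(n_levels))
  H <- nrow(dmap); W <- ncol(dmap)
  valid <- which(!is.na(dmap))
  d <- dmap[valid]
  rows <- (valid - 1L) %% H + 1L
  cols <- (valid - 1L) %/% H + 1L
  v_map <- matrix(0L, H, n_levels)
  u_map <- matrix(0L, n_levels, W)
  v_idx <- rows + H * d                 # column d + 1
  u_idx <- (d + 1L) + n_levels * (cols - 1L)
  v_tab <- tabulate(v_idx, nbins = H * n_levels)
  u_tab <- tabulate(u_idx, nbins = n_levels * W)
  v_map[] <- v_tab
  u_map[] <- u_tab
  list(v_map = v_map, u_map = u_map)
}

# Hough-style line detection on a set of (i, x) points: accumulates votes
# over a grid of slopes m (x = m * i + c) with unit intercept bins, each
# point voting with its histogram count (the UV-disparity maps are
# intensity images), then least-squares refits the inliers of the best
# cell (count-weighted).  Returns c(slope, intercept, votes) or NULL when
# no cell reaches min_votes.
hough_line <- function(i, x, m_range, n_m = 121, min_votes = 5, tol = 1,
                       w = NULL) {
  if (is.null(w)) w <- rep(1, length(i))
  if (sum(w) < min_votes) return(NULL)
  slopes <- seq(m_range[1], m_range[2], length.out = n_m)
  best <- c(votes = 0, m = NA, c = NA)
  for (m in slopes) {
    cc <- round(x - m * i)
    tab <- vapply(split(w, cc), sum, numeric(1))
    v <- max(tab)
    if (v > best["votes"]) {
      best <- c(votes = v, m = m,
                c = as.numeric(names(tab)[which.max(tab)]))
    }
  }
  if (best[["votes"]] < min_votes) return(NULL)
  resid <- x - (best[["m"]] * i + best[["c"]])
  inl <- abs(resid) <= tol
  if (sum(inl) >= 2 && length(unique(i[inl])) >= 2) {
    fit <- stats::lm.wfit(cbind(1, i[inl]), x[inl], w[inl])
    c(slope = fit$coefficients[[2]], intercept = fit$coefficients[[1]],
      votes = as.numeric(best[["votes"]]))
  } else {
    c(slope = best[["m"]], intercept = best[["c"]],
      votes = as.numeric(best[["votes"]]))
  }
}

#' Extract the floor region from the V-disparity map
#'
#' The floor plane projects to the ground correlation line of the
#' V-disparity map: disparity grows linearly towards the bottom image rows.
#' A Hough vote over the binarized V-disparity map finds the strongest line
#' whose slant lies in a plausible window, and every pixel whose disparity
#' sits within `line_tolerance` levels of the line at its row is labelled
#' floor.
#'
#' @param uv UV-disparity maps from [build_uv_disparity()].
#' @param dmap The disparity map the histograms were built from.
#' @param line_tolerance Disparity tolerance (levels) for floor membership.
#' @param binarize_count Minimum V-disparity count for a cell to vote.
#' @param min_votes Minimum Hough votes to accept the line.
#' @param angle_window Slant window in degrees from the horizontal of the
#'   (disparity, row) plot; the default 20-80 degrees accepts any
#'   plausibly tilted ground line while rejecting vertical walls.
#' @return List with `floor_mask` (logical matrix) and `floor_line`
#'   (`c(slope, intercept)` of disparity as a function of image row), or an
#'   empty mask and `NULL` line when no line is found.
#' @export
extract_floor <- function(uv, dmap, line_tolerance = 1, binarize_count = 5,
                          min_votes = 5, angle_window = c(20, 80)) {
  cells <- which(uv$v_map >= binarize_count, arr.ind = TRUE)
  empty <- list(floor_mask = matrix(FALSE, nrow(dmap), ncol(dmap)),
                floor_line = NULL)
  if (nrow(cells) == 0) {
    warning("no V-disparity cells above the vote threshold; empty floor mask")
    return(empty)
  }
  # slope window: d per row between cot(max angle) and cot(min angle)
  m_range <- rev(1 / tan(angle_window * pi / 180))
  line <- hough_line(cells[, 1], cells[, 2] - 1L, m_range,
                     min_votes = min_votes, tol = line_tolerance,
                     w = uv$v_map[cells])
  if (is.null(line) || line[["slope"]] < m_range[1] ||
      line[["slope"]] > m_range[2]) {
    warning("no ground correlation line found; empty floor mask")
    return(empty)
  }
  rows <- matrix(seq_len(nrow(dmap)), nrow(dmap), ncol(dmap))
  pred <- line[["slope"]] * rows + line[["intercept"]]
  mask <- !is.na(dmap) & abs(dmap - pred) <= line_tolerance
  list(floor_mask = mask,
       floor_line = c(slope = line[["slope"]],
                      intercept = line[["intercept"]]))
}

#' Extract the bed region from the floor-free disparity map
#'
#' With floor pixels removed, the bed is assumed to be the largest object:
#' connected-component labelling (8-neighbour) on the binarized V-disparity
#' map selects the component with the largest total pixel count, its four
#' extreme points (min/max image row, min/max disparity) are recorded, and
#' every remaining pixel inside that row and disparity window is a bed
#' candidate.  Because distant wall patches and nearer furniture can share
#' the bed's row/depth band, the candidates are component-labelled once
#' more in image space and the connected region with the largest
#' *physical* area is kept: pixel counts are weighted by squared depth
#' (1/disparity^2), so a nearby wheelchair that subtends many pixels does
#' not outrank the physically much larger bed.
#'
#' @param dmap Disparity map with floor pixels set to `NA`.
#' @param binarize_count Minimum V-disparity count for a cell to enter the
#'   component labelling; thin wall traces stay below it while bed rows
#'   concentrate dozens of pixels into few disparity levels.
#' @return List with `bed_mask` (logical) and `bed_extremes`
#'   (`c(row_min, row_max, disp_min, disp_max)`), empty when nothing
#'   remains.
#' @export
extract_bed <- function(dmap, binarize_count = 20) {
  n_levels <- attr(dmap, "n_levels")
  uv <- build_uv_disparity(dmap)
  bin <- uv$v_map >= binarize_count
  empty <- list(bed_mask = matrix(FALSE, nrow(dmap), ncol(dmap)),
                bed_extremes = NULL)
  if (!any(bin)) {
    warning("empty residual disparity map; no bed region")
    return(empty)
  }
  comp <- label_binary_components(bin)
  # weight each component by its total histogram mass, not cell count
  mass <- vapply(split(uv$v_map[bin], comp), sum, numeric(1))
  keep <- names(mass)[which.max(mass)]
  cells <- which(bin, arr.ind = TRUE)[comp == keep, , drop = FALSE]
  ext <- c(row_min = min(cells[, 1]), row_max = max(cells[, 1]),
           disp_min = min(cells[, 2]) - 1L, disp_max = max(cells[, 2]) - 1L)
  rows <- matrix(seq_len(nrow(dmap)), nrow(dmap), ncol(dmap))
  mask <- !is.na(dmap) &
    rows >= ext[["row_min"]] & rows <= ext[["row_max"]] &
    dmap >= ext[["disp_min"]] & dmap <= ext[["disp_max"]]
  mask[is.na(mask)] <- FALSE
  if (any(mask)) {
    comp <- label_binary_components(mask)
    # physical area ~ sum of squared depths ~ sum 1/d^2
    w <- 1 / pmax(dmap[mask], 1)^2
    areas <- vapply(split(w, comp), sum, numeric(1))
    keep <- which(mask)[comp == as.integer(names(areas)[which.max(areas)])]
    mask[] <- FALSE
    mask[keep] <- TRUE
  }
  list(bed_mask = mask, bed_extremes = ext)
}

# 8-connected component membership of TRUE cells of a logical matrix,
# returned as an integer vector aligned with which(mask).
label_binary_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(integer(0))
  H <- nrow(mask)
  rows <- (idx - 1L) %% H + 1L
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  edges <- NULL
  for (off in offsets) {
    nb <- idx + off[1] + off[2] * H
    ok <- rows + off[1] >= 1L & rows + off[1] <= H &
      nb >= 1L & nb <= length(mask)
    nb_pos <- match(nb[ok], idx)
    from <- which(ok)[!is.na(nb_pos)]
    to <- nb_pos[!is.na(nb_pos)]
    if (length(from)) edges <- rbind(edges, cbind(from, to))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(0), 0, 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(idx)]
}

#' Assemble the region map
#'
#' Combines the floor and bed masks into a per-pixel partition over
#' \{floor, bed, ignored\}; overlapping pixels resolve by precedence
#' floor > bed, every unassigned pixel is ignored.
#'
#' @param floor_mask,bed_mask Logical matrices of the same shape.
#' @param floor_line,bed_extremes Optional line/extreme-point metadata to
#'   carry along.
#' @return An object of class `region_map`: list with `labels` (character
#'   matrix over `"floor"`, `"bed"`, `"ignored"`) plus the metadata.
#' @export
build_region_map <- function(floor_mask, bed_mask,
                             floor_line = NULL, bed_extremes = NULL) {
  stopifnot(identical(dim(floor_mask), dim(bed_mask)))
  labels <- matrix("ignored", nrow(floor_mask), ncol(floor_mask))
  labels[bed_mask] <- "bed"
  labels[floor_mask] <- "floor"   # precedence: floor wins overlaps
  structure(list(labels = labels, floor_line = floor_line,
                 bed_extremes = bed_extremes),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  tab <- table(factor(x$labels, c("floor", "bed", "ignored")))
  cat(sprintf("<region_map> %dx%d px: %d floor, %d bed, %d ignored\n",
              nrow(x$labels), ncol(x$labels),
              tab[["floor"]], tab[["bed"]], tab[["ignored"]]))
  invisible(x)
}

#' Extract all regions of interest from a background frame
#'
#' Convenience wrapper running the whole chain: depth to disparity,
#' UV-disparity maps, ground-line floor extraction, bed extraction on the
#' floor-free map, and region-map assembly.  Far-flagged pixels are
#' excluded beforehand.
#'
#' @param background A [build_background()] model (or a plain depth matrix).
#' @param config A [pipeline_config()].
#' @return A `region_map` (see [build_region_map()]).
#' @export
extract_regions <- function(background, config = pipeline_config()) {
  frame <- if (inherits(background, "background_model"))
    background$average else background
  if (inherits(background, "background_model"))
    frame[background$far_mask] <- HOLE
  disp_K <- camera_intrinsics(
    focal_length = config$intrinsics$focal_length,
    baseline = config$disparity_baseline,
    cx = config$intrinsics$cx, cy = config$intrinsics$cy)
  dmap <- depth_to_disparity(frame, disp_K, config$n_levels)
  uv <- build_uv_disparity(dmap)
  fl <- extract_floor(uv, dmap, line_tolerance = config$line_tolerance,
                      binarize_count = config$binarize_count,
                      min_votes = config$hough_votes)
  dmap_nf <- dmap
  dmap_nf[fl$floor_mask] <- NA_integer_
  attr(dmap_nf, "n_levels") <- attr(dmap, "n_levels")
  bd <- extract_bed(dmap_nf, binarize_count = config$bed_binarize_count)
  build_region_map(fl$floor_mask, bd$bed_mask,
                   floor_line = fl$floor_line,
                   bed_extremes = bd$bed_extremes)
}

#' Locate a blob against the region map
#'
#' A person blob is "on the bed" when more than 70% of its pixels fall in
#' the bed region; failing that it is "on the floor" when more than 30%
#' fall in the floor region; otherwise its location is undetermined
#' (`"other"`).
#'
#' @param blob_mask Logical matrix (or integer pixel indices) of the blob.
#' @param regions A `region_map`.
#' @param bed_frac,floor_frac Decision thresholds.
#' @return `"bed"`, `"floor"` or `"other"`.
#' @export
localize_blob <- function(blob_mask, regions, bed_frac = 0.70,
                          floor_frac = 0.30) {
  idx <- if (is.logical(blob_mask)) which(blob_mask) else as.integer(blob_mask)
  if (length(idx) == 0) stop("empty blob")
  lab <- regions$labels[idx]
  if (mean(lab == "bed") > bed_frac) return("bed")
  if (mean(lab == "floor") > floor_frac) return("floor")
  "other"
}

#' Detect curtain pixels in a foreground frame
#'
#' A hanging curtain is a flat vertical surface: its disparity varies
#' linearly along the image columns, so it projects to a straight line in
#' the U-disparity map of the foreground frame.  A Hough vote finds that
#' line (requiring enough distinct columns to rule out compact person
#' blobs) and every foreground pixel whose (column, disparity) pair lies on
#' it is flagged as curtain.
#'
#' @param dmap Disparity map of the foreground pixels only (`NA`
#'   elsewhere).
#' @param line_tolerance Disparity tolerance for membership.
#' @param binarize_count Minimum U-disparity count for a cell to vote.
#' @param min_votes Minimum line votes (distinct columns).
#' @param min_span Minimum image-column span (px) of the detected line's
#'   inliers: curtains stretch across much of the view while person blobs
#'   are compact, so narrow lines are rejected.
#' @return Logical curtain mask.
#' @export
detect_curtain <- function(dmap, line_tolerance = 1, binarize_count = 5,
                           min_votes = 30, min_span = 60) {
  uv <- build_uv_disparity(dmap)
  cells <- which(uv$u_map >= binarize_count, arr.ind = TRUE)
  if (nrow(cells) < min_votes)
    return(matrix(FALSE, nrow(dmap), ncol(dmap)))
  # points: (column j, disparity d); allow any moderate slant incl. flat;
  # votes here count distinct cells, not pixel mass, so the line must span
  # many columns rather than a tall compact blob
  line <- hough_line(cells[, 2], cells[, 1] - 1L, m_range = c(-1, 1),
                     n_m = 201, min_votes = min_votes, tol = line_tolerance)
  if (is.null(line)) return(matrix(FALSE, nrow(dmap), ncol(dmap)))
  resid <- (cells[, 1] - 1L) - (line[["slope"]] * cells[, 2] +
                                  line[["intercept"]])
  inl_cols <- cells[abs(resid) <= line_tolerance, 2]
  if (length(inl_cols) == 0 || diff(range(inl_cols)) < min_span)
    return(matrix(FALSE, nrow(dmap), ncol(dmap)))
  cols <- matrix(seq_len(ncol(dmap)), nrow(dmap), ncol(dmap), byrow = TRUE)
  pred <- line[["slope"]] * cols + line[["intercept"]]
  !is.na(dmap) & abs(dmap - pred) <= line_tolerance
}
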