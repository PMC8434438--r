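#' Background subtraction
#'
#' A pixel is foreground when the background is deeper than the current
#' frame by at least the threshold: `B(i,j) - I(i,j) >= T`, with
#' `T = factor * sigma(I)` and `sigma(I)` the standard deviation of the
#' current frame's valid depths.  The test is one-sided — only objects
#' nearer than the background count.  Far-flagged background pixels and
#' hole pixels are never foreground.  A degenerate frame (`sigma = 0`)
#' falls back to a 0.05 m threshold floor.
#'
#' @param frame Preprocessed depth matrix.
#' @param bg A [build_background()] model.
#' @param factor Threshold as a multiple of the frame depth standard
#'   deviation.
#' @return Logical foreground mask with attribute `threshold` (metres).
#' @export
subtract_background <- function(frame, bg, factor = 0.2) {
  stopifnot(identical(dim(frame), dim(bg$average)))
  s <- sd(frame[frame > 0])
  th <- if (!is.finite(s) || s <= 0) 0.05 else factor * s
  mask <- (bg$average - frame) >= th & frame > 0 & !bg$far_mask
  attr(mask, "threshold") <- th
  mask
}

# 3x3 binary erosion / dilation via shifted masks.
erode3 <- function(mask) {
  out <- mask
  for (di in -1:1) for (dj in -1:1)
    out <- out & shift_matrix(mask, di, dj)
  out
}

dilate3 <- function(mask) {
  out <- mask
  for (di in -1:1) for (dj in -1:1)
    out <- out | shift_matrix(mask, di, dj)
  out
}

#' Clean a foreground mask
#'
#' Morphological opening then closing (3x3 structuring element) removes
#' speckle noise and seals small gaps; curtain pixels are subtracted; blobs
#' below a minimum area are dropped.
#'
#' @param mask Logical foreground mask.
#' @param curtain_mask Optional logical mask of detected curtain pixels.
#' @param min_area Minimum blob area in pixels.
#' @return Cleaned logical mask.
#' @export
clean_mask <- function(mask, curtain_mask = NULL, min_area = 100) {
  out <- dilate3(erode3(mask))        # opening
  out <- erode3(dilate3(out))         # closing
  if (!is.null(curtain_mask)) out <- out & !curtain_mask
  if (min_area > 0 && any(out)) {
    comp <- label_binary_components(out)
    sizes <- tabulate(comp)
    keep <- which(out)[sizes[comp] >= min_area]
    out[] <- FALSE
    out[keep] <- TRUE
  }
  out
}

#' Segment a cleaned mask into blobs
#'
#' 8-connected components with per-blob statistics used by the tracker.
#'
#' @param mask Cleaned logical mask.
#' @param frame Depth matrix the mask was derived from.
#' @return A tibble with one row per blob: pixel indices (list), centroid
#'   row/col, area, mean depth and bounding box (list `c(rmin, rmax, cmin,
#'   cmax)`).
#' @export
label_blobs <- function(mask, frame) {
  idx <- which(mask)
  if (length(idx) == 0) {
    return(tibble::tibble(pixels = list(), row = numeric(), col = numeric(),
                          area = integer(), mean_depth = numeric(),
                          bbox = list()))
  }
  comp <- label_binary_components(mask)
  H <- nrow(mask)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  by <- split(seq_along(idx), comp)
  tibble::tibble(
    pixels = lapply(by, function(k) idx[k]),
    row = vapply(by, function(k) mean(rows[k]), numeric(1)),
    col = vapply(by, function(k) mean(cols[k]), numeric(1)),
    area = vapply(by, length, integer(1)),
    mean_depth = vapply(by, function(k) mean(frame[idx[k]]), numeric(1)),
    bbox = lapply(by, function(k)
      c(rmin = min(rows[k]), rmax = max(rows[k]),
        cmin = min(cols[k]), cmax = max(cols[k]))))
}

#' Motion inside a bounding box
#'
#' Sum of absolute depth changes between two consecutive frames over a
#' bounding box; the caller compares it against the motion threshold
#' (80 m by default).  Absolute differences are used so oscillating or
#' receding motion does not cancel.
#'
#' @param frame_t,frame_prev Consecutive depth matrices.
#' @param bbox `c(rmin, rmax, cmin, cmax)`.
#' @return The motion sum in metres.
#' @export
frame_motion <- function(frame_t, frame_prev, bbox) {
  stopifnot(identical(dim(frame_t), dim(frame_prev)))
  bbox <- as.integer(bbox)
  if (bbox[1] > bbox[2] || bbox[3] > bbox[4] ||
      bbox[1] < 1 || bbox[3] < 1 ||
      bbox[2] > nrow(frame_t) || bbox[4] > ncol(frame_t))
    stop("empty or out-of-bounds bbox")
  sel_r <- bbox[1]:bbox[2]; sel_c <- bbox[3]:bbox[4]
  sum(abs(frame_t[sel_r, sel_c] - frame_prev[sel_r, sel_c]))
}

#' Person rule
#'
#' An object is confirmed as a person when it moved in more than six of the
#' last ten observed frames (ten seconds at 1 fps).  With fewer than ten
#' observations the object stays an undecided candidate.
#'
#' @param motion_flags Logical vector of per-frame motion decisions.
#' @param window,min_true Rule parameters.
#' @return `TRUE` once the rule is met.
#' @export
classify_person <- function(motion_flags, window = 10, min_true = 6) {
  if (length(motion_flags) < window) return(FALSE)
  sum(tail(motion_flags, window)) > min_true
}

#' Associate blobs between consecutive frames
#'
#' A previous/current pair may match only when all three absolute
#' differences — centroid distance, blob area, mean depth — fall below
#' their thresholds; conflicts are resolved greedily by nearest centroid.
#'
#' @param prev,curr Blob tibbles from [label_blobs()] (columns `row`,
#'   `col`, `area`, `mean_depth`).
#' @param th_dist Centroid distance gate in pixels.
#' @param th_area Area difference gate in pixels.
#' @param th_depth Mean depth gate in metres.
#' @return Integer vector, one entry per current blob: the row index of the
#'   matched previous blob or `NA`.
#' @export
associate <- function(prev, curr, th_dist = 30, th_area = 5000,
                      th_depth = 0.5) {
  match_idx <- rep(NA_integer_, nrow(curr))
  if (nrow(prev) == 0 || nrow(curr) == 0) return(match_idx)
  d_cent <- outer(curr$row, prev$row, `-`)^2 +
    outer(curr$col, prev$col, `-`)^2
  d_cent <- sqrt(d_cent)
  ok <- d_cent < th_dist &
    abs(outer(curr$area, prev$area, `-`)) < th_area &
    abs(outer(curr$mean_depth, prev$mean_depth, `-`)) < th_depth
  cost <- d_cent
  cost[!ok] <- Inf
  while (any(is.finite(cost))) {
    best <- arrayInd(which.min(cost), dim(cost))
    match_idx[best[1]] <- best[2]
    cost[best[1], ] <- Inf
    cost[, best[2]] <- Inf
  }
  match_idx
}

#' Detect and track objects over a sequence
#'
#' Runs background subtraction, curtain removal, mask cleanup and blob
#' association over a preprocessed sequence, maintaining per-track motion
#' history and the person rule.  The person flag is sticky: once an object
#' has moved in more than six of ten consecutive seconds it stays a person
#' for the life of its track.  Lost tracks survive a grace period before
#' being dropped.
#'
#' @param frames List of preprocessed depth matrices.
#' @param bg A [build_background()] model.
#' @param config A [pipeline_config()].
#' @param remove_curtain Run U-disparity curtain removal per frame.
#' @return A tibble with one row per (frame, object): columns `frame`,
#'   `id`, `row`, `col`, `area`, `mean_depth`, `moving`, `person`,
#'   `pixels` (list), `bbox` (list).
#' @export
track_sequence <- function(frames, bg, config = pipeline_config(),
                           remove_curtain = TRUE) {
  disp_K <- camera_intrinsics(
    focal_length = config$intrinsics$focal_length,
    baseline = config$disparity_baseline,
    cx = config$intrinsics$cx, cy = config$intrinsics$cy)
  tracks <- list()      # active: id, blob stats, flags, person, missed
  next_id <- 1L
  out <- vector("list", length(frames))
  prev_frame <- NULL
  for (f in seq_along(frames)) {
    frame <- frames[[f]]
    fg <- subtract_background(frame, bg, config$bg_factor)
    curtain <- NULL
    if (remove_curtain && any(fg)) {
      fg_depth <- frame
      fg_depth[!fg] <- HOLE
      dmap <- depth_to_disparity(fg_depth, disp_K, config$n_levels)
      curtain <- detect_curtain(dmap,
                                line_tolerance = config$line_tolerance,
                                binarize_count = config$binarize_count,
                                min_votes = config$curtain_votes)
    }
    mask <- clean_mask(fg, curtain, min_area = config$min_blob_area)
    blobs <- label_blobs(mask, frame)
    prev_stats <- if (length(tracks))
      dplyr::bind_rows(lapply(tracks, function(tr) tr$stats))
    else blobs[0, ]
    m <- associate(prev_stats, blobs, th_dist = config$th_dist,
                   th_area = config$th_area, th_depth = config$th_depth)
    new_tracks <- list()
    rows <- vector("list", nrow(blobs))
    for (b in seq_len(nrow(blobs))) {
      stats <- blobs[b, ]
      if (!is.na(m[b])) {
        tr <- tracks[[m[b]]]
        moving <- if (!is.null(prev_frame))
          frame_motion(frame, prev_frame, stats$bbox[[1]]) > config$th_motion
        else FALSE
        tr$flags <- c(tr$flags, moving)
        tr$person <- tr$person ||
          classify_person(tr$flags, config$person_window, config$person_min)
        tr$stats <- stats
        tr$missed <- 0L
      } else {
        moving <- FALSE
        tr <- list(id = next_id, stats = stats, flags = logical(0),
                   person = FALSE, missed = 0L)
        next_id <- next_id + 1L
      }
      new_tracks[[length(new_tracks) + 1L]] <- tr
      rows[[b]] <- tibble::tibble(
        frame = f, id = tr$id, row = stats$row, col = stats$col,
        area = stats$area, mean_depth = stats$mean_depth,
        moving = moving, person = tr$person,
        pixels = stats$pixels, bbox = stats$bbox)
    }
    # unmatched previous tracks age out after the grace period
    lost <- setdiff(seq_along(tracks), m[!is.na(m)])
    for (k in lost) {
      tr <- tracks[[k]]
      tr$missed <- tr$missed + 1L
      if (tr$missed <= config$grace)
        new_tracks[[length(new_tracks) + 1L]] <- tr
    }
    tracks <- new_tracks
    out[[f]] <- if (length(rows)) dplyr::bind_rows(rows)
    prev_frame <- frame
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(frame = integer(), id = integer(), row = numeric(),
                          col = numeric(), area = integer(),
                          mean_depth = numeric(), moving = logical(),
                          person = logical(), pixels = list(), bbox = list())
  }
  res
}
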