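#' Fill depth holes from the left
#'
#' Replaces hole pixels (depth 0) row by row with the last valid depth seen
#' to their left; leading holes with no valid pixel to their left are
#' backfilled from the first valid pixel of the row.  Rows with no valid
#' pixel at all are left unchanged (with a warning when the whole frame is
#' holes).
#'
#' @param frame Depth matrix, holes coded as 0.
#' @return Depth matrix with holes filled; valid pixels untouched.
#' @export
fill_holes_from_left <- function(frame) {
  stopifnot(is.matrix(frame))
  if (all(frame == HOLE)) {
    warning("all-hole frame: nothing to fill")
    return(frame)
  }
  t(apply(frame, 1, fill_row_left))
}

fill_row_left <- function(row) {
  valid <- row != HOLE
  if (!any(valid)) return(row)
  idx <- cumsum(valid)              # index of last valid pixel so far
  filled <- row[valid][pmax(idx, 1)]  # leading holes take the first valid
  filled
}

#' Edge-preserving bilateral smoothing
#'
#' Classic bilateral filter: each pixel is replaced by a weighted mean of
#' its neighbourhood, the weights being the product of a spatial Gaussian
#' and a Gaussian on the depth difference, so depth steps much larger than
#' `sigma_value` are preserved while small-amplitude noise is averaged out.
#'
#' @param frame Hole-free depth matrix.
#' @param d Window diameter in pixels (odd).
#' @param sigma_value Range sigma in metres.
#' @param sigma_space Spatial sigma in pixels.
#' @return Smoothed depth matrix.
#' @export
smooth_bilateral <- function(frame, d = 5, sigma_value = 0.1,
                             sigma_space = 3) {
  stopifnot(is.matrix(frame), d >= 1, d %% 2 == 1,
            sigma_value > 0, sigma_space > 0)
  r <- (d - 1) / 2
  num <- matrix(0, nrow(frame), ncol(frame))
  den <- num
  for (di in -r:r) {
    for (dj in -r:r) {
      shifted <- shift_matrix(frame, di, dj)
      w_s <- exp(-(di^2 + dj^2) / (2 * sigma_space^2))
      w <- w_s * exp(-(shifted - frame)^2 / (2 * sigma_value^2))
      num <- num + w * shifted
      den <- den + w
    }
  }
  num / den
}

# Shift with edge replication: out[i, j] = m[i + di, j + dj].
shift_matrix <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + di, 1), H)
  cj <- pmin(pmax(seq_len(W) + dj, 1), W)
  m[ri, cj, drop = FALSE]
}

#' Preprocess a depth frame or sequence
#'
#' Hole filling followed by bilateral smoothing, with the filter parameters
#' taken from the pipeline configuration.
#'
#' @param frame Depth matrix.
#' @param config A [pipeline_config()].
#' @return Enhanced depth matrix (no holes).
#' @export
preprocess_frame <- function(frame, config = pipeline_config()) {
  smooth_bilateral(fill_holes_from_left(frame),
                   d = config$bilateral_d,
                   sigma_value = config$bilateral_sigma_value,
                   sigma_space = config$bilateral_sigma_space)
}

#' @rdname preprocess_frame
#' @param frames List of depth matrices.
#' @export
preprocess_sequence <- function(frames, config = pipeline_config()) {
  lapply(frames, preprocess_frame, config = config)
}

#' Build the background model
#'
#' Averages the first person-free frames of a sequence (30 by default) into
#' a static background image, and flags pixels whose mean depth exceeds
#' `far_threshold` so the unstable far range is excluded from all later
#' background subtraction.
#'
#' @param frames List of exactly `n_frames` preprocessed person-free depth
#'   matrices.
#' @param far_threshold Depth in metres beyond which pixels are flagged.
#' @param n_frames Required number of frames.
#' @return An object of class `background_model`: list with `average`
#'   (depth matrix) and `far_mask` (logical matrix).
#' @export
build_background <- function(frames, far_threshold = 6, n_frames = 30) {
  if (length(frames) != n_frames)
    stop(sprintf("background needs exactly %d frames, got %d",
                 n_frames, length(frames)))
  avg <- Reduce(`+`, frames) / length(frames)
  structure(list(average = avg,
                 far_mask = avg > far_threshold,
                 far_threshold = far_threshold,
                 n_frames = n_frames),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %dx%d px, mean of %d frames, %d far pixels (> %g m)\n",
              nrow(x$average), ncol(x$average), x$n_frames,
              sum(x$far_mask), x$far_threshold))
  invisible(x)
}
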