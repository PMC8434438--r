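#' Camera intrinsics
#'
#' Pinhole parameters of the depth camera.  `focal_length` and the principal
#' point are used to back-project pixels into camera coordinates; `baseline`
#' enters only the depth-to-disparity conversion (the camera is treated as a
#' virtual stereo rig: disparity is derived from depth, never matched).
#'
#' @param focal_length Focal length in pixels.
#' @param baseline Stereo baseline in metres.
#' @param cx,cy Principal point in pixel coordinates (1-based, column/row).
#'   Defaults to the centre of a 320x180 image.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(focal_length = 160, baseline = 0.05,
                              cx = 160.5, cy = 90.5) {
  stopifnot(is.numeric(focal_length), focal_length > 0,
            is.numeric(baseline), baseline > 0)
  structure(list(focal_length = focal_length, baseline = baseline,
                 cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> f = %g px, baseline = %g m, c = (%g, %g)\n",
              x$focal_length, x$baseline, x$cx, x$cy))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the recognition pipeline in one
#' object.  Defaults are the operating values of the system: the background
#' subtraction factor (0.2 of the current frame's depth standard deviation),
#' the motion sum threshold (80 m over a bounding box), the association
#' gates (30 px centroid distance, 5000 px area, 0.5 m mean depth), the
#' history threshold delta (0.01 m), the height overrides (1.0 m for
#' assistance, 0.4 m for falls), the stop probability (0.30), a 30-frame
#' maximum and 5-frame minimum recognition round at 1 fps, and a width-5
#' block median filter.
#'
#' @param intrinsics A [camera_intrinsics()] object used for back-projection.
#' @param bg_factor Background-subtraction threshold as a multiple of the
#'   frame depth standard deviation.
#' @param bg_frames Number of person-free frames averaged into the
#'   background model.
#' @param far_threshold Depth in metres beyond which background pixels are
#'   dropped as unreliable.
#' @param th_motion Motion sum (metres, absolute depth change over a
#'   bounding box) above which an object counts as moving in a frame.
#' @param th_dist,th_area,th_depth Association gates between consecutive
#'   frames: centroid distance (px), blob area difference (px), mean depth
#'   difference (m).
#' @param person_window,person_min Person rule: an object is confirmed as a
#'   person when it moved in more than `person_min` of the last
#'   `person_window` frames.
#' @param grace Frames a lost track is retained before being dropped.
#' @param min_blob_area Minimum blob area (px) kept after mask cleanup.
#' @param delta Depth-difference threshold (m) that refreshes the motion
#'   history template.
#' @param tau Time window (frames) of the motion history template.
#' @param th_assist,th_fall Centroid-to-floor heights (m) triggering the
#'   "Receiving assistance" / "Falling" overrides.
#' @param th_prob Stop probability of the automatic rounding recognizer.
#' @param min_round,max_round Minimum/maximum recognition round length
#'   (frames).
#' @param median_window Block width of the label median filter.
#' @param n_levels Number of integer disparity levels.
#' @param disparity_baseline Virtual stereo baseline (m) used only for the
#'   depth-to-disparity conversion, chosen so the room depth range spreads
#'   over the disparity levels.
#' @param line_tolerance Disparity tolerance (levels) for membership of the
#'   ground correlation line and the curtain line.
#' @param hough_votes Minimum Hough votes to accept a line.
#' @param binarize_count Minimum histogram count for a UV-disparity cell to
#'   take part in line detection.
#' @param bed_binarize_count Minimum V-disparity count for the bed
#'   component labelling (higher, so thin wall traces drop out).
#' @param curtain_votes Minimum Hough votes (distinct columns) to accept a
#'   curtain line.
#' @param bilateral_d,bilateral_sigma_value,bilateral_sigma_space Bilateral
#'   filter window diameter (px), range sigma (m) and spatial sigma (px).
#' @param canvas Height and width (px) of the normalized silhouette canvas.
#' @param hog_cell HOG cell size in pixels.
#' @param hog_bins Number of unsigned orientation bins.
#' @param frame_rate Frames per second of the sequence.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(intrinsics = camera_intrinsics(),
                            bg_factor = 0.2,
                            bg_frames = 30,
                            far_threshold = 6,
                            th_motion = 80,
                            th_dist = 30,
                            th_area = 5000,
                            th_depth = 0.5,
                            person_window = 10,
                            person_min = 6,
                            grace = 5,
                            min_blob_area = 100,
                            delta = 0.01,
                            tau = 30,
                            th_assist = 1.0,
                            th_fall = 0.4,
                            th_prob = 0.30,
                            min_round = 5,
                            max_round = 30,
                            median_window = 5,
                            n_levels = 128,
                            disparity_baseline = 0.75,
                            line_tolerance = 1,
                            hough_votes = 5,
                            binarize_count = 5,
                            bed_binarize_count = 20,
                            curtain_votes = 30,
                            bilateral_d = 5,
                            bilateral_sigma_value = 0.1,
                            bilateral_sigma_space = 3,
                            canvas = c(176, 256),
                            hog_cell = 16,
                            hog_bins = 9,
                            frame_rate = 1) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  stopifnot(all(vapply(cfg[num], function(v) all(v > 0) || identical(v, 0), logical(1))))
  if (min_round > max_round)
    stop("`min_round` must not exceed `max_round`")
  stopifnot(median_window %% 2 == 1)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  flat <- x[!vapply(x, is.list, logical(1))]
  cat(paste0("  ", names(flat), " = ",
             vapply(flat, function(v) paste(format(v), collapse = "x"),
                    character(1))), sep = "\n")
  invisible(x)
}

#' Read one depth frame from CSV
#'
#' The frame dialect is one CSV row per image row, values in metres.
#' Non-numeric or negative cells are mapped to the hole marker (0) with a
#' warning; ragged rows are rejected.
#'
#' @param path Path to a CSV file.
#' @return A numeric matrix (rows = image rows) of depths in metres, holes
#'   coded as 0.
#' @export
read_depth_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty depth CSV: ", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged depth CSV %s: row %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1]))
  }
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  n_bad <- sum(is.na(vals) | vals < 0)
  if (n_bad > 0) {
    warning(sprintf("%d non-numeric/negative cells in %s mapped to hole marker",
                    n_bad, basename(path)))
    vals[is.na(vals) | vals < 0] <- HOLE
  }
  matrix(vals, nrow = length(lines), byrow = TRUE)
}

#' Write one depth frame to CSV
#'
#' Inverse of [read_depth_csv()]; values are written with a fixed decimal
#' precision so that read-after-write is an identity at that precision.
#'
#' @param frame Numeric depth matrix, holes coded as 0.
#' @param path Output path.
#' @param digits Decimal places retained.
#' @export
write_depth_csv <- function(frame, path, digits = 3) {
  stopifnot(is.matrix(frame), is.numeric(frame), all(frame >= 0))
  rows <- apply(frame, 1, function(r)
    paste(formatC(r, digits = digits, format = "f"), collapse = ","))
  writeLines(rows, path)
  invisible(path)
}

#' Load a directory of depth frames
#'
#' Frames are read in lexicographic filename order and must share one
#' resolution.
#'
#' @param directory Directory holding `*.csv` depth frames.
#' @return A list of depth matrices, named by file.
#' @export
load_sequence <- function(directory) {
  files <- sort(list.files(directory, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) {
    warning("no depth CSV files in ", directory)
    return(list())
  }
  frames <- lapply(files, read_depth_csv)
  names(frames) <- basename(files)
  dims <- vapply(frames, dim, integer(2))
  if (nrow(unique(t(dims))) > 1) {
    ref <- basename(files[1])
    bad <- basename(files[which(dims[1, ] != dims[1, 1] |
                                dims[2, ] != dims[2, 1])[1]])
    stop(sprintf("mixed frame dimensions in %s: %s vs %s", directory, ref, bad))
  }
  frames
}

#' Write a sequence of depth frames
#'
#' @param frames List of depth matrices.
#' @param directory Output directory (created if missing).
#' @inheritParams write_depth_csv
#' @export
write_sequence <- function(frames, directory, digits = 3) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (k in seq_along(frames)) {
    write_depth_csv(frames[[k]],
                    file.path(directory, sprintf("frame_%05d.csv", k)),
                    digits = digits)
  }
  invisible(directory)
}
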