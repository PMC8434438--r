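#' Run the full recognition pipeline on a depth sequence
#'
#' End to end: preprocessing (hole filling + bilateral smoothing),
#' background modelling over the first person-free frames, UV-disparity
#' region extraction and floor-plane fitting, detection/tracking, silhouette
#' normalization, and automatic-rounding recognition with the height and
#' location overrides.  When several confirmed person blobs coexist
#' (resident + nurse) the largest is analysed and the frame is counted in
#' `n_multiblob`.
#'
#' @param frames List of raw depth matrices (one sequence).
#' @param model A trained [train_classifier()] model.
#' @param config A [pipeline_config()].
#' @param bg Optional pre-built [build_background()] model; by default the
#'   first `config$bg_frames` frames of the sequence are used.
#' @param regions,plane Optional pre-computed [extract_regions()] /
#'   [fit_floor_plane()] results.
#' @return An object of class `action_recognition`: list with `frames`
#'   (tibble: frame, label, person, location, floor_distance), `rounds`
#'   (tibble from [rounding_recognize()]), `tracks`, `regions`, `plane`,
#'   `config`, `n_multiblob`.
#' @export
recognize_sequence <- function(frames, model, config = pipeline_config(),
                               bg = NULL, regions = NULL, plane = NULL) {
  stopifnot(length(frames) > 0)
  pp <- preprocess_sequence(frames, config)
  if (is.null(bg)) {
    if (length(pp) < config$bg_frames)
      stop("sequence shorter than the background window")
    bg <- build_background(pp[seq_len(config$bg_frames)],
                           far_threshold = config$far_threshold,
                           n_frames = config$bg_frames)
  }
  if (is.null(regions)) regions <- extract_regions(bg, config)
  if (is.null(plane)) {
    fl <- which(regions$labels == "floor")
    H <- nrow(regions$labels)
    avg <- bg$average
    plane <- fit_floor_plane(x = (fl - 1L) %/% H + 1L,
                             y = (fl - 1L) %% H + 1L,
                             depth = avg[fl],
                             intrinsics = config$intrinsics)
  }
  tracks <- track_sequence(pp, bg, config)
  stream <- person_stream(pp, tracks, regions, plane, config)
  rounds <- rounding_recognize(stream, model, config)
  labels <- rounds_to_labels(rounds, length(frames))
  structure(list(
    frames = tibble::tibble(frame = seq_along(frames), label = labels,
                            person = stream$person,
                            location = stream$location,
                            floor_distance = stream$floor_distance),
    rounds = rounds, tracks = tracks, regions = regions, plane = plane,
    config = config, n_multiblob = attr(stream, "n_multiblob")),
    class = "action_recognition")
}

# Build the per-frame stream consumed by the rounding recognizer: pick the
# primary person blob (largest area among confirmed persons), normalize its
# silhouette, locate it and measure its centroid height.
person_stream <- function(pp, tracks, regions, plane, config) {
  n <- length(pp)
  patch <- vector("list", n)
  person <- logical(n)
  location <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  n_multi <- 0L
  persons <- tracks[tracks$person, , drop = FALSE]
  by_frame <- split(seq_len(nrow(persons)), persons$frame)
  for (f_chr in names(by_frame)) {
    f <- as.integer(f_chr)
    rows <- by_frame[[f_chr]]
    if (length(rows) > 1) n_multi <- n_multi + 1L
    b <- rows[which.max(persons$area[rows])]
    idx <- persons$pixels[[b]]
    person[f] <- TRUE
    patch[[f]] <- normalize_silhouette(pp[[f]], idx, config$canvas)
    location[f] <- localize_blob(idx, regions)
    cen <- pixel_to_camera(persons$col[b], persons$row[b],
                           persons$mean_depth[b], config$intrinsics)
    dist[f] <- centroid_floor_distance(cen, plane)
  }
  out <- tibble::tibble(frame = seq_len(n), person = person, patch = patch,
                        location = location, floor_distance = dist)
  attr(out, "n_multiblob") <- n_multi
  out
}

#' @export
print.action_recognition <- function(x, ...) {
  det <- x$rounds[!is.na(x$rounds$label), ]
  cat(sprintf(paste0("<action_recognition> %d frames, %d rounds ",
                     "(%d labelled, %d undetermined)\n"),
              nrow(x$frames), nrow(x$rounds), nrow(det),
              nrow(x$rounds) - nrow(det)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.action_recognition <- function(x, ...) x$frames

#' @exportS3Method generics::glance
glance.action_recognition <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$frames),
    n_rounds = nrow(x$rounds),
    n_undetermined_rounds = sum(is.na(x$rounds$label)),
    mean_round_length = if (nrow(x$rounds)) mean(x$rounds$end - x$rounds$start + 1)
                        else NA_real_,
    n_multiblob = x$n_multiblob)
}

#' Build training features from simulated short action sequences
#'
#' Renders each scripted short sequence in the given room, extracts the
#' person silhouettes with the very same background subtraction and blob
#' segmentation the recognizer uses at test time, accumulates DMA/DMH over
#' the sequence, and returns one fused descriptor per sequence.  The shared
#' background model is learned from person-free renders of the same room.
#'
#' @param spec A [scene_spec()] (its noise settings apply to training too).
#' @param scripts List of single-label [action_script()]s, e.g.
#'   [demo_training_scripts()].
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the rendering noise.
#' @return List with `features` (matrix, one row per sequence) and
#'   `labels` (integer vector).
#' @export
build_training_features <- function(spec, scripts,
                                    config = pipeline_config(),
                                    seed = 1L) {
  absent <- person_pose(posture = "absent")
  bg_script <- action_script(0L, config$bg_frames, list(absent))
  bg_seq <- render_sequence(spec, bg_script, seed = seed)
  bg <- build_background(preprocess_sequence(bg_seq$frames, config),
                         far_threshold = config$far_threshold,
                         n_frames = config$bg_frames)
  feats <- list(); labs <- integer(0)
  for (s in seq_along(scripts)) {
    sq <- render_sequence(spec, scripts[[s]], seed = seed + s)
    pp <- preprocess_sequence(sq$frames, config)
    patches <- list()
    for (fr in pp) {
      fg <- clean_mask(subtract_background(fr, bg, config$bg_factor),
                       min_area = config$min_blob_area)
      blobs <- label_blobs(fg, fr)
      if (nrow(blobs) == 0) next
      b <- which.max(blobs$area)
      patches <- c(patches,
                   list(normalize_silhouette(fr, blobs$pixels[[b]],
                                             config$canvas)))
    }
    if (length(patches) < 2) {
      warning(sprintf("training script %d: person not segmented, skipped", s))
      next
    }
    feats <- c(feats, list(sequence_feature(patches, config)))
    labs <- c(labs, scripts[[s]]$label[1])
  }
  list(features = do.call(rbind, feats), labels = labs)
}
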