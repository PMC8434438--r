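#' Synthetic room specification
#'
#' Describes a care-home bedroom seen by a downward-tilted depth camera:
#' a floor plane, walls, a bed cuboid, additional static cuboids (a
#' wheelchair-sized object), and an optional vertical curtain segment.
#' Everything downstream of the camera is tested against scenes rendered
#' from this description, so the generator also emits ground truth (region
#' masks, per-frame person masks, the floor-plane coefficients, per-frame
#' labels).
#'
#' World coordinates: x to the camera's right, y away from the camera, z up;
#' the floor is z = 0 and the camera sits at (0, 0.05, camera_height)
#' looking down the +y axis, pitched down by `camera_tilt` degrees.
#'
#' @param camera_height Camera height above the floor in metres.
#' @param camera_tilt Downward pitch of the optical axis in degrees.
#' @param intrinsics A [camera_intrinsics()] object.
#' @param room Named vector `c(width, depth, height)` of the room box in
#'   metres.
#' @param bed_box 2x3 matrix `rbind(lo, hi)` of the bed cuboid (metres).
#' @param static_objects Named list of further 2x3 cuboids.
#' @param curtain Optional list `list(x = c(x0, x1), y = c(y0, y1),
#'   z = c(z0, z1))` describing a vertical plane segment hanging between
#'   the two (x, y) endpoints.  Rendered only in frames whose script
#'   segment requests it.
#' @param noise_sigma Depth noise standard deviation in metres.
#' @param hole_rate Fraction of pixels dropped to the hole marker.
#' @param max_range Sensing range in metres: ground-truth region masks mark
#'   pixels farther than this as "ignored", mirroring the pipeline's
#'   far-pixel removal.
#' @param width,height Image resolution in pixels.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(camera_height = 2.1,
                       camera_tilt = 25,
                       intrinsics = camera_intrinsics(),
                       room = c(width = 5, depth = 8, height = 2.6),
                       bed_box = rbind(lo = c(0.6, 2.6, 0),
                                       hi = c(1.6, 4.6, 0.5)),
                       static_objects = list(
                         wheelchair = rbind(lo = c(-1.15, 2.25, 0),
                                            hi = c(-0.45, 3.00, 0.60))),
                       curtain = NULL,
                       noise_sigma = 0,
                       hole_rate = 0,
                       max_range = 6,
                       width = 320, height = 180) {
  stopifnot(camera_height > 0, hole_rate >= 0, hole_rate < 1,
            noise_sigma >= 0, length(room) == 3, all(room > 0),
            is.matrix(bed_box), all(dim(bed_box) == c(2, 3)))
  if (!is.null(bed_box) && bed_box[1, 3] < 0)
    stop("bed_box must lie above the floor plane")
  structure(as.list(environment()), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0("<scene_spec> %dx%d px, camera %.2f m / %.0f deg tilt, ",
                     "room %.1fx%.1fx%.1f m, noise %.3f m, holes %.1f%%\n"),
              x$width, x$height, x$camera_height, x$camera_tilt,
              x$room[1], x$room[2], x$room[3], x$noise_sigma,
              100 * x$hole_rate))
  invisible(x)
}

#' Person pose
#'
#' The person is modelled as a two-cuboid composite (torso + legs) whose
#' extents depend on posture: standing is tall and narrow, seated is an
#' L-shape (legs reaching forward and down), lying is long and low, and
#' `hide_legs = TRUE` collapses the legs into the torso for a wheelchair
#' occupant whose legs are occluded by the chair.  Postures are
#' interpolated corner-wise during transitions, so all postures expose the
#' same number of cuboids.
#'
#' @param x,y Position of the body centre on the floor plan (metres).
#' @param posture One of `"standing"`, `"seated"`, `"lying"`, `"absent"`.
#' @param stature Standing height in metres.
#' @param seat_height Seat height for the seated posture (metres).
#' @param z_base Base height of the lying posture (bed top for lying on
#'   the bed, 0 for lying on the floor).
#' @param lying_axis `"x"` or `"y"`: long axis of the lying posture.
#' @param hide_legs Collapse legs into the torso (wheelchair occupant).
#' @return An object of class `person_pose`.
#' @export
person_pose <- function(x = 0, y = 3, posture = "standing",
                        stature = 1.55, seat_height = 0.45,
                        z_base = 0, lying_axis = "y", hide_legs = FALSE) {
  posture <- match.arg(posture, c("standing", "seated", "lying", "absent"))
  structure(list(x = x, y = y, posture = posture, stature = stature,
                 seat_height = seat_height, z_base = z_base,
                 lying_axis = lying_axis, hide_legs = hide_legs),
            class = "person_pose")
}

# Two cuboids (each 2x3 rbind(lo, hi)) for a pose, or NULL when absent.
pose_cuboids <- function(pose) {
  if (pose$posture == "absent") return(NULL)
  s <- pose$stature / 1.55
  x <- pose$x; y <- pose$y
  cub <- switch(pose$posture,
    standing = list(
      torso = rbind(c(x - 0.22, y - 0.15, 0.75 * s),
                    c(x + 0.22, y + 0.15, 1.55 * s)),
      legs  = rbind(c(x - 0.20, y - 0.13, 0),
                    c(x + 0.20, y + 0.13, 0.75 * s))),
    seated = {
      h <- pose$seat_height
      list(
        torso = rbind(c(x - 0.22, y - 0.15, h),
                      c(x + 0.22, y + 0.15, h + 0.75 * s)),
        legs  = rbind(c(x - 0.20, y - 0.55, 0),
                      c(x + 0.20, y - 0.15, h + 0.05)))
    },
    lying = {
      b <- pose$z_base
      if (pose$lying_axis == "y")
        list(torso = rbind(c(x - 0.22, y, b),
                           c(x + 0.22, y + 0.85, b + 0.30)),
             legs  = rbind(c(x - 0.22, y - 0.85, b),
                           c(x + 0.22, y, b + 0.30)))
      else
        list(torso = rbind(c(x, y - 0.22, b),
                           c(x + 0.85, y + 0.22, b + 0.30)),
             legs  = rbind(c(x - 0.85, y - 0.22, b),
                           c(x, y + 0.22, b + 0.30)))
    })
  if (pose$hide_legs) cub$legs <- cub$torso
  cub
}

lerp_cuboids <- function(a, b, alpha) {
  if (is.null(a)) return(if (alpha >= 0.5) b else NULL)
  if (is.null(b)) return(if (alpha < 0.5) a else NULL)
  Map(function(ca, cb) ca + alpha * (cb - ca), a, b)
}

#' Action script
#'
#' An ordered list of segments, each holding an action label (0-7), a
#' duration in frames, a start and end pose (interpolated linearly over the
#' segment) and whether the curtain is drawn.
#'
#' @param labels Integer vector of action codes (0 = Outside the room,
#'   1 = Transition, 2 = Seated in wheelchair, 3 = Standing, 4 = Sitting on
#'   the bed, 5 = Lying on the bed, 6 = Receiving assistance, 7 = Falling).
#' @param durations Integer vector of segment lengths in frames.
#' @param poses_from,poses_to Lists of [person_pose()] objects (one per
#'   segment); `poses_to` defaults to `poses_from` (static segments).
#' @param curtain Logical vector: render the curtain during the segment.
#' @return A tibble of class `action_script`.
#' @export
action_script <- function(labels, durations, poses_from,
                          poses_to = poses_from,
                          curtain = FALSE) {
  stopifnot(length(labels) == length(durations),
            length(poses_from) == length(labels),
            length(poses_to) == length(labels))
  if (length(labels) == 0) stop("empty action script")
  if (any(durations < 1)) stop("segment durations must be >= 1 frame")
  if (!all(labels %in% 0:7)) stop("labels must be drawn from 0..7")
  out <- tibble::tibble(label = as.integer(labels),
                        duration = as.integer(durations),
                        pose_from = poses_from,
                        pose_to = poses_to,
                        curtain = rep_len(curtain, length(labels)))
  class(out) <- c("action_script", class(out))
  out
}

# --- ray casting ------------------------------------------------------------

# Per-pixel ray directions, parametrised so that depth along the optical
# axis equals the ray parameter.
scene_rays <- function(spec) {
  K <- spec$intrinsics
  th <- spec$camera_tilt * pi / 180
  W <- spec$width; H <- spec$height
  dx <- ( (1:W) - K$cx ) / K$focal_length
  dy <- ( (1:H) - K$cy ) / K$focal_length
  DX <- matrix(dx, H, W, byrow = TRUE)
  DY <- matrix(dy, H, W)
  dir_x <- DX
  dir_y <- -DY * sin(th) + cos(th)
  dir_z <- -DY * cos(th) - sin(th)
  eps <- 1e-12
  dir_x[abs(dir_x) < eps] <- eps
  dir_y[abs(dir_y) < eps] <- eps
  dir_z[abs(dir_z) < eps] <- eps
  list(x = dir_x, y = dir_y, z = dir_z,
       origin = c(0, 0.05, spec$camera_height))
}

# Entry depth of a ray bundle into an axis-aligned cuboid (Inf on miss).
cuboid_depth <- function(rays, cub) {
  if (any(cub[2, ] <= cub[1, ])) {
    return(matrix(Inf, nrow(rays$x), ncol(rays$x)))
  }
  o <- rays$origin
  t_near <- matrix(-Inf, nrow(rays$x), ncol(rays$x))
  t_far <- matrix(Inf, nrow(rays$x), ncol(rays$x))
  for (ax in 1:3) {
    d <- rays[[c("x", "y", "z")[ax]]]
    t1 <- (cub[1, ax] - o[ax]) / d
    t2 <- (cub[2, ax] - o[ax]) / d
    t_near <- pmax(t_near, pmin(t1, t2))
    t_far <- pmin(t_far, pmax(t1, t2))
  }
  hit <- t_near <= t_far & t_far > 0 & t_near > 0
  t_near[!hit] <- Inf
  t_near
}

# Exit depth of rays from inside the room box, plus the face hit.
room_depth <- function(rays, spec) {
  o <- rays$origin
  wx <- spec$room[[1]] / 2; wy <- spec$room[[2]]; wz <- spec$room[[3]]
  tx <- (ifelse(rays$x > 0, wx, -wx) - o[1]) / rays$x
  ty <- (ifelse(rays$y > 0, wy, 0) - o[2]) / rays$y
  tz <- (ifelse(rays$z > 0, wz, 0) - o[3]) / rays$z
  t <- pmin(tx, ty, tz)
  floor_face <- (tz <= pmin(tx, ty)) & (rays$z < 0)
  list(depth = t, floor = floor_face)
}

curtain_depth <- function(rays, curtain) {
  o <- rays$origin
  p0 <- c(curtain$x[1], curtain$y[1])
  dxy <- c(curtain$x[2] - curtain$x[1], curtain$y[2] - curtain$y[1])
  n <- c(-dxy[2], dxy[1])          # horizontal normal of the vertical plane
  denom <- rays$x * n[1] + rays$y * n[2]
  denom[abs(denom) < 1e-12] <- 1e-12
  t <- ((p0[1] - o[1]) * n[1] + (p0[2] - o[2]) * n[2]) / denom
  px <- o[1] + t * rays$x
  py <- o[2] + t * rays$y
  pz <- o[3] + t * rays$z
  s <- ((px - p0[1]) * dxy[1] + (py - p0[2]) * dxy[2]) / sum(dxy^2)
  ok <- t > 0 & s >= 0 & s <= 1 & pz >= curtain$z[1] & pz <= curtain$z[2]
  t[!ok] <- Inf
  t
}

# Static scene (no person, no curtain): depth plus region labels
# 1 = floor, 2 = bed, 3 = ignored.
render_static <- function(spec, rays = scene_rays(spec)) {
  rm <- room_depth(rays, spec)
  depth <- rm$depth
  label <- ifelse(rm$floor, 1L, 3L)
  objs <- c(list(bed = spec$bed_box), spec$static_objects)
  codes <- c(2L, rep(3L, length(spec$static_objects)))
  for (k in seq_along(objs)) {
    t <- cuboid_depth(rays, objs[[k]])
    nearer <- t < depth
    depth[nearer] <- t[nearer]
    label[nearer] <- codes[k]
  }
  label[depth > spec$max_range] <- 3L
  list(depth = depth, label = label)
}

#' Render a depth sequence with ground truth
#'
#' Ray-casts the scene once per frame: the static room (floor, walls, bed,
#' objects) is rendered once and per-frame person cuboids (and the curtain,
#' when drawn) are composited by nearest-surface selection, so the person
#' always occludes the room behind it.  Depth is measured along the optical
#' axis, as a stereo depth camera reports it.  Noise and holes are applied
#' afterwards via [corrupt_frames()].
#'
#' @param spec A [scene_spec()].
#' @param script An [action_script()].
#' @param seed Integer seed for noise and hole placement.
#' @return A list with `frames` (list of depth matrices) and `truth`, a
#'   list holding per-frame `labels`, the static `region_map` (see
#'   [build_region_map()]), the analytic `floor_plane` coefficients in
#'   camera coordinates, and per-frame logical `person_masks`.
#' @export
render_sequence <- function(spec, script, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!inherits(script, "action_script") || nrow(script) == 0)
    stop("`script` must be a non-empty action_script")
  rays <- scene_rays(spec)
  static <- render_static(spec, rays)
  curt <- if (!is.null(spec$curtain)) curtain_depth(rays, spec$curtain)
  n_frames <- sum(script$duration)
  frames <- vector("list", n_frames)
  person_masks <- vector("list", n_frames)
  labels <- integer(n_frames)
  f <- 0L
  for (s in seq_len(nrow(script))) {
    ca <- pose_cuboids(script$pose_from[[s]])
    cb <- pose_cuboids(script$pose_to[[s]])
    n <- script$duration[s]
    for (k in seq_len(n)) {
      f <- f + 1L
      alpha <- if (n == 1) 0 else (k - 1) / (n - 1)
      cubs <- lerp_cuboids(ca, cb, alpha)
      depth <- static$depth
      if (!is.null(curt) && script$curtain[s]) {
        depth <- pmin(depth, curt)
      }
      pmask <- matrix(FALSE, spec$height, spec$width)
      if (!is.null(cubs)) {
        tp <- matrix(Inf, spec$height, spec$width)
        for (cub in cubs) tp <- pmin(tp, cuboid_depth(rays, cub))
        pmask <- tp < depth
        depth <- pmin(depth, tp)
        if (!any(pmask) && script$label[s] != 0L)
          stop(sprintf(
            "segment %d (label %d): person outside the camera frustum", s,
            script$label[s]))
      }
      frames[[f]] <- depth
      person_masks[[f]] <- pmask
      labels[f] <- script$label[s]
    }
  }
  if (spec$noise_sigma > 0 || spec$hole_rate > 0) {
    frames <- corrupt_frames(frames, spec$noise_sigma, spec$hole_rate, seed)
  }
  th <- spec$camera_tilt * pi / 180
  truth <- list(
    labels = labels,
    region_map = build_region_map(static$label == 1L, static$label == 2L),
    floor_plane = c(0, cos(th), sin(th), -spec$camera_height),
    person_masks = person_masks,
    static_depth = static$depth)
  list(frames = frames, truth = truth)
}

#' Corrupt clean depth frames with sensor noise and holes
#'
#' Adds zero-mean Gaussian depth noise and knocks a random fraction of
#' pixels down to the hole marker, reproducibly under `seed`.
#'
#' @param frames List of hole-free depth matrices.
#' @param noise_sigma Noise standard deviation in metres.
#' @param hole_rate Fraction of pixels set to the hole marker.
#' @param seed Integer seed.
#' @return List of corrupted depth matrices.
#' @export
corrupt_frames <- function(frames, noise_sigma, hole_rate, seed = 1L) {
  if (hole_rate >= 1) stop("hole_rate must be < 1")
  stopifnot(noise_sigma >= 0, hole_rate >= 0)
  set.seed(as.integer(seed))
  lapply(frames, function(fr) {
    n <- length(fr)
    if (noise_sigma > 0) fr <- pmax(fr + rnorm(n, 0, noise_sigma), 0.05)
    if (hole_rate > 0) fr[runif(n) < hole_rate] <- HOLE
    fr
  })
}

# --- canned scenes and scripts ---------------------------------------------

#' Demonstration room and day script
#'
#' `demo_scene()` is the default synthetic bedroom (camera 2.1 m high,
#' 25 degree tilt, one bed, one wheelchair-sized object).
#' `demo_day_script()` is the canonical 600-frame benchmark day: the room is
#' empty while the background is learned, then the resident enters, sits in
#' the wheelchair, stands, sits on the bed and lies down, with transitions
#' in between.  `demo_training_scripts()` generates short (6-14 frame)
#' scripted action sequences of the five trainable labels with jittered
#' positions for classifier training.
#'
#' @param noise_sigma,hole_rate Corruption level of the rendered frames.
#' @return `demo_scene()`: a [scene_spec()].
#' @export
demo_scene <- function(noise_sigma = 0.02, hole_rate = 0.05) {
  scene_spec(noise_sigma = noise_sigma, hole_rate = hole_rate)
}

demo_poses <- function() {
  list(
    door      = person_pose(-2.0, 6.4, "standing"),
    approach  = person_pose(-0.85, 3.2, "standing"),
    wheelchair = person_pose(-0.80, 2.65, "seated", seat_height = 0.45,
                             hide_legs = TRUE),
    stand     = person_pose(-0.30, 2.60, "standing"),
    stand_bed = person_pose(0.90, 2.55, "standing"),
    sit_bed   = person_pose(1.00, 2.95, "seated", seat_height = 0.55),
    lie_bed   = person_pose(1.10, 3.55, "lying", z_base = 0.5,
                            lying_axis = "y"))
}

#' @rdname demo_scene
#' @param n_frames Total benchmark length in frames (default 600).
#' @return `demo_day_script()`: an [action_script()].
#' @export
demo_day_script <- function(n_frames = 600) {
  p <- demo_poses()
  absent <- person_pose(posture = "absent")
  labels    <- c(0L, 1L, 1L, 2L, 1L, 3L, 1L, 1L, 4L, 1L, 5L)
  durations <- c(40, 15, 8, 120, 8, 80, 6, 4, 140, 8, 171)
  stopifnot(sum(durations) == 600)
  if (n_frames != 600) {
    durations <- pmax(1L, as.integer(round(durations * n_frames / 600)))
    durations[length(durations)] <-
      durations[length(durations)] + n_frames - sum(durations)
  }
  action_script(
    labels, durations,
    poses_from = list(absent, p$door, p$approach, p$wheelchair, p$wheelchair,
                      p$stand, p$stand, p$stand_bed, p$sit_bed, p$sit_bed,
                      p$lie_bed),
    poses_to   = list(absent, p$approach, p$wheelchair, p$wheelchair, p$stand,
                      p$stand, p$stand_bed, p$sit_bed, p$sit_bed, p$lie_bed,
                      p$lie_bed))
}

#' @rdname demo_scene
#' @param n_per_class Training sequences generated per label.
#' @param seed Integer seed for the pose jitter.
#' @return `demo_training_scripts()`: a list of [action_script()] objects,
#'   each a single-label short sequence, named by label code.
#' @export
demo_training_scripts <- function(n_per_class = 8, seed = 1L) {
  set.seed(as.integer(seed))
  p <- demo_poses()
  jitter_pose <- function(pose, dx, dy) {
    pose$x <- pose$x + dx; pose$y <- pose$y + dy
    pose
  }
  scripts <- list()
  for (k in seq_len(n_per_class)) {
    dx <- runif(1, -0.15, 0.15); dy <- runif(1, -0.15, 0.15)
    dur <- sample(8:14, 1)
    # class 1: transitions, cycling through the day's transition types
    tr <- switch((k - 1) %% 4 + 1,
      list(from = p$wheelchair, to = p$stand),
      list(from = p$stand_bed, to = p$sit_bed),
      list(from = p$sit_bed, to = p$lie_bed),
      list(from = p$door, to = p$approach))
    scripts <- c(scripts, list(
      `1` = action_script(1L, dur, list(jitter_pose(tr$from, dx, dy)),
                          list(jitter_pose(tr$to, dx, dy))),
      `2` = action_script(2L, sample(6:14, 1),
                          list(jitter_pose(p$wheelchair, dx / 2, dy / 2))),
      `3` = action_script(3L, sample(6:14, 1),
                          list(jitter_pose(p$stand, dx, dy))),
      `4` = action_script(4L, sample(6:14, 1),
                          list(jitter_pose(p$sit_bed, dx / 2, dy / 4))),
      `5` = action_script(5L, sample(6:14, 1),
                          list(jitter_pose(p$lie_bed, dx / 4, dy)))))
  }
  scripts
}

#' Write simulator ground truth as a JSON sidecar
#'
#' Stores per-frame labels and the floor-plane coefficients next to a
#' written depth sequence.
#'
#' @param truth The `truth` component returned by [render_sequence()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(labels = truth$labels, floor_plane = truth$floor_plane),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
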