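make_dmap <- function(values, n_levels = 128) {
  d <- matrix(as.integer(values), nrow(values), ncol(values))
  attr(d, "n_levels") <- as.integer(n_levels)
  d
}

test_that("depth converts to disparity by the inverse-proportional law", {
  K <- camera_intrinsics(focal_length = 320, baseline = 0.05)
  d <- depth_to_disparity(matrix(2, 2, 2), K, 128)
  expect_true(all(d == 8L))                       # 320 * 0.05 / 2
  # halving depth doubles disparity
  expect_true(all(depth_to_disparity(matrix(1, 2, 2), K, 128) == 16L))
  # holes are excluded, clipping applies
  frame <- matrix(c(2, 0, 0.01, 4), 2, 2)
  d2 <- depth_to_disparity(frame, K, 128)
  expect_true(is.na(d2[frame == 0]))
  expect_equal(max(d2, na.rm = TRUE), 127L)
})

test_that("disparity is order-reversing in depth", {
  set.seed(8)
  depths <- matrix(runif(100, 0.5, 8), 10, 10)
  d <- depth_to_disparity(depths, camera_intrinsics(160, 0.75), 128)
  ord <- order(depths)
  expect_true(all(diff(d[ord]) <= 0))
})

test_that("UV-disparity maps match a brute-force histogram and conserve counts", {
  set.seed(9)
  vals <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
  vals[1, 1] <- NA
  dmap <- make_dmap(vals, n_levels = 8)
  uv <- build_uv_disparity(dmap)

  v_ref <- matrix(0L, 8, 8); u_ref <- matrix(0L, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    d <- dmap[i, j]
    if (!is.na(d)) {
      v_ref[i, d + 1] <- v_ref[i, d + 1] + 1L
      u_ref[d + 1, j] <- u_ref[d + 1, j] + 1L
    }
  }
  expect_identical(uv$v_map, v_ref)
  expect_identical(uv$u_map, u_ref)
  expect_equal(sum(uv$v_map), sum(!is.na(dmap)))
  expect_equal(sum(uv$u_map), sum(!is.na(dmap)))

  # constant-disparity image: the V-map column holds the full width per row
  dc <- make_dmap(matrix(3L, 5, 12), 8)
  uvc <- build_uv_disparity(dc)
  expect_true(all(uvc$v_map[, 4] == 12L))
})

test_that("the ground correlation line recovers the floor of a rendered room", {
  spec <- scene_spec(camera_tilt = 25, static_objects = list())
  sq <- render_empty_frame(spec)
  bg <- build_background(rep(sq$frames, 30))
  regions <- extract_regions(bg, pipeline_config())
  gt <- sq$truth$region_map$labels
  sc <- mask_scores(regions$labels, gt, "floor")
  expect_gte(sc[["precision"]], 0.9)
  expect_gte(sc[["recall"]], 0.9)
  # nearer floor (bottom rows) has larger disparity
  line <- regions$floor_line
  expect_gt(line[["slope"]], 0)
  expect_gt(line[["slope"]] * 170 + line[["intercept"]],
            line[["slope"]] * 100 + line[["intercept"]])
})

test_that("a pure vertical wall yields no ground line", {
  dmap <- make_dmap(matrix(30L, 60, 80), 128)
  uv <- build_uv_disparity(dmap)
  expect_warning(fl <- extract_floor(uv, dmap), "no ground correlation line")
  expect_false(any(fl$floor_mask))
})

test_that("bed extraction selects the dominant component and its window", {
  # two blocks at distinct disparities; the "bed" is 10x larger
  vals <- matrix(NA_integer_, 60, 80)
  vals[10:39, 5:64] <- 40L      # 1800 px
  vals[50:52, 10:69] <- 70L     # 180 px
  dmap <- make_dmap(vals, 128)
  bd <- extract_bed(dmap, binarize_count = 20)
  expect_equal(unname(bd$bed_extremes),
               c(10, 39, 40, 40))
  expect_true(all(which(bd$bed_mask) == which(vals == 40L)))

  empty <- make_dmap(matrix(NA_integer_, 10, 10), 128)
  expect_warning(b0 <- extract_bed(empty), "no bed region")
  expect_false(any(b0$bed_mask))
})

test_that("the region map is an exhaustive partition with floor precedence", {
  f <- matrix(FALSE, 5, 5); b <- matrix(FALSE, 5, 5)
  rm0 <- build_region_map(f, b)
  expect_true(all(rm0$labels == "ignored"))

  f[1:2, ] <- TRUE; b[4:5, ] <- TRUE
  rm1 <- build_region_map(f, b)
  expect_true(all(rm1$labels[1:2, ] == "floor"))
  expect_true(all(rm1$labels[4:5, ] == "bed"))
  expect_true(all(rm1$labels[3, ] == "ignored"))

  b[2, ] <- TRUE   # overlap resolves to floor
  rm2 <- suppressMessages(build_region_map(f, b))
  expect_true(all(rm2$labels[2, ] == "floor"))
})

test_that("blob localization applies the 70% bed / 30% floor rules in order", {
  labels <- matrix("ignored", 10, 10)
  labels[1:5, ] <- "bed"
  labels[6:9, ] <- "floor"
  regions <- structure(list(labels = labels), class = "region_map")

  blob <- matrix(FALSE, 10, 10)
  blob[1:4, 1:10] <- TRUE; blob[6, 1:10] <- TRUE   # 80% bed
  expect_equal(localize_blob(blob, regions), "bed")

  blob2 <- matrix(FALSE, 10, 10)                    # 50% bed, 40% floor
  blob2[1:5, 1:8] <- TRUE; blob2[6:9, 1:8] <- TRUE
  blob2[10, 1:8] <- TRUE                            # plus 10% ignored
  expect_equal(localize_blob(blob2, regions), "floor")

  blob3 <- matrix(FALSE, 10, 10)                    # ~14% bed, ~14% floor
  blob3[5, 1:2] <- TRUE; blob3[6, 1:2] <- TRUE
  blob3[10, 1:10] <- TRUE
  expect_equal(localize_blob(blob3, regions), "other")

  expect_error(localize_blob(matrix(FALSE, 10, 10), regions), "empty blob")
})

test_that("curtain removal takes the U-disparity line but spares the person", {
  vals <- matrix(NA_integer_, 180, 320)
  cols <- 1:320
  curt_d <- as.integer(round(20 + 0.05 * cols))
  for (j in cols) vals[30:150, j] <- curt_d[j]      # slanted flat surface
  vals[60:120, 150:180] <- 60L                      # person blob in front
  dmap <- make_dmap(vals, 128)
  cmask <- detect_curtain(dmap)
  curt_px <- !is.na(vals) & vals != 60L
  person_px <- !is.na(vals) & vals == 60L
  expect_gte(sum(cmask & curt_px) / sum(curt_px), 0.8)
  expect_lte(sum(cmask & person_px) / sum(person_px), 0.05)

  # person blob alone is too compact to form a curtain line
  vals2 <- matrix(NA_integer_, 180, 320)
  vals2[60:120, 150:180] <- 60L
  expect_false(any(detect_curtain(make_dmap(vals2, 128))))

  # empty foreground
  expect_false(any(detect_curtain(make_dmap(matrix(NA_integer_, 20, 20), 128))))
})
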