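geom_default <- imaging_geometry()

test_that("pixel-to-isocenter conversion follows the divergent-beam formula", {
  expect_equal(
    pixel_to_isocenter_mm(15, imaging_geometry(1000, 1500, 0.336)),
    15 * 0.336 * 1000 / 1500
  )
  expect_equal(
    pixel_to_isocenter_mm(15, imaging_geometry(1000, 1500, 0.336)),
    3.36,
    tolerance = 1e-12
  )
  # SID = SAD: scale factor is exactly the pixel pitch
  g <- imaging_geometry(1000, 1000, 0.5)
  expect_identical(pixel_to_isocenter_mm(7, g), 7 * 0.5)
  expect_identical(pixel_to_isocenter_mm(0, geom_default), 0)
  # strictly increasing in pixel displacement
  d <- pixel_to_isocenter_mm(seq(-5, 5, by = 0.5), geom_default)
  expect_true(all(diff(d) > 0))
  expect_error(imaging_geometry(1500, 1000), "sid_mm >= sad_mm")
  expect_error(imaging_geometry(1000, 1500, 0), "pixel_pitch_mm")
})

test_that("noise-free bb detection is sub-0.1 px and matches the centroid oracle", {
  img <- render_mv_image(c(120.00, 80.50), geom_default, size_px = c(256L, 256L))
  det <- detect_bb_center(img)
  expect_lt(abs(det$row_px - 120.00), 0.1)
  expect_lt(abs(det$col_px - 80.50), 0.1)
  expect_gte(det$score, 0.5)
  expect_lte(det$score, 1)
  orc <- oracle_centroid(img$pixels)
  expect_lt(abs(det$row_px - orc[1]), 0.05)
  expect_lt(abs(det$col_px - orc[2]), 0.05)
  # the plain threshold-centroid fallback agrees
  det2 <- detect_bb_center_threshold(img)
  expect_lt(abs(det2$row_px - det$row_px), 0.2)
  expect_lt(abs(det2$col_px - det$col_px), 0.2)
})

test_that("detection is equivariant under mirroring and translation", {
  img <- render_mv_image(c(60.3, 70.8), geom_default, size_px = c(128L, 128L))
  det <- detect_bb_center(img)
  mirrored <- mv_image(img$pixels[, ncol(img$pixels):1], geom_default)
  det_m <- detect_bb_center(mirrored)
  expect_lt(abs(det_m$col_px - (ncol(img$pixels) - 1 - det$col_px)), 0.1)
  expect_lt(abs(det_m$row_px - det$row_px), 0.1)

  withr::with_seed(601, {
    for (rep in 1:5) {
      dr <- runif(1, -15, 15)
      dc <- runif(1, -15, 15)
      img2 <- render_mv_image(c(60.3 + dr, 70.8 + dc), geom_default,
        size_px = c(128L, 128L)
      )
      det2 <- detect_bb_center(img2)
      expect_lt(abs((det2$row_px - det$row_px) - dr), 0.1)
      expect_lt(abs((det2$col_px - det$col_px) - dc), 0.1)
    }
  })
})

test_that("images without a bb raise detection-failed errors", {
  expect_error(
    detect_bb_center(mv_image(matrix(0.5, 128, 128), geom_default)),
    "detection failed"
  )
  withr::with_seed(602, {
    px <- matrix(0.6 + rnorm(128 * 128, 0, 0.03), 128)
    px[px < 0] <- 0
    px[px > 1] <- 1
    expect_error(
      detect_bb_center(mv_image(px, geom_default)),
      "detection failed"
    )
  })
  expect_error(
    detect_bb_center(mv_image(matrix(0.5, 10, 10), geom_default)),
    "too small"
  )
})

test_that("image offsets recover simulated couch shifts at both gantries", {
  # lat +10 mm at gantry 0
  ref0 <- render_mv_image(c(95.5, 95.5), geom_default,
    gantry_deg = 0,
    step_index = 1L, size_px = c(192L, 192L)
  )
  ctr <- sgrtdynqa:::project_delta_to_px(
    as_pose6dof(c(lat_mm = 10)), 0, geom_default, c(192L, 192L)
  )
  meas0 <- render_mv_image(ctr, geom_default,
    gantry_deg = 0, step_index = 2L,
    size_px = c(192L, 192L)
  )
  off <- compute_image_offsets(
    detect_bb_center(ref0), ref0,
    list(detect_bb_center(meas0)), list(meas0)
  )
  expect_equal(off$lat_mm, 10, tolerance = 0.005)
  expect_equal(off$lng_mm, 0, tolerance = 0.05)
  expect_true(is.na(off$vrt_mm))

  # vrt +50 mm at gantry 90 (wide detector field)
  ref90 <- render_mv_image(c(255.5, 255.5), geom_default,
    gantry_deg = 90,
    step_index = 3L, size_px = c(512L, 512L)
  )
  ctr90 <- sgrtdynqa:::project_delta_to_px(
    as_pose6dof(c(vrt_mm = 50)), 90, geom_default, c(512L, 512L)
  )
  meas90 <- render_mv_image(ctr90, geom_default,
    gantry_deg = 90,
    step_index = 4L, size_px = c(512L, 512L)
  )
  off90 <- compute_image_offsets(
    detect_bb_center(ref90), ref90,
    list(detect_bb_center(meas90)), list(meas90)
  )
  expect_equal(off90$vrt_mm, 50, tolerance = 0.005)
  expect_true(is.na(off90$lat_mm))

  # zero displacement -> zero offset
  off_zero <- compute_image_offsets(
    detect_bb_center(ref0), ref0,
    list(detect_bb_center(ref0)), list(ref0)
  )
  expect_equal(off_zero$lat_mm, 0)
  expect_equal(off_zero$lng_mm, 0)
})

test_that("unsupported geometries are rejected", {
  img45 <- render_mv_image(c(95.5, 95.5), geom_default,
    gantry_deg = 45,
    size_px = c(192L, 192L)
  )
  ref <- render_mv_image(c(95.5, 95.5), geom_default,
    gantry_deg = 0,
    size_px = c(192L, 192L)
  )
  d <- detect_bb_center(ref)
  expect_error(
    compute_image_offsets(d, ref, list(d), list(img45)),
    "unsupported gantry angle"
  )
  img90 <- render_mv_image(c(95.5, 95.5), geom_default,
    gantry_deg = 90,
    size_px = c(192L, 192L)
  )
  expect_error(
    compute_image_offsets(d, ref, list(d), list(img90)),
    "separate reference per gantry"
  )
})

test_that("end-to-end projection closure holds for a zero-noise session", {
  plan <- tiny_plan()
  ses <- simulate_session(plan, sim_zero(17))
  offs <- offsets_from_images(ses$images, plan)
  st <- plan$steps
  for (i in seq_len(nrow(offs))) {
    srow <- st[st$index == offs$step_index[i], ]
    ax <- sgrtdynqa:::step_moved_axis(srow)
    expect_lt(abs(offs[[ax]][i] - srow[[ax]]), 0.1)
  }
})

test_that("offsets_from_images requires a reference image per gantry", {
  plan <- tiny_plan()
  ses <- simulate_session(plan, sim_zero(18))
  moved <- vapply(ses$images, function(im) {
    srow <- plan$steps[plan$steps$index == im$step_index, ]
    !is.na(sgrtdynqa:::step_moved_axis(srow))
  }, logical(1))
  expect_error(
    offsets_from_images(ses$images[moved], plan),
    "no delta-zero reference image"
  )
})
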