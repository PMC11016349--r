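# bb detection in MV portal images and conversion of projected
# displacements to couch-axis millimetres at the isocenter plane.
#
# Pixel coordinate convention: (0, 0) is the center of the top-left pixel,
# rows increase downward, columns rightward; sub-pixel centers are
# continuous pixel units. Detector orientation convention (validated
# against the simulator's ground truth):
#   gantry  0: +column <-> +lateral,  +row <-> +longitudinal
#   gantry 90: +column <-> +vertical, +row <-> +longitudinal
# The bb is radio-opaque, so it projects as a dark disc on the bright
# open-field background.

#' Imaging geometry
#'
#' @param sad_mm Source-to-axis distance (mm).
#' @param sid_mm Source-to-imager distance (mm); must be >= `sad_mm`.
#' @param pixel_pitch_mm Detector pixel size at the imager plane (mm).
#' @return Object of class `imaging_geometry`.
#' @export
imaging_geometry <- function(sad_mm = 1000, sid_mm = 1500,
                             pixel_pitch_mm = 0.336) {
  if (!(sid_mm >= sad_mm && sad_mm > 0)) {
    stop("imaging geometry requires sid_mm >= sad_mm > 0", call. = FALSE)
  }
  if (pixel_pitch_mm <= 0) {
    stop("imaging geometry requires pixel_pitch_mm > 0", call. = FALSE)
  }
  structure(
    list(sad_mm = sad_mm, sid_mm = sid_mm, pixel_pitch_mm = pixel_pitch_mm),
    class = "imaging_geometry"
  )
}

#' Construct an MV image
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]` (rows = detector
#'   rows).
#' @param geometry An [imaging_geometry()], or individual values via the
#'   `...` fields below.
#' @param gantry_deg Gantry angle at acquisition (deg).
#' @param step_index Associated motion-plan step (`NA` for free images).
#' @return Object of class `mv_image`.
#' @export
mv_image <- function(pixels, geometry = imaging_geometry(), gantry_deg = 0,
                     step_index = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || !length(pixels)) {
    stop("mv_image: pixels must be a non-empty numeric matrix", call. = FALSE)
  }
  stopifnot(inherits(geometry, "imaging_geometry"))
  structure(
    list(
      pixels = pixels,
      pixel_pitch_mm = geometry$pixel_pitch_mm,
      sid_mm = geometry$sid_mm,
      sad_mm = geometry$sad_mm,
      gantry_deg = gantry_deg,
      step_index = step_index
    ),
    class = "mv_image"
  )
}

#' @export
print.mv_image <- function(x, ...) {
  cat("<mv_image> ", nrow(x$pixels), "x", ncol(x$pixels),
    " px @ ", x$pixel_pitch_mm, " mm, gantry ", x$gantry_deg,
    " deg, step ", x$step_index, "\n",
    sep = ""
  )
  invisible(x)
}

image_geometry <- function(img) {
  imaging_geometry(img$sad_mm, img$sid_mm, img$pixel_pitch_mm)
}

# Projected bb radius in pixels.
projected_radius_px <- function(img, bb_diameter_mm) {
  (bb_diameter_mm / 2) * img$sid_mm / img$sad_mm / img$pixel_pitch_mm
}

#' Convert a detector pixel displacement to millimetres at the isocenter
#'
#' Standard divergent-beam demagnification:
#' `delta_px * pixel_pitch_mm * sad_mm / sid_mm`. When SID equals SAD the
#' scale factor is exactly the pixel pitch.
#'
#' @param delta_px Pixel displacement (any sign, vectorized).
#' @param img An [mv_image()] or [imaging_geometry()].
#' @return Displacement in mm at the isocenter plane.
#' @export
#' @examples
#' pixel_to_isocenter_mm(15, imaging_geometry(1000, 1500, 0.336))
pixel_to_isocenter_mm <- function(delta_px, img) {
  delta_px * img$pixel_pitch_mm * img$sad_mm / img$sid_mm
}

#' Detect the bb center in an MV image
#'
#' Background-subtracted matched filtering with a projected-disc template,
#' followed by an iterated intensity-weighted sub-pixel centroid over a
#' circular mask around the correlation peak. Deterministic for fixed
#' input. If no candidate exceeds the correlation floor (peak robust
#' z-score below `min_peak_z`, or template correlation below
#' `min_template_cor`), a detection-failed error is raised so QA flags the
#' image rather than guessing.
#'
#' @param img An [mv_image()]; the bb projection must lie fully inside the
#'   image.
#' @param bb_diameter_mm Physical bb diameter (mm); the projected diameter
#'   is `bb_diameter_mm * sid_mm / sad_mm`.
#' @param min_peak_z Robust z-score floor for the matched-filter peak.
#' @param min_template_cor Pearson correlation floor between the local
#'   patch and the disc template.
#' @param centroid_iterations Recentering iterations for the masked
#'   centroid.
#' @return Object of class `bb_detection`: `row_px`, `col_px` (0-based
#'   sub-pixel center), and `score` in `[0, 1]`.
#' @export
detect_bb_center <- function(img, bb_diameter_mm = 5, min_peak_z = 8,
                             min_template_cor = 0.5,
                             centroid_iterations = 3L) {
  px <- img$pixels
  r_px <- projected_radius_px(img, bb_diameter_mm)
  t_half <- ceiling(r_px) + 2L
  t_size <- 2L * t_half + 1L
  margin <- t_half + 1L
  if (nrow(px) < t_size + 2L * margin || ncol(px) < t_size + 2L * margin) {
    stop("detection failed: image too small for the projected bb template",
      call. = FALSE
    )
  }

  # radio-opaque bb: invert so the bb is a positive blob on ~zero background
  d <- stats::median(px) - px

  tc <- t_half # template center (1-based offset t_half+1)
  dist_t <- sqrt(outer((-tc:tc)^2, (-tc:tc)^2, "+"))
  template <- disc_profile(dist_t, r_px)
  m <- EBImage::filter2(d, template / sum(template), boundary = "replicate")

  interior <- m
  interior[seq_len(margin), ] <- -Inf
  interior[(nrow(m) - margin + 1L):nrow(m), ] <- -Inf
  interior[, seq_len(margin)] <- -Inf
  interior[, (ncol(m) - margin + 1L):ncol(m)] <- -Inf
  peak_idx <- which.max(interior)
  peak_r <- (peak_idx - 1L) %% nrow(m) + 1L
  peak_c <- (peak_idx - 1L) %/% nrow(m) + 1L
  finite_m <- m[is.finite(interior)]
  z <- (m[peak_r, peak_c] - stats::median(finite_m)) /
    (stats::mad(finite_m) + 1e-12)
  if (!is.finite(z) || z < min_peak_z) {
    stop(sprintf(
      "detection failed: no candidate above correlation floor (peak z = %.2f)",
      if (is.finite(z)) z else 0
    ), call. = FALSE)
  }

  patch <- d[(peak_r - t_half):(peak_r + t_half), (peak_c - t_half):(peak_c + t_half)]
  if (stats::sd(patch) == 0) {
    stop("detection failed: no candidate above correlation floor (flat patch)",
      call. = FALSE
    )
  }
  template_cor <- stats::cor(as.vector(patch), as.vector(template))
  if (!is.finite(template_cor) || template_cor < min_template_cor) {
    stop(sprintf(
      "detection failed: template correlation %.2f below floor %.2f",
      template_cor, min_template_cor
    ), call. = FALSE)
  }

  # iterated masked centroid; mask radius r + 3 px keeps the soft edge
  # fully inside while bounding the noise lever arm
  w_half <- ceiling(r_px) + 4L
  rows <- (peak_r - w_half):(peak_r + w_half)
  cols <- (peak_c - w_half):(peak_c + w_half)
  rows <- rows[rows >= 1L & rows <= nrow(d)]
  cols <- cols[cols >= 1L & cols <= ncol(d)]
  local <- d[rows, cols, drop = FALSE]
  rr <- matrix(rows - 1, nrow = length(rows), ncol = length(cols)) # 0-based
  cc <- matrix(cols - 1, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  est <- c(peak_r - 1, peak_c - 1)
  mask_r <- r_px + 3
  for (it in seq_len(centroid_iterations)) {
    inside <- (rr - est[1])^2 + (cc - est[2])^2 <= mask_r^2
    w <- pmax(local, 0) * inside
    sw <- sum(w)
    if (sw <= 0) {
      stop("detection failed: empty centroid window", call. = FALSE)
    }
    est <- c(sum(rr * w), sum(cc * w)) / sw
  }
  if (est[1] < 0 || est[1] > nrow(px) - 1 || est[2] < 0 || est[2] > ncol(px) - 1) {
    stop("detection failed: centroid outside image bounds", call. = FALSE)
  }
  structure(
    list(
      row_px = est[1], col_px = est[2],
      score = max(0, min(1, template_cor))
    ),
    class = "bb_detection"
  )
}

#' Plain threshold-centroid bb detector
#'
#' Simple cross-check for [detect_bb_center()]: background-subtract,
#' threshold at half the peak contrast, and take the intensity-weighted
#' centroid of the surviving pixels. Less robust than the matched filter;
#' intended for validation, not production use.
#'
#' @inheritParams detect_bb_center
#' @param min_contrast Minimum peak contrast (background minus bb level)
#'   required to accept a detection.
#' @return A `bb_detection`.
#' @export
detect_bb_center_threshold <- function(img, min_contrast = 0.05) {
  d <- stats::median(img$pixels) - img$pixels
  peak <- max(d)
  if (peak < min_contrast) {
    stop("detection failed: contrast below floor", call. = FALSE)
  }
  mask <- d > peak / 2
  w <- d * mask
  rr <- matrix(seq_len(nrow(d)) - 1, nrow(d), ncol(d))
  cc <- matrix(seq_len(ncol(d)) - 1, nrow(d), ncol(d), byrow = TRUE)
  structure(
    list(
      row_px = sum(rr * w) / sum(w), col_px = sum(cc * w) / sum(w),
      score = NA_real_
    ),
    class = "bb_detection"
  )
}

#' @export
print.bb_detection <- function(x, ...) {
  cat(sprintf(
    "<bb_detection> row %.3f, col %.3f px (score %.3f)\n",
    x$row_px, x$col_px, x$score
  ))
  invisible(x)
}

supported_gantry <- function(gantry_deg, tol = 0.5) {
  g <- normalize_angle_deg(gantry_deg)
  if (abs(g) <= tol) {
    return(0)
  }
  if (abs(g - 90) <= tol) {
    return(90)
  }
  stop("unsupported gantry angle ", gantry_deg,
    " deg: image offsets are defined at gantry 0 and 90 only",
    call. = FALSE
  )
}

# Couch axes visible on the detector at a supported gantry angle:
# c(column axis, row axis).
gantry_image_axes <- function(gantry) {
  if (gantry == 0) c("lat_mm", "lng_mm") else c("vrt_mm", "lng_mm")
}

#' Convert bb detections into couch-axis offsets at the isocenter
#'
#' For each measurement image, the pixel displacement of the bb relative to
#' the reference detection (taken at the same gantry angle) is demagnified
#' via [pixel_to_isocenter_mm()] and mapped to the two couch axes visible
#' at that gantry angle (gantry 0: columns = lateral, rows = longitudinal;
#' gantry 90: columns = vertical, rows = longitudinal).
#'
#' @param reference A `bb_detection` for the reference image.
#' @param reference_img The reference [mv_image()].
#' @param detections List of `bb_detection`s for the measurement images.
#' @param images List of the corresponding [mv_image()]s (same order).
#' @return Data frame with one row per measurement: `step_index`,
#'   `gantry_deg`, and the six pose-axis columns, with exactly the two
#'   visible translation axes populated and all others `NA`.
#' @export
compute_image_offsets <- function(reference, reference_img, detections, images) {
  if (length(detections) != length(images)) {
    stop("detections and images must have the same length", call. = FALSE)
  }
  ref_gantry <- supported_gantry(reference_img$gantry_deg)
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    det <- detections[[i]]
    g <- supported_gantry(img$gantry_deg)
    if (g != ref_gantry) {
      stop(
        "unsupported geometry: measurement at gantry ", g,
        " compared against reference at gantry ", ref_gantry,
        " (a separate reference per gantry angle is required)",
        call. = FALSE
      )
    }
    col_mm <- pixel_to_isocenter_mm(det$col_px - reference$col_px, img)
    row_mm <- pixel_to_isocenter_mm(det$row_px - reference$row_px, img)
    axes <- gantry_image_axes(g)
    row <- data.frame(
      step_index = img$step_index, gantry_deg = g,
      lat_mm = NA_real_, lng_mm = NA_real_, vrt_mm = NA_real_,
      yaw_deg = NA_real_, pitch_deg = NA_real_, roll_deg = NA_real_
    )
    row[[axes[1]]] <- col_mm
    row[[axes[2]]] <- row_mm
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Detect and convert all images of a session against a plan
#'
#' Convenience wrapper: identifies the delta-zero reference image at each
#' gantry angle from the plan, detects the bb in every image, and computes
#' isocenter offsets for every moved imaging step.
#'
#' @param images List of [mv_image()]s with `step_index` set.
#' @param plan The generating [motion_plan()].
#' @param bb_diameter_mm Physical bb diameter (mm).
#' @param ... Passed to [detect_bb_center()].
#' @return As [compute_image_offsets()], rows ordered by step index.
#' @export
offsets_from_images <- function(images, plan, bb_diameter_mm = 5, ...) {
  if (!length(images)) {
    return(NULL)
  }
  st <- plan$steps
  idx_of <- vapply(images, function(im) as.integer(im$step_index), integer(1))
  if (any(is.na(idx_of)) || !all(idx_of %in% st$index)) {
    stop("consistency error: image step indices do not match the plan",
      call. = FALSE
    )
  }
  deltas <- st[match(idx_of, st$index), POSE_AXES, drop = FALSE]
  moved <- rowSums(deltas != 0) > 0
  dets <- lapply(images, detect_bb_center, bb_diameter_mm = bb_diameter_mm, ...)

  out <- list()
  for (g in c(0, 90)) {
    at_g <- vapply(images, function(im) {
      isTRUE(all.equal(supported_gantry(im$gantry_deg), g))
    }, logical(1))
    meas <- which(at_g & moved)
    if (!length(meas)) next
    ref_i <- which(at_g & !moved)
    if (!length(ref_i)) {
      stop("consistency error: no delta-zero reference image at gantry ", g,
        call. = FALSE
      )
    }
    out[[length(out) + 1L]] <- compute_image_offsets(
      dets[[ref_i[1]]], images[[ref_i[1]]],
      dets[meas], images[meas]
    )
  }
  if (!length(out)) {
    return(NULL)
  }
  res <- do.call(rbind, out)
  res[order(res$step_index), , drop = FALSE]
}
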