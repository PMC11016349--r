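# 6-DoF couch/surface pose: three translations (mm) and three rotations (deg).
# Axis order is fixed package-wide; translations follow IEC 61217
# (lat = X, lng = Y, vrt = Z), rotations are couch yaw (table rotation),
# pitch, and roll.

#' Canonical 6-DoF axis names
#'
#' Returns the axis names used throughout the package for couch and surface
#' poses, in canonical order: three translations in millimetres
#' (`lat_mm`, `lng_mm`, `vrt_mm`, IEC 61217 X/Y/Z) followed by three
#' rotations in degrees (`yaw_deg`, `pitch_deg`, `roll_deg`).
#'
#' @param kind `"all"` (default), `"translation"`, or `"rotation"`.
#' @return Character vector of axis names.
#' @export
#' @examples
#' pose_axes()
#' pose_axes("rotation")
pose_axes <- function(kind = c("all", "translation", "rotation")) {
  switch(match.arg(kind),
    all = POSE_AXES,
    translation = TRANSLATION_AXES,
    rotation = ROTATION_AXES
  )
}

#' Construct a 6-DoF pose
#'
#' A pose is a named numeric vector with one element per axis (see
#' [pose_axes()]). Translations are millimetres, rotations degrees.
#' Rotations are normalized to the half-open interval (-180, 180].
#'
#' @param lat_mm,lng_mm,vrt_mm Translations along the lateral, longitudinal,
#'   and vertical couch axes (mm).
#' @param yaw_deg,pitch_deg,roll_deg Rotations about the vertical,
#'   lateral, and longitudinal axes (deg).
#' @return Named numeric vector of length 6.
#' @export
#' @examples
#' pose6dof(lat_mm = 10)
pose6dof <- function(lat_mm = 0, lng_mm = 0, vrt_mm = 0,
                     yaw_deg = 0, pitch_deg = 0, roll_deg = 0) {
  p <- c(
    lat_mm = lat_mm, lng_mm = lng_mm, vrt_mm = vrt_mm,
    yaw_deg = yaw_deg, pitch_deg = pitch_deg, roll_deg = roll_deg
  )
  if (!all(is.finite(p))) {
    stop("pose6dof: all components must be finite", call. = FALSE)
  }
  p[ROTATION_AXES] <- normalize_angle_deg(p[ROTATION_AXES])
  p
}

#' Coerce to a 6-DoF pose
#'
#' Accepts a named numeric vector or list carrying any subset of the
#' canonical axis names; missing axes default to zero.
#'
#' @param x Named numeric vector or list.
#' @return Named numeric vector of length 6 (see [pose6dof()]).
#' @export
as_pose6dof <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) && length(x) == 6L) names(x) <- POSE_AXES
  unknown <- setdiff(names(x), POSE_AXES)
  if (length(unknown)) {
    stop("as_pose6dof: unknown axis name(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  p <- stats::setNames(numeric(6), POSE_AXES)
  p[names(x)] <- as.numeric(x)
  do.call(pose6dof, as.list(p))
}

#' Normalize angles to (-180, 180] degrees
#'
#' @param a Numeric vector of angles in degrees.
#' @return Angles mapped into the half-open interval (-180, 180].
#' @export
#' @examples
#' normalize_angle_deg(c(270, -180, 180))
normalize_angle_deg <- function(a) {
  r <- (a + 180) %% 360 - 180
  r[r == -180] <- 180
  r
}

# Wrap-safe mean of angles in degrees. All planned rotations are <= 3 deg so
# the plain mean is exact in practice; the circular fallback only engages if
# the sample spread straddles the +/-180 wrap.
mean_angle_deg <- function(a) {
  a <- normalize_angle_deg(a)
  if (length(a) == 0L) return(NaN)
  if (max(a) - min(a) > 180) {
    a <- ifelse(a < 0, a + 360, a)
  }
  normalize_angle_deg(mean(a))
}

# Smallest signed angular difference a - b in degrees.
angle_diff_deg <- function(a, b) {
  normalize_angle_deg(a - b)
}
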