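# QA motion plan: an ordered sequence of single-axis couch offsets with the
# gantry angle, MU, and imaging directive for each step. Step deltas are
# absolute offsets from the reference pose (the couch returns through zero
# between axes), so the cumulative pose after any step is reference + delta.

PLAN_SCHEMA_VERSION <- "1.0"

STEP_COLUMNS <- c(
  "index", POSE_AXES, "gantry_deg", "acquire_mv", "mu"
)

#' Construct a motion plan
#'
#' Low-level constructor; most users will call [build_motion_plan()].
#'
#' @param reference Absolute starting couch pose ([pose6dof()]).
#' @param steps Data frame with columns `index`, the six axis deltas (see
#'   [pose_axes()]), `gantry_deg`, `acquire_mv`, `mu`. Deltas are offsets
#'   from `reference`.
#' @param metadata Named list; `label`, `created`, `schema_version`, and
#'   `convention` are used by the XML renderer.
#' @return Object of class `motion_plan`.
#' @export
motion_plan <- function(reference = pose6dof(), steps = empty_steps(),
                        metadata = list()) {
  reference <- as_pose6dof(reference)
  if (!is.data.frame(steps)) stop("steps must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(STEP_COLUMNS, names(steps))
  if (length(missing_cols)) {
    stop("steps is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  steps <- steps[STEP_COLUMNS]
  steps$index <- as.integer(steps$index)
  steps$acquire_mv <- as.logical(steps$acquire_mv)
  rownames(steps) <- NULL
  metadata$schema_version <- metadata$schema_version %||% PLAN_SCHEMA_VERSION
  structure(
    list(reference = reference, steps = steps, metadata = metadata),
    class = "motion_plan"
  )
}

empty_steps <- function() {
  data.frame(
    index = integer(0),
    lat_mm = numeric(0), lng_mm = numeric(0), vrt_mm = numeric(0),
    yaw_deg = numeric(0), pitch_deg = numeric(0), roll_deg = numeric(0),
    gantry_deg = numeric(0), acquire_mv = logical(0), mu = numeric(0)
  )
}

step_row <- function(index, delta = pose6dof(), gantry_deg = 0,
                     acquire_mv = FALSE, mu = 0) {
  delta <- as_pose6dof(delta)
  data.frame(
    index = as.integer(index),
    lat_mm = delta[["lat_mm"]], lng_mm = delta[["lng_mm"]],
    vrt_mm = delta[["vrt_mm"]], yaw_deg = delta[["yaw_deg"]],
    pitch_deg = delta[["pitch_deg"]], roll_deg = delta[["roll_deg"]],
    gantry_deg = gantry_deg, acquire_mv = acquire_mv, mu = mu
  )
}

#' Build the monthly dynamic-localization QA motion plan
#'
#' Constructs the standard sequence: an MV reference image at the starting
#' position, lateral then longitudinal couch offsets at gantry 0 with an MV
#' image and beam delivery at each position, a reference image and the same
#' offsets on the vertical axis at gantry 90, then yaw/pitch/roll sweeps at
#' gantry 0. With defaults the translation offsets are
#' -50, -10, +10, +50 mm per axis and the rotations sweep -3 to +3 degrees
#' in 0.5-degree increments (zero skipped; 12 steps per rotation axis).
#'
#' Each step's delta is an absolute offset from the reference pose and moves
#' exactly one axis; the plan ends with an explicit return to the reference.
#' Rotation steps acquire no MV image (a single-bb phantom cannot resolve
#' rotations radiographically) but do deliver a beam-on dwell so that every
#' couch position can be averaged over beam-on time.
#'
#' @param translations_mm Nonzero finite offsets applied, in order, to the
#'   lateral and longitudinal axes at gantry 0 and the vertical axis at
#'   gantry 90. May be empty.
#' @param rotation_range_deg Maximum rotation magnitude per axis (deg);
#'   0 disables rotation steps.
#' @param rotation_step_deg Rotation increment (deg); must divide
#'   `rotation_range_deg` evenly.
#' @param mu_per_image Monitor units delivered at each imaging position.
#' @param mu_per_rotation Monitor units delivered at each rotation dwell
#'   (defaults to `mu_per_image`; set 0 to skip beam at rotations).
#' @param reference Absolute starting couch pose.
#' @param include_reference_images Acquire delta-zero MV reference images at
#'   each gantry angle used for translations (required downstream by
#'   [compute_image_offsets()]).
#' @param label Free-form plan label stored in the metadata.
#' @return A [motion_plan()].
#' @export
#' @examples
#' plan <- build_motion_plan()
#' nrow(plan$steps)
build_motion_plan <- function(translations_mm = c(-50, -10, 10, 50),
                              rotation_range_deg = 3,
                              rotation_step_deg = 0.5,
                              mu_per_image = 50,
                              mu_per_rotation = mu_per_image,
                              reference = pose6dof(),
                              include_reference_images = TRUE,
                              label = "sgrt-dynqa-monthly") {
  translations_mm <- as.numeric(translations_mm)
  if (length(translations_mm) &&
    (!all(is.finite(translations_mm)) || any(translations_mm == 0))) {
    stop("configuration error: translation offsets must be finite and nonzero",
      call. = FALSE
    )
  }
  if (!is.finite(rotation_range_deg) || rotation_range_deg < 0) {
    stop("configuration error: rotation_range_deg must be finite and >= 0",
      call. = FALSE
    )
  }
  rot_deltas <- numeric(0)
  if (rotation_range_deg > 0) {
    if (!is.finite(rotation_step_deg) || rotation_step_deg <= 0) {
      stop("configuration error: rotation increment must be > 0", call. = FALSE)
    }
    k <- rotation_range_deg / rotation_step_deg
    if (abs(k - round(k)) > 1e-9) {
      stop(
        "configuration error: rotation range ", rotation_range_deg,
        " is not a multiple of increment ", rotation_step_deg,
        call. = FALSE
      )
    }
    pos <- seq(rotation_step_deg, rotation_range_deg, by = rotation_step_deg)
    rot_deltas <- c(-rev(pos), pos) # monotone sweep, zero skipped
  }
  if (mu_per_image < 0 || mu_per_rotation < 0) {
    stop("configuration error: MU must be >= 0", call. = FALSE)
  }

  rows <- list()
  idx <- 0L
  add <- function(delta, gantry_deg, acquire_mv, mu) {
    idx <<- idx + 1L
    rows[[length(rows) + 1L]] <<- step_row(idx, delta, gantry_deg, acquire_mv, mu)
  }

  if (length(translations_mm)) {
    if (include_reference_images) {
      add(pose6dof(), 0, TRUE, mu_per_image)
    }
    for (v in translations_mm) add(pose6dof(lat_mm = v), 0, TRUE, mu_per_image)
    for (v in translations_mm) add(pose6dof(lng_mm = v), 0, TRUE, mu_per_image)
    if (include_reference_images) {
      add(pose6dof(), 90, TRUE, mu_per_image)
    }
    for (v in translations_mm) add(pose6dof(vrt_mm = v), 90, TRUE, mu_per_image)
  }
  if (length(rot_deltas)) {
    if (length(translations_mm)) {
      add(pose6dof(), 0, FALSE, 0) # couch and gantry return home first
    }
    for (v in rot_deltas) add(pose6dof(yaw_deg = v), 0, FALSE, mu_per_rotation)
    for (v in rot_deltas) add(pose6dof(pitch_deg = v), 0, FALSE, mu_per_rotation)
    for (v in rot_deltas) add(pose6dof(roll_deg = v), 0, FALSE, mu_per_rotation)
  }
  if (length(rows)) {
    add(pose6dof(), 0, FALSE, 0) # plan returns home
  }

  steps <- if (length(rows)) do.call(rbind, rows) else empty_steps()
  motion_plan(
    reference = reference,
    steps = steps,
    metadata = list(
      label = label,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      schema_version = PLAN_SCHEMA_VERSION,
      convention = paste(
        "IEC 61217 couch axes (lat=X, lng=Y, vrt=Z);",
        "step deltas are absolute offsets from the reference pose;",
        "one axis moves per step; rotations sweep monotonically, zero skipped"
      )
    )
  )
}

#' Validate a motion plan
#'
#' Checks the per-step invariants (finite values, non-negative MU, at most
#' one moved axis, gantry 0 for lateral/longitudinal and rotation steps,
#' gantry 90 for vertical steps, unique indices) and, when `strict = TRUE`,
#' the plan-level home property (first and last step deltas are zero, so the
#' effective pose starts and ends at the reference).
#'
#' @param plan A [motion_plan()].
#' @param strict Also enforce the home property.
#' @return Character vector of violations (empty when valid), each naming
#'   the offending step.
#' @export
validate_motion_plan <- function(plan, strict = FALSE) {
  if (!inherits(plan, "motion_plan")) {
    stop("not a motion_plan", call. = FALSE)
  }
  st <- plan$steps
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  if (anyDuplicated(st$index)) {
    note("duplicate step index: ", paste(unique(st$index[duplicated(st$index)]),
      collapse = ", "
    ))
  }
  num_cols <- c(POSE_AXES, "gantry_deg", "mu")
  for (i in seq_len(nrow(st))) {
    row <- st[i, ]
    if (!all(vapply(num_cols, function(cl) is.finite(row[[cl]]), logical(1)))) {
      note("step ", row$index, ": non-finite value")
      next
    }
    if (row$mu < 0) note("step ", row$index, ": mu must be >= 0")
    moved <- POSE_AXES[vapply(POSE_AXES, function(a) row[[a]] != 0, logical(1))]
    if (length(moved) > 1L) {
      note(
        "step ", row$index, ": more than one axis moved (",
        paste(moved, collapse = ", "), ")"
      )
    }
    if (length(moved) == 1L) {
      if (moved %in% c("lat_mm", "lng_mm") && abs(row$gantry_deg) > 1e-9) {
        note("step ", row$index, ": ", moved, " offsets require gantry 0")
      }
      if (moved == "vrt_mm" && abs(row$gantry_deg - 90) > 1e-9) {
        note("step ", row$index, ": vertical offsets require gantry 90")
      }
      if (moved %in% ROTATION_AXES && abs(row$gantry_deg) > 1e-9) {
        note("step ", row$index, ": rotation steps require gantry 0")
      }
    }
  }
  if (strict && nrow(st)) {
    first_delta <- as.numeric(st[1, POSE_AXES])
    last_delta <- as.numeric(st[nrow(st), POSE_AXES])
    if (any(first_delta != 0)) note("step ", st$index[1], ": plan must start at the reference pose")
    if (any(last_delta != 0)) note("step ", st$index[nrow(st)], ": plan must return to the reference pose")
  }
  problems
}

# Steps that deliver beam, in plan order; these map one-to-one onto the
# beam-on intervals segmented from the trajectory log.
plan_beam_steps <- function(plan) {
  plan$steps[plan$steps$mu > 0, , drop = FALSE]
}

# Single moved axis per step (NA_character_ for delta-zero steps).
step_moved_axis <- function(step_row) {
  moved <- POSE_AXES[vapply(POSE_AXES, function(a) step_row[[a]] != 0, logical(1))]
  if (length(moved) == 0L) NA_character_ else moved[[1L]]
}

#' @export
print.motion_plan <- function(x, ...) {
  st <- x$steps
  cat("<motion_plan> ", x$metadata$label %||% "", "\n", sep = "")
  cat("  steps: ", nrow(st),
    " (", sum(st$acquire_mv), " imaging, ",
    sum(st$mu > 0), " beam-on)\n",
    sep = ""
  )
  cat("  reference: ", paste(sprintf("%s=%g", POSE_AXES, x$reference),
    collapse = " "
  ), "\n", sep = "")
  invisible(x)
}
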