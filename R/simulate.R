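# Synthetic QA sessions with known ground truth: trajectory log, surface
# log, and MV images generated from a motion plan, so every pipeline stage
# is testable without a linac.
#
# Motion model: constant-speed ramps between poses (all moving axes ramp
# simultaneously over the duration of the slowest axis), a quiet
# beam_settle_s gap after motion stops, then a stationary dwell during
# which the cumulative MU ramps linearly. The surface is rigid with the
# phantom, so the true surface offset equals the couch offset (optionally
# scaled per axis to model miscalibration), delayed by surf_latency_s,
# sampled at the surface rate, with independent Gaussian noise per axis
# per sample.

# Soft-edged projected disc: logistic fall-off around radius r. The
# softness models source/detector blur; a soft edge also keeps the
# intensity-weighted centroid of the sampled disc within well under
# 1e-2 px of the true center, which a hard anti-aliased edge does not.
disc_profile <- function(d, r, softness = 0.5) {
  1 / (1 + exp((d - r) / softness))
}

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a 50 Hz trajectory log,
#' a 15 Hz surface stream with 0.05 mm / 0.05 deg Gaussian noise, couch
#' speeds of 20 mm/s and 3 deg/s, a 2 s beam-on dwell delivering the plan's
#' MU at each position, and a 5 mm bb imaged at SAD 1000 / SID 1500 /
#' 0.336 mm pixel pitch.
#'
#' @param seed Integer seed; fixes every stochastic draw (bit-reproducible).
#' @param traj_rate_hz,surf_rate_hz Sampling rates (Hz).
#' @param surf_noise_mm,surf_noise_deg Per-axis Gaussian sigma of the
#'   surface stream (mm / deg).
#' @param surf_latency_s Injected surface reporting latency (s).
#' @param surf_scale Named per-axis scale factors applied to the true
#'   surface offset (all 1 for a calibrated system).
#' @param couch_speed_mm_s,couch_speed_deg_s Couch ramp speeds.
#' @param gantry_speed_deg_s Gantry ramp speed.
#' @param settle_s Stationary lead-in/out (s); must cover the onset
#'   detector's baseline window.
#' @param beam_settle_s Quiet gap between motion and beam-on (s).
#' @param dwell_s Beam-on dwell per position (s); at least two trajectory
#'   samples.
#' @param bb_diameter_mm Physical bb diameter (mm).
#' @param image_noise_sigma Additive Gaussian pixel noise (intensity units).
#' @param image_size_px Image size `c(rows, cols)`.
#' @param bb_contrast Attenuation depth of the bb below background.
#' @param image_background Open-field background intensity in `[0, 1]`.
#' @param edge_softness_px Logistic edge softness of the rendered bb (px).
#' @param geometry An [imaging_geometry()].
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              traj_rate_hz = 50,
                              surf_rate_hz = 15,
                              surf_noise_mm = 0.05,
                              surf_noise_deg = 0.05,
                              surf_latency_s = 0,
                              surf_scale = NULL,
                              couch_speed_mm_s = 20,
                              couch_speed_deg_s = 3,
                              gantry_speed_deg_s = 6,
                              settle_s = 1.5,
                              beam_settle_s = 0.3,
                              dwell_s = 2,
                              bb_diameter_mm = 5,
                              image_noise_sigma = 0.01,
                              image_size_px = c(512L, 512L),
                              bb_contrast = 0.3,
                              image_background = 0.6,
                              edge_softness_px = 0.5,
                              geometry = imaging_geometry()) {
  if (traj_rate_hz <= 0 || surf_rate_hz <= 0) {
    stop("config error: sampling rates must be > 0", call. = FALSE)
  }
  if (surf_noise_mm < 0 || surf_noise_deg < 0 || image_noise_sigma < 0) {
    stop("config error: noise sigmas must be >= 0", call. = FALSE)
  }
  if (couch_speed_mm_s <= 0 || couch_speed_deg_s <= 0 || gantry_speed_deg_s <= 0) {
    stop("config error: speeds must be > 0", call. = FALSE)
  }
  if (dwell_s < 2 / traj_rate_hz) {
    stop("config error: dwell_s shorter than 2 trajectory samples",
      call. = FALSE
    )
  }
  if (is.null(surf_scale)) {
    surf_scale <- stats::setNames(rep(1, 6), POSE_AXES)
  } else {
    surf_scale <- as_surf_scale(surf_scale)
  }
  structure(
    list(
      seed = as.integer(seed),
      traj_rate_hz = traj_rate_hz, surf_rate_hz = surf_rate_hz,
      surf_noise_mm = surf_noise_mm, surf_noise_deg = surf_noise_deg,
      surf_latency_s = surf_latency_s, surf_scale = surf_scale,
      couch_speed_mm_s = couch_speed_mm_s,
      couch_speed_deg_s = couch_speed_deg_s,
      gantry_speed_deg_s = gantry_speed_deg_s,
      settle_s = settle_s, beam_settle_s = beam_settle_s, dwell_s = dwell_s,
      bb_diameter_mm = bb_diameter_mm,
      image_noise_sigma = image_noise_sigma,
      image_size_px = as.integer(image_size_px),
      bb_contrast = bb_contrast, image_background = image_background,
      edge_softness_px = edge_softness_px,
      geometry = geometry
    ),
    class = "simulation_config"
  )
}

as_surf_scale <- function(x) {
  s <- stats::setNames(rep(1, 6), POSE_AXES)
  if (is.null(names(x))) {
    if (length(x) != 6L) stop("surf_scale must be named or length 6", call. = FALSE)
    names(x) <- POSE_AXES
  }
  s[names(x)] <- as.numeric(x)
  s
}

# Piecewise-linear keyframe track of the session: t, six absolute couch
# axes, gantry, cumulative mu.
build_keyframes <- function(plan, config) {
  ref <- plan$reference
  cols <- c("t", POSE_AXES, "gantry", "mu")
  kf <- matrix(0, nrow = 0, ncol = length(cols), dimnames = list(NULL, cols))
  state <- c(ref, gantry = 0, mu = 0)
  t <- 0
  push <- function(t) {
    kf <<- rbind(kf, c(t, state))
  }
  push(0)
  t <- t + config$settle_s
  push(t)
  st <- plan$steps
  for (i in seq_len(nrow(st))) {
    target <- ref + as.numeric(st[i, POSE_AXES])
    names(target) <- POSE_AXES
    d_trans <- abs(target[TRANSLATION_AXES] - state[TRANSLATION_AXES])
    d_rot <- abs(angle_diff_deg(target[ROTATION_AXES], state[ROTATION_AXES]))
    d_gantry <- abs(angle_diff_deg(st$gantry_deg[i], state[["gantry"]]))
    move_t <- max(
      d_trans / config$couch_speed_mm_s,
      d_rot / config$couch_speed_deg_s,
      d_gantry / config$gantry_speed_deg_s
    )
    if (move_t > 0) {
      t <- t + move_t
      state[POSE_AXES] <- target
      state[["gantry"]] <- st$gantry_deg[i]
      push(t)
    }
    t <- t + config$beam_settle_s
    push(t)
    t <- t + config$dwell_s
    state[["mu"]] <- state[["mu"]] + st$mu[i]
    push(t)
    t <- t + config$beam_settle_s
    push(t)
  }
  t <- t + config$settle_s
  push(t)
  kf
}

sample_track <- function(kf, t_query, columns) {
  out <- lapply(columns, function(cl) {
    stats::approx(kf[, "t"], kf[, cl], xout = t_query, rule = 2)$y
  })
  names(out) <- columns
  as.data.frame(out)
}

#' Simulate a complete QA session
#'
#' Generates the trajectory log, surface log, MV images, and a ground-truth
#' record for a motion plan under a [simulation_config()]. Identical
#' `(plan, config)` pairs produce bit-identical output.
#'
#' @param plan A valid [motion_plan()].
#' @param config A [simulation_config()].
#' @param images Render MV images for `acquire_mv` steps (set `FALSE` to
#'   skip the renderer in log-only studies).
#' @return Object of class `qa_session`: `trajectory` ([trajectory_log()]),
#'   `surface` ([surface_log()]), `images` (list of [mv_image()]), and
#'   `truth` (per-step true deltas and beam windows, per-image true pixel
#'   centers, the injected latency, and the seed).
#' @export
simulate_session <- function(plan, config = simulation_config(), images = TRUE) {
  problems <- validate_motion_plan(plan)
  if (length(problems)) {
    stop("invalid motion plan:\n  ", paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  withr::with_seed(config$seed, {
    kf <- build_keyframes(plan, config)
    t_end <- kf[nrow(kf), "t"]

    dt <- 1 / config$traj_rate_hz
    t_traj <- seq(0, by = dt, length.out = floor(t_end / dt) + 1L)
    track <- sample_track(kf, t_traj, c(POSE_AXES, "gantry", "mu"))
    td <- data.frame(t_s = t_traj)
    for (a in POSE_AXES) {
      td[[paste0(a, "_expected")]] <- track[[a]]
      td[[paste0(a, "_actual")]] <- track[[a]]
    }
    td$gantry_deg_expected <- track$gantry
    td$gantry_deg_actual <- track$gantry
    td$mu <- track$mu
    traj <- trajectory_log(dt, td, meta = list(source = "sgrtdynqa-simulator"))

    dts <- 1 / config$surf_rate_hz
    t_surf <- seq(0, by = dts, length.out = floor(t_end / dts) + 1L)
    delayed <- sample_track(kf, t_surf - config$surf_latency_s, POSE_AXES)
    sd_ <- data.frame(t_s = t_surf)
    for (a in POSE_AXES) {
      sigma <- if (a %in% TRANSLATION_AXES) {
        config$surf_noise_mm
      } else {
        config$surf_noise_deg
      }
      true_offset <- (delayed[[a]] - plan$reference[[a]]) * config$surf_scale[[a]]
      sd_[[a]] <- true_offset + stats::rnorm(length(t_surf), 0, sigma)
    }
    surf <- surface_log(sd_, meta = list(source = "sgrtdynqa-simulator"))

    # beam windows per beam-delivering step, in keyframe time
    beam <- plan_beam_steps(plan)
    beam_truth <- NULL
    if (nrow(beam)) {
      mu_kf <- kf[, "mu"]
      ramp_starts <- which(diff(mu_kf) > 0)
      stopifnot(length(ramp_starts) == nrow(beam))
      beam_truth <- data.frame(
        step_index = beam$index,
        beam_start_s = kf[ramp_starts, "t"],
        beam_end_s = kf[ramp_starts + 1L, "t"],
        mu = beam$mu
      )
    }

    img_list <- list()
    img_truth <- NULL
    if (images) {
      img_steps <- plan$steps[plan$steps$acquire_mv, , drop = FALSE]
      rows <- vector("list", nrow(img_steps))
      for (i in seq_len(nrow(img_steps))) {
        step <- img_steps[i, ]
        center <- project_delta_to_px(
          as.numeric(step[POSE_AXES]), step$gantry_deg,
          config$geometry, config$image_size_px
        )
        img_list[[length(img_list) + 1L]] <- render_mv_image(
          center_px = center,
          geometry = config$geometry,
          gantry_deg = step$gantry_deg,
          step_index = step$index,
          size_px = config$image_size_px,
          bb_diameter_mm = config$bb_diameter_mm,
          contrast = config$bb_contrast,
          background = config$image_background,
          noise_sigma = config$image_noise_sigma,
          edge_softness_px = config$edge_softness_px
        )
        rows[[i]] <- data.frame(
          step_index = step$index, gantry_deg = step$gantry_deg,
          row_px = center[1], col_px = center[2]
        )
      }
      if (length(rows)) img_truth <- do.call(rbind, rows)
    }

    truth <- list(
      steps = cbind(
        plan$steps[c("index", POSE_AXES, "gantry_deg", "acquire_mv", "mu")]
      ),
      beam_windows = beam_truth,
      images = img_truth,
      latency_s = config$surf_latency_s,
      surf_scale = config$surf_scale,
      seed = config$seed
    )
    structure(
      list(trajectory = traj, surface = surf, images = img_list, truth = truth),
      class = "qa_session"
    )
  })
}

#' @export
print.qa_session <- function(x, ...) {
  cat("<qa_session> ", nrow(x$trajectory$data), " trajectory samples, ",
    nrow(x$surface$data), " surface samples, ",
    length(x$images), " MV images (seed ", x$truth$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

# Map a single-axis couch delta to the projected bb pixel center (0-based)
# at a supported gantry angle. Uses the documented detector orientation:
# +column = +lat (gantry 0) / +vrt (gantry 90); +row = +lng.
project_delta_to_px <- function(delta, gantry_deg, geometry, size_px) {
  names(delta) <- POSE_AXES
  g <- supported_gantry(gantry_deg)
  axes <- gantry_image_axes(g)
  mag <- geometry$sid_mm / geometry$sad_mm
  center_row <- (size_px[1] - 1) / 2
  center_col <- (size_px[2] - 1) / 2
  c(
    center_row + delta[[axes[2]]] * mag / geometry$pixel_pitch_mm,
    center_col + delta[[axes[1]]] * mag / geometry$pixel_pitch_mm
  )
}

#' Render a synthetic MV image of the bb
#'
#' Forward model for the detector: a soft-edged projected disc of diameter
#' `bb_diameter_mm * sid/sad` at the magnified pixel position, darker than
#' the open-field background by `contrast`, with optional additive
#' Gaussian pixel noise (clamped to `[0, 1]`).
#'
#' @param center_px True bb center `c(row_px, col_px)`, 0-based pixels.
#' @param geometry An [imaging_geometry()].
#' @param gantry_deg,step_index Stored in the [mv_image()] metadata.
#' @param size_px Image size `c(rows, cols)`.
#' @param bb_diameter_mm Physical bb diameter (mm).
#' @param contrast Attenuation depth below background (intensity units).
#' @param background Open-field intensity in `[0, 1]`.
#' @param noise_sigma Additive Gaussian pixel noise sigma.
#' @param edge_softness_px Logistic edge softness (px).
#' @return An [mv_image()].
#' @export
render_mv_image <- function(center_px, geometry = imaging_geometry(),
                            gantry_deg = 0, step_index = NA_integer_,
                            size_px = c(512L, 512L), bb_diameter_mm = 5,
                            contrast = 0.3, background = 0.6,
                            noise_sigma = 0, edge_softness_px = 0.5) {
  r_px <- (bb_diameter_mm / 2) * geometry$sid_mm / geometry$sad_mm /
    geometry$pixel_pitch_mm
  pad <- r_px + 4 * edge_softness_px
  if (center_px[1] < pad || center_px[1] > size_px[1] - 1 - pad ||
    center_px[2] < pad || center_px[2] > size_px[2] - 1 - pad) {
    stop("render error: bb projection outside the detector field",
      call. = FALSE
    )
  }
  px <- matrix(background, nrow = size_px[1], ncol = size_px[2])
  half <- ceiling(r_px + 8 * edge_softness_px)
  rows <- max(1L, floor(center_px[1]) - half):min(size_px[1], ceiling(center_px[1]) + half + 1L)
  cols <- max(1L, floor(center_px[2]) - half):min(size_px[2], ceiling(center_px[2]) + half + 1L)
  d <- sqrt(
    outer((rows - 1 - center_px[1])^2, (cols - 1 - center_px[2])^2, "+")
  )
  px[rows, cols] <- background - contrast * disc_profile(d, r_px, edge_softness_px)
  if (noise_sigma > 0) {
    px <- px + matrix(
      stats::rnorm(length(px), 0, noise_sigma),
      nrow = nrow(px)
    )
    px[px < 0] <- 0
    px[px > 1] <- 1
  }
  mv_image(px,
    geometry = geometry, gantry_deg = gantry_deg,
    step_index = step_index
  )
}
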