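# Temporal alignment of the surface-imaging log to the trajectory log and
# reduction of both to one averaged pose per couch position.
#
# The two logs do not share a clock and the surface log carries no beam-on
# flag, so alignment uses the first instance of motion in each source: the
# surface timestamps are shifted by (surface onset - trajectory onset) and
# the surface series is linearly interpolated onto the trajectory grid.
# Beam-on windows are segmented from the cumulative-MU channel of the
# trajectory log and both pose series are averaged within each window.

#' Resample a surface log onto a time grid
#'
#' Per-axis linear interpolation; queries outside the log's span take the
#' nearest-edge value (clamping).
#'
#' @param surf A [surface_log()] with at least 2 samples.
#' @param t_grid Query timestamps (s), in the surface log's own clock.
#' @return Data frame with the six pose axes, one row per grid point.
#' @export
resample_surface_log <- function(surf, t_grid) {
  d <- surf$data
  if (nrow(d) < 2L) {
    stop("cannot interpolate: surface log has fewer than 2 samples",
      call. = FALSE
    )
  }
  out <- lapply(POSE_AXES, function(a) {
    stats::approx(d$t_s, d[[a]], xout = t_grid, rule = 2)$y
  })
  names(out) <- POSE_AXES
  as.data.frame(out)
}

#' Detect the first instance of motion in a pose time series
#'
#' The baseline is the per-axis mean over the first `baseline_s` seconds.
#' Motion onset is the earliest sample, over all axes, that starts a run of
#' at least `min_run` consecutive samples (a run truncated by the end of
#' the series counts) on which that axis deviates from its baseline by more
#' than the threshold (translations: `threshold_mm`; rotations:
#' `threshold_deg`). The per-axis run requirement makes the detector robust
#' to isolated noise excursions while still reporting a sustained step at
#' exactly its first sample.
#'
#' @param t Timestamps (s), strictly increasing.
#' @param pose Data frame with some or all of the [pose_axes()] columns.
#' @param threshold_mm,threshold_deg Per-axis deviation thresholds (> 0).
#' @param baseline_s Length of the initial baseline window (s).
#' @param min_run Consecutive exceedances required (>= 1).
#' @return Onset time (s), or `NA_real_` if motion is never detected.
#' @export
detect_motion_onset <- function(t, pose, threshold_mm = 0.1,
                                threshold_deg = 0.1, baseline_s = 1,
                                min_run = 5L) {
  if (length(t) == 0L || nrow(pose) == 0L) {
    stop("motion onset: series is empty", call. = FALSE)
  }
  if (threshold_mm <= 0 || threshold_deg <= 0) {
    stop("motion onset: thresholds must be > 0", call. = FALSE)
  }
  axes <- intersect(POSE_AXES, names(pose))
  if (!length(axes)) {
    stop("motion onset: no pose axis columns present", call. = FALSE)
  }
  in_baseline <- t <= t[1] + baseline_s
  onset_idx <- Inf
  for (a in axes) {
    thr <- if (a %in% TRANSLATION_AXES) threshold_mm else threshold_deg
    base <- mean(pose[[a]][in_baseline])
    exceeds <- abs(pose[[a]] - base) > thr
    r <- rle(exceeds)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      truncated <- ends[k] == length(t) # run reaches end of series
      if (r$lengths[k] >= min_run || truncated) {
        onset_idx <- min(onset_idx, starts[k])
        break
      }
    }
  }
  if (is.finite(onset_idx)) t[onset_idx] else NA_real_
}

#' Synchronize a surface log to a trajectory log
#'
#' Finds the first instance of motion in each log (couch *actual* axes for
#' the trajectory log), shifts the surface clock by the onset difference,
#' and resamples the surface series onto the trajectory grid. The stored
#' `surface_shift_s` (surface onset minus trajectory onset) is positive
#' when the surface log lags the couch.
#'
#' @param traj A [trajectory_log()].
#' @param surf A [surface_log()].
#' @inheritParams detect_motion_onset
#' @return Object of class `aligned_session`: the common time base `t_s`,
#'   `couch_expected`/`couch_actual`/`surface` pose data frames, the `mu`
#'   channel, detected onsets, and the applied shift.
#' @export
synchronize_logs <- function(traj, surf, threshold_mm = 0.1,
                             threshold_deg = 0.1, baseline_s = 1,
                             min_run = 5L) {
  td <- traj$data
  couch_actual <- stats::setNames(td[paste0(POSE_AXES, "_actual")], POSE_AXES)
  couch_expected <- stats::setNames(td[paste0(POSE_AXES, "_expected")], POSE_AXES)
  onset_traj <- detect_motion_onset(
    td$t_s, couch_actual, threshold_mm, threshold_deg, baseline_s, min_run
  )
  if (is.na(onset_traj)) {
    stop("synchronization error: no motion onset found in trajectory log",
      call. = FALSE
    )
  }
  onset_surf <- detect_motion_onset(
    surf$data$t_s, surf$data, threshold_mm, threshold_deg, baseline_s, min_run
  )
  if (is.na(onset_surf)) {
    stop("synchronization error: no motion onset found in surface log",
      call. = FALSE
    )
  }
  shift <- onset_surf - onset_traj
  surface <- resample_surface_log(surf, td$t_s + shift)
  structure(
    list(
      t_s = td$t_s,
      sample_interval_s = traj$sample_interval_s,
      couch_expected = couch_expected,
      couch_actual = couch_actual,
      surface = surface,
      mu = td$mu,
      onset_traj_s = onset_traj,
      onset_surf_s = onset_surf,
      surface_shift_s = shift
    ),
    class = "aligned_session"
  )
}

#' @export
print.aligned_session <- function(x, ...) {
  cat("<aligned_session> ", length(x$t_s), " samples @ ",
    1 / x$sample_interval_s, " Hz; onsets traj=",
    sprintf("%.3f", x$onset_traj_s), " s, surf=",
    sprintf("%.3f", x$onset_surf_s), " s (shift ",
    sprintf("%.3f", x$surface_shift_s), " s)\n",
    sep = ""
  )
  invisible(x)
}

#' Export an aligned session as a data frame
#'
#' Debugging aid: one row per sample with couch expected/actual and aligned
#' surface axes side by side.
#'
#' @param x An `aligned_session`.
#' @param ... Unused.
#' @return Data frame.
#' @export
as.data.frame.aligned_session <- function(x, ...) {
  out <- data.frame(t_s = x$t_s, mu = x$mu)
  for (a in POSE_AXES) {
    out[[paste0(a, "_expected")]] <- x$couch_expected[[a]]
    out[[paste0(a, "_actual")]] <- x$couch_actual[[a]]
    out[[paste0(a, "_surface")]] <- x$surface[[a]]
  }
  out
}

#' Segment beam-on intervals from the cumulative MU channel
#'
#' A beam-on interval is a maximal run of samples over which the per-sample
#' MU increment exceeds `mu_epsilon`. Interval bounds span from the sample
#' at which the MU ramp starts to the sample at which it ends, so
#' `mu_delivered = mu[last] - mu[first]` recovers the full delivery.
#'
#' @param traj A [trajectory_log()].
#' @param mu_epsilon Minimum per-sample MU increment counted as beam-on.
#' @return Data frame with columns `interval`, `start_s`, `end_s`,
#'   `mu_delivered` (zero rows when the beam is never on).
#' @export
segment_beam_on <- function(traj, mu_epsilon = 1e-3) {
  mu <- traj$data$mu
  t <- traj$data$t_s
  if (length(mu) < 2L) {
    return(data.frame(
      interval = integer(0), start_s = numeric(0), end_s = numeric(0),
      mu_delivered = numeric(0)
    ))
  }
  on <- diff(mu) > mu_epsilon
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    interval = seq_along(keep),
    start_s = t[starts[keep]], # increment k spans samples k..k+1
    end_s = t[ends[keep] + 1L],
    mu_delivered = mu[ends[keep] + 1L] - mu[starts[keep]]
  )
}

#' Map beam-on intervals onto plan steps
#'
#' Intervals are associated with the plan's beam-delivering steps by order
#' of occurrence; the counts must match.
#'
#' @param intervals Output of [segment_beam_on()].
#' @param plan The [motion_plan()] that generated the session.
#' @return `intervals` with a `step_index` column added.
#' @export
map_intervals_to_plan <- function(intervals, plan) {
  beam_steps <- plan_beam_steps(plan)
  if (nrow(intervals) != nrow(beam_steps)) {
    stop(
      "consistency error: ", nrow(intervals), " beam-on interval(s) but plan ",
      "has ", nrow(beam_steps), " beam-delivering step(s)",
      call. = FALSE
    )
  }
  intervals$step_index <- beam_steps$index
  intervals
}

#' Average couch and surface poses over each beam-on interval
#'
#' Arithmetic mean of the couch-actual and aligned surface series over the
#' samples inside each `[start_s, end_s]` window. Rotation axes use a
#' wrap-safe mean (all planned rotations are well inside +/-180 degrees, so
#' this coincides with the plain mean in practice).
#'
#' @param session An `aligned_session` from [synchronize_logs()].
#' @param intervals Data frame from [segment_beam_on()], optionally carrying
#'   `step_index` (see [map_intervals_to_plan()]); otherwise intervals are
#'   numbered in order.
#' @return Data frame with one row per interval: `step_index`, `n_samples`,
#'   `couch_<axis>` (absolute couch pose), and `surf_<axis>` (surface
#'   offset from reference).
#' @export
average_over_beam_on <- function(session, intervals) {
  n_int <- nrow(intervals)
  step_index <- intervals$step_index %||% seq_len(n_int)
  rows <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    inside <- session$t_s >= intervals$start_s[i] - 1e-9 &
      session$t_s <= intervals$end_s[i] + 1e-9
    n <- sum(inside)
    if (n < 1L) {
      stop("averaging error: interval ", i, " contains no session samples",
        call. = FALSE
      )
    }
    row <- data.frame(step_index = step_index[i], n_samples = n)
    for (a in POSE_AXES) {
      cv <- session$couch_actual[[a]][inside]
      sv <- session$surface[[a]][inside]
      if (a %in% ROTATION_AXES) {
        row[[paste0("couch_", a)]] <- mean_angle_deg(cv)
        row[[paste0("surf_", a)]] <- mean_angle_deg(sv)
      } else {
        row[[paste0("couch_", a)]] <- mean(cv)
        row[[paste0("surf_", a)]] <- mean(sv)
      }
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Estimate the surface-imaging temporal latency
#'
#' Total latency of the surface trace behind the couch trace: the onset
#' shift already applied by [synchronize_logs()] plus the residual lag that
#' maximizes the normalized cross-correlation (summed over translation
#' axes with nonzero variance) between the couch-actual and aligned surface
#' series, searched over `+/- max_lag_s`. Positive values mean the surface
#' log lags the couch.
#'
#' Because the session is already onset-aligned, the residual term is
#' near zero by construction; the total is reported as informational and is
#' never a pass/fail criterion.
#'
#' @param session An `aligned_session`.
#' @param max_lag_s Half-width of the residual lag search window (s).
#' @return Latency (s), with attributes `shift_s` (onset alignment) and
#'   `residual_s` (cross-correlation refinement).
#' @export
estimate_time_lag <- function(session, max_lag_s = 1) {
  dt <- session$sample_interval_s
  k_max <- max(1L, round(max_lag_s / dt))
  axes <- TRANSLATION_AXES[vapply(TRANSLATION_AXES, function(a) {
    stats::sd(session$couch_actual[[a]]) > 0 && stats::sd(session$surface[[a]]) > 0
  }, logical(1))]
  if (!length(axes)) {
    stop("lag estimation error: session contains no translational motion",
      call. = FALSE
    )
  }
  total <- NULL
  for (a in axes) {
    cc <- stats::ccf(session$couch_actual[[a]], session$surface[[a]],
      lag.max = k_max, plot = FALSE, demean = TRUE
    )
    acf_a <- as.numeric(cc$acf)
    total <- if (is.null(total)) acf_a else total + acf_a
    lags <- as.numeric(cc$lag)
  }
  # ccf(x, y) peaks at lag -L when y lags x by L samples
  residual_s <- -lags[which.max(total)] * dt
  structure(
    session$surface_shift_s + residual_s,
    shift_s = session$surface_shift_s,
    residual_s = residual_s
  )
}
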