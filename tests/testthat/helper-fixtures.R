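# Shared fixtures and independent brute-force oracles. Oracles implement
# the operation definitions directly (loops, no vectorized shortcuts) and
# never call the code paths they check.

AXES <- pose_axes()
TRANS <- pose_axes("translation")
ROT <- pose_axes("rotation")

# Small plan used by most integration tests: 2 offsets per translation
# axis, +/-1 deg rotations in 0.5 deg steps (4 per rotation axis).
tiny_plan <- function(...) {
  build_motion_plan(
    translations_mm = c(-10, 10),
    rotation_range_deg = 1,
    rotation_step_deg = 0.5,
    ...
  )
}

# Zero-noise, zero-latency configuration sized for +/-10 mm offsets;
# any field can be overridden through ...
sim_zero <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    surf_noise_mm = 0, surf_noise_deg = 0, surf_latency_s = 0,
    image_noise_sigma = 0, image_size_px = c(192L, 192L)
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(simulation_config, args)
}

# Noisy study-condition configuration (log-only studies).
sim_noisy <- function(seed, latency_s = 0.2, ...) {
  simulation_config(seed = seed, surf_latency_s = latency_s, ...)
}

random_plan <- function(allow_reference = TRUE) {
  k <- sample(1:4, 1)
  trans <- sample(c(-60:-1, 1:60), k)
  rng <- sample(c(0, 1, 2, 3), 1)
  plan <- build_motion_plan(
    translations_mm = trans,
    rotation_range_deg = rng,
    rotation_step_deg = if (rng > 0) rng / sample(1:4, 1) else 0.5,
    mu_per_image = stats::runif(1, 10, 100),
    reference = if (allow_reference) {
      pose6dof(
        lat_mm = stats::runif(1, -20, 20), lng_mm = stats::runif(1, -20, 20),
        vrt_mm = stats::runif(1, -20, 20), yaw_deg = stats::runif(1, -5, 5),
        pitch_deg = stats::runif(1, -5, 5), roll_deg = stats::runif(1, -5, 5)
      )
    } else {
      pose6dof()
    },
    label = paste0("random-", sample(1e6, 1))
  )
  plan
}

# Random valid trajectory log built directly (independent of the simulator).
random_traj_log <- function(n = NULL, dt = 0.02) {
  n <- n %||% sample(5:40, 1)
  t <- (seq_len(n) - 1) * dt
  d <- data.frame(t_s = t)
  for (a in c(AXES, "gantry_deg")) {
    v <- round(cumsum(stats::rnorm(n, 0, 0.5)), 4)
    d[[paste0(a, "_expected")]] <- v
    d[[paste0(a, "_actual")]] <- round(v + stats::rnorm(n, 0, 0.01), 4)
  }
  d$mu <- round(cumsum(stats::runif(n, 0, 0.6)), 4)
  trajectory_log(dt, d, meta = list(machine = "synthetic-unit"))
}

random_surf_log <- function(n = NULL) {
  n <- n %||% sample(5:40, 1)
  t <- round(cumsum(stats::runif(n, 0.02, 0.2)), 4)
  d <- data.frame(t_s = t)
  for (a in AXES) d[[a]] <- round(stats::rnorm(n, 0, 2), 4)
  surface_log(d, meta = list(camera = "synthetic-unit"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- oracles -------------------------------------------------------------

# Linear interpolation with edge clamping, one query at a time.
oracle_interp <- function(t, v, tq) {
  vapply(tq, function(q) {
    if (q <= t[1]) {
      return(v[1])
    }
    if (q >= t[length(t)]) {
      return(v[length(v)])
    }
    i <- max(which(t <= q))
    if (t[i] == q) {
      return(v[i])
    }
    f <- (q - t[i]) / (t[i + 1] - t[i])
    v[i] + f * (v[i + 1] - v[i])
  }, numeric(1))
}

# Exhaustive linear scan for the first sustained threshold exceedance.
oracle_onset <- function(t, pose, threshold_mm, threshold_deg,
                         baseline_s = 1, min_run = 5L) {
  axes <- intersect(AXES, names(pose))
  best <- Inf
  for (a in axes) {
    thr <- if (a %in% TRANS) threshold_mm else threshold_deg
    base <- mean(pose[[a]][t <= t[1] + baseline_s])
    for (i in seq_along(t)) {
      run_end <- min(length(t), i + min_run - 1L)
      all_over <- TRUE
      for (j in i:run_end) {
        if (abs(pose[[a]][j] - base) <= thr) {
          all_over <- FALSE
          break
        }
      }
      if (all_over) {
        best <- min(best, i)
        break
      }
    }
  }
  if (is.finite(best)) t[best] else NA_real_
}

# Brute-force masked mean over an interval (translations only arithmetic;
# rotations here are far from the wrap so the plain mean applies).
oracle_masked_mean <- function(t, values, start_s, end_s) {
  total <- 0
  n <- 0L
  for (i in seq_along(t)) {
    if (t[i] >= start_s - 1e-9 && t[i] <= end_s + 1e-9) {
      total <- total + values[i]
      n <- n + 1L
    }
  }
  total / n
}

# Exhaustive lag scan: shift y by k samples, correlate overlap, return the
# lag (seconds, positive = y lags x) with the highest summed correlation.
oracle_lag <- function(x_df, y_df, dt, max_lag_s, axes = TRANS) {
  n <- nrow(x_df)
  k_max <- round(max_lag_s / dt)
  best_k <- 0L
  best_c <- -Inf
  for (k in -k_max:k_max) {
    total <- 0
    used <- 0L
    for (a in axes) {
      x <- x_df[[a]]
      y <- y_df[[a]]
      if (k >= 0) {
        xs <- x[1:(n - k)]
        ys <- y[(1 + k):n]
      } else {
        xs <- x[(1 - k):n]
        ys <- y[1:(n + k)]
      }
      if (stats::sd(xs) > 0 && stats::sd(ys) > 0) {
        total <- total + stats::cor(xs, ys)
        used <- used + 1L
      }
    }
    if (used > 0L && total > best_c) {
      best_c <- total
      best_k <- k
    }
  }
  best_k * dt
}

# Intensity-weighted centroid of the inverted image over all pixels
# (0-based coordinates); valid for clean single-blob images.
oracle_centroid <- function(pixels) {
  d <- pmax(stats::median(pixels) - pixels, 0)
  rr <- matrix(seq_len(nrow(d)) - 1, nrow(d), ncol(d))
  cc <- matrix(seq_len(ncol(d)) - 1, nrow(d), ncol(d), byrow = TRUE)
  c(sum(rr * d), sum(cc * d)) / sum(d)
}

# Ground-truth surface-mean error per moved step of a session analysis.
moved_step_errors <- function(plan, summaries) {
  st <- plan$steps
  out <- NULL
  for (i in seq_len(nrow(summaries))) {
    srow <- st[st$index == summaries$step_index[i], ]
    ax <- AXES[which(as.numeric(srow[1, AXES]) != 0)]
    if (length(ax) != 1L) next
    out <- rbind(out, data.frame(
      step_index = srow$index, axis = ax,
      err = summaries[[paste0("surf_", ax)]][i] - srow[[ax]],
      is_rotation = ax %in% ROT
    ))
  }
  out
}
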