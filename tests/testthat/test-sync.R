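surf_from_df <- function(t, lat = 0, lng = 0, vrt = 0, yaw = 0, pitch = 0, roll = 0) {
  surface_log(data.frame(
    t_s = t, lat_mm = lat, lng_mm = lng, vrt_mm = vrt,
    yaw_deg = yaw, pitch_deg = pitch, roll_deg = roll
  ))
}

test_that("surface resampling is linear with edge clamping", {
  log <- surf_from_df(c(0, 1), lat = c(0, 10))
  out <- resample_surface_log(log, c(0, 0.5, 1))
  expect_equal(out$lat_mm, c(0, 5, 10))
  # exactly at a sample time
  expect_equal(resample_surface_log(log, 1)$lat_mm, 10)
  # clamped outside the span
  expect_equal(resample_surface_log(log, c(-5, 5))$lat_mm, c(0, 10))
  expect_error(
    resample_surface_log(surf_from_df(0), 0.5),
    "cannot interpolate"
  )
})

test_that("resampling matches a brute-force interpolation oracle", {
  withr::with_seed(501, {
    t15 <- seq(0, 4, by = 1 / 15)
    vals <- cumsum(rnorm(length(t15), 0, 2))
    log <- surf_from_df(t15, lat = vals)
    tq <- seq(-0.2, 4.2, by = 1 / 50)
    got <- resample_surface_log(log, tq)$lat_mm
    expect_equal(got, oracle_interp(t15, vals, tq), tolerance = 1e-12)
  })
})

test_that("motion onset detection finds sustained steps at their first sample", {
  t <- seq(0, 5, by = 0.02)
  flat <- data.frame(lat_mm = rep(0, length(t)))
  expect_true(is.na(detect_motion_onset(t, flat, 0.5, 0.5)))

  k <- 180L
  stepped <- data.frame(lat_mm = c(rep(0, k - 1), rep(10, length(t) - k + 1)))
  expect_equal(detect_motion_onset(t, stepped, 0.5, 0.5), t[k])
  expect_error(detect_motion_onset(numeric(0), flat[0, , drop = FALSE], 0.5, 0.5), "empty")
  expect_error(detect_motion_onset(t, stepped, -1, 0.5), "> 0")
})

test_that("noisy onset matches the exhaustive-scan oracle within one sample", {
  withr::with_seed(502, {
    t <- seq(0, 5, by = 0.02)
    for (rep in 1:10) {
      x <- rnorm(length(t), 0, 0.02)
      x[t >= 2.0] <- x[t >= 2.0] + 10
      pose <- data.frame(lat_mm = x)
      got <- detect_motion_onset(t, pose, 0.1, 0.1)
      expect_lte(abs(got - 2.0), 0.02 + 1e-12)
      expect_equal(got, oracle_onset(t, pose, 0.1, 0.1))
    }
  })
})

test_that("raising the onset threshold never yields an earlier onset", {
  withr::with_seed(503, {
    t <- seq(0, 6, by = 0.05)
    x <- cumsum(rnorm(length(t), 0, 0.05))
    pose <- data.frame(lng_mm = x)
    onsets <- vapply(
      c(0.05, 0.1, 0.2, 0.5, 1, 2),
      function(thr) {
        o <- detect_motion_onset(t, pose, thr, thr)
        if (is.na(o)) Inf else o
      },
      numeric(1)
    )
    expect_false(is.unsorted(onsets))
  })
})

test_that("synchronization recovers a constructed pure delay", {
  ses <- simulate_session(tiny_plan(), sim_zero(7), images = FALSE)
  td <- ses$trajectory$data
  # surface = actual couch trace delayed by 0.30 s, zero noise
  delay <- 0.30
  surf <- surface_log(data.frame(
    t_s = td$t_s + delay,
    lat_mm = td$lat_mm_actual, lng_mm = td$lng_mm_actual,
    vrt_mm = td$vrt_mm_actual, yaw_deg = td$yaw_deg_actual,
    pitch_deg = td$pitch_deg_actual, roll_deg = td$roll_deg_actual
  ))
  sess <- synchronize_logs(ses$trajectory, surf)
  expect_equal(sess$surface_shift_s, delay, tolerance = 1e-9)
  for (a in pose_axes()) {
    expect_lt(max(abs(sess$surface[[a]] - sess$couch_actual[[a]])), 1e-9)
  }
})

test_that("identical logs synchronize with zero shift", {
  ses <- simulate_session(tiny_plan(), sim_zero(8), images = FALSE)
  td <- ses$trajectory$data
  surf <- surface_log(data.frame(
    t_s = td$t_s,
    lat_mm = td$lat_mm_actual, lng_mm = td$lng_mm_actual,
    vrt_mm = td$vrt_mm_actual, yaw_deg = td$yaw_deg_actual,
    pitch_deg = td$pitch_deg_actual, roll_deg = td$roll_deg_actual
  ))
  sess <- synchronize_logs(ses$trajectory, surf)
  expect_equal(sess$surface_shift_s, 0)
})

test_that("synchronization errors name the motionless source", {
  ses <- simulate_session(
    build_motion_plan(translations_mm = numeric(0), rotation_range_deg = 1),
    sim_zero(9),
    images = FALSE
  )
  flat_surf <- surf_from_df(seq(0, 10, by = 1 / 15))
  expect_error(
    synchronize_logs(ses$trajectory, flat_surf),
    "surface log"
  )
  td <- ses$trajectory$data
  td[paste0(pose_axes(), "_actual")] <- 0
  td[paste0(pose_axes(), "_expected")] <- 0
  flat_traj <- trajectory_log(ses$trajectory$sample_interval_s, td)
  expect_error(
    synchronize_logs(flat_traj, ses$surface),
    "trajectory log"
  )
})

test_that("simulator latency is recovered by the applied shift", {
  ses <- simulate_session(
    tiny_plan(),
    sim_zero(10, surf_latency_s = 0.20),
    images = FALSE
  )
  sess <- synchronize_logs(ses$trajectory, ses$surface)
  expect_lte(abs(sess$surface_shift_s - 0.20), ses$trajectory$sample_interval_s + 1e-12)
})

test_that("beam-on segmentation finds MU ramps exactly", {
  n <- 400L
  t <- (seq_len(n) - 1) * 0.02
  mu <- rep(0, n)
  mu[100:199] <- seq(0, 50, length.out = 100)
  mu[200:n] <- 50
  d <- data.frame(t_s = t)
  for (a in c(pose_axes(), "gantry_deg")) {
    d[[paste0(a, "_expected")]] <- 0
    d[[paste0(a, "_actual")]] <- 0
  }
  d$mu <- mu
  traj <- trajectory_log(0.02, d)
  iv <- segment_beam_on(traj)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start_s, t[100])
  expect_equal(iv$end_s, t[199])
  expect_equal(iv$mu_delivered, 50)

  d$mu <- rep(2, n) # constant -> no beam
  expect_equal(nrow(segment_beam_on(trajectory_log(0.02, d))), 0L)
})

test_that("a 12-imaging-step plan yields 12 intervals of 50 MU", {
  plan <- build_motion_plan(
    rotation_range_deg = 0,
    include_reference_images = FALSE
  )
  ses <- simulate_session(plan, sim_zero(11, image_size_px = c(512L, 512L)),
    images = FALSE
  )
  iv <- segment_beam_on(ses$trajectory)
  expect_equal(nrow(iv), 12L)
  expect_true(all(abs(iv$mu_delivered - 50) <= 1e-6))
  iv2 <- map_intervals_to_plan(iv, plan)
  expect_equal(iv2$step_index, plan$steps$index[plan$steps$mu > 0])
  expect_error(
    map_intervals_to_plan(iv[-1, ], plan),
    "consistency error"
  )
})

test_that("total MU across intervals matches the cumulative MU channel", {
  ses <- simulate_session(tiny_plan(), sim_noisy(12), images = FALSE)
  iv <- segment_beam_on(ses$trajectory)
  mu <- ses$trajectory$data$mu
  expect_lte(
    abs(sum(iv$mu_delivered) - (mu[length(mu)] - mu[1])),
    1e-3 * length(mu)
  )
})

test_that("beam-on averaging equals the brute-force masked mean", {
  ses <- simulate_session(tiny_plan(), sim_noisy(13), images = FALSE)
  sess <- synchronize_logs(ses$trajectory, ses$surface)
  iv <- map_intervals_to_plan(segment_beam_on(ses$trajectory), tiny_plan())
  summ <- average_over_beam_on(sess, iv)
  expect_true(all(summ$n_samples >= 1))
  for (i in seq_len(nrow(iv))) {
    for (a in c("lat_mm", "yaw_deg")) {
      expect_lt(abs(
        summ[[paste0("couch_", a)]][i] -
          oracle_masked_mean(
            sess$t_s, sess$couch_actual[[a]], iv$start_s[i], iv$end_s[i]
          )
      ), 1e-12)
      expect_lt(abs(
        summ[[paste0("surf_", a)]][i] -
          oracle_masked_mean(
            sess$t_s, sess$surface[[a]], iv$start_s[i], iv$end_s[i]
          )
      ), 1e-12)
    }
  }
  # constant and two-sample arithmetic cases
  mini <- list(
    t_s = c(0, 1, 2, 3), sample_interval_s = 1,
    couch_actual = data.frame(
      lat_mm = c(9, 11, 10, 10), lng_mm = 0, vrt_mm = 0,
      yaw_deg = 0, pitch_deg = 0, roll_deg = 0
    ),
    surface = data.frame(
      lat_mm = c(10, 10, 10, 10), lng_mm = 0, vrt_mm = 0,
      yaw_deg = 0, pitch_deg = 0, roll_deg = 0
    )
  )
  class(mini) <- "aligned_session"
  out <- average_over_beam_on(mini, data.frame(start_s = 0, end_s = 1))
  expect_equal(out$couch_lat_mm, 10) # mean of 9 and 11
  expect_equal(out$surf_lat_mm, 10) # constant
  expect_error(
    average_over_beam_on(mini, data.frame(start_s = 5, end_s = 6)),
    "interval 1"
  )
})

test_that("zero-noise sessions close: surface mean equals couch mean", {
  ses <- simulate_session(tiny_plan(), sim_zero(14), images = FALSE)
  sess <- synchronize_logs(ses$trajectory, ses$surface)
  iv <- map_intervals_to_plan(segment_beam_on(ses$trajectory), tiny_plan())
  summ <- average_over_beam_on(sess, iv)
  for (a in pose_axes()) {
    expect_lt(
      max(abs(summ[[paste0("surf_", a)]] - summ[[paste0("couch_", a)]])),
      1e-6
    )
  }
})

test_that("lag estimation recovers constructed and simulated latencies", {
  ses <- simulate_session(tiny_plan(), sim_zero(15), images = FALSE)
  td <- ses$trajectory$data
  dt <- ses$trajectory$sample_interval_s
  mk_surf <- function(delay) {
    surface_log(data.frame(
      t_s = td$t_s + delay,
      lat_mm = td$lat_mm_actual, lng_mm = td$lng_mm_actual,
      vrt_mm = td$vrt_mm_actual, yaw_deg = td$yaw_deg_actual,
      pitch_deg = td$pitch_deg_actual, roll_deg = td$roll_deg_actual
    ))
  }
  # identical traces -> zero lag
  sess0 <- synchronize_logs(ses$trajectory, mk_surf(0))
  expect_lte(abs(as.numeric(estimate_time_lag(sess0))), dt + 1e-12)
  # constructed 0.24 s delay
  sess24 <- synchronize_logs(ses$trajectory, mk_surf(0.24))
  expect_lte(abs(as.numeric(estimate_time_lag(sess24)) - 0.24), dt + 1e-12)

  # simulated latency 0.10 s with noise, checked against exhaustive scan
  ses2 <- simulate_session(tiny_plan(), sim_noisy(16, latency_s = 0.10),
    images = FALSE
  )
  sess2 <- synchronize_logs(ses2$trajectory, ses2$surface)
  lag <- estimate_time_lag(sess2)
  expect_lte(abs(as.numeric(lag) - 0.10), dt + 1e-12)
  # implementation residual against the exhaustive scan (both use the
  # convention positive = surface lags couch)
  res_oracle <- oracle_lag(sess2$couch_actual, sess2$surface, dt, 1)
  expect_lte(abs(attr(lag, "residual_s") - res_oracle), dt + 1e-12)

  # motionless session errors
  flat <- sess0
  for (a in pose_axes()) {
    flat$couch_actual[[a]] <- 0
    flat$surface[[a]] <- 0
  }
  expect_error(estimate_time_lag(flat), "motion")
})
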