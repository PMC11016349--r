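# Minimal summaries/records builders for unit-level report tests.
mk_summary <- function(step_index, axis, couch, surf) {
  row <- data.frame(step_index = step_index, n_samples = 10L)
  for (a in pose_axes()) {
    row[[paste0("couch_", a)]] <- if (a == axis) couch else 0
    row[[paste0("surf_", a)]] <- if (a == axis) surf else 0
  }
  row
}

mk_plan_one <- function(axis, delta, gantry = if (axis == "vrt_mm") 90 else 0) {
  args <- stats::setNames(list(delta), axis)
  motion_plan(steps = sgrtdynqa:::step_row(
    1, do.call(pose6dof, args), gantry, FALSE, 50
  ))
}

test_that("deviations are measured minus expected, signed", {
  plan <- mk_plan_one("lat_mm", 10)
  rec <- compute_deviations(plan, mk_summary(1, "lat_mm", 9.06, 9.5))
  expect_equal(rec$expected, 10)
  expect_equal(rec$dev_traj, -0.94)
  expect_equal(rec$dev_surf, -0.5)
  expect_true(is.na(rec$dev_mv))
  expect_equal(rec$kind, "translation")

  # measured equals expected -> zero deviation
  rec0 <- compute_deviations(plan, mk_summary(1, "lat_mm", 10, 10))
  expect_equal(rec0$dev_traj, 0)
  expect_equal(rec0$dev_surf, 0)
})

test_that("rotation records carry trajectory and surface deviations only", {
  plan <- mk_plan_one("yaw_deg", 2)
  offs <- data.frame(
    step_index = 1, gantry_deg = 0, lat_mm = 5, lng_mm = 0,
    vrt_mm = NA, yaw_deg = NA, pitch_deg = NA, roll_deg = NA
  )
  rec <- compute_deviations(plan, mk_summary(1, "yaw_deg", 2.01, 1.8), offs)
  expect_equal(rec$kind, "rotation")
  expect_equal(rec$dev_traj, 0.01, tolerance = 1e-9)
  expect_equal(rec$dev_surf, -0.2, tolerance = 1e-9)
  expect_true(is.na(rec$measured_mv)) # structurally absent, not zero
})

test_that("mismatched step indices raise consistency errors", {
  plan <- mk_plan_one("lat_mm", 10)
  expect_error(
    compute_deviations(plan, mk_summary(2, "lat_mm", 10, 10)),
    "consistency error"
  )
  offs <- data.frame(
    step_index = 9, gantry_deg = 0, lat_mm = 5, lng_mm = 0,
    vrt_mm = NA, yaw_deg = NA, pitch_deg = NA, roll_deg = NA
  )
  expect_error(
    compute_deviations(plan, mk_summary(1, "lat_mm", 10, 10), offs),
    "consistency error"
  )
})

mk_records <- function(devs_mm, devs_deg = numeric(0)) {
  n <- length(devs_mm) + length(devs_deg)
  data.frame(
    step_index = seq_len(n),
    axis = c(rep("lat_mm", length(devs_mm)), rep("yaw_deg", length(devs_deg))),
    kind = c(
      rep("translation", length(devs_mm)),
      rep("rotation", length(devs_deg))
    ),
    expected = 10,
    measured_traj = 10 + c(devs_mm, devs_deg),
    measured_surf = 10 + c(devs_mm, devs_deg),
    measured_mv = NA_real_,
    dev_traj = c(devs_mm, devs_deg),
    dev_surf = c(devs_mm, devs_deg),
    dev_mv = NA_real_
  )
}

test_that("TG-142 SABR tolerance logic uses an inclusive boundary", {
  expect_equal(
    evaluate_tolerances(mk_records(0.94))$verdicts$traj, "pass"
  )
  expect_equal(
    evaluate_tolerances(mk_records(1.000))$verdicts$traj, "pass"
  )
  rep_fail <- evaluate_tolerances(mk_records(1.001))
  expect_equal(rep_fail$verdicts$traj, "fail")
  expect_false(rep_fail$records$pass_traj[1])
  rep_rot <- evaluate_tolerances(mk_records(0.1, devs_deg = 1.5))
  expect_equal(rep_rot$verdicts$traj, "fail")
  expect_false(rep_rot$records$pass_traj[rep_rot$records$kind == "rotation"])
  expect_equal(rep_rot$overall, "fail")
  # MV has no measurements here -> n/a, never a failure
  expect_equal(rep_rot$verdicts$mv, "n/a")
  expect_error(evaluate_tolerances(mk_records(0.5)[0, ]), "non-empty")
})

test_that("reported maxima equal the brute-force extremum and loosening never fails", {
  withr::with_seed(801, {
    for (rep in 1:10) {
      devs <- round(rnorm(8, 0, 0.6), 3)
      rot <- round(rnorm(4, 0, 0.4), 3)
      rpt <- evaluate_tolerances(mk_records(devs, rot))
      mt <- rpt$maxima[rpt$maxima$source == "traj" & rpt$maxima$kind == "translation", ]
      expect_equal(mt$max_deviation, devs[which.max(abs(devs))])
      mr <- rpt$maxima[rpt$maxima$source == "traj" & rpt$maxima$kind == "rotation", ]
      expect_equal(mr$max_deviation, rot[which.max(abs(rot))])

      strict <- evaluate_tolerances(mk_records(devs, rot), tolerance_set(0.5, 0.3))
      loose <- evaluate_tolerances(mk_records(devs, rot), tolerance_set(5, 3))
      for (src in c("traj", "surf")) {
        if (strict$verdicts[[src]] == "pass") {
          expect_equal(loose$verdicts[[src]], "pass")
        }
      }
    }
  })
})

test_that("JSON reports round-trip losslessly", {
  withr::with_seed(802, {
    rpt <- evaluate_tolerances(
      mk_records(rnorm(5, 0, 0.4), rnorm(3, 0, 0.2)),
      metadata = list(session = "unit", operator = "qa")
    )
    json <- generate_report(rpt, "json")
    back <- parse_report_json(json)
    expect_equal(back$records, rpt$records)
    expect_equal(back$maxima, rpt$maxima)
    expect_equal(back$verdicts, rpt$verdicts)
    expect_equal(back$overall, rpt$overall)
    expect_equal(back$tolerances, rpt$tolerances)
    expect_identical(generate_report(back, "json"), json)
  })
})

test_that("markdown rendering marks failures and refuses empty reports", {
  ok <- evaluate_tolerances(mk_records(c(0.2, -0.5)))
  md <- generate_report(ok, "markdown")
  expect_false(grepl("FAIL", md))
  expect_match(md, "overall verdict: \\*\\*pass\\*\\*")

  bad <- evaluate_tolerances(mk_records(c(0.2, 1.7)))
  expect_match(generate_report(bad, "markdown"), "FAIL")

  empty <- ok
  empty$records <- ok$records[0, ]
  expect_error(generate_report(empty, "markdown"), "refused")
  expect_error(generate_report(ok, "pdf"), "unknown report format")
})
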