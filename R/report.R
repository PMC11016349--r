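# Deviations of measured couch motion from the commanded plan, evaluated
# against AAPM TG-142 SABR tolerances (1 mm translations, 1 degree
# rotations). Deviations are signed, measured - expected; the "maximum
# deviation" reported per source is the signed value of largest magnitude.
# A deviation exactly equal to the tolerance passes (<=).

REPORT_SCHEMA_VERSION <- "1.0"
REPORT_SOURCES <- c("traj", "surf", "mv")

#' TG-142 SABR tolerance set
#'
#' @param translation_tol_mm Translation tolerance (mm); default 1 mm.
#' @param rotation_tol_deg Rotation tolerance (deg); default 1 degree.
#' @return Object of class `tolerance_set`.
#' @export
tolerance_set <- function(translation_tol_mm = 1, rotation_tol_deg = 1) {
  if (translation_tol_mm <= 0 || rotation_tol_deg <= 0) {
    stop("tolerances must be > 0", call. = FALSE)
  }
  structure(
    list(
      translation_tol_mm = translation_tol_mm,
      rotation_tol_deg = rotation_tol_deg
    ),
    class = "tolerance_set"
  )
}

#' Compute deviation records from plan, position summaries, and image offsets
#'
#' One record per moved plan step (delta-zero reference and home steps
#' carry no record). For each record: `expected` is the commanded delta on
#' the moved axis; `measured_traj` is the beam-on-averaged couch-actual
#' pose minus the reference; `measured_surf` is the beam-on-averaged
#' surface offset; `measured_mv` is the radiographic offset (translation
#' steps whose moved axis is visible at the image's gantry angle only —
#' rotations are structurally absent from MV, not zero). Deviations are
#' `measured - expected`.
#'
#' @param plan The [motion_plan()].
#' @param summaries Position summaries from [average_over_beam_on()], keyed
#'   by `step_index`.
#' @param offsets Optional image offsets from [offsets_from_images()].
#' @return Data frame of deviation records.
#' @export
compute_deviations <- function(plan, summaries, offsets = NULL) {
  st <- plan$steps
  if (!is.null(offsets) && nrow(offsets) &&
    !all(offsets$step_index %in% st$index)) {
    stop("consistency error: image offset step indices not found in plan",
      call. = FALSE
    )
  }
  if (!all(summaries$step_index %in% st$index)) {
    stop("consistency error: summary step indices not found in plan",
      call. = FALSE
    )
  }
  rows <- list()
  for (i in seq_len(nrow(st))) {
    step <- st[i, ]
    axis <- step_moved_axis(step)
    if (is.na(axis)) next
    is_rot <- axis %in% ROTATION_AXES
    expected <- step[[axis]]

    s_row <- summaries[summaries$step_index == step$index, , drop = FALSE]
    if (nrow(s_row) == 0L) {
      stop("consistency error: no position summary for plan step ", step$index,
        call. = FALSE
      )
    }
    couch_abs <- s_row[[paste0("couch_", axis)]][1]
    measured_traj <- if (is_rot) {
      angle_diff_deg(couch_abs, plan$reference[[axis]])
    } else {
      couch_abs - plan$reference[[axis]]
    }
    measured_surf <- s_row[[paste0("surf_", axis)]][1]

    measured_mv <- NA_real_
    if (!is_rot && !is.null(offsets) && nrow(offsets)) {
      o_row <- offsets[offsets$step_index == step$index, , drop = FALSE]
      if (nrow(o_row) && !is.na(o_row[[axis]][1])) {
        measured_mv <- o_row[[axis]][1]
      }
    }

    rows[[length(rows) + 1L]] <- data.frame(
      step_index = step$index,
      axis = axis,
      kind = if (is_rot) "rotation" else "translation",
      expected = expected,
      measured_traj = measured_traj,
      measured_surf = measured_surf,
      measured_mv = measured_mv,
      dev_traj = measured_traj - expected,
      dev_surf = measured_surf - expected,
      dev_mv = measured_mv - expected
    )
  }
  if (!length(rows)) {
    stop("consistency error: plan contains no moved steps", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Signed value of largest magnitude (the convention used for reported
# maxima); NA when no finite values.
signed_extreme <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) {
    return(NA_real_)
  }
  x[which.max(abs(x))]
}

#' Evaluate deviation records against tolerances
#'
#' Applies the tolerance set per record and per source. The boundary rule
#' is inclusive: a deviation whose magnitude exactly equals the tolerance
#' passes. Per source and motion kind, the reported maximum is the signed
#' deviation of largest magnitude. A source with no applicable records
#' (MV for rotations) is reported as `"n/a"`, never as a failure.
#'
#' @param records Data frame from [compute_deviations()]; must be
#'   non-empty.
#' @param tol A [tolerance_set()].
#' @param metadata Named list stored in the report (session label, date,
#'   plan label, ...).
#' @return Object of class `qa_report` with `records`, `maxima`,
#'   `verdicts`, `overall`, `tolerances`, and `metadata`.
#' @export
evaluate_tolerances <- function(records, tol = tolerance_set(),
                                metadata = list()) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("evaluation error: records must be non-empty", call. = FALSE)
  }
  stopifnot(inherits(tol, "tolerance_set"))
  tol_for <- function(kind) {
    ifelse(kind == "rotation", tol$rotation_tol_deg, tol$translation_tol_mm)
  }
  rec <- records
  for (src in REPORT_SOURCES) {
    dev <- rec[[paste0("dev_", src)]]
    rec[[paste0("pass_", src)]] <- ifelse(
      is.na(dev), NA, abs(dev) <= tol_for(rec$kind)
    )
  }

  maxima <- do.call(rbind, lapply(REPORT_SOURCES, function(src) {
    do.call(rbind, lapply(c("translation", "rotation"), function(kind) {
      dev <- rec[[paste0("dev_", src)]][rec$kind == kind]
      data.frame(
        source = src, kind = kind,
        max_deviation = signed_extreme(dev),
        n = sum(is.finite(dev))
      )
    }))
  }))
  rownames(maxima) <- NULL

  verdicts <- vapply(REPORT_SOURCES, function(src) {
    p <- rec[[paste0("pass_", src)]]
    p <- p[!is.na(p)]
    if (!length(p)) {
      return("n/a")
    }
    if (all(p)) "pass" else "fail"
  }, character(1))

  applicable <- verdicts[verdicts != "n/a"]
  structure(
    list(
      schema_version = REPORT_SCHEMA_VERSION,
      records = rec,
      maxima = maxima,
      verdicts = as.list(verdicts),
      overall = if (length(applicable) && all(applicable == "pass")) "pass" else "fail",
      tolerances = list(
        translation_tol_mm = tol$translation_tol_mm,
        rotation_tol_deg = tol$rotation_tol_deg
      ),
      metadata = metadata
    ),
    class = "qa_report"
  )
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report> overall: ", x$overall, "\n", sep = "")
  for (src in names(x$verdicts)) {
    cat("  ", src, ": ", x$verdicts[[src]], "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a QA report
#'
#' `"json"` writes a versioned machine-readable document that round-trips
#' losslessly through [parse_report_json()]; `"markdown"` renders a
#' human-readable summary with per-record deviations, per-source maxima,
#' and verdicts (failing records are marked `FAIL`).
#'
#' @param report A `qa_report` with at least one record.
#' @param format `"json"` or `"markdown"`.
#' @return Character string (single document).
#' @export
generate_report <- function(report, format = c("json", "markdown")) {
  stopifnot(inherits(report, "qa_report"))
  if (is.null(report$records) || nrow(report$records) == 0L) {
    stop("generation refused: report has no records", call. = FALSE)
  }
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unknown report format", call. = FALSE)
  })
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      unclass(report),
      dataframe = "columns", auto_unbox = TRUE, digits = I(17), na = "null",
      null = "null"
    )))
  }
  md_report(report)
}

fmt_dev <- function(x) ifelse(is.na(x), "-", sprintf("%+.3f", x))

md_report <- function(report) {
  rec <- report$records
  lines <- c(
    "# SGRT dynamic localization QA report",
    "",
    sprintf(
      "- overall verdict: **%s**",
      if (report$overall == "pass") "pass" else "FAIL"
    ),
    sprintf(
      "- tolerances (TG-142 SABR): %.3g mm translations, %.3g deg rotations",
      report$tolerances$translation_tol_mm, report$tolerances$rotation_tol_deg
    )
  )
  if (length(report$metadata)) {
    lines <- c(lines, vapply(names(report$metadata), function(k) {
      sprintf("- %s: %s", k, as.character(report$metadata[[k]]))
    }, character(1)))
  }
  lines <- c(
    lines, "",
    "## Maximum deviation per source (signed, largest magnitude)", "",
    "| source | kind | max deviation | n |",
    "|---|---|---|---|",
    sprintf(
      "| %s | %s | %s | %d |",
      report$maxima$source, report$maxima$kind,
      fmt_dev(report$maxima$max_deviation), report$maxima$n
    ),
    "",
    "## Verdicts", "",
    sprintf(
      "- %s: %s", names(report$verdicts),
      ifelse(unlist(report$verdicts) == "fail", "FAIL", unlist(report$verdicts))
    ),
    "",
    "## Per-step deviations (measured - expected)", "",
    "| step | axis | expected | dev traj | dev surf | dev MV | status |",
    "|---|---|---|---|---|---|---|"
  )
  status <- apply(rec[paste0("pass_", REPORT_SOURCES)], 1, function(p) {
    p <- p[!is.na(p)]
    if (length(p) && all(p)) "pass" else "FAIL"
  })
  lines <- c(lines, sprintf(
    "| %d | %s | %+.3f | %s | %s | %s | %s |",
    rec$step_index, rec$axis, rec$expected,
    fmt_dev(rec$dev_traj), fmt_dev(rec$dev_surf), fmt_dev(rec$dev_mv),
    status
  ))
  paste(lines, collapse = "\n")
}

#' Parse a JSON QA report
#'
#' Inverse of `generate_report(report, "json")`.
#'
#' @param text JSON document as a character string.
#' @return A `qa_report`.
#' @export
parse_report_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || !startsWith(obj$schema_version, "1")) {
    stop("parse error: unsupported report schema_version", call. = FALSE)
  }
  rec <- as.data.frame(obj$records)
  for (src in REPORT_SOURCES) {
    mcol <- paste0("measured_", src)
    dcol <- paste0("dev_", src)
    pcol <- paste0("pass_", src)
    if (is.null(rec[[mcol]])) rec[[mcol]] <- NA_real_
    if (is.null(rec[[dcol]])) rec[[dcol]] <- NA_real_
    rec[[mcol]] <- as.numeric(rec[[mcol]])
    rec[[dcol]] <- as.numeric(rec[[dcol]])
    rec[[pcol]] <- as.logical(rec[[pcol]])
  }
  maxima <- as.data.frame(obj$maxima)
  maxima$max_deviation <- as.numeric(maxima$max_deviation)
  structure(
    list(
      schema_version = obj$schema_version,
      records = rec,
      maxima = maxima,
      verdicts = obj$verdicts,
      overall = obj$overall,
      tolerances = obj$tolerances,
      metadata = if (length(obj$metadata)) obj$metadata else list(),
      class = NULL
    )[c(
      "schema_version", "records", "maxima", "verdicts", "overall",
      "tolerances", "metadata"
    )],
    class = "qa_report"
  )
}
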