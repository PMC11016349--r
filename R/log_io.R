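# Open text dialects for machine time series.
#
# trajlog v1: `# key: value` header block, then CSV. One row per sample on a
# uniform grid. Mandatory columns: t_s, <axis>_expected and <axis>_actual
# for the six couch axes and gantry_deg, and cumulative mu. Extra columns
# are preserved verbatim.
#
# surflog v1: same header block; columns t_s plus the six surface offset
# axes (offsets from the reference capture). Timestamps may be non-uniform.
# The dialect has no beam-on flag; a beam-like column is ignored with a
# warning. Values are written with six decimals, so round-trips are exact
# to 1e-6.

TRAJ_AXES <- c(POSE_AXES, "gantry_deg")
TRAJ_COLUMNS <- c(
  "t_s",
  as.vector(t(outer(TRAJ_AXES, c("expected", "actual"), paste, sep = "_"))),
  "mu"
)
SURF_COLUMNS <- c("t_s", POSE_AXES)

#' Construct a trajectory log
#'
#' @param sample_interval_s Uniform sampling period (s).
#' @param data Data frame with the trajlog v1 columns: `t_s`,
#'   `<axis>_expected`/`<axis>_actual` for the six couch axes and
#'   `gantry_deg`, and cumulative `mu`. Extra columns are carried through.
#' @param meta Named list of free-form header metadata.
#' @return Object of class `trajectory_log`.
#' @export
trajectory_log <- function(sample_interval_s, data, meta = list()) {
  log <- structure(
    list(
      sample_interval_s = as.numeric(sample_interval_s),
      data = as.data.frame(data),
      meta = meta
    ),
    class = "trajectory_log"
  )
  err <- validate_trajectory_log(log)
  if (length(err)) {
    stop("validation error: ", paste(err, collapse = "; "), call. = FALSE)
  }
  log
}

#' Validate a trajectory log
#'
#' @param log A `trajectory_log`.
#' @return Character vector of violations, each naming the violated rule
#'   (empty when valid).
#' @export
validate_trajectory_log <- function(log) {
  problems <- character(0)
  d <- log$data
  missing_cols <- setdiff(TRAJ_COLUMNS, names(d))
  if (length(missing_cols)) {
    return(paste0(
      "missing mandatory column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!is.finite(log$sample_interval_s) || log$sample_interval_s <= 0) {
    problems <- c(problems, "sample_interval_s must be finite and > 0")
  }
  for (cl in names(d)) {
    if (!is.numeric(d[[cl]])) next
    bad <- which(!is.finite(d[[cl]]))
    if (length(bad)) {
      problems <- c(problems, paste0(
        "non-finite value in column '", cl, "' at row ", bad[1]
      ))
    }
  }
  if (nrow(d) > 1L) {
    dt <- diff(d$t_s)
    if (any(dt <= 0)) {
      problems <- c(problems, paste0(
        "timestamps must be strictly increasing (violated at row ",
        which(dt <= 0)[1] + 1L, ")"
      ))
    } else if (any(abs(dt - log$sample_interval_s) > 1e-9)) {
      problems <- c(problems, paste0(
        "timestamps must be uniform at sample_interval_s within 1e-9 s ",
        "(violated at row ", which(abs(dt - log$sample_interval_s) > 1e-9)[1] + 1L, ")"
      ))
    }
    dmu <- diff(d$mu)
    if (any(dmu < -1e-9)) {
      problems <- c(problems, paste0(
        "mu must be non-decreasing (violated at row ", which(dmu < -1e-9)[1] + 1L, ")"
      ))
    }
  }
  problems
}

#' Construct a surface-imaging log
#'
#' @param data Data frame with columns `t_s` and the six surface offset
#'   axes (see [pose_axes()]); offsets are relative to the reference
#'   capture. Timestamps may be non-uniform.
#' @param meta Named list of free-form header metadata.
#' @return Object of class `surface_log`.
#' @export
surface_log <- function(data, meta = list()) {
  log <- structure(
    list(data = as.data.frame(data), meta = meta),
    class = "surface_log"
  )
  err <- validate_surface_log(log)
  if (length(err)) {
    stop("validation error: ", paste(err, collapse = "; "), call. = FALSE)
  }
  log
}

#' Validate a surface log
#'
#' @param log A `surface_log`.
#' @return Character vector of violations (empty when valid).
#' @export
validate_surface_log <- function(log) {
  problems <- character(0)
  d <- log$data
  missing_cols <- setdiff(SURF_COLUMNS, names(d))
  if (length(missing_cols)) {
    return(paste0(
      "missing mandatory column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  for (cl in names(d)) {
    if (!is.numeric(d[[cl]])) next
    bad <- which(!is.finite(d[[cl]]))
    if (length(bad)) {
      problems <- c(problems, paste0(
        "non-finite value in column '", cl, "' at row ", bad[1]
      ))
    }
  }
  if (nrow(d) > 1L && any(diff(d$t_s) <= 0)) {
    problems <- c(problems, paste0(
      "timestamps must be strictly increasing (violated at row ",
      which(diff(d$t_s) <= 0)[1] + 1L, ")"
    ))
  }
  problems
}

split_stream <- function(stream) {
  if (length(stream) == 1L && grepl("\n", stream, fixed = TRUE)) {
    stream <- strsplit(stream, "\n", fixed = TRUE)[[1]]
  }
  stream
}

parse_header_block <- function(lines) {
  hdr_idx <- grep("^#", lines)
  hdr_idx <- hdr_idx[hdr_idx == seq_along(hdr_idx)] # leading block only
  kv <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  list(meta = kv, body = lines[setdiff(seq_along(lines), hdr_idx)])
}

read_dialect_body <- function(body) {
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    stop("parse error: no column header line found", call. = FALSE)
  }
  utils::read.csv(text = paste(body, collapse = "\n"), check.names = FALSE)
}

#' Parse a trajectory log (trajlog dialect v1)
#'
#' @param stream Text: a single string, a character vector of lines, or a
#'   file path (see [read_trajectory_log()] for the file convenience).
#' @return A [trajectory_log()].
#' @export
parse_trajectory_log <- function(stream) {
  lines <- split_stream(stream)
  hb <- parse_header_block(lines)
  if (!identical(hb$meta$dialect, "trajlog")) {
    stop("parse error: header must declare '# dialect: trajlog'", call. = FALSE)
  }
  if (!identical(hb$meta$version, "1")) {
    stop("parse error: unsupported trajlog version '", hb$meta$version, "'",
      call. = FALSE
    )
  }
  si <- suppressWarnings(as.numeric(hb$meta$sample_interval_s))
  if (is.na(si)) {
    stop("parse error: header must declare sample_interval_s", call. = FALSE)
  }
  d <- read_dialect_body(hb$body)
  missing_cols <- setdiff(TRAJ_COLUMNS, names(d))
  if (length(missing_cols)) {
    stop("parse error: missing mandatory column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  meta <- hb$meta[setdiff(names(hb$meta), c("dialect", "version", "sample_interval_s"))]
  trajectory_log(si, d, meta = meta)
}

#' Read a trajectory log file
#' @param path File path.
#' @return A [trajectory_log()].
#' @export
read_trajectory_log <- function(path) parse_trajectory_log(readLines(path))

#' Parse a surface-imaging log (surflog dialect v1)
#'
#' A beam-on-like column (name containing "beam") is not part of the
#' dialect; it is dropped with a warning.
#'
#' @param stream Text: a single string or a character vector of lines.
#' @return A [surface_log()].
#' @export
parse_surface_log <- function(stream) {
  lines <- split_stream(stream)
  hb <- parse_header_block(lines)
  if (!identical(hb$meta$dialect, "surflog")) {
    stop("parse error: header must declare '# dialect: surflog'", call. = FALSE)
  }
  if (!identical(hb$meta$version, "1")) {
    stop("parse error: unsupported surflog version '", hb$meta$version, "'",
      call. = FALSE
    )
  }
  d <- read_dialect_body(hb$body)
  beam_cols <- grep("beam", names(d), ignore.case = TRUE, value = TRUE)
  if (length(beam_cols)) {
    warning(
      "surflog dialect has no beam-on flag; ignoring column(s): ",
      paste(beam_cols, collapse = ", "),
      call. = FALSE
    )
    d <- d[setdiff(names(d), beam_cols)]
  }
  missing_cols <- setdiff(SURF_COLUMNS, names(d))
  if (length(missing_cols)) {
    stop("parse error: missing mandatory column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  meta <- hb$meta[setdiff(names(hb$meta), c("dialect", "version"))]
  surface_log(d, meta = meta)
}

#' Read a surface log file
#' @param path File path.
#' @return A [surface_log()].
#' @export
read_surface_log <- function(path) parse_surface_log(readLines(path))

format_body <- function(d) {
  cols <- lapply(d, function(v) {
    if (is.numeric(v)) sprintf("%.6f", v) else as.character(v)
  })
  header <- paste(names(d), collapse = ",")
  if (!nrow(d)) {
    return(header)
  }
  c(header, do.call(paste, c(cols, sep = ",")))
}

check_writable <- function(d, what) {
  for (cl in names(d)) {
    if (is.numeric(d[[cl]])) {
      bad <- which(!is.finite(d[[cl]]))
      if (length(bad)) {
        stop("write error: non-finite value in ", what, " column '", cl,
          "' at row ", bad[1],
          call. = FALSE
        )
      }
    }
  }
}

#' Write a trajectory log (trajlog dialect v1)
#'
#' @param log A [trajectory_log()].
#' @param file Optional path; when `NULL` the text is returned only.
#' @return Character vector of lines, invisibly when `file` is given.
#' @export
write_trajectory_log <- function(log, file = NULL) {
  err <- validate_trajectory_log(log)
  if (length(err)) {
    stop("write error: ", paste(err, collapse = "; "), call. = FALSE)
  }
  d <- log$data
  check_writable(d, "trajectory log")
  d <- d[c(TRAJ_COLUMNS, setdiff(names(d), TRAJ_COLUMNS))]
  lines <- c(
    "# dialect: trajlog",
    "# version: 1",
    sprintf("# sample_interval_s: %.6f", log$sample_interval_s),
    sprintf("# %s: %s", names(log$meta), vapply(log$meta, as.character, character(1))),
    format_body(d)
  )
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Write a surface log (surflog dialect v1)
#'
#' @param log A [surface_log()].
#' @param file Optional path; when `NULL` the text is returned only.
#' @return Character vector of lines, invisibly when `file` is given.
#' @export
write_surface_log <- function(log, file = NULL) {
  err <- validate_surface_log(log)
  if (length(err)) {
    stop("write error: ", paste(err, collapse = "; "), call. = FALSE)
  }
  d <- log$data
  check_writable(d, "surface log")
  d <- d[c(SURF_COLUMNS, setdiff(names(d), SURF_COLUMNS))]
  lines <- c(
    "# dialect: surflog",
    "# version: 1",
    sprintf("# %s: %s", names(log$meta), vapply(log$meta, as.character, character(1))),
    format_body(d)
  )
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @export
print.trajectory_log <- function(x, ...) {
  cat("<trajectory_log> ", nrow(x$data), " samples @ ",
    1 / x$sample_interval_s, " Hz, ",
    "mu ", if (nrow(x$data)) max(x$data$mu) else 0, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.surface_log <- function(x, ...) {
  cat("<surface_log> ", nrow(x$data), " samples",
    if (nrow(x$data) > 1) {
      sprintf(
        " over %.2f s", x$data$t_s[nrow(x$data)] - x$data$t_s[1]
      )
    } else {
      ""
    }, "\n",
    sep = ""
  )
  invisible(x)
}
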