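# XML rendering of a motion plan in the package's own versioned control
# schema (dynqa-plan v1). The proprietary vendor scripting schema is not
# published, so this schema is self-defined: one <controlPoint> per step
# carrying absolute axis values (reference + delta), the gantry angle, MU,
# and the imaging directive. Documents round-trip byte-identically through
# parse_developer_xml() / render_developer_xml().

# %.17g preserves doubles exactly through print -> parse.
fmt_num <- function(x) sprintf("%.17g", x)

#' Render a motion plan as an XML control script
#'
#' Serializes the plan into the package's versioned `dynqaPlan` schema.
#' Axis values inside each `<controlPoint>` are absolute (reference +
#' delta); the sign convention (IEC 61217: +lat = couch X, +lng = couch Y,
#' +vrt = couch Z, rotations right-handed about those axes) is embedded as
#' a comment in the document header.
#'
#' @param plan A valid [motion_plan()]; step-level invariant violations are
#'   rejected with a message listing the offending steps.
#' @return XML document as a single character string.
#' @seealso [parse_developer_xml()]
#' @export
render_developer_xml <- function(plan) {
  problems <- validate_motion_plan(plan)
  if (length(problems)) {
    stop("validation error: invalid motion plan:\n  ",
      paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  doc <- xml2::xml_new_root(
    "dynqaPlan",
    schemaVersion = plan$metadata$schema_version %||% PLAN_SCHEMA_VERSION
  )
  xml2::xml_add_child(doc, xml2::xml_comment(paste(
    " axes: IEC 61217; lat=X (+ couch left), lng=Y (+ toward gantry),",
    "vrt=Z (+ up); yaw/pitch/roll right-handed, degrees "
  )))
  md <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(md, "label", plan$metadata$label %||% "")
  xml2::xml_add_child(md, "created", plan$metadata$created %||% "")
  xml2::xml_add_child(md, "convention", plan$metadata$convention %||% "")
  ref <- xml2::xml_add_child(doc, "reference")
  for (a in POSE_AXES) xml2::xml_set_attr(ref, a, fmt_num(plan$reference[[a]]))
  seq_node <- xml2::xml_add_child(doc, "sequence")
  st <- plan$steps
  for (i in seq_len(nrow(st))) {
    cp <- xml2::xml_add_child(
      seq_node, "controlPoint",
      index = as.character(st$index[i]),
      gantry_deg = fmt_num(st$gantry_deg[i]),
      mu = fmt_num(st$mu[i]),
      acquireMV = if (st$acquire_mv[i]) "true" else "false"
    )
    couch <- xml2::xml_add_child(cp, "couch")
    for (a in POSE_AXES) {
      xml2::xml_set_attr(couch, a, fmt_num(plan$reference[[a]] + st[[a]][i]))
    }
  }
  as.character(doc)
}

xml_num_attr <- function(node, attr, where) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) {
    stop("parse error: missing attribute '", attr, "' in ", where, call. = FALSE)
  }
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) {
    stop("parse error: non-numeric attribute '", attr, "' in ", where, call. = FALSE)
  }
  out
}

#' Parse an XML control script into a motion plan
#'
#' Inverse of [render_developer_xml()]: absolute control-point axis values
#' are converted back to deltas from the `<reference>` pose. The recovered
#' plan is field-wise exact (the renderer prints full double precision).
#'
#' @param text XML document as a character string, or a file path.
#' @return A [motion_plan()].
#' @export
parse_developer_xml <- function(text) {
  doc <- tryCatch(
    xml2::read_xml(text),
    error = function(e) {
      stop("parse error: ", conditionMessage(e), call. = FALSE)
    }
  )
  root <- xml2::xml_name(doc)
  if (root != "dynqaPlan") {
    stop("parse error: unknown root element '", root, "'", call. = FALSE)
  }
  schema <- xml2::xml_attr(doc, "schemaVersion")
  if (is.na(schema) || !startsWith(schema, "1")) {
    stop("parse error: unsupported schemaVersion '", schema, "'", call. = FALSE)
  }
  kids <- xml2::xml_children(doc)
  known <- c("metadata", "reference", "sequence")
  for (k in kids) {
    nm <- xml2::xml_name(k)
    if (!nm %in% known) {
      stop("parse error: unknown element '", nm, "' under <dynqaPlan>",
        call. = FALSE
      )
    }
  }
  md_node <- xml2::xml_find_first(doc, "./metadata")
  ref_node <- xml2::xml_find_first(doc, "./reference")
  seq_node <- xml2::xml_find_first(doc, "./sequence")
  if (inherits(ref_node, "xml_missing") || inherits(seq_node, "xml_missing")) {
    stop("parse error: document must contain <reference> and <sequence>",
      call. = FALSE
    )
  }
  reference <- as_pose6dof(vapply(
    POSE_AXES, function(a) xml_num_attr(ref_node, a, "<reference>"), numeric(1)
  ))
  metadata <- list(schema_version = schema)
  if (!inherits(md_node, "xml_missing")) {
    for (f in c("label", "created", "convention")) {
      n <- xml2::xml_find_first(md_node, paste0("./", f))
      if (!inherits(n, "xml_missing")) metadata[[f]] <- xml2::xml_text(n)
    }
  }
  cps <- xml2::xml_children(seq_node)
  rows <- vector("list", length(cps))
  for (i in seq_along(cps)) {
    cp <- cps[[i]]
    if (xml2::xml_name(cp) != "controlPoint") {
      stop("parse error: unknown element '", xml2::xml_name(cp),
        "' under <sequence> (position ", i, ")",
        call. = FALSE
      )
    }
    where <- paste0("<controlPoint> #", i)
    couch <- xml2::xml_find_first(cp, "./couch")
    if (inherits(couch, "xml_missing")) {
      stop("parse error: missing <couch> in ", where, call. = FALSE)
    }
    absolute <- vapply(
      POSE_AXES, function(a) xml_num_attr(couch, a, where), numeric(1)
    )
    acq <- xml2::xml_attr(cp, "acquireMV")
    if (is.na(acq) || !acq %in% c("true", "false")) {
      stop("parse error: acquireMV must be 'true' or 'false' in ", where,
        call. = FALSE
      )
    }
    rows[[i]] <- step_row(
      index = as.integer(xml_num_attr(cp, "index", where)),
      delta = as_pose6dof(absolute - reference),
      gantry_deg = xml_num_attr(cp, "gantry_deg", where),
      acquire_mv = identical(acq, "true"),
      mu = xml_num_attr(cp, "mu", where)
    )
  }
  steps <- if (length(rows)) do.call(rbind, rows) else empty_steps()
  motion_plan(reference = reference, steps = steps, metadata = metadata)
}
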