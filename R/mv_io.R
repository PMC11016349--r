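# On-disk MV image formats: 16-bit grayscale TIFF (canonical, lossless to
# 1/65535) or 8-bit PNG, each with a JSON geometry sidecar
# (<image>.json) carrying pixel pitch, SAD/SID, gantry angle, and the
# associated plan step. DICOM export from the linac is converted upstream;
# the sidecar mirrors the tags that matter (pixel spacing, distances).

sidecar_path <- function(path) paste0(path, ".json")

#' Write an MV image with its geometry sidecar
#'
#' @param img An [mv_image()].
#' @param path Output path ending in `.tif`/`.tiff` (16-bit) or `.png`
#'   (8-bit).
#' @return `path`, invisibly.
#' @export
write_mv_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img$pixels, path, bits.per.sample = 16)
  } else if (ext == "png") {
    png::writePNG(img$pixels, path)
  } else {
    stop("unsupported image format '.", ext, "' (use .tif/.tiff or .png)",
      call. = FALSE
    )
  }
  jsonlite::write_json(
    list(
      pixel_pitch_mm = img$pixel_pitch_mm,
      sid_mm = img$sid_mm,
      sad_mm = img$sad_mm,
      gantry_deg = img$gantry_deg,
      step_index = img$step_index
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = I(17), na = "null"
  )
  invisible(path)
}

#' Read an MV image and its geometry sidecar
#'
#' @param path Image path (`.tif`/`.tiff`/`.png`); the sidecar
#'   `<path>.json` must exist.
#' @return An [mv_image()].
#' @export
read_mv_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pixels <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image format '.", ext, "'", call. = FALSE)
  }
  if (length(dim(pixels)) == 3L) pixels <- pixels[, , 1] # grayscale expected
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing geometry sidecar: ", sc, call. = FALSE)
  }
  g <- jsonlite::read_json(sc, simplifyVector = TRUE)
  mv_image(
    pixels,
    geometry = imaging_geometry(g$sad_mm, g$sid_mm, g$pixel_pitch_mm),
    gantry_deg = g$gantry_deg,
    step_index = if (is.null(g$step_index)) NA_integer_ else as.integer(g$step_index)
  )
}

#' Write a simulated session to a directory
#'
#' Writes `trajlog.csv`, `surflog.csv`, an `images/` directory of 16-bit
#' TIFFs with sidecars, and `truth.json`.
#'
#' @param session A `qa_session` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory_log(session$trajectory, file.path(dir, "trajlog.csv"))
  write_surface_log(session$surface, file.path(dir, "surflog.csv"))
  if (length(session$images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (img in session$images) {
      write_mv_image(
        img,
        file.path(img_dir, sprintf("step_%03d_g%03.0f.tif", img$step_index, img$gantry_deg))
      )
    }
  }
  jsonlite::write_json(
    session$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = I(17), dataframe = "columns"
  )
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return List with `trajectory`, `surface`, and `images` (truth is not
#'   reloaded; analysis must not peek at it).
#' @export
read_session <- function(dir) {
  img_dir <- file.path(dir, "images")
  images <- list()
  if (dir.exists(img_dir)) {
    paths <- sort(list.files(img_dir, pattern = "\\.(tif|tiff|png)$", full.names = TRUE))
    images <- lapply(paths, read_mv_image)
  }
  list(
    trajectory = read_trajectory_log(file.path(dir, "trajlog.csv")),
    surface = read_surface_log(file.path(dir, "surflog.csv")),
    images = images
  )
}
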