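#' Read an en-face image from TIFF or PNG
#'
#' Accepts 8-bit grayscale or 8-bit RGB (RGB is collapsed through
#' [to_grayscale8()]; an alpha channel is dropped with a warning).
#' 16-bit input is rejected: rescale to 8-bit before analysis, since the
#' whole pipeline is defined on the 0–255 scale.
#'
#' @param path TIFF (`.tif`/`.tiff`) or PNG file.
#' @param slab_label Provenance tag for the returned image.
#' @return An [enface_image].
#' @export
read_enface_image <- function(path, slab_label = "other") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && any(bits > 8))
      stopf("%s is %d-bit; convert to 8-bit (0-255) before analysis",
            path, max(bits))
    vals <- img
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8)
      stopf("%s is %d-bit; convert to 8-bit (0-255) before analysis",
            path, info$bit.depth)
    vals <- round_half_up(img * 255)
  } else {
    stopf("unsupported image format '%s' (use TIFF or PNG)", ext)
  }
  if (length(dim(vals)) == 3L && dim(vals)[3] %in% c(2L, 4L)) {
    warning(sprintf("dropping alpha channel of %s", path), call. = FALSE)
    vals <- if (dim(vals)[3] == 2L) vals[, , 1L, drop = TRUE]
            else vals[, , 1:3, drop = FALSE]
  }
  if (length(vals) == 0L) stopf("zero-size image: %s", path)
  to_grayscale8(vals, slab_label = slab_label)
}

#' Write an en-face image to TIFF or PNG
#'
#' Writes 8-bit grayscale; the format follows the file extension.
#'
#' @param image An [enface_image] or matrix in `[0, 255]`.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_enface_image <- function(image, path) {
  px <- round_half_up(as_pixels(image)) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(px, path, bits.per.sample = 8L)
  else if (ext == "png")
    png::writePNG(px, path)
  else stopf("unsupported image format '%s' (use TIFF or PNG)", ext)
  invisible(path)
}

#' Read an OCTA volume with its sidecar header
#'
#' The volume is a multi-page grayscale TIFF, one en-face lateral plane
#' per page from anterior to posterior. The JSON sidecar supplies
#' `axial_pitch_um`, `lateral_pitch_um`, optional `field_size_mm`, the
#' `rpe_outer_depth_um` and `csi_depth_um` surfaces (scalar for a flat
#' surface or a full per-A-scan matrix), and the 1-based `fovea`
#' position.
#'
#' @param tiff_path Multi-page TIFF of the flow volume.
#' @param header_path JSON sidecar; defaults to `tiff_path` with a
#'   `.json` extension.
#' @return A list: `volume` ([octa_volume]), `surfaces` ([surface_map]).
#' @export
read_octa_volume <- function(tiff_path,
                             header_path = paste0(
                               tools::file_path_sans_ext(tiff_path),
                               ".json")) {
  if (!file.exists(tiff_path)) stopf("file not found: %s", tiff_path)
  if (!file.exists(header_path)) stopf("sidecar header not found: %s",
                                       header_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  hdr <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  for (k in c("axial_pitch_um", "lateral_pitch_um", "fovea"))
    if (is.null(hdr[[k]])) stopf("header is missing '%s'", k)
  dlat <- dim(pages[[1]])[1:2]
  flow <- array(0, c(dlat, length(pages)))
  for (d in seq_along(pages)) flow[, , d] <- pages[[d]]
  as_surface <- function(x) {
    if (length(x) == 1L) matrix(as.numeric(x), dlat[1], dlat[2])
    else as.matrix(x)
  }
  list(volume = octa_volume(flow, hdr$axial_pitch_um, hdr$lateral_pitch_um,
                            hdr$field_size_mm),
       surfaces = surface_map(as_surface(hdr$rpe_outer_depth_um),
                              as_surface(hdr$csi_depth_um),
                              fovea = hdr$fovea))
}

#' Write an OCTA volume with its sidecar header
#'
#' @param volume An [octa_volume].
#' @param surfaces A [surface_map].
#' @param tiff_path Output multi-page TIFF path.
#' @param header_path Output JSON sidecar path.
#' @return `tiff_path`, invisibly.
#' @export
write_octa_volume <- function(volume, surfaces, tiff_path,
                              header_path = paste0(
                                tools::file_path_sans_ext(tiff_path),
                                ".json")) {
  pages <- lapply(seq_len(dim(volume$flow)[3]),
                  function(d) round_half_up(volume$flow[, , d]) / 255)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 8L)
  hdr <- list(axial_pitch_um = volume$axial_pitch_um,
              lateral_pitch_um = volume$lateral_pitch_um,
              field_size_mm = volume$field_size_mm,
              rpe_outer_depth_um = surfaces$rpe_outer_depth_um,
              csi_depth_um = surfaces$csi_depth_um,
              fovea = surfaces$fovea)
  jsonlite::write_json(hdr, header_path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(tiff_path)
}

cohort_columns <- c("case_id", "eye_index", "laterality", "sex", "age",
                    "sct_um", "flow_pct", "sd_octa")

#' Read and validate a cohort CSV
#'
#' Required columns: `case_id, eye_index, laterality, sex, age, sct_um,
#' flow_pct, sd_octa` (header required, UTF-8, "." decimal; `sd_octa`
#' as `+`/`-` or logical). Malformed rows are reported with their line
#' numbers; a duplicated `(case_id, laterality)` pair is an error.
#'
#' @param path CSV file.
#' @return Data frame of validated eye records.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0L) stopf("empty cohort file: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(cohort_columns, names(d))
  if (length(missing))
    stopf("cohort table is missing column(s): %s",
          paste(missing, collapse = ", "))
  if (nrow(d) == 0L) stopf("cohort table has no rows: %s", path)
  line <- seq_len(nrow(d)) + 1L  # header is line 1
  num <- function(col) suppressWarnings(as.numeric(d[[col]]))
  problems <- character()
  flag <- function(ok, what) {
    if (any(!ok))
      problems <<- c(problems, sprintf("%s (line %s)", what,
                                       paste(line[!ok], collapse = ", ")))
  }
  case_id <- num("case_id"); eye_index <- num("eye_index")
  age <- num("age"); sct <- num("sct_um"); flow <- num("flow_pct")
  flag(!is.na(case_id) & case_id > 0, "non-numeric or invalid case_id")
  flag(!is.na(eye_index), "non-numeric eye_index")
  flag(d$laterality %in% c("OD", "OS"), "laterality must be OD or OS")
  flag(d$sex %in% c("M", "F"), "sex must be M or F")
  flag(!is.na(age) & age > 0, "non-numeric or invalid age")
  flag(!is.na(sct) & sct > 0, "sct_um must be a positive number")
  flag(!is.na(flow) & flow >= 0 & flow <= 100,
       "flow_pct must lie in [0, 100]")
  flag(d$sd_octa %in% c("+", "-", "TRUE", "FALSE", "true", "false"),
       "sd_octa must be +/- or logical")
  if (length(problems))
    stopf("invalid cohort table %s:\n  %s", path,
          paste(problems, collapse = "\n  "))
  key <- paste(case_id, d$laterality)
  if (anyDuplicated(key))
    stopf("duplicate (case_id, laterality) pair(s): %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  data.frame(case_id = as.integer(case_id),
             eye_index = as.integer(eye_index),
             laterality = d$laterality, sex = d$sex, age = age,
             sct_um = sct, flow_pct = flow,
             sd_octa = d$sd_octa %in% c("+", "TRUE", "true"),
             stringsAsFactors = FALSE)
}

#' Write a cohort summary (or any report) as JSON
#'
#' @param summary A [summarize_cohort()] result or any list of scalars.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' A flat key-value configuration covering every tunable of the
#' pipeline, with schema validation: unknown keys are rejected and each
#' value must lie in its owning module's declared range. Serializes to
#' JSON and round-trips exactly.
#'
#' @param ... Named overrides of the defaults; see
#'   `names(pipeline_config())`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    cc_offset_um = 30, cc_width_um = 30,
    hc_width_um = 30, hc_placement = "centered",
    projection = "max", grayscale = "mean",
    bernsen_radius_px = 15, bernsen_contrast = 15,
    disc_center_row = NA_real_, disc_center_col = NA_real_,
    disc_semi_axis_row = NA_real_, disc_semi_axis_col = NA_real_,
    eligibility_min_sct_um = 150, not_visible_threshold = 5,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$hc_placement %in% c("centered", "start"))
    stopf("hc_placement must be 'centered' or 'start'")
  if (!cfg$projection %in% c("max", "mean"))
    stopf("projection must be 'max' or 'mean'")
  if (!cfg$grayscale %in% c("mean", "luma"))
    stopf("grayscale must be 'mean' or 'luma'")
  bernsen_params(cfg$bernsen_radius_px, cfg$bernsen_contrast)  # validate
  if (cfg$cc_offset_um < 0 || cfg$cc_width_um <= 0 || cfg$hc_width_um <= 0)
    stopf("slab offsets must be >= 0 and widths > 0")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with a flat configuration object.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- vals[!vapply(vals, function(x) is.null(x) ||
                         (length(x) == 1L && is.na(x)), logical(1))]
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
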