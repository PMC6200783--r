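#' En-face OCTA image
#'
#' A 2-D grid of 8-bit flow intensities with lateral pixel pitch and a
#' provenance tag saying which slab (or subtraction stage) it came from.
#'
#' @param pixels Numeric matrix with values in `[0, 255]` (rows x cols,
#'   origin top-left).
#' @param lateral_pitch Lateral sampling pitch in micrometres per pixel
#'   (`NA` if unknown, e.g. for images read from file without metadata).
#' @param slab_label Provenance tag, one of `"choriocapillaris"`,
#'   `"half_choroid"`, `"sub_a"`, `"sub_b"`, `"final"` or `"other"`.
#' @return An `enface_image`: the pixel matrix with class and metadata
#'   attributes attached.
#' @examples
#' img <- enface_image(matrix(0:255, 16, 16), lateral_pitch = 12)
#' dim(img)
#' @export
enface_image <- function(pixels, lateral_pitch = NA_real_,
                         slab_label = c("other", "choriocapillaris",
                                        "half_choroid", "sub_a", "sub_b",
                                        "final")) {
  slab_label <- match.arg(slab_label)
  pixels <- as.matrix(pixels)
  if (!is_pixel_matrix(pixels))
    stopf("en-face pixels must be a finite numeric matrix in [0, 255]")
  structure(pixels, class = c("enface_image", class(pixels)),
            lateral_pitch = lateral_pitch, slab_label = slab_label)
}

# Accept either an enface_image or a bare matrix; return the pixel matrix.
as_pixels <- function(x, arg = "image") {
  if (inherits(x, "enface_image")) {
    y <- unclass(x)
    attr(y, "lateral_pitch") <- NULL
    attr(y, "slab_label") <- NULL
    return(y)
  }
  x <- as.matrix(x)
  if (!is_pixel_matrix(x))
    stopf("%s must be an enface_image or a numeric matrix in [0, 255]", arg)
  x
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, slab '%s', lateral pitch %s um/px\n",
              nrow(x), ncol(x), attr(x, "slab_label"),
              format(attr(x, "lateral_pitch"))))
  cat(sprintf("  intensity range [%g, %g], mean %.1f\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' OCTA flow volume
#'
#' A 3-D grid of flow-signal intensities, `rows x cols` laterally and
#' `depth` axially, with the physical sampling pitches needed to cut
#' micrometre-defined slabs out of it.
#'
#' @param flow 3-D numeric array `[row, col, depth]`, values in `[0, 255]`;
#'   depth increases posteriorly.
#' @param axial_pitch_um Micrometres per axial sample (> 0).
#' @param lateral_pitch_um Micrometres per lateral sample (> 0).
#' @param field_size_mm Lateral scan extent in millimetres (e.g. `c(12, 12)`
#'   for a wide-field macular scan); metadata only.
#' @return An `octa_volume` list.
#' @export
octa_volume <- function(flow, axial_pitch_um, lateral_pitch_um,
                        field_size_mm = NULL) {
  if (!(is.array(flow) && length(dim(flow)) == 3L))
    stopf("flow must be a 3-D array [row, col, depth]")
  if (dim(flow)[3] < 2L) stopf("volume needs at least 2 depth samples")
  if (!all(is.finite(flow)) || min(flow) < 0 || max(flow) > 255)
    stopf("flow intensities must lie in [0, 255]")
  if (!(axial_pitch_um > 0) || !(lateral_pitch_um > 0))
    stopf("axial_pitch_um and lateral_pitch_um must be positive")
  structure(list(flow = flow, axial_pitch_um = axial_pitch_um,
                 lateral_pitch_um = lateral_pitch_um,
                 field_size_mm = field_size_mm),
            class = "octa_volume")
}

#' @export
print.octa_volume <- function(x, ...) {
  d <- dim(x$flow)
  cat(sprintf(
    "<octa_volume> %d x %d lateral, %d depth samples (%g um axial pitch)\n",
    d[1], d[2], d[3], x$axial_pitch_um))
  invisible(x)
}

#' Reference surfaces for slab anchoring
#'
#' Per-A-scan axial depths (micrometres from the top of the volume) of the
#' outer retinal pigment epithelium surface and the choroid-sclera
#' interface, plus the lateral position of the fovea. These are inputs —
#' device-exported segmentations or phantom ground truth — not something
#' this package segments.
#'
#' @param rpe_outer_depth_um Matrix of outer-RPE depths, micrometres.
#' @param csi_depth_um Matrix of choroid-sclera interface depths,
#'   micrometres; must be `>= rpe_outer_depth_um` everywhere.
#' @param fovea `(row, col)` 1-based lateral index of the fovea.
#' @return A `surface_map` list.
#' @export
surface_map <- function(rpe_outer_depth_um, csi_depth_um, fovea) {
  rpe <- as.matrix(rpe_outer_depth_um)
  csi <- as.matrix(csi_depth_um)
  if (!identical(dim(rpe), dim(csi)))
    stopf("surface grids must share dimensions")
  if (any(csi < rpe))
    stopf("choroid-sclera interface lies above the outer RPE at %d positions",
          sum(csi < rpe))
  fovea <- as.integer(fovea)
  if (length(fovea) != 2L || any(fovea < 1L) ||
      fovea[1] > nrow(rpe) || fovea[2] > ncol(rpe))
    stopf("fovea position (%s) is outside the lateral grid",
          paste(fovea, collapse = ", "))
  structure(list(rpe_outer_depth_um = rpe, csi_depth_um = csi,
                 fovea = fovea),
            class = "surface_map")
}

#' Measure subfoveal choroidal thickness
#'
#' The caliper measurement: distance from the outer RPE surface to the
#' choroid-sclera interface at the fovea, in micrometres. By default it is
#' read at the single foveal A-scan; `window` > 0 takes the median over a
#' `(2*window+1)^2` lateral neighbourhood, useful on noisy phantom
#' surfaces.
#'
#' @param surfaces A [surface_map].
#' @param window Half-width of the lateral median window (default 0 = the
#'   single foveal A-scan).
#' @return Thickness in micrometres (non-negative scalar).
#' @examples
#' s <- surface_map(matrix(100, 8, 8), matrix(390, 8, 8), fovea = c(4, 4))
#' measure_sct(s)  # 290
#' @export
measure_sct <- function(surfaces, window = 0L) {
  stopifnot(inherits(surfaces, "surface_map"))
  f <- surfaces$fovea
  k <- as.integer(window)
  rows <- max(1L, f[1] - k):min(nrow(surfaces$rpe_outer_depth_um), f[1] + k)
  cols <- max(1L, f[2] - k):min(ncol(surfaces$rpe_outer_depth_um), f[2] + k)
  thick <- surfaces$csi_depth_um[rows, cols, drop = FALSE] -
    surfaces$rpe_outer_depth_um[rows, cols, drop = FALSE]
  stats::median(thick)
}

#' Slab specification
#'
#' An en-face slab defined relative to a reference surface: start
#' `offset_um` micrometres below it, `width_um` micrometres thick, with an
#' aggregation rule over depth.
#'
#' @param offset_um Axial distance from the reference surface to the slab
#'   start, micrometres (>= 0).
#' @param width_um Slab thickness, micrometres (> 0).
#' @param reference Anchoring surface; only the outer RPE is supported.
#' @param projection Aggregation over depth: `"max"` (default, typical
#'   angiography slab rendering) or `"mean"`.
#' @param label Provenance tag stored on images cut with this spec.
#' @return A `slab_spec` list.
#' @export
slab_spec <- function(offset_um, width_um, reference = "rpe_outer",
                      projection = c("max", "mean"), label = "other") {
  projection <- match.arg(projection)
  reference <- match.arg(reference)
  if (!(width_um > 0)) stopf("width_um must be positive")
  if (offset_um < 0) stopf("offset_um must be non-negative")
  structure(list(reference = reference, offset_um = offset_um,
                 width_um = width_um, projection = projection,
                 label = label),
            class = "slab_spec")
}

#' Choriocapillaris slab presets
#'
#' The analysis slab spans 30–60 um below the outer RPE surface (30 um
#' width, chosen to catch the full choriocapillaris while avoiding retinal
#' capillary projection); the `"device"` preset is the instrument's
#' default 29–49 um (20 um width).
#'
#' @param preset `"analysis"` (offset 30, width 30) or `"device"`
#'   (offset 29, width 20).
#' @param projection Depth aggregation rule, see [slab_spec()].
#' @return A `slab_spec`.
#' @export
cc_slab_spec <- function(preset = c("analysis", "device"),
                         projection = "max") {
  preset <- match.arg(preset)
  if (preset == "analysis")
    slab_spec(30, 30, projection = projection, label = "choriocapillaris")
  else
    slab_spec(29, 20, projection = projection, label = "choriocapillaris")
}

#' Half-choroid slab specification
#'
#' A 30 um-thick slab positioned at one-half of the subfoveal choroidal
#' thickness below the outer RPE — the depth at which the middle and large
#' choroidal vessels run. By default the window is centred on SCT/2
#' (`offset = sct/2 - width/2`); `placement = "start"` instead starts the
#' slab at SCT/2.
#'
#' @param sct_um Subfoveal choroidal thickness, micrometres. Values below
#'   150 um trigger a warning: such eyes are excluded from analysis to
#'   avoid pathologically thin choroids.
#' @param width_um Slab thickness, micrometres (default 30).
#' @param placement `"centered"` (default) or `"start"`.
#' @param projection Depth aggregation rule, see [slab_spec()].
#' @return A `slab_spec`.
#' @examples
#' half_choroid_spec(290)$offset_um  # 130: slab spans 130-160 um below RPE
#' @export
half_choroid_spec <- function(sct_um, width_um = 30,
                              placement = c("centered", "start"),
                              projection = "max") {
  placement <- match.arg(placement)
  if (sct_um <= width_um)
    stopf("SCT (%g um) must exceed the slab width (%g um): the half-choroid slab would reach the RPE",
          sct_um, width_um)
  if (sct_um < 150)
    warning(sprintf(
      "SCT %g um is below the 150 um eligibility cutoff; eye should be excluded",
      sct_um), call. = FALSE)
  offset <- if (placement == "centered") sct_um / 2 - width_um / 2
            else sct_um / 2
  slab_spec(offset, width_um, projection = projection,
            label = "half_choroid")
}

#' Resolve a slab to voxel index intervals
#'
#' Converts the micrometre-defined slab into per-A-scan axial voxel index
#' ranges. The depth interval `[rpe + offset, rpe + offset + width)` um is
#' mapped to a half-open sample interval by rounding `depth / axial_pitch`
#' half-up at both ends; the interval is never empty (at least one sample
#' even when the slab is thinner than one pitch).
#'
#' @param spec A [slab_spec].
#' @param surfaces A [surface_map] on the volume's lateral grid.
#' @param volume An [octa_volume].
#' @return A `slab_intervals` list with integer matrices `first` and
#'   `last` (1-based, inclusive) per lateral position.
#' @export
resolve_slab <- function(spec, surfaces, volume) {
  stopifnot(inherits(spec, "slab_spec"), inherits(surfaces, "surface_map"),
            inherits(volume, "octa_volume"))
  dlat <- dim(volume$flow)[1:2]
  if (!identical(dim(surfaces$rpe_outer_depth_um), dlat))
    stopf("surface grid (%s) does not match volume lateral grid (%s)",
          paste(dim(surfaces$rpe_outer_depth_um), collapse = "x"),
          paste(dlat, collapse = "x"))
  pitch <- volume$axial_pitch_um
  z0 <- surfaces$rpe_outer_depth_um + spec$offset_um
  z1 <- z0 + spec$width_um
  i0 <- round_half_up(z0 / pitch)        # 0-based half-open start
  i1 <- pmax(round_half_up(z1 / pitch), i0 + 1)
  ndepth <- dim(volume$flow)[3]
  bad <- which(i0 < 0 | i1 > ndepth)
  if (length(bad)) {
    pos <- arrayInd(utils::head(bad, 5L), dlat)
    stopf("slab exits the volume axial extent at %d lateral positions (first: %s)",
          length(bad),
          paste(apply(pos, 1, function(p) sprintf("(%d,%d)", p[1], p[2])),
                collapse = ", "))
  }
  structure(list(first = i0 + 1L, last = i1, spec = spec),
            class = "slab_intervals")
}

#' Project a volume slab to an en-face image
#'
#' Aggregates flow over each A-scan's resolved depth interval with the
#' spec's rule (`max` or `mean`); mean values are rounded half-up to
#' 8-bit.
#'
#' @param volume An [octa_volume].
#' @param intervals Output of [resolve_slab()] on the same volume.
#' @param projection Override of the spec's aggregation rule (optional).
#' @return An [enface_image] on the volume's lateral grid.
#' @export
project_slab <- function(volume, intervals, projection = NULL) {
  stopifnot(inherits(volume, "octa_volume"),
            inherits(intervals, "slab_intervals"))
  dlat <- dim(volume$flow)[1:2]
  if (!identical(dim(intervals$first), dlat))
    stopf("intervals were resolved on a different lateral grid")
  projection <- if (is.null(projection)) intervals$spec$projection
                else match.arg(projection, c("max", "mean"))
  first <- intervals$first
  last <- intervals$last
  out <- matrix(0, dlat[1], dlat[2])
  if (length(unique(first)) == 1L && length(unique(last)) == 1L) {
    slab <- volume$flow[, , first[1]:last[1], drop = FALSE]
    out[] <- apply(slab, c(1, 2),
                   if (projection == "max") max else mean)
  } else {
    for (r in seq_len(dlat[1]))
      for (c in seq_len(dlat[2])) {
        v <- volume$flow[r, c, first[r, c]:last[r, c]]
        out[r, c] <- if (projection == "max") max(v) else mean(v)
      }
  }
  if (projection == "mean") out <- round_half_up(out)
  enface_image(out, lateral_pitch = volume$lateral_pitch_um,
               slab_label = intervals$spec$label)
}
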