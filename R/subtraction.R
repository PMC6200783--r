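#' Convert an image to 8-bit grayscale
#'
#' RGB input (a `rows x cols x 3` array) is collapsed by the unweighted
#' channel mean, rounded half-up — the plain RGB-to-8-bit conversion of
#' common image software — or by Rec. 601 luma weights. Grayscale input
#' passes through unchanged.
#'
#' @param image An [enface_image], a numeric matrix, or a 3-channel array
#'   with values in `[0, 255]`.
#' @param weights `"mean"` (default, equal weights) or `"luma"`
#'   (0.299 R + 0.587 G + 0.114 B).
#' @param ... Passed to [enface_image()] (e.g. `slab_label`).
#' @return An [enface_image].
#' @examples
#' px <- array(c(30, 60, 90), c(1, 1, 3))
#' to_grayscale8(px)[1, 1]  # 60
#' @export
to_grayscale8 <- function(image, weights = c("mean", "luma"), ...) {
  weights <- match.arg(weights)
  if (inherits(image, "enface_image")) return(image)
  if (is.matrix(image)) return(enface_image(image, ...))
  if (is.array(image) && length(dim(image)) == 3L) {
    nch <- dim(image)[3]
    if (nch == 1L) return(enface_image(image[, , 1L], ...))
    if (nch != 3L)
      stopf("unsupported channel count: %d (expected grayscale or RGB)", nch)
    if (!all(is.finite(image)) || min(image) < 0 || max(image) > 255)
      stopf("channel values must lie in [0, 255]")
    w <- if (weights == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
    g <- image[, , 1L] * w[1] + image[, , 2L] * w[2] + image[, , 3L] * w[3]
    return(enface_image(round_half_up(g), ...))
  }
  stopf("image must be a matrix or a rows x cols x channels array")
}

#' Saturating 8-bit subtraction
#'
#' Pixelwise `max(a - b, 0)`: differences clamp at zero instead of
#' wrapping around, matching the 8-bit "Subtract" of ImageJ's Image
#' Calculator. The projection-artifact removal chain depends entirely on
#' this clamping.
#'
#' @param a,b En-face images (or matrices) of identical dimensions.
#' @param slab_label Provenance tag for the result.
#' @return An [enface_image] with `a`'s lateral pitch.
#' @examples
#' subtract_saturating(matrix(80), matrix(200))[1, 1]  # 0, not -120
#' @export
subtract_saturating <- function(a, b, slab_label = "other") {
  pa <- as_pixels(a, "a")
  pb <- as_pixels(b, "b")
  if (!identical(dim(pa), dim(pb)))
    stopf("image dimensions differ: %s vs %s",
          paste(dim(pa), collapse = "x"), paste(dim(pb), collapse = "x"))
  enface_image(pmax(pa - pb, 0),
               lateral_pitch = attr(a, "lateral_pitch") %||% NA_real_,
               slab_label = slab_label)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Remove the choriocapillaris projection artifact
#'
#' The core three-step saturating-subtraction chain. In the half-choroid
#' slab of a swept-source OCTA scan, flow in the overlying
#' choriocapillaris projects onto the choroidal stroma, so stroma appears
#' white while vessel lumina appear dark. Three subtractions recover the
#' luminal flow signal and zero out the stromal artifact:
#'
#' 1. `sub_a = cc - hc` (saturating): bright where the half-choroid is
#'    dark relative to the choriocapillaris, i.e. white vessel shapes.
#' 2. `sub_b = hc - sub_a`: near zero in the vessel lumina, retains the
#'    stroma.
#' 3. `final = hc - sub_b`: the half-choroid signal with the stromal
#'    projection removed — the choroidal blood-flow image.
#'
#' The chain has the closed form
#' `final = min(max(cc - hc, 0), hc)` per pixel: wherever the
#' choriocapillaris is at least twice the half-choroid signal the luminal
#' flow is returned in full, and wherever `cc <= hc` (pure projection)
#' the output is zero.
#'
#' @param cc Choriocapillaris en-face image.
#' @param hc Half-choroid en-face image, same dimensions.
#' @return A `subtraction_chain` list with elements `sub_a`, `sub_b`,
#'   `final` (all [enface_image]s) and `inputs_label`.
#' @examples
#' cc <- matrix(200, 2, 2); hc <- matrix(c(200, 80, 200, 80), 2, 2)
#' remove_projection_artifact(cc, hc)$final
#' # stroma (hc = 200) -> 0; lumen (hc = 80) -> 80
#' @export
remove_projection_artifact <- function(cc, hc) {
  pcc <- as_pixels(cc, "cc")
  phc <- as_pixels(hc, "hc")
  if (!identical(dim(pcc), dim(phc)))
    stopf("cc and hc dimensions differ: %s vs %s",
          paste(dim(pcc), collapse = "x"), paste(dim(phc), collapse = "x"))
  sub_a <- subtract_saturating(pcc, phc, slab_label = "sub_a")
  sub_b <- subtract_saturating(phc, sub_a, slab_label = "sub_b")
  final <- subtract_saturating(phc, sub_b, slab_label = "final")
  structure(list(sub_a = sub_a, sub_b = sub_b, final = final,
                 inputs_label = c(cc = attr(cc, "slab_label") %||%
                                    "choriocapillaris",
                                  hc = attr(hc, "slab_label") %||%
                                    "half_choroid")),
            class = "subtraction_chain")
}

#' @export
print.subtraction_chain <- function(x, ...) {
  cat(sprintf("<subtraction_chain> %d x %d px\n",
              nrow(x$final), ncol(x$final)))
  cat(sprintf("  final: mean %.1f, %.1f%% non-zero\n", mean(x$final),
              100 * mean(x$final > 0)))
  invisible(x)
}
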