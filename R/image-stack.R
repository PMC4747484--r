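#' Image stack container
#'
#' A 3-D stack of 2-D image slices with physical spacing metadata, as produced
#' by a stepped B-mode ultrasound sweep or a reconstructed micro-CT scan.
#' Pixel values are stored raw: 0-250 for grayscale ultrasound, 0-65535 for
#' 16-bit micro-CT. Slices are indexed 1-based along the stepping axis; within
#' a slice, coordinates are (row, col), 1-based.
#'
#' @param pixels 3-D numeric array, `slice x row x col`, all values
#'   non-negative and inside `pv_range`.
#' @param pixel_spacing_mm length-2 numeric, in-plane (row, col) spacing in mm.
#' @param slice_spacing_mm scalar, distance between consecutive slices in mm.
#' @param modality `"US"` or `"CT"`. Sets the admissible pixel-value range:
#'   (0, 250) for US, (0, 65535) for CT.
#' @param axis_label `"short"`, `"long"` or `"none"` — which anatomical axis
#'   the sweep stepped along (ultrasound protocols image each speck twice,
#'   with the probe across and along its long axis).
#' @param calibration optional [ct_calibration()] attached to CT stacks.
#'
#' @return An object of class `image_stack`.
#' @seealso [ct_calibration()], [score_stack_us()], [score_stack_ct()]
#' @export
image_stack <- function(pixels, pixel_spacing_mm, slice_spacing_mm,
                        modality = c("US", "CT"), axis_label = "none",
                        calibration = NULL) {
  modality <- match.arg(modality)
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    abort_format("`pixels` must be a 3-D array (slice x row x col).")
  }
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0)) {
    abort_input("`pixel_spacing_mm` must be two strictly positive values (row, col).")
  }
  if (length(slice_spacing_mm) != 1L || slice_spacing_mm <= 0) {
    abort_input("`slice_spacing_mm` must be a single strictly positive value.")
  }
  axis_label <- match.arg(axis_label, c("short", "long", "none"))
  pv_range <- pv_range_for(modality)
  if (any(pixels < pv_range[1]) || any(pixels > pv_range[2])) {
    abort_format(sprintf(
      "pixel values outside the %s range [%g, %g]",
      modality, pv_range[1], pv_range[2]
    ))
  }
  if (!is.null(calibration) && !inherits(calibration, "ct_calibration")) {
    abort_input("`calibration` must be created with ct_calibration().")
  }
  structure(
    list(
      pixels = pixels,
      pixel_spacing_mm = as.numeric(pixel_spacing_mm),
      slice_spacing_mm = as.numeric(slice_spacing_mm),
      modality = modality,
      pv_range = pv_range,
      axis_label = axis_label,
      calibration = calibration
    ),
    class = "image_stack"
  )
}

#' Representable pixel-value range of a modality
#'
#' Grayscale ultrasound frames use 0-250; 16-bit micro-CT uses 0-65535.
#'
#' @param modality `"US"` or `"CT"`.
#' @return Length-2 numeric `(min, max)`.
#' @export
pv_range_for <- function(modality) {
  switch(match.arg(modality, c("US", "CT")), US = c(0, 250), CT = c(0, 65535))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<image_stack> %s, %d slices of %d x %d px (%.3g x %.3g mm/px, %.3g mm step), axis: %s\n",
    x$modality, d[1], d[2], d[3],
    x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$slice_spacing_mm,
    x$axis_label
  ))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

n_slices <- function(stack) dim(stack$pixels)[1]

get_slice <- function(stack, i) stack$pixels[i, , , drop = TRUE]

#' Water/air calibration anchoring the Hounsfield scale
#'
#' Micro-CT reconstructions store raw 16-bit pixel values; the Hounsfield
#' scale is anchored by scanning water and air references, which by definition
#' sit at 0 HU and -1000 HU.
#'
#' @param pv_water pixel value of the water reference.
#' @param pv_air pixel value of the air reference. Must be strictly less than
#'   `pv_water`, otherwise the scale is degenerate.
#'
#' @return An object of class `ct_calibration`.
#' @examples
#' cal <- ct_calibration(pv_water = 2000, pv_air = 1000)
#' hu_from_pv(2000, cal) # 0
#' hu_from_pv(1000, cal) # -1000
#' @export
ct_calibration <- function(pv_water, pv_air) {
  if (!is.numeric(pv_water) || !is.numeric(pv_air) ||
      length(pv_water) != 1L || length(pv_air) != 1L) {
    abort_input("`pv_water` and `pv_air` must be single numbers.")
  }
  if (pv_water <= pv_air) {
    abort_calibration("degenerate calibration: `pv_water` must exceed `pv_air`.")
  }
  structure(
    list(pv_water = as.numeric(pv_water), pv_air = as.numeric(pv_air)),
    class = "ct_calibration"
  )
}

#' @export
print.ct_calibration <- function(x, ...) {
  cat(sprintf("<ct_calibration> water = %g PV (0 HU), air = %g PV (-1000 HU)\n",
              x$pv_water, x$pv_air))
  invisible(x)
}
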