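#' Convert an RGB frame to the ultrasound gray scale
#'
#' B-mode frames exported as RGB are collapsed to a single intensity channel
#' before any pixel analysis. Luma is computed with the ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), then rescaled linearly from the 8-bit range
#' to the 0-250 ultrasound pixel-value range, rounding half up. Achromatic
#' pixels (R = G = B = v) therefore map to `round(v * 250 / 255)`, and a pure
#' white frame maps to exactly 250.
#'
#' @param frame numeric array `row x col x 3`, channel values in \[0, 255\].
#' @return A `row x col` matrix of integer pixel values in \[0, 250\].
#' @examples
#' f <- array(100, dim = c(2, 2, 3))
#' rgb_to_gray(f) # all 98
#' @export
rgb_to_gray <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L) {
    abort_format("`frame` must be a row x col x 3 RGB array.")
  }
  if (any(frame < 0) || any(frame > 255)) {
    abort_format("RGB channel values must lie in [0, 255].")
  }
  luma <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  round_half_up(luma * 250 / 255)
}

#' Zero every pixel outside a region of interest
#'
#' The scoring workflow isolates each calcium speck by setting all pixel
#' values outside a wide manual ROI to zero, so that global thresholding only
#' ever selects pixels inside it. Pixels inside the region are untouched; the
#' operation is idempotent.
#'
#' @param slice 2-D numeric matrix of pixel values.
#' @param region an [roi_rect()] or [roi_polygon()].
#' @return A matrix of the same shape with zeros outside the region.
#' @export
zero_outside_roi <- function(slice, region) {
  if (!is.matrix(slice)) abort_format("`slice` must be a 2-D matrix.")
  mask <- roi_mask(region, dim(slice))
  out <- slice
  out[!mask] <- 0
  out
}

#' Select calcium pixels by global thresholding
#'
#' Marks every pixel whose value is greater than or equal to the threshold
#' (inclusive). No connectivity or minimum-size filtering is applied: global
#' thresholding selects pixels, not regions, so isolated pixels count.
#'
#' @param slice 2-D numeric matrix (typically after [zero_outside_roi()]).
#' @param threshold pixel-value threshold; 130 is the ultrasound default,
#'   chosen above the maximum gray-scale density of agar.
#' @return A logical matrix, `TRUE` where `slice >= threshold`.
#' @examples
#' s <- rbind(c(0, 129, 130), c(250, 10, 140), c(0, 0, 0))
#' select_calcium_mask(s, 130) # 3 TRUE pixels
#' @export
select_calcium_mask <- function(slice, threshold) {
  if (!is.matrix(slice)) abort_format("`slice` must be a 2-D matrix.")
  if (length(threshold) != 1L || !is.numeric(threshold)) {
    abort_input("`threshold` must be a single number.")
  }
  slice >= threshold
}

#' Measure calcium area and peak intensity on one slice
#'
#' Converts a calcium selection mask to physical area using the in-plane
#' pixel spacing, and records the maximum pixel value over the selected
#' pixels. An empty mask yields area 0 and `pv_max` 0.
#'
#' @param mask logical matrix from [select_calcium_mask()].
#' @param slice the pixel matrix the mask was computed from (same shape).
#' @param pixel_spacing_mm length-2 (row, col) spacing in mm.
#' @return A one-row tibble with columns `area_calcium_mm2` and `pv_max`.
#' @export
measure_slice <- function(mask, slice, pixel_spacing_mm) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_format("`mask` must be a logical matrix.")
  }
  if (!identical(dim(mask), dim(slice))) {
    abort_format("`mask` and `slice` must have identical dimensions.")
  }
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0)) {
    abort_input("`pixel_spacing_mm` must be two strictly positive values.")
  }
  n_sel <- sum(mask)
  tibble(
    area_calcium_mm2 = n_sel * pixel_spacing_mm[1] * pixel_spacing_mm[2],
    pv_max = if (n_sel == 0L) 0 else max(slice[mask])
  )
}
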