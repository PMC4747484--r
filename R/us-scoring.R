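#' Ultrasound calcium score for a single slice
#'
#' Runs the per-image pipeline: zero pixels outside the ROI, select calcium by
#' global thresholding at `threshold` (>= is inclusive), measure the selected
#' area and peak pixel value, and form the slice score
#' `area_calcium_mm2 * pv_max`.
#'
#' @param slice 2-D matrix of ultrasound pixel values (0-250).
#' @param region [roi_rect()]/[roi_polygon()] isolating the speck, or `NULL`
#'   for no ROI restriction (whole slice).
#' @param threshold calcium selection threshold in pixel values; the default
#'   130 sits above the maximum gray-scale density of agar.
#' @param pixel_spacing_mm length-2 (row, col) spacing in mm.
#' @return One-row tibble: `area_calcium_mm2`, `pv_max`, `score`.
#' @examples
#' s <- rbind(c(0, 129, 130), c(250, 10, 140), c(0, 0, 0))
#' score_slice_us(s, roi_rect(1, 1, 3, 3), pixel_spacing_mm = c(1, 1))
#' # area 3 mm2, pv_max 250, score 750
#' @export
score_slice_us <- function(slice, region, threshold = 130,
                           pixel_spacing_mm) {
  masked <- if (is.null(region)) slice else zero_outside_roi(slice, region)
  mask <- select_calcium_mask(masked, threshold)
  m <- measure_slice(mask, masked, pixel_spacing_mm)
  mutate(m, score = .data$area_calcium_mm2 * .data$pv_max)
}

#' Ultrasound calcium score for an image stack
#'
#' Scores every slice of a stepped sweep with [score_slice_us()] and sums the
#' per-slice scores into the axis total. Slices without a region in `rois`
#' contribute (0, 0, 0). The axis calcium volume index is the summed calcium
#' area, numerically a volume in mm^3 when the stepping interval is 1 mm; a
#' spacing-corrected `total_volume_mm3` is also reported.
#'
#' @param stack an ultrasound [image_stack()].
#' @param rois an [roi_set()] mapping slice indices to regions.
#' @param threshold calcium pixel-value threshold (default 130).
#' @return A `stack_score` object; see [tidy.stack_score()] for the per-slice
#'   table and [glance.stack_score()] for totals.
#' @export
score_stack_us <- function(stack, rois, threshold = 130) {
  if (!inherits(stack, "image_stack")) abort_input("`stack` must be an image_stack.")
  if (stack$modality != "US") abort_input("`stack` must have US modality.")
  per_slice <- map(seq_len(n_slices(stack)), function(i) {
    region <- roi_for_slice(rois, i)
    if (is.null(region)) {
      tibble(slice_index = i, area_calcium_mm2 = 0, pv_max = 0, score = 0)
    } else {
      m <- score_slice_us(get_slice(stack, i), region, threshold,
                          stack$pixel_spacing_mm)
      mutate(m, slice_index = i, .before = 1)
    }
  })
  new_stack_score(bind_rows(per_slice), stack, threshold)
}

new_stack_score <- function(per_slice, stack, threshold) {
  structure(
    list(
      per_slice = per_slice,
      total_score = sum(per_slice$score),
      total_volume_index = sum(per_slice$area_calcium_mm2),
      total_volume_mm3 = sum(per_slice$area_calcium_mm2) * stack$slice_spacing_mm,
      axis_label = stack$axis_label,
      modality = stack$modality,
      threshold = threshold
    ),
    class = "stack_score"
  )
}

#' @export
print.stack_score <- function(x, ...) {
  cat(sprintf(
    "<stack_score> %s %s axis: total score %.6g, volume index %.6g mm2 (%d slices)\n",
    x$modality, x$axis_label, x$total_score, x$total_volume_index,
    nrow(x$per_slice)
  ))
  invisible(x)
}

#' Combine short- and long-axis ultrasound results
#'
#' The ultrasound calcium score of a speck is the arithmetic mean of the two
#' axis totals; the ultrasound calcium volume is the mean of the two summed
#' areas.
#'
#' @param short,long `stack_score` objects for the short- and long-axis
#'   sweeps (axis labels are checked).
#' @return A `us_calcium_result` with fields `us_calcium_score`,
#'   `us_calcium_volume`, and the two axis results.
#' @export
combine_axes <- function(short, long) {
  if (!inherits(short, "stack_score") || !inherits(long, "stack_score")) {
    abort_input("`short` and `long` must be stack_score objects.")
  }
  if (!identical(short$axis_label, "short") || !identical(long$axis_label, "long")) {
    abort_input("axis labels must be 'short' and 'long' respectively.")
  }
  structure(
    list(
      short_axis = short,
      long_axis = long,
      us_calcium_score = (short$total_score + long$total_score) / 2,
      us_calcium_volume = (short$total_volume_index + long$total_volume_index) / 2
    ),
    class = "us_calcium_result"
  )
}

#' @export
print.us_calcium_result <- function(x, ...) {
  cat(sprintf(
    "<us_calcium_result> US calcium score %.6g, volume %.6g (short %.6g / long %.6g)\n",
    x$us_calcium_score, x$us_calcium_volume,
    x$short_axis$total_score, x$long_axis$total_score
  ))
  invisible(x)
}
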