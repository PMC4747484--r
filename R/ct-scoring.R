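#' Convert raw pixel values to Hounsfield units
#'
#' Linear calibration anchored by the water and air references, which sit at
#' 0 HU and -1000 HU by definition:
#' `HU = (pv - pv_water) / (pv_water - pv_air) * 1000`.
#'
#' @param pv numeric vector of pixel values.
#' @param cal a [ct_calibration()].
#' @return Hounsfield units, same length as `pv`.
#' @examples
#' cal <- ct_calibration(pv_water = 1000, pv_air = 0)
#' hu_from_pv(c(0, 1000, 1700), cal) # -1000, 0, 700
#' @export
hu_from_pv <- function(pv, cal) {
  if (!inherits(cal, "ct_calibration")) {
    abort_calibration("`cal` must be a ct_calibration.")
  }
  (pv - cal$pv_water) / (cal$pv_water - cal$pv_air) * 1000
}

#' Convert Hounsfield units to raw pixel values
#'
#' Exact algebraic inverse of [hu_from_pv()]. When deriving a discrete
#' selection threshold (`discrete = TRUE`) the result is rounded up to the
#' next integer pixel value, so that every selected pixel is guaranteed to be
#' at or above the HU threshold.
#'
#' @param hu numeric vector of Hounsfield units.
#' @param cal a [ct_calibration()].
#' @param discrete round up to the next representable pixel value.
#' @return Pixel values, same length as `hu`.
#' @examples
#' cal <- ct_calibration(pv_water = 1000, pv_air = 0)
#' pv_from_hu(700, cal) # 1700
#' @export
pv_from_hu <- function(hu, cal, discrete = FALSE) {
  if (!inherits(cal, "ct_calibration")) {
    abort_calibration("`cal` must be a ct_calibration.")
  }
  pv <- hu / 1000 * (cal$pv_water - cal$pv_air) + cal$pv_water
  if (discrete) ceiling(pv) else pv
}

#' Density weighting-factor table
#'
#' Agatston-style weighting bins for micro-CT: the integer factor `wf`
#' assigned from the maximal density `HU_max` within a region, multiplied by
#' the calcium area to give the slice calcification score. The default maps
#' < 700 HU to 0, 700-999 to 1, 1000-1999 to 2, 2000-2999 to 3, and
#' everything from 3000 HU up to 4 (the gap at exactly 3000 HU between the
#' conventional "2000-2999" and "> 3000" bins is closed upward to keep the
#' factor monotone).
#'
#' @param lower_hu strictly increasing lower bin bounds (inclusive), in HU.
#' @param wf strictly increasing non-negative integer factors, one per bound.
#' @return A `wf_table`.
#' @export
wf_table <- function(lower_hu = c(700, 1000, 2000, 3000),
                     wf = c(1L, 2L, 3L, 4L)) {
  if (length(lower_hu) != length(wf) || length(wf) == 0L) {
    abort_input("`lower_hu` and `wf` must be non-empty and of equal length.")
  }
  if (is.unsorted(lower_hu, strictly = TRUE)) {
    abort_input("`lower_hu` bounds must be strictly increasing.")
  }
  if (is.unsorted(wf, strictly = TRUE) || any(wf < 0)) {
    abort_input("`wf` values must be non-negative and strictly increasing.")
  }
  structure(list(lower_hu = as.numeric(lower_hu), wf = as.integer(wf)),
            class = "wf_table")
}

#' @export
print.wf_table <- function(x, ...) {
  cat("<wf_table>\n")
  bounds <- c(x$lower_hu, Inf)
  for (i in seq_along(x$wf)) {
    cat(sprintf("  [%g, %g) HU -> wf %d\n", bounds[i], bounds[i + 1], x$wf[i]))
  }
  invisible(x)
}

#' Weighting factor for a region's maximal density
#'
#' Returns the factor of the highest bin whose lower bound does not exceed
#' `hu_max`; 0 below the first bin.
#'
#' @param hu_max numeric vector of maximal densities in HU.
#' @param table a [wf_table()].
#' @return Integer factors, same length as `hu_max`.
#' @examples
#' weighting_factor(c(699, 850, 1500, 2500, 3000)) # 0 1 2 3 4
#' @export
weighting_factor <- function(hu_max, table = wf_table()) {
  if (!inherits(table, "wf_table")) abort_input("`table` must be a wf_table.")
  idx <- findInterval(hu_max, table$lower_hu)
  ifelse(idx == 0L, 0L, table$wf[pmax(idx, 1L)])
}

#' Agatston-style calcium score for a micro-CT stack
#'
#' Per slice: pixels outside the ROI are zeroed, pixels at or above the pixel
#' value corresponding to `hu_threshold` (derived with [pv_from_hu()],
#' rounded up) are selected as calcium, their area and maximum pixel value
#' are measured, the maximum is converted back to `HU_max`, a weighting
#' factor is assigned from `table`, and the slice calcification score is
#' `wf * area_calcium_mm2`. Totals are summed over slices; the calcium
#' volume index is the summed area.
#'
#' @param stack a CT [image_stack()].
#' @param rois an [roi_set()], typically from [interpolate_rois()].
#' @param cal a [ct_calibration()]; defaults to the calibration attached to
#'   the stack.
#' @param hu_threshold selection threshold in HU; the default 700 excludes
#'   agar and corresponds to denser bone and hydroxyapatite.
#' @param table a [wf_table()].
#' @return A `ct_calcium_result`; `tidy()` gives the per-slice table
#'   (`slice_index`, `area_calcium_mm2`, `pv_max`, `hu_max`, `wf`, `ccs`),
#'   `glance()` the totals.
#' @export
score_stack_ct <- function(stack, rois, cal = stack$calibration,
                           hu_threshold = 700, table = wf_table()) {
  if (!inherits(stack, "image_stack")) abort_input("`stack` must be an image_stack.")
  if (stack$modality != "CT") abort_input("`stack` must have CT modality.")
  if (is.null(cal)) {
    abort_calibration("no calibration: supply `cal` or attach one to the stack.")
  }
  pv_thr <- pv_from_hu(hu_threshold, cal, discrete = TRUE)
  per_slice <- map(seq_len(n_slices(stack)), function(i) {
    region <- roi_for_slice(rois, i)
    if (is.null(region)) {
      return(tibble(slice_index = i, area_calcium_mm2 = 0, pv_max = 0,
                    hu_max = 0, wf = 0L, ccs = 0))
    }
    masked <- zero_outside_roi(get_slice(stack, i), region)
    mask <- select_calcium_mask(masked, pv_thr)
    m <- measure_slice(mask, masked, stack$pixel_spacing_mm)
    hu_max <- if (m$pv_max == 0) 0 else hu_from_pv(m$pv_max, cal)
    w <- if (m$area_calcium_mm2 == 0) 0L else weighting_factor(hu_max, table)
    tibble(slice_index = i, area_calcium_mm2 = m$area_calcium_mm2,
           pv_max = m$pv_max, hu_max = hu_max, wf = w,
           ccs = w * m$area_calcium_mm2)
  })
  per_slice <- bind_rows(per_slice)
  structure(
    list(
      per_slice = per_slice,
      ct_calcium_score = sum(per_slice$ccs),
      ct_calcium_volume = sum(per_slice$area_calcium_mm2),
      total_volume_mm3 = sum(per_slice$area_calcium_mm2) * stack$slice_spacing_mm,
      hu_threshold = hu_threshold,
      pv_threshold = pv_thr
    ),
    class = "ct_calcium_result"
  )
}

#' @export
print.ct_calcium_result <- function(x, ...) {
  cat(sprintf(
    "<ct_calcium_result> CT calcium score %.6g, volume index %.6g mm2 (threshold %g HU -> PV %g)\n",
    x$ct_calcium_score, x$ct_calcium_volume, x$hu_threshold, x$pv_threshold
  ))
  invisible(x)
}
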