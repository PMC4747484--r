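#' Read and write image stacks as multi-page TIFF with a JSON sidecar
#'
#' Stacks are stored as multi-page TIFF (8-bit for ultrasound, 16-bit for
#' CT) next to a JSON sidecar (`<stem>.json`) carrying the physical
#' metadata: modality, pixel and slice spacing, pixel-value range, axis
#' label, and the water/air calibration for CT. `read_stack()` validates
#' pixel values against the modality range. DICOM series and NPZ archives
#' are not supported by this reader; convert to TIFF + sidecar first.
#'
#' @param path TIFF file path.
#' @param sidecar sidecar path; default replaces the extension with `.json`.
#' @return `read_stack()` an [image_stack()]; `write_stack()` the input,
#'   invisibly.
#' @examples
#' st <- render_us(phantom_scene(masses_mg = 10), noise = us_noise_off())$stack[[1]]
#' p <- tempfile(fileext = ".tif")
#' write_stack(st, p)
#' st2 <- read_stack(p)
#' identical(st$pixels, st2$pixels)
#' @export
read_stack <- function(path, sidecar = NULL) {
  if (grepl("\\.(dcm|npz)$", path, ignore.case = TRUE)) {
    abort_format("DICOM/NPZ import is not supported; supply multi-page TIFF + JSON sidecar.")
  }
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  sidecar <- sidecar %||% sidecar_path(path)
  if (!file.exists(sidecar)) {
    abort_format(paste0("missing JSON sidecar: ", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("modality", "pixel_spacing_mm", "slice_spacing_mm")) {
    if (is.null(meta[[f]])) abort_format(paste0("sidecar lacks field: ", f))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  pixels <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) pixels[i, , ] <- pages[[i]]
  cal <- NULL
  if (!is.null(meta$calibration)) {
    cal <- ct_calibration(meta$calibration$pv_water, meta$calibration$pv_air)
  }
  image_stack(
    pixels,
    pixel_spacing_mm = as.numeric(meta$pixel_spacing_mm),
    slice_spacing_mm = as.numeric(meta$slice_spacing_mm),
    modality = meta$modality,
    axis_label = meta$axis_label %||% "none",
    calibration = cal
  )
}

#' @rdname read_stack
#' @param stack an [image_stack()] to write.
#' @export
write_stack <- function(stack, path, sidecar = NULL) {
  if (!inherits(stack, "image_stack")) abort_input("`stack` must be an image_stack.")
  sidecar <- sidecar %||% sidecar_path(path)
  bps <- if (stack$modality == "US") 8L else 16L
  denom <- 2^bps - 1
  pages <- lapply(seq_len(n_slices(stack)), function(i) {
    get_slice(stack, i) / denom  # tiff::writeTIFF stores [0,1] * (2^bps - 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bps, compression = "none")
  meta <- list(
    modality = stack$modality,
    pixel_spacing_mm = stack$pixel_spacing_mm,
    slice_spacing_mm = stack$slice_spacing_mm,
    pv_range = stack$pv_range,
    axis_label = stack$axis_label
  )
  if (!is.null(stack$calibration)) {
    meta$calibration <- list(pv_water = stack$calibration$pv_water,
                             pv_air = stack$calibration$pv_air)
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(stack)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read per-slice integrated-backscatter readings from CSV
#'
#' Expected columns: `slice_index`, `axis` (`"short"`/`"long"`),
#' `ib_calcium_db`, `ib_agar_db`, `d_long_mm`, `d_short_mm`. Extra columns
#' are preserved.
#'
#' @param path CSV file path.
#' @return A tibble of readings suitable for [cib_slice()] / [cib_score()].
#' @export
read_ib_readings <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  readings <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("slice_index", "axis", "ib_calcium_db", "ib_agar_db",
                "d_long_mm", "d_short_mm")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols) > 0) {
    abort_format(paste0("readings CSV lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  readings
}

#' Write per-slice measurements and totals to disk
#'
#' Writes the per-slice table as CSV (deterministic column order, floats at
#' 6 significant digits) and, optionally, the stack-level totals as JSON, so
#' that rereading the CSV reproduces the totals at the stored precision.
#'
#' @param result a `stack_score`, `ct_calcium_result`, `us_calcium_result`
#'   or `cib_result`.
#' @param path CSV output path.
#' @param json_path optional JSON output path for the totals.
#' @return `path`, invisibly.
#' @export
write_scores <- function(result, path, json_path = NULL) {
  per_slice <- tidy(result)
  num <- vapply(per_slice, is.numeric, logical(1))
  per_slice[num] <- lapply(per_slice[num], signif, digits = 6)
  readr::write_csv(per_slice, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(glance(result)), json_path,
                         auto_unbox = TRUE, digits = 6)
  }
  invisible(path)
}
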