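#' Region-of-interest primitives
#'
#' Calcium scoring operates inside a wide, manually drawn region of interest
#' per slice: everything outside is zeroed before thresholding. Regions are
#' rectangles or polygons in 1-based (row, col) pixel coordinates; rectangle
#' bounds are inclusive.
#'
#' @param row0,col0,row1,col1 inclusive rectangle bounds, `row0 <= row1`,
#'   `col0 <= col1`.
#' @return An object of class `roi_region`.
#' @examples
#' roi_rect(1, 1, 10, 20)
#' roi_polygon(rows = c(1, 1, 10), cols = c(1, 20, 10))
#' @export
roi_rect <- function(row0, col0, row1, col1) {
  if (row1 < row0 || col1 < col0) {
    abort_geometry("rectangle bounds must satisfy row0 <= row1 and col0 <= col1.")
  }
  structure(
    list(type = "rect", coords = c(row0 = row0, col0 = col0,
                                   row1 = row1, col1 = col1)),
    class = "roi_region"
  )
}

#' @rdname roi_rect
#' @param rows,cols polygon vertex coordinates (closed implicitly).
#' @export
roi_polygon <- function(rows, cols) {
  if (length(rows) != length(cols) || length(rows) < 3L) {
    abort_geometry("a polygon needs >= 3 vertices with matching rows/cols.")
  }
  structure(
    list(type = "polygon", rows = as.numeric(rows), cols = as.numeric(cols)),
    class = "roi_region"
  )
}

#' @export
print.roi_region <- function(x, ...) {
  if (x$type == "rect") {
    cat(sprintf("<roi_region> rect [%g, %g] x [%g, %g]\n",
                x$coords["row0"], x$coords["row1"],
                x$coords["col0"], x$coords["col1"]))
  } else {
    cat(sprintf("<roi_region> polygon, %d vertices\n", length(x$rows)))
  }
  invisible(x)
}

#' Per-slice ROI collection
#'
#' Maps slice indices to regions. Slices without a region contribute zero to
#' all scores. `kind = "endpoints_interpolated"` marks a set produced by
#' [interpolate_rois()], mirroring the micro-CT workflow where only the first
#' and last slice of a speck are drawn manually.
#'
#' @param regions named list of [roi_rect()]/[roi_polygon()] regions; names
#'   are slice indices.
#' @param kind provenance of the set.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(regions, kind = c("explicit_per_slice", "endpoints_interpolated")) {
  kind <- match.arg(kind)
  if (length(regions) == 0L) {
    abort_input("`regions` must contain at least one region.")
  }
  if (is.null(names(regions)) || anyNA(suppressWarnings(as.integer(names(regions))))) {
    abort_input("`regions` must be a list named by integer slice indices.")
  }
  ok <- vapply(regions, inherits, logical(1), "roi_region")
  if (!all(ok)) abort_input("every element of `regions` must be an roi_region.")
  structure(list(regions = regions, kind = kind), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d slice region(s), kind: %s\n",
              length(x$regions), x$kind))
  invisible(x)
}

roi_for_slice <- function(rois, slice_index) {
  rois$regions[[as.character(slice_index)]]
}

# Logical mask of pixels covered by the region; pixel centers are at integer
# (row, col). Polygon membership includes the boundary.
roi_mask <- function(region, dims) {
  nr <- dims[1]; nc <- dims[2]
  if (region$type == "rect") {
    co <- region$coords
    if (co["row0"] < 1 || co["col0"] < 1 || co["row1"] > nr || co["col1"] > nc) {
      abort_geometry("rectangle ROI extends outside the slice.")
    }
    m <- matrix(FALSE, nr, nc)
    # pixel centers at integer coordinates; fractional bounds arise from
    # interpolation and include exactly the centers they cover
    r0 <- ceiling(co[["row0"]]); r1 <- floor(co[["row1"]])
    c0 <- ceiling(co[["col0"]]); c1 <- floor(co[["col1"]])
    if (r0 <= r1 && c0 <= c1) m[r0:r1, c0:c1] <- TRUE
    m
  } else {
    if (any(region$rows < 1) || any(region$rows > nr) ||
        any(region$cols < 1) || any(region$cols > nc)) {
      abort_geometry("polygon ROI extends outside the slice.")
    }
    pts <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    inside <- pracma::inpolygon(pts$row, pts$col, region$rows, region$cols,
                                boundary = TRUE)
    matrix(inside, nr, nc)
  }
}

#' Interpolate per-slice ROIs between two drawn endpoints
#'
#' Reproduces the stack-scoring convenience of drawing a wide ROI only on the
#' first and last slice of a calcium speck and generating the ones in between
#' by linear interpolation of the region coordinates.
#'
#' @param first_region,last_region regions on the first and last slice; both
#'   rectangles, or both polygons with the same vertex count.
#' @param first_slice,last_slice slice indices of the endpoints;
#'   `last_slice >= first_slice + 1`.
#' @return An [roi_set()] with one region per slice in
#'   `first_slice:last_slice`, endpoints reproduced exactly.
#' @examples
#' rs <- interpolate_rois(roi_rect(1, 1, 5, 11), roi_rect(1, 11, 5, 21), 1, 3)
#' rs$regions[["2"]] # rect [1,5] x [6,16]
#' @export
interpolate_rois <- function(first_region, last_region, first_slice, last_slice) {
  if (last_slice < first_slice + 1L) {
    abort_input("the speck must span at least two slices.")
  }
  if (first_region$type != last_region$type) {
    abort_geometry("endpoint ROIs must be of the same type.")
  }
  if (first_region$type == "polygon" &&
      length(first_region$rows) != length(last_region$rows)) {
    abort_geometry("endpoint polygons must have the same number of vertices.")
  }
  idx <- first_slice:last_slice
  span <- last_slice - first_slice
  regions <- lapply(idx, function(i) {
    t <- (i - first_slice) / span
    if (first_region$type == "rect") {
      co <- (1 - t) * first_region$coords + t * last_region$coords
      roi_rect(co[["row0"]], co[["col0"]], co[["row1"]], co[["col1"]])
    } else {
      roi_polygon(
        rows = (1 - t) * first_region$rows + t * last_region$rows,
        cols = (1 - t) * first_region$cols + t * last_region$cols
      )
    }
  })
  roi_set(setNames(regions, idx), kind = "endpoints_interpolated")
}
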