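#' Synthetic calcium-containing agar phantom scene
#'
#' Describes a tissue-mimicking agar block with rectangular holes, each
#' loaded with a known mass of dry hydroxyapatite powder. The default scene
#' is a 100 x 100 x 25 mm block with nine 15 x 3 x 5 mm holes whose tops sit
#' 10 mm below the surface, loaded with 2, 4, 6, 8, 10, 20, 30, 40 and 50 mg.
#'
#' The powder settles as a bottom layer of fixed packing density
#' (`packing_density_mg_mm3`, default 0.25 mg/mm^3, a loose 20 um powder),
#' spread uniformly over the 15 x 3 mm hole footprint, so a speck of mass
#' `m` forms a layer of height `m / (0.25 * 45)` mm. Layer height, not
#' in-layer density, is therefore the primary carrier of mass information,
#' which is what makes calcium area grow with mass in every modality.
#'
#' @param masses_mg calcium masses, one per speck, in mg; `0` renders an
#'   empty hole. Default: the nine-speck ladder above.
#' @param seed integer seed recorded in the scene; renderers derive their
#'   random streams from it.
#' @param speck_dims_mm hole dimensions (length x width x height) in mm.
#' @param depth_mm depth of the hole top below the phantom surface.
#' @param interspace_mm gap between adjacent holes. The default 9 mm keeps
#'   nine 3 mm holes inside a 100 mm block.
#' @param block_dims_mm phantom block dimensions in mm.
#' @param packing_density_mg_mm3 powder packing density in mg/mm^3.
#'
#' @return A `phantom_scene`: list with a `specks` tibble (`speck_id`,
#'   `mass_mg`, footprint `x0/x1/y0/y1`, layer bounds `z_top/z_bot`, layer
#'   height `h_mm`, areal density `rho_areal_mg_mm2`) plus the geometry
#'   parameters.
#' @examples
#' sc <- phantom_scene(seed = 0)
#' sc$specks$mass_mg
#' @export
phantom_scene <- function(masses_mg = c(2, 4, 6, 8, 10, 20, 30, 40, 50),
                          seed = 0,
                          speck_dims_mm = c(15, 3, 5),
                          depth_mm = 10,
                          interspace_mm = 9,
                          block_dims_mm = c(100, 100, 25),
                          packing_density_mg_mm3 = 0.25) {
  if (length(masses_mg) < 1L || any(masses_mg < 0)) {
    abort_input("`masses_mg` must be non-negative (0 = empty hole).")
  }
  if (length(speck_dims_mm) != 3L || any(speck_dims_mm <= 0)) {
    abort_input("`speck_dims_mm` must be three positive dimensions.")
  }
  footprint <- speck_dims_mm[1] * speck_dims_mm[2]
  h <- masses_mg / (packing_density_mg_mm3 * footprint)
  if (any(h > speck_dims_mm[3])) {
    abort_input("a speck's powder layer exceeds the hole height; lower the mass or raise the packing density.")
  }
  n <- length(masses_mg)
  pitch <- speck_dims_mm[2] + interspace_mm
  span <- n * speck_dims_mm[2] + (n - 1) * interspace_mm
  if (span > block_dims_mm[2] || speck_dims_mm[1] > block_dims_mm[1] ||
      depth_mm + speck_dims_mm[3] > block_dims_mm[3]) {
    abort_input("specks do not fit inside the block.")
  }
  y_start <- (block_dims_mm[2] - span) / 2
  x0 <- (block_dims_mm[1] - speck_dims_mm[1]) / 2
  specks <- tibble(
    speck_id = seq_len(n),
    mass_mg = as.numeric(masses_mg),
    x0 = x0,
    x1 = x0 + speck_dims_mm[1],
    y0 = y_start + (seq_len(n) - 1) * pitch,
    y1 = y_start + (seq_len(n) - 1) * pitch + speck_dims_mm[2],
    z_top = depth_mm + speck_dims_mm[3] - h,
    z_bot = depth_mm + speck_dims_mm[3],
    h_mm = h,
    rho_areal_mg_mm2 = masses_mg / footprint
  )
  structure(
    list(
      specks = specks,
      seed = as.integer(seed),
      speck_dims_mm = speck_dims_mm,
      depth_mm = depth_mm,
      block_dims_mm = block_dims_mm,
      packing_density_mg_mm3 = packing_density_mg_mm3
    ),
    class = "phantom_scene"
  )
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %d speck(s), masses %s mg, block %s mm, seed %d\n",
    nrow(x$specks), paste(x$specks$mass_mg, collapse = "/"),
    paste(x$block_dims_mm, collapse = "x"), x$seed
  ))
  invisible(x)
}

#' Default nine-speck phantom scene
#'
#' Convenience wrapper for [phantom_scene()] with the standard mass ladder.
#'
#' @param seed integer seed.
#' @param masses_mg optional mass override.
#' @return A `phantom_scene`.
#' @export
default_scene <- function(seed = 0, masses_mg = c(2, 4, 6, 8, 10, 20, 30, 40, 50)) {
  phantom_scene(masses_mg = masses_mg, seed = seed)
}

# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# per-speck, per-purpose derived seed, kept well below 2^31
derive_seed <- function(seed, speck_id, offset) {
  (abs(seed) %% 1000003L) * 1009L + speck_id * 31L + offset
}

# exact overlap length of pixel slabs [center - w/2, center + w/2) with [lo, hi)
overlap_len <- function(centers, width, lo, hi) {
  pmax(0, pmin(centers + width / 2, hi) - pmax(centers - width / 2, lo))
}

# pixel-center grid over [lo, lo + n*ps)
grid_centers <- function(lo, hi, ps) {
  n <- max(1L, round((hi - lo) / ps))
  lo + (seq_len(n) - 0.5) * ps
}
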