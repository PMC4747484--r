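#' Noise models for the phantom renderers
#'
#' Each renderer takes a small validated parameter list. `us_noise()`
#' controls the ultrasound renderer: Rayleigh speckle in the agar background
#' (scaled and clipped so no agar pixel reaches the 130 PV calcium
#' threshold), Gaussian intensity jitter on calcium pixels, and optional
#' acoustic shadowing attenuating pixels beneath a calcium layer.
#' `ct_noise()` controls additive Gaussian HU noise, a Gaussian
#' partial-volume blur at speck boundaries, and the agar HU band.
#' `ib_noise()` adds Gaussian jitter to integrated-backscatter readings.
#' The `*_off()` variants disable every stochastic term, giving fully
#' deterministic renders in which the calcium selection masks equal the
#' ground truth exactly.
#'
#' @param speckle draw Rayleigh speckle in the agar background?
#' @param speckle_scale Rayleigh scale parameter (pixel values).
#' @param sigma_calcium standard deviation of calcium pixel intensities (PV).
#' @param shadow_db_per_mm acoustic shadowing below calcium, dB per mm of
#'   calcium layer traversed; 0 disables shadowing (the default, so that
#'   noiseless scores reflect geometry alone).
#' @return A classed parameter list.
#' @export
us_noise <- function(speckle = TRUE, speckle_scale = 35, sigma_calcium = 8,
                     shadow_db_per_mm = 0) {
  if (speckle_scale <= 0 || sigma_calcium < 0 || shadow_db_per_mm < 0) {
    abort_config("invalid ultrasound noise parameters.")
  }
  structure(list(speckle = isTRUE(speckle), speckle_scale = speckle_scale,
                 sigma_calcium = sigma_calcium,
                 shadow_db_per_mm = shadow_db_per_mm),
            class = "us_noise")
}

#' @rdname us_noise
#' @export
us_noise_off <- function() us_noise(speckle = FALSE, sigma_calcium = 0,
                                    shadow_db_per_mm = 0)

#' @rdname us_noise
#' @param sigma_hu standard deviation of additive HU noise.
#' @param blur_sigma_px Gaussian partial-volume blur at speck boundaries, in
#'   pixels; 0 disables blurring.
#' @param agar_hu_range HU band of the agar background (agar is close to
#'   water); with noise on, agar pixels are drawn uniformly from this band.
#' @export
ct_noise <- function(sigma_hu = 30, blur_sigma_px = 1,
                     agar_hu_range = c(0, 60)) {
  if (sigma_hu < 0 || blur_sigma_px < 0 || length(agar_hu_range) != 2L ||
      agar_hu_range[1] > agar_hu_range[2]) {
    abort_config("invalid CT noise parameters.")
  }
  structure(list(sigma_hu = sigma_hu, blur_sigma_px = blur_sigma_px,
                 agar_hu_range = as.numeric(agar_hu_range)),
            class = "ct_noise")
}

#' @rdname us_noise
#' @export
ct_noise_off <- function() ct_noise(sigma_hu = 0, blur_sigma_px = 0)

#' @rdname us_noise
#' @param sigma_db standard deviation of IB reading jitter in dB.
#' @export
ib_noise <- function(sigma_db = 0.5) {
  if (sigma_db < 0) abort_config("invalid IB noise parameters.")
  structure(list(sigma_db = sigma_db), class = "ib_noise")
}

#' @rdname us_noise
#' @export
ib_noise_off <- function() ib_noise(sigma_db = 0)

# mean ultrasound intensity of a calcium layer of areal density rho (mg/mm^2);
# starts at the 130 PV selection threshold and saturates toward the 250 PV
# ceiling, emulating the plateau seen above 40 mg
us_mean_intensity <- function(rho_areal, threshold = 130, ceiling_pv = 250,
                              rho_sat = 40 / 45) {
  threshold + (ceiling_pv - threshold) * (1 - exp(-rho_areal / rho_sat))
}

# apparent peak density of a calcium layer in HU; thin layers are diluted by
# partial volume, thick layers saturate toward the pure-hydroxyapatite ceiling
ct_hu_of <- function(rho_areal, hu_base = 700, hu_span = 3300, rho_sat = 0.25) {
  ifelse(rho_areal <= 0, 0,
         hu_base + hu_span * (1 - exp(-rho_areal / rho_sat)))
}

#' Ground truth accompanying a rendered stack
#'
#' Binary calcium masks aligned to the rendered slices, plus the rasterizer's
#' exact-overlap volume, which recovers `mass / packing_density` to floating
#' point precision (the binary mask volume is pixel-quantized).
#'
#' @keywords internal
new_ground_truth <- function(mass_mg, masks, raster_volume_mm3,
                             mask_volume_mm3) {
  structure(list(mass_mg = mass_mg, masks = masks,
                 raster_volume_mm3 = raster_volume_mm3,
                 mask_volume_mm3 = mask_volume_mm3),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %g mg, %d calcium pixel(s), raster volume %.4g mm3\n",
    x$mass_mg, sum(x$masks), x$raster_volume_mm3
  ))
  invisible(x)
}

# shared slicing geometry for one speck: stepping positions, in-plane grids,
# geometric masks, exact raster volume
speck_slices <- function(scene, speck, axis, pixel_spacing_mm,
                         slice_spacing_mm, lateral_margin_mm = 2,
                         depth_margin_mm = 2) {
  z_lo <- scene$depth_mm - depth_margin_mm
  z_hi <- scene$depth_mm + scene$speck_dims_mm[3] + depth_margin_mm
  if (axis == "short") {
    step_lo <- speck$x0 - lateral_margin_mm
    step_hi <- speck$x1 + lateral_margin_mm
    lat_lo <- speck$y0 - lateral_margin_mm
    lat_hi <- speck$y1 + lateral_margin_mm
    step_in <- c(speck$x0, speck$x1)
    lat_in <- c(speck$y0, speck$y1)
  } else {
    step_lo <- speck$y0 - lateral_margin_mm
    step_hi <- speck$y1 + lateral_margin_mm
    lat_lo <- speck$x0 - lateral_margin_mm
    lat_hi <- speck$x1 + lateral_margin_mm
    step_in <- c(speck$y0, speck$y1)
    lat_in <- c(speck$x0, speck$x1)
  }
  positions <- seq(step_lo, step_hi - 1e-9, by = slice_spacing_mm)
  rows <- grid_centers(z_lo, z_hi, pixel_spacing_mm)   # depth
  cols <- grid_centers(lat_lo, lat_hi, pixel_spacing_mm) # lateral
  in_speck <- positions >= step_in[1] & positions < step_in[2]
  row_in <- rows >= speck$z_top & rows < speck$z_bot
  col_in <- cols >= lat_in[1] & cols < lat_in[2]
  # exact overlap fractions for the mass-conservation volume
  slab_ov <- overlap_len(positions, slice_spacing_mm, step_in[1], step_in[2])
  row_ov <- overlap_len(rows, pixel_spacing_mm, speck$z_top, speck$z_bot)
  col_ov <- overlap_len(cols, pixel_spacing_mm, lat_in[1], lat_in[2])
  raster_volume <- sum(slab_ov) * sum(row_ov) * sum(col_ov)
  list(positions = positions, rows = rows, cols = cols,
       in_speck = in_speck, row_in = row_in, col_in = col_in,
       raster_volume = raster_volume)
}

render_one_us <- function(scene, speck, axis, pixel_spacing_mm,
                          slice_spacing_mm, noise, seed, threshold,
                          roi_margin_px = 10L) {
  geo <- speck_slices(scene, speck, axis, pixel_spacing_mm, slice_spacing_mm)
  nr <- length(geo$rows); nc <- length(geo$cols); ns <- length(geo$positions)
  mu <- us_mean_intensity(speck$rho_areal_mg_mm2)
  pixels <- array(0, dim = c(ns, nr, nc))
  masks <- array(FALSE, dim = c(ns, nr, nc))
  regions <- list()
  with_seed(seed, {
    for (s in seq_len(ns)) {
      if (noise$speckle) {
        u <- matrix(runif(nr * nc), nr, nc)
        img <- round(pmin(noise$speckle_scale * sqrt(-2 * log(u)),
                          threshold - 1))
      } else {
        img <- matrix(80, nr, nc)
      }
      has_ca <- geo$in_speck[s] && speck$mass_mg > 0 &&
        any(geo$row_in) && any(geo$col_in)
      if (has_ca) {
        ca <- outer(geo$row_in, geo$col_in, "&")
        n_ca <- sum(ca)
        vals <- if (noise$sigma_calcium > 0) {
          round(pmin(pmax(rnorm(n_ca, mu, noise$sigma_calcium), 0), 250))
        } else {
          rep(round_half_up(mu), n_ca)
        }
        img[ca] <- vals
        if (noise$shadow_db_per_mm > 0) {
          shadow_rows <- geo$rows >= speck$z_bot
          atten <- 10^(-noise$shadow_db_per_mm * speck$h_mm / 20)
          img[shadow_rows, geo$col_in] <-
            round(img[shadow_rows, geo$col_in] * atten)
        }
        masks[s, , ] <- ca
        rr <- range(which(geo$row_in)); cc <- range(which(geo$col_in))
        regions[[as.character(s)]] <- roi_rect(
          max(1L, rr[1] - roi_margin_px), max(1L, cc[1] - roi_margin_px),
          min(nr, rr[2] + roi_margin_px), min(nc, cc[2] + roi_margin_px)
        )
      }
      pixels[s, , ] <- img
    }
  })
  stack <- image_stack(pixels, rep(pixel_spacing_mm, 2), slice_spacing_mm,
                       modality = "US", axis_label = axis)
  truth <- new_ground_truth(
    speck$mass_mg, masks, geo$raster_volume,
    sum(masks) * pixel_spacing_mm^2 * slice_spacing_mm
  )
  rois <- if (length(regions) > 0) roi_set(regions) else NULL
  list(stack = stack, truth = truth, rois = rois)
}

#' Render ultrasound sweeps of a phantom scene
#'
#' Emulates a stepped B-mode acquisition: one 2-D slice per millimetre along
#' the chosen axis (probe across the speck for `"short"`, along it for
#' `"long"`). The agar background is Rayleigh speckle scaled to stay strictly
#' below the 130 PV calcium threshold; calcium pixels are drawn around a mean
#' intensity that starts at 130 and saturates toward the 250 PV ceiling with
#' increasing areal density, reproducing the score plateau above 40 mg.
#' Optional acoustic shadowing darkens pixels beneath the calcium layer.
#'
#' @param scene a [phantom_scene()].
#' @param axis `"short"` or `"long"` stepping axis.
#' @param pixel_spacing_mm in-plane pixel size (default 0.1 mm, so a 3 mm
#'   speck spans 30 pixels).
#' @param slice_spacing_mm stepping interval (default 1 mm).
#' @param noise a [us_noise()] parameter set; [us_noise_off()] gives a
#'   deterministic render whose thresholded mask equals the ground truth.
#' @param seed integer; defaults to the scene seed. Every slice's random
#'   draws derive from it, so renders are reproducible.
#' @return A tibble with one row per speck: `speck_id`, `mass_mg`, and
#'   list-columns `stack` ([image_stack()]), `truth` (ground truth masks),
#'   `rois` ([roi_set()] of wide per-slice ROIs).
#' @examples
#' r <- render_us(phantom_scene(masses_mg = 10), noise = us_noise_off())
#' r$stack[[1]]
#' @export
render_us <- function(scene, axis = c("short", "long"), pixel_spacing_mm = 0.1,
                      slice_spacing_mm = 1, noise = us_noise(),
                      seed = scene$seed) {
  axis <- match.arg(axis)
  if (!inherits(scene, "phantom_scene")) abort_input("`scene` must be a phantom_scene.")
  if (!inherits(noise, "us_noise")) abort_config("`noise` must come from us_noise().")
  offset <- if (axis == "short") 1L else 2L
  rows <- lapply(seq_len(nrow(scene$specks)), function(i) {
    speck <- scene$specks[i, ]
    r <- render_one_us(scene, speck, axis, pixel_spacing_mm, slice_spacing_mm,
                       noise, derive_seed(seed, speck$speck_id, offset),
                       threshold = 130)
    tibble(speck_id = speck$speck_id, mass_mg = speck$mass_mg,
           stack = list(r$stack), truth = list(r$truth), rois = list(r$rois))
  })
  bind_rows(rows)
}

# small separable Gaussian blur with replicate padding
gaussian_blur_2d <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    padded <- m[c(rep(1L, half), seq_len(n), rep(n, half)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[seq_len(n) + j - 1L, , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

render_one_ct <- function(scene, speck, pixel_spacing_mm, slice_spacing_mm,
                          cal, noise, seed, roi_margin_px = 12L) {
  # CT stepping runs along each speck's long axis, like the US short-axis sweep
  geo <- speck_slices(scene, speck, "short", pixel_spacing_mm, slice_spacing_mm)
  nr <- length(geo$rows); nc <- length(geo$cols); ns <- length(geo$positions)
  hu_ca <- ct_hu_of(speck$rho_areal_mg_mm2)
  agar_mid <- mean(noise$agar_hu_range)
  pixels <- array(0, dim = c(ns, nr, nc))
  masks <- array(FALSE, dim = c(ns, nr, nc))
  regions <- list()
  with_seed(seed, {
    for (s in seq_len(ns)) {
      hu <- if (noise$sigma_hu > 0) {
        matrix(runif(nr * nc, noise$agar_hu_range[1], noise$agar_hu_range[2]),
               nr, nc)
      } else {
        matrix(agar_mid, nr, nc)
      }
      has_ca <- geo$in_speck[s] && speck$mass_mg > 0 &&
        any(geo$row_in) && any(geo$col_in)
      if (has_ca) {
        ca <- outer(geo$row_in, geo$col_in, "&")
        hu[ca] <- hu_ca
        masks[s, , ] <- ca
        rr <- range(which(geo$row_in)); cc <- range(which(geo$col_in))
        regions[[as.character(s)]] <- roi_rect(
          max(1L, rr[1] - roi_margin_px), max(1L, cc[1] - roi_margin_px),
          min(nr, rr[2] + roi_margin_px), min(nc, cc[2] + roi_margin_px)
        )
      }
      hu <- gaussian_blur_2d(hu, noise$blur_sigma_px)
      if (noise$sigma_hu > 0) hu <- hu + rnorm(nr * nc, 0, noise$sigma_hu)
      pv <- round(pv_from_hu(hu, cal))
      pixels[s, , ] <- pmin(pmax(pv, 0), 65535)
    }
  })
  stack <- image_stack(pixels, rep(pixel_spacing_mm, 2), slice_spacing_mm,
                       modality = "CT", calibration = cal)
  truth <- new_ground_truth(
    speck$mass_mg, masks, geo$raster_volume,
    sum(masks) * pixel_spacing_mm^2 * slice_spacing_mm
  )
  rois <- if (length(regions) > 0) roi_set(regions) else NULL
  list(stack = stack, truth = truth, rois = rois)
}

#' Render a micro-CT scan of a phantom scene
#'
#' Produces cross-sectional slices stepped along each speck's long axis at
#' `slice_spacing_mm`, with 83 um in-plane pixels by default. Agar sits in a
#' configurable near-water HU band; a calcium layer's apparent density starts
#' just above the 700 HU selection threshold for the thinnest layers and
#' saturates toward the ~4000 HU of pure hydroxyapatite as the layer
#' thickness grows beyond the partial-volume scale. HU values receive
#' optional Gaussian noise and boundary blur, then are converted to raw
#' 16-bit pixel values through the water/air calibration.
#'
#' @param scene a [phantom_scene()].
#' @param cal a [ct_calibration()] used both to synthesize pixel values and,
#'   attached to the returned stacks, to score them.
#' @param pixel_spacing_mm in-plane pixel size (default 0.083 mm).
#' @param slice_spacing_mm stepping interval (default 1 mm).
#' @param noise a [ct_noise()] set; [ct_noise_off()] gives a deterministic
#'   render whose thresholded mask equals the ground truth.
#' @param seed integer; defaults to the scene seed.
#' @return A tibble like [render_us()]'s.
#' @export
render_ct <- function(scene, cal = ct_calibration(10000, 5000),
                      pixel_spacing_mm = 0.083, slice_spacing_mm = 1,
                      noise = ct_noise(), seed = scene$seed) {
  if (!inherits(scene, "phantom_scene")) abort_input("`scene` must be a phantom_scene.")
  if (!inherits(noise, "ct_noise")) abort_config("`noise` must come from ct_noise().")
  rows <- lapply(seq_len(nrow(scene$specks)), function(i) {
    speck <- scene$specks[i, ]
    r <- render_one_ct(scene, speck, pixel_spacing_mm, slice_spacing_mm, cal,
                       noise, derive_seed(seed, speck$speck_id, 3L))
    tibble(speck_id = speck$speck_id, mass_mg = speck$mass_mg,
           stack = list(r$stack), truth = list(r$truth), rois = list(r$rois))
  })
  bind_rows(rows)
}

#' Synthesize integrated-backscatter readings for a phantom scene
#'
#' Emulates the per-slice IB measurement workflow: for every slice through a
#' speck, a mean IB value inside the calcium ellipse and an agar reference IB
#' from a small ROI above the calcium, both in dB, plus the ellipse diameters
#' taken from the calcium cross-section. Calcium contrast grows as
#' `gain * log1p(rho_areal)`; an empty hole yields zero contrast.
#'
#' @param scene a [phantom_scene()].
#' @param axis `"short"` or `"long"`.
#' @param baseline_db agar IB baseline in dB.
#' @param gain_db contrast gain per unit `log1p`(areal density).
#' @param noise an [ib_noise()] set.
#' @param seed integer; defaults to the scene seed.
#' @param slice_spacing_mm stepping interval (default 1 mm).
#' @return A tibble of readings: `speck_id`, `mass_mg`, `slice_index`,
#'   `axis`, `ib_calcium_db`, `ib_agar_db`, `d_long_mm`, `d_short_mm`.
#' @export
render_ib <- function(scene, axis = c("short", "long"), baseline_db = -55,
                      gain_db = 8, noise = ib_noise(), seed = scene$seed,
                      slice_spacing_mm = 1) {
  axis <- match.arg(axis)
  if (!inherits(scene, "phantom_scene")) abort_input("`scene` must be a phantom_scene.")
  if (!inherits(noise, "ib_noise")) abort_config("`noise` must come from ib_noise().")
  offset <- if (axis == "short") 4L else 5L
  rows <- lapply(seq_len(nrow(scene$specks)), function(i) {
    speck <- scene$specks[i, ]
    geo <- speck_slices(scene, speck, axis, 0.1, slice_spacing_mm)
    idx <- which(geo$in_speck)
    if (length(idx) == 0L) return(NULL)
    contrast <- gain_db * log1p(speck$rho_areal_mg_mm2)
    cross <- if (axis == "short") scene$speck_dims_mm[2] else scene$speck_dims_mm[1]
    d <- sort(c(cross, max(speck$h_mm, 0.5)))  # operator draws >= 0.5 mm
    with_seed(derive_seed(seed, speck$speck_id, offset), {
      tibble(
        speck_id = speck$speck_id, mass_mg = speck$mass_mg,
        slice_index = idx, axis = axis,
        ib_calcium_db = baseline_db + contrast +
          rnorm(length(idx), 0, noise$sigma_db),
        ib_agar_db = baseline_db + rnorm(length(idx), 0, noise$sigma_db),
        d_long_mm = d[2], d_short_mm = d[1]
      )
    })
  })
  bind_rows(rows)
}
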