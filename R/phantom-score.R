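#' Simulate and score a whole phantom
#'
#' End-to-end convenience: renders short- and long-axis ultrasound sweeps, a
#' micro-CT scan, and integrated-backscatter readings for every speck of a
#' scene, scores them with [score_stack_us()], [score_stack_ct()] (with
#' endpoint-interpolated ROIs, as in the manual micro-CT workflow) and
#' [cib_score()], and returns one long score table.
#'
#' @param scene a [phantom_scene()].
#' @param seed integer seed for every renderer; defaults to the scene seed.
#' @param us_noise_params,ct_noise_params,ib_noise_params noise parameter
#'   sets; pass the `*_off()` variants for deterministic renders.
#' @param threshold ultrasound calcium threshold in PV.
#' @param hu_threshold CT calcium threshold in HU.
#' @param cal CT water/air calibration used for rendering and scoring.
#' @return A tibble with columns `speck_id`, `mass_mg`, `method`
#'   (`"US"`, `"US_volume"`, `"CT"`, `"CT_volume"`, `"cIB"`) and `value`.
#' @examples
#' \donttest{
#' tab <- phantom_score_table(phantom_scene(masses_mg = c(5, 25), seed = 1))
#' tidyr::pivot_wider(tab, names_from = method, values_from = value)
#' }
#' @export
phantom_score_table <- function(scene, seed = scene$seed,
                                us_noise_params = us_noise(),
                                ct_noise_params = ct_noise(),
                                ib_noise_params = ib_noise(),
                                threshold = 130, hu_threshold = 700,
                                cal = ct_calibration(10000, 5000)) {
  us_short <- render_us(scene, "short", noise = us_noise_params, seed = seed)
  us_long <- render_us(scene, "long", noise = us_noise_params, seed = seed)
  ct <- render_ct(scene, cal = cal, noise = ct_noise_params, seed = seed)
  ib_short <- render_ib(scene, "short", noise = ib_noise_params, seed = seed)
  ib_long <- render_ib(scene, "long", noise = ib_noise_params, seed = seed)

  rows <- lapply(seq_len(nrow(scene$specks)), function(i) {
    id <- scene$specks$speck_id[i]
    mass <- scene$specks$mass_mg[i]
    us <- score_phantom_speck_us(us_short, us_long, i, threshold)
    ctr <- score_phantom_speck_ct(ct, i, hu_threshold)
    cib <- score_phantom_speck_cib(ib_short, ib_long, id)
    tibble(
      speck_id = id, mass_mg = mass,
      method = c("US", "US_volume", "CT", "CT_volume", "cIB"),
      value = c(us$us_calcium_score, us$us_calcium_volume,
                ctr$ct_calcium_score, ctr$ct_calcium_volume, cib)
    )
  })
  bind_rows(rows)
}

# US result for one rendered speck (row i of the render tables)
score_phantom_speck_us <- function(us_short, us_long, i, threshold = 130) {
  empty <- list(us_calcium_score = 0, us_calcium_volume = 0)
  rs <- us_short$rois[[i]]
  rl <- us_long$rois[[i]]
  if (is.null(rs) || is.null(rl)) return(empty)
  combine_axes(
    score_stack_us(us_short$stack[[i]], rs, threshold),
    score_stack_us(us_long$stack[[i]], rl, threshold)
  )
}

# CT result for one rendered speck, ROIs interpolated from the speck's first
# and last calcium slice as in the manual workflow
score_phantom_speck_ct <- function(ct, i, hu_threshold = 700) {
  rois <- ct$rois[[i]]
  if (is.null(rois)) return(list(ct_calcium_score = 0, ct_calcium_volume = 0))
  idx <- sort(as.integer(names(rois$regions)))
  first <- idx[1]; last <- idx[length(idx)]
  rois_used <- if (last > first) {
    interpolate_rois(rois$regions[[as.character(first)]],
                     rois$regions[[as.character(last)]], first, last)
  } else {
    rois
  }
  score_stack_ct(ct$stack[[i]], rois_used, hu_threshold = hu_threshold)
}

score_phantom_speck_cib <- function(ib_short, ib_long, id) {
  s <- filter(ib_short, .data$speck_id == id)
  l <- filter(ib_long, .data$speck_id == id)
  if (nrow(s) == 0L || nrow(l) == 0L) return(0)
  cib_score(s, l)$cib_calcium_score
}
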