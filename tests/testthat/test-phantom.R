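test_that("default scene carries the nine-mass ladder and is deterministic", {
  sc <- default_scene(0)
  expect_equal(sc$specks$mass_mg, c(2, 4, 6, 8, 10, 20, 30, 40, 50))
  expect_equal(nrow(sc$specks), 9)
  expect_identical(default_scene(0), default_scene(0))

  single <- phantom_scene(masses_mg = 5)
  expect_equal(nrow(single$specks), 1)

  # specks stay inside the block and below the hole height
  expect_true(all(sc$specks$y0 >= 0 & sc$specks$y1 <= sc$block_dims_mm[2]))
  expect_true(all(sc$specks$h_mm <= sc$speck_dims_mm[3]))
  expect_error(phantom_scene(masses_mg = -1), class = "calscore_input_error")
  expect_error(phantom_scene(masses_mg = 1000), class = "calscore_input_error")
})

test_that("renderers are deterministic given scene, seed and params", {
  sc <- phantom_scene(masses_mg = c(4, 30), seed = 3)
  a <- render_us(sc, "short")
  b <- render_us(sc, "short")
  expect_identical(a$stack[[1]]$pixels, b$stack[[1]]$pixels)
  c2 <- render_us(sc, "short", seed = 99)
  expect_false(identical(a$stack[[1]]$pixels, c2$stack[[1]]$pixels))

  ia <- render_ib(sc, "long")
  ib <- render_ib(sc, "long")
  expect_identical(ia, ib)

  ct1 <- render_ct(sc)
  ct2 <- render_ct(sc)
  expect_identical(ct1$stack[[2]]$pixels, ct2$stack[[2]]$pixels)
})

test_that("rasterized speck volume conserves the input mass", {
  sc <- default_scene(0)
  for (r in list(render_us(sc, "short", noise = us_noise_off()),
                 render_us(sc, "long", noise = us_noise_off()))) {
    err <- vapply(seq_len(nrow(r)), function(i) {
      tr <- r$truth[[i]]
      abs(tr$raster_volume_mm3 * sc$packing_density_mg_mm3 - tr$mass_mg) /
        tr$mass_mg
    }, numeric(1))
    expect_lt(max(err), 0.01)
  }
  rct <- render_ct(sc, noise = ct_noise_off())
  err <- vapply(seq_len(nrow(rct)), function(i) {
    tr <- rct$truth[[i]]
    abs(tr$raster_volume_mm3 * sc$packing_density_mg_mm3 - tr$mass_mg) /
      tr$mass_mg
  }, numeric(1))
  expect_lt(max(err), 0.01)
})

test_that("noiseless ultrasound renders separate agar from calcium exactly", {
  sc <- phantom_scene(masses_mg = c(2, 50), seed = 0)
  r <- render_us(sc, "short", noise = us_noise_off())
  for (i in 1:2) {
    st <- r$stack[[i]]; tr <- r$truth[[i]]
    expect_true(all(st$pixels[tr$masks] >= 130))
    expect_true(all(st$pixels[!tr$masks] < 130))
  }
  # pure agar: no pixel anywhere reaches the threshold, even with speckle
  agar <- render_us(phantom_scene(masses_mg = 0), "short")
  expect_lt(max(agar$stack[[1]]$pixels), 130)
})

test_that("with noise off the scored masks equal the ground truth on every slice", {
  sc <- default_scene(0)
  r <- render_us(sc, "short", noise = us_noise_off())
  for (i in seq_len(nrow(r))) {
    st <- r$stack[[i]]; tr <- r$truth[[i]]; rois <- r$rois[[i]]
    for (s in seq_len(dim(st)[1])) {
      region <- rois$regions[[as.character(s)]]
      sl <- st$pixels[s, , ]
      m <- if (is.null(region)) {
        matrix(FALSE, nrow(sl), ncol(sl))
      } else {
        select_calcium_mask(zero_outside_roi(sl, region), 130)
      }
      expect_identical(m, tr$masks[s, , ])
    }
  }

  rct <- render_ct(sc, noise = ct_noise_off())
  pvt <- pv_from_hu(700, rct$stack[[1]]$calibration, discrete = TRUE)
  for (i in seq_len(nrow(rct))) {
    st <- rct$stack[[i]]; tr <- rct$truth[[i]]; rois <- rct$rois[[i]]
    for (s in seq_len(dim(st)[1])) {
      region <- rois$regions[[as.character(s)]]
      sl <- st$pixels[s, , ]
      m <- if (is.null(region)) {
        matrix(FALSE, nrow(sl), ncol(sl))
      } else {
        select_calcium_mask(zero_outside_roi(sl, region), pvt)
      }
      expect_identical(m, tr$masks[s, , ])
    }
  }
})

test_that("noiseless scores increase strictly with mass and track it linearly", {
  tab <- phantom_score_table(default_scene(0),
                             us_noise_params = us_noise_off(),
                             ct_noise_params = ct_noise_off(),
                             ib_noise_params = ib_noise_off())
  w <- tidyr::pivot_wider(tab, names_from = method, values_from = value)
  w <- dplyr::arrange(w, mass_mg)
  for (m in c("US", "CT", "cIB", "US_volume", "CT_volume")) {
    expect_false(is.unsorted(w[[m]], strictly = TRUE))
  }
  low <- w$mass_mg <= 40
  expect_gte(pearson_r2(w$mass_mg[low], w$US[low])$r_squared, 0.99)
  expect_gte(pearson_r2(w$mass_mg, w$CT)$r_squared, 0.99)
})

test_that("ultrasound and cIB scores agree strongly on common scenes", {
  tab <- phantom_score_table(default_scene(4))
  w <- tidyr::pivot_wider(tab, names_from = method, values_from = value)
  expect_gt(pearson_r2(w$US, w$cIB)$r_squared, 0.9)
})

test_that("zero-mass and IB edge cases render sensibly", {
  z <- render_ib(phantom_scene(masses_mg = 0), "short", noise = ib_noise_off())
  expect_true(all(z$ib_calcium_db == z$ib_agar_db)) # zero contrast

  sc <- phantom_scene(masses_mg = c(10, 40), seed = 2)
  r <- render_ib(sc, "short", noise = ib_noise_off())
  mean_contrast <- tapply(r$ib_calcium_db - r$ib_agar_db, r$mass_mg, mean)
  expect_true(all(diff(mean_contrast) > 0)) # more mass, more contrast
  expect_true(all(r$d_long_mm >= r$d_short_mm))

  expect_error(render_us(sc, noise = ct_noise_off()),
               class = "calscore_config_error")
  expect_error(us_noise(speckle_scale = -1), class = "calscore_config_error")
  expect_error(ct_noise(sigma_hu = -1), class = "calscore_config_error")
})

test_that("shadowing attenuates pixels beneath the calcium layer", {
  sc <- phantom_scene(masses_mg = 50, seed = 1)
  plain <- render_us(sc, "short", noise = us_noise_off())
  shadowed <- render_us(sc, "short",
                        noise = us_noise(speckle = FALSE, sigma_calcium = 0,
                                         shadow_db_per_mm = 3))
  st_p <- plain$stack[[1]]; st_s <- shadowed$stack[[1]]
  tr <- plain$truth[[1]]
  mid <- which(apply(tr$masks, 1, any))[5]
  ca_cols <- which(apply(tr$masks[mid, , ], 2, any))
  deep_rows <- which(st_p$pixels[mid, , ca_cols[1]] > 0 &
                       seq_len(dim(st_p)[2]) >
                         max(which(tr$masks[mid, , ca_cols[1]])))
  expect_true(all(st_s$pixels[mid, deep_rows, ca_cols[1]] <=
                    st_p$pixels[mid, deep_rows, ca_cols[1]]))
  expect_lt(mean(st_s$pixels[mid, deep_rows, ca_cols[1]]),
            mean(st_p$pixels[mid, deep_rows, ca_cols[1]]))
})
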