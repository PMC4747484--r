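test_that("hu_from_pv reproduces the water/air anchors and is linear", {
  cal <- ct_calibration(pv_water = 1000, pv_air = 0)
  expect_equal(hu_from_pv(1000, cal), 0)
  expect_equal(hu_from_pv(0, cal), -1000)
  expect_equal(hu_from_pv(1700, cal), 700)

  # strictly increasing in pv
  pv <- seq(0, 5000, by = 250)
  expect_true(all(diff(hu_from_pv(pv, cal)) > 0))

  expect_error(ct_calibration(1000, 1000),
               class = "calscore_calibration_error")
})

test_that("pv_from_hu inverts hu_from_pv; discrete thresholds round up", {
  cal <- ct_calibration(pv_water = 1000, pv_air = 0)
  expect_equal(pv_from_hu(0, cal), 1000)
  expect_equal(pv_from_hu(700, cal), 1700)
  x <- c(0, 123.4, 999.9, 65535)
  expect_equal(pv_from_hu(hu_from_pv(x, cal), cal), x)

  # ceiling: no sub-threshold pixel may be admitted
  cal2 <- ct_calibration(pv_water = 2000, pv_air = 500)
  pvt <- pv_from_hu(700, cal2, discrete = TRUE) # 2000 + 0.7*1500 = 3050
  expect_equal(pvt, 3050)
  pvt2 <- pv_from_hu(701, cal2, discrete = TRUE) # 3051.5 -> 3052
  expect_equal(pvt2, 3052)
  expect_gte(hu_from_pv(pvt2, cal2), 701)
})

test_that("weighting_factor follows the density bins, gap at 3000 closed up", {
  expect_equal(weighting_factor(699), 0L)
  expect_equal(weighting_factor(700), 1L)
  expect_equal(weighting_factor(850), 1L)
  expect_equal(weighting_factor(999), 1L)
  expect_equal(weighting_factor(1500), 2L)
  expect_equal(weighting_factor(2500), 3L)
  expect_equal(weighting_factor(2999), 3L)
  expect_equal(weighting_factor(3000), 4L)
  expect_equal(weighting_factor(10000), 4L)

  # non-decreasing in hu_max
  hu <- seq(0, 5000, by = 50)
  expect_true(all(diff(weighting_factor(hu)) >= 0))

  expect_error(wf_table(c(700, 600), c(1, 2)), class = "calscore_input_error")
  expect_error(wf_table(c(700, 1000), c(2, 1)), class = "calscore_input_error")
})

test_that("interpolate_rois reproduces endpoints and linear midpoints", {
  a <- roi_rect(1, 1, 11, 11)
  b <- roi_rect(1, 11, 11, 21)
  rs <- interpolate_rois(a, b, 1, 3)
  expect_equal(rs$kind, "endpoints_interpolated")
  expect_equal(length(rs$regions), 3)
  expect_equal(unname(rs$regions[["1"]]$coords), c(1, 1, 11, 11))
  expect_equal(unname(rs$regions[["3"]]$coords), c(1, 11, 11, 21))
  expect_equal(unname(rs$regions[["2"]]$coords), c(1, 6, 11, 16))

  # identical endpoints -> identical intermediates
  rs2 <- interpolate_rois(a, a, 5, 8)
  for (r in rs2$regions) expect_equal(unname(r$coords), c(1, 1, 11, 11))

  # span of two slices -> just the endpoints
  rs3 <- interpolate_rois(a, b, 1, 2)
  expect_equal(length(rs3$regions), 2)

  p1 <- roi_polygon(c(1, 1, 5), c(1, 5, 1))
  p2 <- roi_polygon(c(1, 1, 5, 5), c(1, 5, 5, 1))
  expect_error(interpolate_rois(p1, p2, 1, 3),
               class = "calscore_geometry_error")
  expect_error(interpolate_rois(a, b, 3, 3), class = "calscore_input_error")
})

test_that("score_stack_ct thresholds in HU, weights by wf, sums slices", {
  cal <- ct_calibration(pv_water = 1000, pv_air = 0)
  sl <- matrix(900, 3, 3)
  sl[1, 1] <- 1800 # 800 HU
  sl[2, 2] <- 2500 # 1500 HU
  arr <- array(0, dim = c(1, 3, 3)); arr[1, , ] <- sl
  st <- image_stack(arr, c(1, 1), 1, "CT", calibration = cal)
  rois <- roi_set(list("1" = roi_rect(1, 1, 3, 3)))
  res <- score_stack_ct(st, rois)
  ps <- tidy(res)
  expect_equal(ps$area_calcium_mm2, 2)
  expect_equal(ps$hu_max, 1500)
  expect_equal(ps$wf, 2L)
  expect_equal(ps$ccs, 4)
  expect_equal(res$ct_calcium_score, 4)
  expect_equal(res$ct_calcium_volume, 2)

  # two identical slices double the totals (linearity in area)
  arr2 <- array(0, dim = c(2, 3, 3)); arr2[1, , ] <- sl; arr2[2, , ] <- sl
  st2 <- image_stack(arr2, c(1, 1), 1, "CT", calibration = cal)
  res2 <- score_stack_ct(st2, roi_set(list("1" = roi_rect(1, 1, 3, 3),
                                           "2" = roi_rect(1, 1, 3, 3))))
  expect_equal(res2$ct_calcium_score, 8)

  # everything below threshold scores zero
  low <- array(1500, dim = c(2, 3, 3)) # 500 HU
  st3 <- image_stack(low, c(1, 1), 1, "CT", calibration = cal)
  res3 <- score_stack_ct(st3, roi_set(list("1" = roi_rect(1, 1, 3, 3),
                                           "2" = roi_rect(1, 1, 3, 3))))
  expect_equal(res3$ct_calcium_score, 0)
  expect_equal(res3$ct_calcium_volume, 0)

  # missing calibration
  st4 <- image_stack(arr, c(1, 1), 1, "CT")
  expect_error(score_stack_ct(st4, rois), class = "calscore_calibration_error")
})

test_that("integer-exact calibration makes PV selection match the HU rule", {
  cal <- ct_calibration(pv_water = 1000, pv_air = 0) # 1 PV per HU
  pvt <- pv_from_hu(700, cal, discrete = TRUE)
  set.seed(5)
  for (rep in 1:10) {
    sl <- matrix(sample(0:4000, 64, replace = TRUE), 8, 8)
    sel_pv <- select_calcium_mask(sl, pvt)
    sel_hu <- matrix(hu_from_pv(sl, cal) >= 700, 8, 8)
    expect_identical(sel_pv, sel_hu)
  }
})
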