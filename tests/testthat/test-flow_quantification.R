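test_that("Bernsen low-contrast rule classifies uniform images by midpoint", {
  expect_true(all(bernsen_binarize(matrix(200, 10, 10), bernsen_params(3))))
  expect_false(any(bernsen_binarize(matrix(50, 10, 10), bernsen_params(3))))
  expect_true(all(bernsen_binarize(matrix(128, 10, 10), bernsen_params(3))))
  expect_error(bernsen_binarize(matrix(0, 5, 5), bernsen_params(5)),
               "smaller than the image extent")
})

test_that("Bernsen matches the brute-force neighbourhood oracle", {
  cases <- list(list(r = 3, ct = 15, seed = 1), list(r = 5, ct = 15, seed = 2),
                list(r = 2, ct = 40, seed = 3), list(r = 7, ct = 5, seed = 4))
  for (cs in cases) {
    px <- with_test_seed(cs$seed, matrix(sample(0:255, 24 * 24, TRUE), 24, 24))
    got <- bernsen_binarize(px, bernsen_params(cs$r, cs$ct))
    expect_identical(got, brute_bernsen(px, cs$r, cs$ct))
  }
})

test_that("oval exclusion mask enumerates the correct grid points", {
  m <- make_oval_mask(c(9, 9), c(5, 5), c(1, 1))
  expect_equal(sum(m), 5L)  # center plus its 4-neighbours
  expect_true(m[5, 5] && m[4, 5] && m[6, 5] && m[5, 4] && m[5, 6])

  tiny <- make_oval_mask(c(9, 9), c(5, 5), c(1e-6, 1e-6))
  expect_equal(sum(tiny), 1L)
  expect_true(tiny[5, 5])

  big <- make_oval_mask(c(100, 100), c(40, 60), c(10, 10))
  expect_equal(sum(big), brute_oval_count(c(100, 100), c(40, 60), c(10, 10)))

  expect_error(make_oval_mask(c(10, 10), c(5, 5), c(0, 3)), "positive")
  expect_error(make_oval_mask(c(10, 10), c(50, 5), c(2, 2)), "inside")
})

test_that("flow-area ratio counts flow pixels outside the exclusion zone", {
  all_flow <- matrix(TRUE, 10, 10)
  expect_equal(flow_area_ratio(all_flow)$ratio_pct, 100)
  expect_equal(flow_area_ratio(!all_flow)$ratio_pct, 0)

  mask <- matrix(FALSE, 100, 100)
  mask[seq_len(2730)] <- TRUE
  r <- flow_area_ratio(mask)
  expect_equal(r$ratio_pct, 27.3)
  expect_equal(r$n_flow_px, 2730L)
  expect_equal(r$n_analyzed_px, 10000L)

  # relabeling pixels inside the exclusion does not change the ratio
  excl <- make_oval_mask(c(100, 100), c(50, 50), c(8, 8))
  mask2 <- mask
  mask2[excl] <- !mask2[excl]
  expect_equal(flow_area_ratio(mask, excl)$ratio_pct,
               flow_area_ratio(mask2, excl)$ratio_pct)

  # excluding a purely background region weakly increases the ratio
  bg_excl <- matrix(FALSE, 100, 100)
  bg_excl[80:100, 80:100] <- TRUE
  mask3 <- mask
  mask3[bg_excl] <- FALSE
  expect_gte(flow_area_ratio(mask3, bg_excl)$ratio_pct,
             flow_area_ratio(mask3, NULL)$ratio_pct)

  expect_error(flow_area_ratio(mask, matrix(TRUE, 100, 100)),
               "entire image")
  expect_error(flow_area_ratio(mask, matrix(TRUE, 2, 2)),
               "dimensions differ")
})

test_that("quantify_eye recovers the phantom lumen fraction", {
  ph <- render_phantom(phantom_params(seed = 5))
  q <- quantify_eye(ph$cc, ph$hc)
  truth_frac <- 100 * mean(ph$truth$lumen_mask)
  expect_lt(abs(q$ratio$ratio_pct - truth_frac), 3)
  expect_true(q$vessels_visible)
  expect_gte(dice_coefficient(q$flow_mask, ph$truth$lumen_mask), 0.8)
})

test_that("identical slabs quantify to zero flow", {
  img <- with_test_seed(9, matrix(sample(0:120, 64 * 64, TRUE), 64, 64))
  q <- suppressWarnings(quantify_eye(img, img))
  expect_equal(q$ratio$ratio_pct, 0)
})

test_that("spectral-domain attenuation yields no visible vessels", {
  ph <- render_phantom(phantom_params(attenuation_mode = "sd_octa",
                                      seed = 6))
  expect_warning(q <- quantify_eye(ph$cc, ph$hc), "not visible")
  expect_lt(q$ratio$ratio_pct, 2)
  expect_false(q$vessels_visible)
})

test_that("dice coefficient handles full, partial and empty overlap", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  b <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(dice_coefficient(a, b), 2 * 1 / (2 + 1))
  none <- matrix(FALSE, 2, 2)
  expect_equal(dice_coefficient(none, none), 1)
})
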