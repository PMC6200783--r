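test_that("subfoveal choroidal thickness is the surface difference at the fovea", {
  flat <- surface_map(matrix(100, 8, 8), matrix(390, 8, 8), fovea = c(4, 4))
  expect_equal(measure_sct(flat), 290)

  zero <- surface_map(matrix(120, 8, 8), matrix(120, 8, 8), fovea = c(2, 7))
  expect_equal(measure_sct(zero), 0)

  rpe <- matrix(120, 9, 9); csi <- matrix(550, 9, 9)
  rpe[5, 5] <- 120; csi[5, 5] <- 550
  expect_equal(measure_sct(surface_map(rpe, csi, c(5, 5))), 430)

  # translation invariance: shifting both surfaces leaves SCT unchanged
  shifted <- surface_map(rpe + 37, csi + 37, c(5, 5))
  expect_equal(measure_sct(shifted), measure_sct(surface_map(rpe, csi, c(5, 5))))

  # lateral median window
  csi2 <- csi; csi2[5, 5] <- 5000  # a spike the median should reject
  expect_equal(measure_sct(surface_map(rpe, csi2, c(5, 5)), window = 1), 430)

  expect_error(surface_map(matrix(200, 4, 4), matrix(100, 4, 4), c(2, 2)),
               "above the outer RPE")
  expect_error(surface_map(matrix(1, 4, 4), matrix(2, 4, 4), c(9, 2)),
               "outside the lateral grid")
})

test_that("half-choroid slab is a 30 um window centred on SCT/2", {
  s <- half_choroid_spec(290)
  expect_equal(s$offset_um, 130)
  expect_equal(s$width_um, 30)

  expect_equal(half_choroid_spec(500)$offset_um, 235)
  expect_equal(half_choroid_spec(400, placement = "start")$offset_um, 200)
  expect_error(half_choroid_spec(30), "exceed the slab width")
  expect_warning(half_choroid_spec(140), "150 um eligibility cutoff")
})

test_that("choriocapillaris presets match the analysis and device slabs", {
  a <- cc_slab_spec()
  expect_equal(c(a$offset_um, a$width_um), c(30, 30))
  d <- cc_slab_spec("device")
  expect_equal(c(d$offset_um, d$width_um), c(29, 20))
})

test_that("slab resolution maps micrometre windows to voxel intervals half-up", {
  vol <- make_test_volume(4, 4, ndepth = 40, axial_pitch = 10)
  surf <- surface_map(matrix(100, 4, 4), matrix(350, 4, 4), c(2, 2))
  iv <- resolve_slab(slab_spec(30, 30), surf, vol)
  # depths [130, 160) um at 10 um pitch: zero-based samples 13, 14, 15
  expect_true(all(iv$first == 14L))  # 1-based inclusive
  expect_true(all(iv$last == 16L))

  vol5 <- make_test_volume(4, 4, ndepth = 40, axial_pitch = 5)
  surf0 <- surface_map(matrix(0, 4, 4), matrix(150, 4, 4), c(2, 2))
  iv5 <- resolve_slab(slab_spec(30, 30), surf0, vol5)
  expect_true(all(iv5$first == 7L) && all(iv5$last == 12L))  # [6, 12) zero-based

  # slab thinner than one pitch still yields at least one sample
  thin <- resolve_slab(slab_spec(30, 2), surf, vol)
  expect_true(all(thin$last - thin$first >= 0L))

  # monotone in offset: larger offset never starts earlier
  o1 <- resolve_slab(slab_spec(30, 30), surf, vol)
  o2 <- resolve_slab(slab_spec(50, 30), surf, vol)
  expect_true(all(o2$first >= o1$first))

  expect_error(resolve_slab(slab_spec(500, 30), surf, vol),
               "exits the volume")
})

test_that("slab projection matches a per-pixel loop oracle", {
  vol <- make_test_volume(6, 5, ndepth = 30, axial_pitch = 10, seed = 7)
  rpe <- with_test_seed(8, matrix(sample(seq(0, 100, 10), 30, TRUE), 6, 5))
  surf <- surface_map(rpe, rpe + 200, c(3, 3))
  iv <- resolve_slab(slab_spec(40, 50), surf, vol)
  for (rule in c("max", "mean")) {
    got <- project_slab(vol, iv, projection = rule)
    want <- matrix(0, 6, 5)
    for (r in 1:6) for (c in 1:5) {
      v <- vol$flow[r, c, iv$first[r, c]:iv$last[r, c]]
      want[r, c] <- if (rule == "max") max(v) else floor(mean(v) + 0.5)
    }
    expect_equal(unclass(got), want, ignore_attr = TRUE)
  }
})

test_that("max projection dominates mean projection pixelwise", {
  vol <- make_test_volume(8, 8, seed = 11)
  surf <- surface_map(matrix(50, 8, 8), matrix(300, 8, 8), c(4, 4))
  iv <- resolve_slab(slab_spec(30, 80), surf, vol)
  expect_true(all(project_slab(vol, iv, "max") >=
                    project_slab(vol, iv, "mean")))
})

test_that("projection recovers a known bright layer (round trip)", {
  # bright layer exactly 30-60 um below a flat RPE, value 180
  flow <- array(0, c(8, 8, 30))
  depth_um <- (1:30 - 0.5) * 10
  flow[, , depth_um >= 130 & depth_um < 160] <- 180
  vol <- octa_volume(flow, 10, 12)
  surf <- surface_map(matrix(100, 8, 8), matrix(400, 8, 8), c(4, 4))
  img <- project_slab(vol, resolve_slab(cc_slab_spec(), surf, vol))
  expect_equal(mean(img), 180)
})

test_that("constructors enforce their invariants", {
  expect_error(octa_volume(array(300, c(2, 2, 3)), 10, 12), "\\[0, 255\\]")
  expect_error(octa_volume(array(0, c(2, 2, 1)), 10, 12), "2 depth")
  expect_error(enface_image(matrix(-1, 2, 2)), "\\[0, 255\\]")
  expect_error(slab_spec(10, 0), "width_um")
  expect_error(slab_spec(-5, 30), "offset_um")
})
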