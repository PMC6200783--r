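test_that("vessel networks are reproducible and hit the target fraction", {
  p <- phantom_params(rows = 96, cols = 96, vessel_fraction = 0.25, seed = 3)
  m1 <- generate_vessel_network(p)
  m2 <- generate_vessel_network(p)
  expect_identical(m1, m2)

  frac <- mean(m1)
  expect_gte(frac, 0.20)
  expect_lte(frac, 0.30)

  near_zero <- generate_vessel_network(phantom_params(rows = 96, cols = 96,
                                                      vessel_fraction = 1e-5,
                                                      seed = 3))
  expect_lt(mean(near_zero), 0.01)
  expect_error(generate_vessel_network(phantom_params(vessel_fraction = 0.95)),
               "unattainable")
  expect_error(generate_vessel_network(phantom_params(rows = 32, cols = 32)),
               "64 x 64")
})

test_that("noiseless rendering follows the projection-artifact law exactly", {
  p <- phantom_params(rows = 96, cols = 96, noise_sd = 0, artifact_gain = 1,
                      cc_intensity = 200, lumen_intensity = 80, seed = 4)
  ph <- render_phantom(p)
  expect_true(all(ph$cc == 200))
  expect_true(all(ph$hc[ph$truth$lumen_mask] == 80))
  expect_true(all(ph$hc[!ph$truth$lumen_mask] == 200))
})

test_that("sd-octa attenuation leaves essentially no half-choroid signal", {
  p <- phantom_params(rows = 96, cols = 96, noise_sd = 0,
                      attenuation_mode = "sd_octa", seed = 4)
  ph <- render_phantom(p)
  expect_true(all(ph$hc <= 10))  # bounded by 0.05 x cc_intensity
  expect_true(all(ph$cc == 200))  # choriocapillaris unaffected
})

test_that("noiseless strong-contrast phantom is recovered exactly by the chain", {
  p <- phantom_params(rows = 96, cols = 96, noise_sd = 0, artifact_gain = 1,
                      cc_intensity = 200, lumen_intensity = 80, seed = 5)
  ph <- render_phantom(p)
  final <- remove_projection_artifact(ph$cc, ph$hc)$final
  expect_identical(unclass(final) > 0, ph$truth$lumen_mask)
  expect_true(all(final[ph$truth$lumen_mask] == 80))
})

test_that("rendering rejects intensity configurations without dark lumina", {
  expect_error(render_phantom(phantom_params(lumen_intensity = 250)),
               "dark-lumen")
  expect_error(phantom_params(cc_intensity = 300), "\\[0, 255\\]")
  expect_error(phantom_params(sd_attenuation = 0.2), "0.05")
})

test_that("segmentation Dice degrades monotonically along a noise ladder", {
  dice_at <- function(noise) {
    p <- phantom_params(rows = 128, cols = 128, noise_sd = noise, seed = 11)
    ph <- render_phantom(p)
    q <- suppressWarnings(quantify_eye(ph$cc, ph$hc))
    dice_coefficient(q$flow_mask, ph$truth$lumen_mask)
  }
  ladder <- vapply(c(0, 8, 30, 60), dice_at, numeric(1))
  expect_gte(ladder[2], 0.8)  # default-noise operating point
  expect_true(all(diff(ladder) <= 0))
})

test_that("phantom cohorts are deterministic and couple flow to thickness", {
  c1 <- generate_cohort(6, seed = 2, coupling = 1,
                        base_params = phantom_params(rows = 96, cols = 96))
  c2 <- generate_cohort(6, seed = 2, coupling = 1,
                        base_params = phantom_params(rows = 96, cols = 96))
  expect_identical(c1, c2)
  scts <- vapply(c1, function(ph) ph$truth$sct_um, numeric(1))
  fracs <- vapply(c1, function(ph) mean(ph$truth$lumen_mask), numeric(1))
  targets <- vapply(c1, function(ph) ph$truth$params$vessel_fraction,
                    numeric(1))
  expect_true(all(scts >= 180 & scts <= 500))
  # at full coupling the target fraction is strictly monotone in SCT,
  # and every achieved fraction is within 20% relative of its target
  expect_equal(cor(scts, targets, method = "spearman"), 1)
  expect_true(all(abs(fracs - targets) / targets <= 0.2))
  expect_error(generate_cohort(3), "at least 5")
})

test_that("phantom volume rendering reproduces the slab pair through geometry", {
  p <- phantom_params(rows = 96, cols = 96, noise_sd = 0, seed = 8)
  pv <- render_phantom_volume(p)
  sct <- measure_sct(pv$surfaces)
  expect_equal(sct, p$sct_um)
  cc <- project_slab(pv$volume,
                     resolve_slab(cc_slab_spec(), pv$surfaces, pv$volume))
  hc <- project_slab(pv$volume,
                     resolve_slab(half_choroid_spec(sct), pv$surfaces,
                                  pv$volume))
  ph <- render_phantom(p)
  expect_equal(unclass(cc), unclass(ph$cc), ignore_attr = TRUE)
  expect_equal(unclass(hc), unclass(ph$hc), ignore_attr = TRUE)
})
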