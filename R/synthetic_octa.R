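#' Phantom generator parameters
#'
#' Conditions for the synthetic en-face slab phantom: a laterally
#' uniform bright choriocapillaris, dark vessel lumina embedded in
#' stroma at half-choroid depth, a stromal "projection" signal
#' proportional to the overlying choriocapillaris signal, additive
#' Gaussian noise, and an optional spectral-domain attenuation mode in
#' which essentially no flow signal reaches the half-choroid.
#'
#' @param rows,cols Lateral grid size (>= 64 for vessel-network
#'   generation).
#' @param sct_um Subfoveal choroidal thickness of the phantom eye, um.
#' @param cc_intensity Choriocapillaris flow signal (0–255).
#' @param lumen_intensity Residual luminal flow signal in the
#'   half-choroid (0–255); must stay below `artifact_gain *
#'   cc_intensity` so lumina appear dark on the white stroma.
#' @param artifact_gain Fraction of the overlying choriocapillaris
#'   signal projected onto the stroma, in `[0, 1]`.
#' @param vessel_fraction Target fraction of the grid covered by vessel
#'   lumina, in `(0, 0.9]`.
#' @param vessel_width_px Range `c(min, max)` of vessel tube widths in
#'   pixels.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (clipped to 8-bit).
#' @param attenuation_mode `"none"` (swept-source-like penetration) or
#'   `"sd_octa"` (half-choroid signal multiplied by
#'   `sd_attenuation`).
#' @param sd_attenuation Residual signal factor in `sd_octa` mode
#'   (<= 0.05).
#' @param axial_pitch_um,lateral_pitch_um Sampling pitches used when a
#'   full volume is rendered.
#' @param seed Integer seed; every random draw of the phantom flows from
#'   it.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(rows = 192, cols = 192, sct_um = 300,
                           cc_intensity = 200, lumen_intensity = 80,
                           artifact_gain = 1, vessel_fraction = 0.25,
                           vessel_width_px = c(4, 10), noise_sd = 8,
                           attenuation_mode = c("none", "sd_octa"),
                           sd_attenuation = 0.02,
                           axial_pitch_um = 10, lateral_pitch_um = 12,
                           seed = 1L) {
  attenuation_mode <- match.arg(attenuation_mode)
  if (cc_intensity < 0 || cc_intensity > 255 ||
      lumen_intensity < 0 || lumen_intensity > 255)
    stopf("intensities must lie in [0, 255]")
  if (artifact_gain < 0 || artifact_gain > 1)
    stopf("artifact_gain must lie in [0, 1]")
  if (sd_attenuation > 0.05)
    stopf("sd_attenuation must be <= 0.05 to emulate no penetration")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 sct_um = sct_um, cc_intensity = cc_intensity,
                 lumen_intensity = lumen_intensity,
                 artifact_gain = artifact_gain,
                 vessel_fraction = vessel_fraction,
                 vessel_width_px = vessel_width_px, noise_sd = noise_sd,
                 attenuation_mode = attenuation_mode,
                 sd_attenuation = sd_attenuation,
                 axial_pitch_um = axial_pitch_um,
                 lateral_pitch_um = lateral_pitch_um,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Stamp a filled disc of radius `rad` centred at (r0, c0) into `mask`.
stamp_disc <- function(mask, r0, c0, rad) {
  n <- nrow(mask); m <- ncol(mask)
  rr <- max(1L, floor(r0 - rad)):min(n, ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(m, ceiling(c0 + rad))
  if (length(rr) == 0L || length(cc) == 0L) return(mask)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  mask[rr, cc] <- mask[rr, cc] | (d2 <= rad^2)
  mask
}

#' Generate a synthetic vessel network
#'
#' Curvilinear vessel lumina as seeded random-walk tubes: each walk
#' starts at a random position and heading, drifts with small angular
#' jitter, and stamps a disc of the tube's half-width at every step.
#' Walks are added until approximately `vessel_fraction` of the grid is
#' covered; the result is reproducible from the seed.
#'
#' @param params A [phantom_params] (supplies grid size, target
#'   fraction, width range and the seed), or `NULL` to pass the fields
#'   explicitly.
#' @param rows,cols,vessel_fraction,vessel_width_px,seed Overrides of
#'   the corresponding `params` fields.
#' @return Logical matrix, `TRUE` = vessel lumen.
#' @export
generate_vessel_network <- function(params = phantom_params(),
                                    rows = params$rows, cols = params$cols,
                                    vessel_fraction = params$vessel_fraction,
                                    vessel_width_px = params$vessel_width_px,
                                    seed = params$seed) {
  if (rows < 64L || cols < 64L)
    stopf("vessel-network grid must be at least 64 x 64")
  if (vessel_fraction > 0.9)
    stopf("vessel_fraction %.2f is unattainable (> 0.9)", vessel_fraction)
  mask <- matrix(FALSE, rows, cols)
  target <- vessel_fraction * rows * cols
  if (target < 1) return(mask)
  with_seed(seed, {
    guard <- 0L
    while (sum(mask) < target && guard < 10000L) {
      guard <- guard + 1L
      r <- stats::runif(1, 1, rows)
      c <- stats::runif(1, 1, cols)
      ang <- stats::runif(1, 0, 2 * pi)
      w <- stats::runif(1, vessel_width_px[1], vessel_width_px[2])
      steps <- as.integer(1.5 * max(rows, cols))
      for (s in seq_len(steps)) {
        mask <- stamp_disc(mask, r, c, w / 2)
        ang <- ang + stats::rnorm(1, 0, 0.15)
        r <- r + sin(ang)
        c <- c + cos(ang)
        if (r < 1 || r > rows || c < 1 || c > cols) break
        if (s %% 25L == 0L && sum(mask) >= target) break
      }
    }
  })
  mask
}

#' Render a phantom slab pair
#'
#' Applies the projection-artifact rendering law: the choriocapillaris
#' image is the uniform `cc_intensity`; the half-choroid image carries
#' `artifact_gain * cc_intensity` on stroma (the projection artifact)
#' and `lumen_intensity` inside vessel lumina. Gaussian noise is added
#' independently to each slab; in `sd_octa` attenuation mode the entire
#' noisy half-choroid signal (fluctuations included) is scaled by
#' `sd_attenuation`, emulating a source whose detected flow signal does
#' not reach the half-choroid. All images are rounded half-up and
#' clipped to 8-bit.
#'
#' @param params A [phantom_params].
#' @param lumen_mask Optional precomputed vessel mask; generated from
#'   `params` when `NULL`.
#' @return A `phantom` list: `cc`, `hc` ([enface_image]s), and `truth`
#'   (`lumen_mask`, `params`, `sct_um`).
#' @export
render_phantom <- function(params = phantom_params(), lumen_mask = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  if (params$lumen_intensity >= params$artifact_gain * params$cc_intensity)
    stopf("lumen_intensity (%g) must stay below artifact_gain * cc_intensity (%g) for dark-lumen appearance",
          params$lumen_intensity,
          params$artifact_gain * params$cc_intensity)
  if (is.null(lumen_mask))
    lumen_mask <- generate_vessel_network(params)
  if (!identical(dim(lumen_mask), c(params$rows, params$cols)))
    stopf("lumen_mask dimensions do not match the phantom grid")
  cc_base <- matrix(params$cc_intensity, params$rows, params$cols)
  hc_base <- matrix(params$artifact_gain * params$cc_intensity,
                    params$rows, params$cols)
  hc_base[lumen_mask] <- params$lumen_intensity
  noisy <- function(base, stream_offset, attenuation = 1) {
    if (params$noise_sd > 0)
      base <- base + with_seed(derive_seed(params$seed, stream_offset),
                               stats::rnorm(length(base),
                                            sd = params$noise_sd))
    clip8(round_half_up(base * attenuation))
  }
  hc_att <- if (params$attenuation_mode == "sd_octa")
    params$sd_attenuation else 1
  cc <- enface_image(noisy(cc_base, 101L),
                     lateral_pitch = params$lateral_pitch_um,
                     slab_label = "choriocapillaris")
  hc <- enface_image(noisy(hc_base, 202L, hc_att),
                     lateral_pitch = params$lateral_pitch_um,
                     slab_label = "half_choroid")
  structure(list(cc = cc, hc = hc,
                 truth = list(lumen_mask = lumen_mask, params = params,
                              sct_um = params$sct_um)),
            class = "phantom")
}

#' Render a phantom as a full OCTA volume with surfaces
#'
#' Embeds the phantom's slabs into a 3-D flow volume: a bright
#' choriocapillaris layer 30–60 um below a flat outer RPE surface, the
#' half-choroid pattern (stromal projection plus dark lumina) in a 30 um
#' band centred at half the phantom's choroidal thickness, and a flat
#' choroid-sclera interface at `sct_um`. Useful for exercising the slab
#' geometry path end to end.
#'
#' @param params A [phantom_params].
#' @param lumen_mask Optional precomputed vessel mask.
#' @return A list: `volume` ([octa_volume]), `surfaces` ([surface_map]),
#'   and `truth` as in [render_phantom()].
#' @export
render_phantom_volume <- function(params = phantom_params(),
                                  lumen_mask = NULL) {
  ph <- render_phantom(params, lumen_mask)
  rpe_um <- 100
  ndepth <- as.integer(ceiling((rpe_um + params$sct_um + 60) /
                                 params$axial_pitch_um))
  flow <- array(0, c(params$rows, params$cols, ndepth))
  depth_um <- (seq_len(ndepth) - 0.5) * params$axial_pitch_um
  cc_band <- which(depth_um >= rpe_um + 30 & depth_um < rpe_um + 60)
  hc_mid <- rpe_um + params$sct_um / 2
  hc_band <- which(depth_um >= hc_mid - 15 & depth_um < hc_mid + 15)
  for (d in cc_band) flow[, , d] <- unclass(ph$cc)
  for (d in hc_band) flow[, , d] <- unclass(ph$hc)
  vol <- octa_volume(flow, axial_pitch_um = params$axial_pitch_um,
                     lateral_pitch_um = params$lateral_pitch_um)
  surf <- surface_map(matrix(rpe_um, params$rows, params$cols),
                      matrix(rpe_um + params$sct_um, params$rows,
                             params$cols),
                      fovea = c(params$rows %/% 2L, params$cols %/% 2L))
  list(volume = vol, surfaces = surf, truth = ph$truth)
}

#' Generate a synthetic cohort of phantom eyes
#'
#' Draws per-eye choroidal thickness uniformly over `sct_range_um`
#' (defaults to the 180–500 um range of normal adult eyes) and couples
#' the vessel fraction linearly to it: `coupling = 1` spans the full
#' `fraction_range`, `coupling = 0` removes the association (the null).
#' Per-eye seeds are derived deterministically from the master seed, so
#' a fixed seed reproduces the cohort bitwise.
#'
#' @param n_eyes Number of phantom eyes (>= 5).
#' @param seed Master seed.
#' @param coupling Strength of the SCT-vessel-fraction association in
#'   `[0, 1]`.
#' @param base_params [phantom_params] template for every eye.
#' @param sct_range_um Range SCT is drawn from.
#' @param fraction_range Vessel-fraction range mapped onto the SCT range
#'   at `coupling = 1`.
#' @return A `phantom_cohort`: list of `phantom` objects.
#' @export
generate_cohort <- function(n_eyes = 30, seed = 1L, coupling = 0.5,
                            base_params = phantom_params(),
                            sct_range_um = c(180, 500),
                            fraction_range = c(0.12, 0.40)) {
  if (n_eyes < 5L) stopf("a cohort needs at least 5 eyes")
  if (coupling < 0 || coupling > 1) stopf("coupling must lie in [0, 1]")
  scts <- with_seed(seed,
                    stats::runif(n_eyes, sct_range_um[1], sct_range_um[2]))
  f_mid <- mean(fraction_range)
  eyes <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    rel <- (scts[i] - sct_range_um[1]) / diff(sct_range_um) - 0.5
    frac <- f_mid + coupling * diff(fraction_range) * rel
    p <- base_params
    p$sct_um <- scts[i]
    p$vessel_fraction <- min(max(frac, 0.02), 0.9)
    p$seed <- derive_seed(seed, i)
    eyes[[i]] <- render_phantom(p)
  }
  structure(eyes, class = "phantom_cohort")
}

#' Run the quantification pipeline over a phantom cohort
#'
#' Applies [quantify_eye()] to every phantom and returns per-eye SCT and
#' flow ratio plus the Spearman association between them — the synthetic
#' counterpart of the clinical thickness-flow correlation.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param bernsen A [bernsen_params].
#' @return A list: `eyes` (data frame with `sct_um`, `flow_pct`,
#'   `truth_fraction`), `spearman_rho`, `spearman_p`.
#' @export
quantify_cohort <- function(cohort, bernsen = bernsen_params()) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  rows <- lapply(cohort, function(ph) {
    q <- quantify_eye(ph$cc, ph$hc, bernsen = bernsen)
    data.frame(sct_um = ph$truth$sct_um, flow_pct = q$ratio$ratio_pct,
               truth_fraction = mean(ph$truth$lumen_mask))
  })
  eyes <- do.call(rbind, rows)
  sp <- spearman_correlation(eyes$sct_um, eyes$flow_pct)
  list(eyes = eyes, spearman_rho = sp$rho, spearman_p = sp$p_value)
}
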