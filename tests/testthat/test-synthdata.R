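op_small <- optics_spec(field_px = c(512L, 512L))

test_that("scene construction handles empty, absent and deterministic cases", {
  sc0 <- build_scene(op_small, n_synapses = 0, seed = 1)
  expect_length(sc0$synapses, 0)
  expect_equal(nrow(truth_table(sc0)), 0)

  sc_abs <- build_scene(op_small, 3, amplitude_regime = "absent", seed = 1)
  expect_true(all(truth_table(sc_abs)$channel_amplitude == 0))

  sc_a <- build_scene(op_small, 4, seed = 42)
  sc_b <- build_scene(op_small, 4, seed = 42)
  expect_identical(sc_a, sc_b)

  # seed splitting: adding synapses does not perturb earlier ones
  sc_more <- build_scene(op_small, 6, seed = 42)
  expect_identical(sc_more$synapses[1:4], sc_a$synapses)
})

test_that("synapse placement respects spacing and rejects overfull fields", {
  sc <- build_scene(op_small, 8, seed = 3, min_spacing_nm = 1500)
  tt <- truth_table(sc)
  d <- as.matrix(stats::dist(cbind(tt$center_x_nm, tt$center_y_nm)))
  expect_true(min(d[upper.tri(d)]) >= 1500)
  ext <- 512 * 14.194
  expect_true(all(tt$center_x_nm > 0 & tt$center_x_nm < ext))
  expect_error(build_scene(op_small, 1000, seed = 1), "at most")
  expect_error(build_scene(optics_spec(field_px = c(64L, 64L)), 1, seed = 1),
               "too small")
})

test_that("requested offsets are stored exactly and round-trip through CSV", {
  sc <- build_scene(op_small, 3, offset_mean_nm = -40, offset_sd_nm = 0,
                    seed = 9)
  tt <- truth_table(sc)
  expect_identical(tt$channel_offset_nm, rep(-40, 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_truth_table(tt, f)
  expect_equal(as.data.frame(read_truth_table(f)), as.data.frame(tt))
})

test_that("noiseless rendering: background-only and amplitude linearity", {
  sc <- build_scene(op_small, 2, amplitude_regime = "absent", seed = 5,
                    truth_args = list(psd_amplitude = 0,
                                      synapsin_amplitude = 0))
  stk <- render_stack(sc, noise = "none")
  for (ch in stk$pixels) expect_true(all(ch == 5))

  sc1 <- build_scene(op_small, 2, seed = 5)
  sc2 <- sc1
  sc2$synapses <- lapply(sc2$synapses, function(s) {
    s$psd_amplitude <- 2 * s$psd_amplitude
    s$channel_amplitude <- 2 * s$channel_amplitude
    s$synapsin_amplitude <- 2 * s$synapsin_amplitude
    s
  })
  r1 <- render_stack(sc1, noise = "none")
  r2 <- render_stack(sc2, noise = "none")
  for (ch in names(r1$pixels)) {
    expect_equal(r2$pixels[[ch]] - 5, 2 * (r1$pixels[[ch]] - 5),
                 tolerance = 1e-12)
  }
})

test_that("Poisson rendering is seed-deterministic", {
  sc <- build_scene(op_small, 1, seed = 11)
  a <- render_stack(sc, noise = "poisson", seed = 7)
  b <- render_stack(sc, noise = "poisson", seed = 7)
  expect_identical(a, b)
  c <- render_stack(sc, noise = "poisson", seed = 8)
  expect_false(identical(a$pixels[[1]], c$pixels[[1]]))
})

test_that("rendered point source has the configured PSF width", {
  op <- optics_spec(pixel_size_nm = 2, field_px = c(512L, 512L),
                    background_counts = 0)
  scene <- build_scene(op, 0, seed = 1)
  center <- c(512, 512)  # nm
  syn <- synapse_truth(center_nm = center, axis_angle_rad = 0,
                       vesicle_cloud_radius_nm = 1,
                       vesicle_cloud_offset_nm = 1e-9)
  # place the cloud exactly at the center: offset ~ 0
  scene$synapses <- list(syn)
  stk <- render_stack(scene, noise = "none")
  img <- get_channel(stk, "synapsin")
  row <- img[256, ]
  xs <- (seq_len(512) - 0.5) * 2
  fwhm <- measure_fwhm(xs, row)
  expect_lt(abs(fwhm - 250) / 250, 0.05)  # confocal synapsin channel
})

test_that("a PSD bar's cross-section FWHM follows quadrature widening", {
  op <- optics_spec(pixel_size_nm = 4, field_px = c(512L, 512L),
                    background_counts = 0)
  scene <- build_scene(op, 0, seed = 1)
  scene$synapses <- list(synapse_truth(
    center_nm = c(1024, 1024), axis_angle_rad = 0,
    psd_length_nm = 1200, psd_thickness_nm = 150, channel_amplitude = 0))
  stk <- render_stack(scene, noise = "none")
  img <- get_channel(stk, "psd95")  # STED, FWHM 60 nm
  col <- img[, 256]
  ys <- (seq_len(512) - 0.5) * 4
  fwhm <- measure_fwhm(ys, col)
  expected <- sqrt(150^2 + 60^2)
  expect_lt(abs(fwhm - expected) / expected, 0.10)
})

test_that("Poisson sampling is calibrated against the noiseless expectation", {
  op <- optics_spec(pixel_size_nm = 14.194, field_px = c(48L, 48L),
                    channels = c(synapsin = "confocal"),
                    background_counts = 5)
  scene <- build_scene(op, 0, seed = 1)
  scene$synapses <- list(synapse_truth(
    center_nm = c(340, 340), axis_angle_rad = 0,
    vesicle_cloud_radius_nm = 120, vesicle_cloud_offset_nm = 1e-9,
    channel_amplitude = 0, psd_amplitude = 0, synapsin_amplitude = 50))
  expected <- get_channel(render_stack(scene, noise = "none"), "synapsin")
  n_rep <- 1000L
  acc <- matrix(0, 48, 48)
  for (k in seq_len(n_rep)) {
    acc <- acc + get_channel(render_stack(scene, noise = "poisson", seed = k),
                             "synapsin")
  }
  mean_img <- acc / n_rep
  se <- sqrt(expected / n_rep)
  z <- (mean_img - expected) / se
  expect_gt(mean(abs(z) <= 3), 0.995)  # per-pixel means match to 3 SE
  expect_lt(max(abs(z)), 6)
})
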