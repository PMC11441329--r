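test_that("rolling average: identity, impulse, shrink-edge rule, bounds", {
  expect_equal(smooth_rolling_average(rep(3.5, 9), 5), rep(3.5, 9))
  imp <- c(0, 0, 0, 0, 5, 0, 0, 0, 0)
  expect_equal(smooth_rolling_average(imp, 5)[5], 1.0)
  expect_equal(smooth_rolling_average(c(5, 0, 0, 0, 0), 5)[1], 5 / 3)
  expect_error(smooth_rolling_average(1:10, 4), "odd")
  expect_error(smooth_rolling_average(1:3, 5), "length")
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(sample(5:40, 1))
    s <- smooth_rolling_average(v, 5)
    expect_true(all(s >= min(v) - 1e-12 & s <= max(v) + 1e-12))
    expect_length(s, length(v))
  }
})

test_that("PSD peak location: analytic center, tie rule, degenerate cases", {
  pos <- seq(-500, 500, by = 10)
  gauss <- exp(-(pos - 300)^2 / (2 * 80^2))
  expect_lte(abs(locate_psd_peak(pos, gauss) - 300), 5)

  twin <- rep(0, length(pos))
  twin[pos == -50] <- 1; twin[pos == 50] <- 1
  expect_equal(locate_psd_peak(pos, twin, smooth_px = 1L), -50)

  expect_error(locate_psd_peak(pos, rep(0, length(pos))), "all zero")
  expect_warning(p <- locate_psd_peak(pos, rep(2, length(pos))), "flat")
  expect_equal(p, pos[1])
})

test_that("profile extraction: zero image, uniform band plateau, boundaries", {
  psz <- 14.194
  zero <- matrix(0, 256, 256)
  stack <- image_stack(list(psd95 = zero),
                       c(psd95 = "sted"), psz)
  prof <- extract_profile(stack, c(1800, 1800), 0)
  expect_true(all(prof$value == 0))
  expect_true(all(abs(diff(sort(unique(prof$position_nm))) - psz) < 1e-9))
  expect_gte(diff(range(prof$position_nm)), 950)

  # axis-aligned uniform horizontal band: the profile (drawn vertically)
  # reproduces the band's 1-D cross-section with plateau v
  band <- matrix(0, 256, 256)
  band[121:136, ] <- 7  # rows 121..136 -> y in [1703, 1930] nm
  stack <- image_stack(list(psd95 = band), c(psd95 = "sted"), psz)
  prof <- extract_profile(stack, c(1800, 1816.6), 0)  # center of band rows
  inside <- abs(prof$position_nm) <= 60
  outside <- abs(prof$position_nm) >= 200
  expect_true(all(abs(prof$value[inside] - 7) < 1e-9))
  expect_true(all(prof$value[outside] == 0))

  expect_error(extract_profile(stack, c(30, 30), 0),
               class = "synquant_boundary_error")
})

test_that("extraction is equivariant under rotation and pixel translation", {
  base <- render_single_synapse(offset_nm = -50, angle = 0)
  rot <- render_single_synapse(offset_nm = -50, angle = pi / 6)
  p0 <- extract_profile(base$stack, base$truth$center_nm, 0)
  p30 <- extract_profile(rot$stack, rot$truth$center_nm, pi / 6)
  for (ch in unique(p0$channel)) {
    a <- p0$value[p0$channel == ch]
    b <- p30$value[p30$channel == ch]
    expect_lt(sqrt(mean((a - b)^2)) / max(a), 0.02)
  }

  shift <- render_single_synapse(offset_nm = -50, angle = 0)
  shift_nm <- 3 * 14.194
  shift$truth$center_nm <- shift$truth$center_nm + c(shift_nm, 0)
  shift$scene$synapses[[1]] <- shift$truth
  sstk <- render_stack(shift$scene, noise = "none")
  p1 <- extract_profile(sstk, shift$truth$center_nm, 0)
  expect_equal(p1$value, p0$value, tolerance = 1e-9)
})

test_that("alignment puts every smoothed PSD-95 maximum at zero", {
  op <- optics_spec(field_px = c(1024L, 1024L))
  sc <- build_scene(op, 12, seed = 31)
  stk <- render_stack(sc, noise = "poisson")
  prof <- extract_profiles(stk, truth_table(sc))
  al <- align_profiles(prof)
  psd <- al$profiles |> dplyr::filter(channel == "psd95")
  for (id in unique(psd$synapse_id)) {
    d <- psd[psd$synapse_id == id, ]
    expect_lte(abs(d$position_nm[which.max(d$value)]), al$step_nm / 2)
  }
})

test_that("alignment: single profile, shift invariance, offset recovery", {
  single <- render_single_synapse(offset_nm = -50, angle = 1.1)
  prof <- extract_profile(single$stack, single$truth$center_nm, 1.1)
  al <- align_profiles(prof)
  expect_true(all(al$summary$sem == 0))
  expect_equal(nrow(dplyr::distinct(al$profiles, synapse_id)), 1)

  # two copies of one profile shifted by whole grid steps align identically
  k <- 4
  p2 <- prof |>
    dplyr::mutate(synapse_id = 2L, position_nm = position_nm + k * 14.194)
  al2 <- align_profiles(dplyr::bind_rows(prof, p2))
  wide <- al2$profiles |>
    tidyr::pivot_wider(names_from = synapse_id, values_from = value) |>
    stats::na.omit()
  expect_equal(wide$`1`, wide$`2`, tolerance = 1e-12)

  # targeted regime: mean channel profile peaks at the true offset
  mean_ch <- al$summary |> dplyr::filter(channel == "channel_of_interest")
  peak_pos <- mean_ch$position_nm[which.max(mean_ch$mean)]
  expect_lte(abs(peak_pos - (-50)), 14.194)

  expect_error(align_profiles(prof[0, ]), "no profiles")
})

test_that("in-window peaks: window restriction, ties, zero channel, monotonicity", {
  pos <- seq(-500, 500, by = 10)
  val <- exp(-(pos + 300)^2 / (2 * 30^2)) * 10      # global max outside
  val[pos == -40] <- 7                               # local max inside
  prof <- tibble::tibble(synapse_id = 1L, position_nm = pos,
                         channel = "channel_of_interest", value = val)
  pk <- peak_in_window(prof, window_nm = 200)
  expect_equal(pk$peak_value, 7)
  expect_equal(pk$peak_position_nm, -40)

  zero <- tibble::tibble(synapse_id = 1L, position_nm = pos,
                         channel = "channel_of_interest", value = 0)
  pk0 <- peak_in_window(zero, window_nm = 200)
  expect_equal(pk0$peak_value, 0)
  expect_equal(pk0$peak_position_nm, 0)  # tie -> nearest zero

  tie <- zero
  tie$value[pos %in% c(-50, 50)] <- 3
  expect_equal(peak_in_window(tie, 200)$peak_position_nm, -50)  # negative side

  # enlarging the window never decreases the peak value
  set.seed(9)
  noisy <- tibble::tibble(synapse_id = 1L, position_nm = pos,
                          channel = "channel_of_interest",
                          value = abs(rnorm(length(pos))))
  peaks <- vapply(c(100, 200, 400, 800),
                  function(w) peak_in_window(noisy, w)$peak_value, numeric(1))
  expect_true(all(diff(peaks) >= 0))

  expect_error(peak_in_window(noisy, window_nm = 5000), "exceeds")
})

test_that("summarize_peaks produces one row per synapse per condition", {
  mk <- function(n, base) tibble::tibble(
    synapse_id = seq_len(n), channel = "channel_of_interest",
    peak_value = base + seq_len(n), peak_position_nm = 0)
  out <- summarize_peaks(list(a = mk(3, 0), b = mk(3, 10)))
  expect_equal(nrow(out), 6)
  expect_equal(sort(unique(out$condition)), c("a", "b"))
  expect_warning(out2 <- summarize_peaks(list(a = mk(2, 0), b = mk(0, 0)[0, ])),
                 "empty")
  expect_equal(unique(out2$condition), "a")
  expect_identical(out$peak_value[out$condition == "b"], mk(3, 10)$peak_value)
})

test_that("automated side-view detection matches ground truth", {
  op <- optics_spec(field_px = c(512L, 512L))
  sc <- build_scene(op, 1, seed = 13)
  stk <- render_stack(sc, noise = "poisson")
  det <- detect_side_view_synapses(stk)
  expect_equal(nrow(det), 1)
  truth <- truth_table(sc)
  ang_err <- abs(det$axis_angle_rad - truth$axis_angle_rad)
  ang_err <- min(ang_err, pi - ang_err)
  expect_lt(ang_err, 5 * pi / 180)
  expect_lt(abs(det$anchor_x_nm - truth$center_x_nm), 50)
  expect_lt(abs(det$anchor_y_nm - truth$center_y_nm), 50)

  # round PSD (face view) fails the elongation criterion
  scf <- build_scene(op, 1, seed = 13, view = "face")
  detf <- detect_side_view_synapses(render_stack(scf, noise = "poisson"),
                                    min_elongation = 2)
  expect_equal(nrow(detf), 0)

  # blank PSD channel -> no detections
  blank <- stk
  blank$pixels$psd95[] <- 0
  expect_equal(nrow(detect_side_view_synapses(blank)), 0)
})

test_that("noiseless offsets up to 150 nm are recovered within one pixel", {
  for (off in c(0, 25, 50, 100, 150)) {
    single <- render_single_synapse(offset_nm = -off, angle = 0.8)
    prof <- extract_profile(single$stack, single$truth$center_nm, 0.8)
    al <- align_profiles(prof)
    pk <- peak_in_window(al, 400, channels = "channel_of_interest")
    expect_lte(abs(pk$peak_position_nm - (-off)), 14.194 + 1e-9)
  }
})
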