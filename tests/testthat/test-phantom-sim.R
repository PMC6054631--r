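test_that("rasterization reproduces analytic tube geometry", {
  geom <- phantom_geometry("straight_tube", inner_diameter = 4)
  grid <- grid_spec(c(96, 96), 0.5)
  maps <- rasterize_structure(geom, grid)

  # a 4 mm lumen on a 0.5 mm grid is 8 pixels across
  cross <- maps$lumen[, 48]
  expect_equal(sum(cross > 0.5), 8)

  # partial-volume conservation: lumen area within 2% of width x length
  area <- sum(maps$lumen) * prod(grid$spacing)
  expect_lt(abs(area / (96 * 0.5) - 4) / 4, 0.02)

  # mirror symmetry across the tube centerline, exact by construction
  expect_identical(maps$lumen, maps$lumen[96:1, ])
  expect_identical(maps$wall, maps$wall[96:1, ])

  # lumen and wall fractions partition each pixel at most once
  expect_true(all(maps$lumen + maps$wall <= 1 + 1e-12))
})

test_that("degenerate and oversized structures are handled", {
  grid <- grid_spec(c(64, 64), 0.5)
  tiny <- phantom_geometry("straight_tube", inner_diameter = 1e-4,
                           wall_thickness = 1e-4)
  maps <- rasterize_structure(tiny, grid)
  expect_true(all(maps$lumen == 0))

  big <- phantom_geometry("one_sided_aneurysm", inner_diameter = 20,
                          aneurysm_diameter = 60)
  expect_error(rasterize_structure(big, grid), "field of view")
})

test_that("all six structure kinds rasterize with plausible support", {
  grid <- grid_spec(c(96, 96), 1.0)
  for (kind in c("straight_tube", "stenosis", "helix", "bifurcation",
                 "one_sided_aneurysm", "two_sided_aneurysm")) {
    maps <- rasterize_structure(phantom_geometry(kind, inner_diameter = 4),
                                grid)
    expect_gt(sum(maps$lumen), 0, label = kind)
    expect_gt(sum(maps$wall), 0, label = kind)
  }
  # the stenosis throat is narrower than the parent tube
  st <- rasterize_structure(phantom_geometry("stenosis", inner_diameter = 4,
                                             stenosis_fraction = 0.4), grid)
  expect_lt(sum(st$lumen[, 48]), sum(st$lumen[, 5]))
})

test_that("bolus curve honours arrival, peak and valve gating", {
  p <- bolus_profile(t_arrival = 5)
  expect_identical(bolus_intensity(0, p), p$baseline)
  expect_identical(bolus_intensity(4.999, p), p$baseline)

  # gamma-variate maximum at alpha * beta after arrival (dense scan oracle)
  p0 <- bolus_profile(gate_depth = 0)
  tt <- seq(p0$t_arrival, p0$t_arrival + 30, by = 1e-3)
  expect_equal(bolus_intensity(p0$t_arrival + p0$alpha * p0$beta, p0),
               p0$peak)
  expect_equal(max(bolus_intensity(tt, p0)), p0$peak, tolerance = 1e-6)

  # 60 bpm gating is 1 s periodic
  p60 <- bolus_profile(pulse_rate = 60)
  ts <- p60$t_arrival + seq(0.012, 4.9, by = 0.1)
  gate <- phantomflow:::gate_factor(ts, p60)
  expect_identical(gate, phantomflow:::gate_factor(ts + 1, p60))
  expect_setequal(unique(gate), c(1 - p60$gate_depth, 1))
  expect_true(all(bolus_intensity(seq(0, 40, 0.1), p60) >= 0))
})

test_that("rendered sequences are static, bolus-driven and reproducible", {
  geom <- phantom_geometry("straight_tube", inner_diameter = 4)
  grid <- twist_grid(64)
  prof <- bolus_profile()
  m0 <- imaging_model("twist_mri", noise_sigma = 0)

  # constant-intensity control: no noise, no gating, peak = baseline
  flat <- bolus_profile(peak = 30, baseline = 30, gate_depth = 0)
  s <- render_sequence(geom, grid, flat, m0, n_frames = 4, seed = 1)
  expect_equal(max(abs(sweep(s$frames, c(1, 2), s$frames[, , 1L]))), 0)

  # lumen ROI mean tracks the analytic bolus curve
  sb <- render_sequence(geom, grid, prof, m0, n_frames = 40, seed = 1)
  maps <- rasterize_structure(geom, grid)
  roi <- roi_mask(maps$lumen > 0.9, "lumen")
  trace <- roi_intensity_trace(sb, roi)
  expect_gt(cor(trace, bolus_intensity(sb$frame_times, prof)), 0.99)

  # determinism: same seed bit-identical; different seed, same clean part
  m <- imaging_model("twist_mri")
  s1 <- render_sequence(geom, grid, prof, m, n_frames = 3, seed = 11)
  s2 <- render_sequence(geom, grid, prof, m, n_frames = 3, seed = 11)
  expect_identical(s1$frames, s2$frames)
  c1 <- render_sequence(geom, grid, prof, m0, n_frames = 3, seed = 11)
  c2 <- render_sequence(geom, grid, prof, m0, n_frames = 3, seed = 12)
  expect_identical(c1$frames, c2$frames)
  expect_false(identical(
    render_sequence(geom, grid, prof, m, n_frames = 3, seed = 12)$frames,
    s1$frames))
})

test_that("noise level controls background variance monotonically", {
  geom <- phantom_geometry("straight_tube", inner_diameter = 4)
  grid <- twist_grid(64)
  prof <- bolus_profile()
  bgvar <- sapply(c(1, 3, 6), function(sig) {
    m <- imaging_model("twist_mri", noise_sigma = sig)
    s <- render_sequence(geom, grid, prof, m, n_frames = 2, seed = 4)
    var(as.vector(s$frames[1:15, , 1L]))  # rows far from the tube
  })
  expect_true(all(diff(bgvar) > 0))
})

test_that("known deformations move content by the stated displacement", {
  grid <- twist_grid()
  f1 <- tube_frame()
  seq2 <- two_frame_sequence(f1, grid)
  idt <- identity_transform(grid, 8 * 1.3)

  # identity warp reproduces the frame
  w <- apply_known_deformation(seq2, list(idt, idt))
  rng <- diff(range(f1))
  expect_lt(max(abs(w$frames[, , 2L] - f1)) / rng, 1e-9)

  # 2 px translation moves the lumen centroid by 2 px
  tr <- identity_transform(grid, 8 * 1.3)
  tr$coef_y[] <- 2 * 1.3
  w2 <- apply_known_deformation(seq2, list(idt, tr))
  centroid_row <- function(fr) {
    m <- fr > (max(fr) + min(fr)) / 2
    mean(which(m, arr.ind = TRUE)[, 1L])
  }
  shift <- centroid_row(w2$frames[, , 2L]) - centroid_row(w2$frames[, , 1L])
  expect_lt(abs(shift - 2), 0.05)

  # provenance records the true transforms
  expect_identical(w2$provenance$true_transforms[[2L]]$coef_y, tr$coef_y)

  expect_error(apply_known_deformation(seq2, list(idt)), "one transform")
})
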