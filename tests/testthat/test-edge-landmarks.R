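test_that("Sobel magnitude matches the hand-applied kernel", {
  expect_identical(sobel_edges(matrix(5, 10, 12)), matrix(0, 10, 12))

  # vertical step of height h: magnitude 4h on the two adjacent columns
  h <- 2.5
  f <- matrix(0, 12, 12); f[, 7:12] <- h
  mag <- sobel_edges(f)
  expect_equal(mag[2:11, 6], rep(4 * h, 10))
  expect_equal(mag[2:11, 7], rep(4 * h, 10))
  expect_equal(mag[2:11, c(2:5, 8:11)], matrix(0, 10, 8))

  # kernel-pair symmetry: transpose commutes
  set.seed(9)
  r <- matrix(rnorm(90), 9, 10)
  expect_equal(sobel_edges(t(r)), t(sobel_edges(r)))

  expect_error(sobel_edges(array(0, c(3, 3, 3))), "matrix")
  expect_error(sobel_edges(matrix(c(1, NA, 1, 1), 2)), "finite")
})

test_that("landmark sampling is thresholded, seeded and exhaustive", {
  seq0 <- tube_sequence()
  grid <- seq0$grid
  edge <- sobel_edges(seq0$frames[, , 1L])
  roi <- auto_roi(seq0)

  lm <- sample_landmarks(edge, roi, grid, n = 150, seed = 3)
  expect_equal(nrow(lm$points), 150)
  # every landmark clears the recorded threshold (top quantile of the ROI)
  thr <- quantile(edge[roi$mask], 0.80, names = FALSE)
  idx <- cbind(lm$points$y_px + 1L, lm$points$x_px + 1L)
  expect_true(all(edge[idx] >= thr))
  expect_true(all(roi$mask[idx]))
  expect_match(lm$edge_threshold_rule, "q0.80")

  # determinism
  lm2 <- sample_landmarks(edge, roi, grid, n = 150, seed = 3)
  expect_identical(lm$points, lm2$points)
  lm3 <- sample_landmarks(edge, roi, grid, n = 150, seed = 4)
  expect_false(identical(lm$points, lm3$points))

  # exhaustion: a ring whose eligible set has exactly n pixels
  ring <- matrix(0, 20, 20)
  ring[5, 5:15] <- 1; ring[15, 5:15] <- 1
  ring[5:15, 5] <- 1; ring[5:15, 15] <- 1
  rg <- grid_spec(c(20, 20), 1)
  rroi <- roi_box(rg, 1:20, 1:20)
  em <- sobel_edges(ring)
  n_eligible <- sum(em >= quantile(em, 0.8))
  out <- sample_landmarks(em, rroi, rg, n = n_eligible, seed = 1)
  eligible_px <- which(em >= quantile(em, 0.8), arr.ind = TRUE)
  expect_setequal(paste(out$points$y_px + 1L, out$points$x_px + 1L),
                  paste(eligible_px[, 1L], eligible_px[, 2L]))

  expect_error(sample_landmarks(em, rroi, rg, n = n_eligible + 1, seed = 1),
               "eligible")
})

test_that("landmarks localize the true interfaces on noise-free frames", {
  seq0 <- tube_sequence()
  lm <- tube_landmarks()
  geom <- seq0$provenance$geometry
  d <- structure_signed_distance(geom, lm$points$x_mm, lm$points$y_mm)
  dist_to_interface <- pmin(abs(d), abs(d - geom$wall_thickness))
  expect_gte(mean(dist_to_interface <= seq0$grid$spacing[1L]), 0.9)
})

test_that("automatic ROI boxes the structure support", {
  seq0 <- tube_sequence()
  geom <- seq0$provenance$geometry
  maps <- rasterize_structure(geom, seq0$grid)
  support <- maps$lumen + maps$wall > 0
  tight <- auto_roi(seq0, dilation_mm = 0)
  expect_identical(range(which(rowSums(tight$mask) > 0)),
                   range(which(rowSums(support) > 0)))

  roi2 <- auto_roi(seq0, dilation_mm = 2.6)  # 2 px at 1.3 mm
  h_tight <- sum(rowSums(tight$mask) > 0)
  h_dil <- sum(rowSums(roi2$mask) > 0)
  expect_equal(h_dil, h_tight + 4)
  expect_equal(roi2$source, "auto_from_provenance")

  # disjoint aneurysm lobes end up in one connected box
  seq_two <- render_sequence(
    phantom_geometry("two_sided_aneurysm", inner_diameter = 4),
    twist_grid(), bolus_profile(), imaging_model("twist_mri", noise_sigma = 0),
    n_frames = 2, seed = 1)
  roi_two <- auto_roi(seq_two)
  rows_on <- which(rowSums(roi_two$mask) > 0)
  expect_identical(rows_on, seq(min(rows_on), max(rows_on)))

  ext <- image_sequence(array(0:1, c(4, 4, 2)), grid_spec(c(4, 4), 1), 0:1)
  expect_error(auto_roi(ext), "manual ROI")
})
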