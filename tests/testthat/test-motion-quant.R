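test_that("landmark propagation follows the transform exactly", {
  grid <- twist_grid()
  lm <- tube_landmarks()
  pts <- phantomflow:::landmark_coords(lm)

  idt <- identity_transform(grid, 8 * 1.3)
  expect_equal(propagate_landmarks(lm, idt), pts, ignore_attr = TRUE)

  # uniform coefficients: exact translation by partition of unity
  tr <- identity_transform(grid, 8 * 1.3)
  tr$coef_x[] <- 0.3; tr$coef_y[] <- 0.4
  moved <- propagate_landmarks(lm, tr)
  expect_lt(max(abs(moved - cbind(pts[, 1L] + 0.3, pts[, 2L] + 0.4))), 1e-12)

  # one-hot coefficient at a control point: analytic tensor weights
  oh <- identity_transform(grid, 8 * 1.3)
  oh$coef_x[8, 8] <- 1
  cp <- c(oh$grid_origin[1L] + 7 * oh$grid_spacing[1L],
          oh$grid_origin[2L] + 7 * oh$grid_spacing[2L])
  got <- bspline_displace(oh, rbind(cp))
  # B3(0) central weight is 2/3 in each axis
  expect_equal(got[1L, 1L] - cp[1L], (2 / 3)^2, tolerance = 1e-12)
  expect_equal(got[1L, 2L] - cp[2L], 0)
})

test_that("displacement traces convert and aggregate correctly", {
  grid <- twist_grid()
  lm <- tube_landmarks()
  idt <- identity_transform(grid, 8 * 1.3)
  tr <- identity_transform(grid, 8 * 1.3)
  tr$coef_x[] <- 0.3; tr$coef_y[] <- 0.4

  # all-identity: zero trace
  tz <- displacement_trace(lm, list(idt, idt, idt), grid)
  expect_identical(max(tz$per_landmark), 0)

  # 3-4-5: uniform (0.3, 0.4) mm displacement is 0.5 mm everywhere
  td <- displacement_trace(lm, list(idt, tr, tr), grid,
                           frame_times = c(0, 1, 2))
  expect_equal(max(abs(td$per_landmark[, 2:3] - 0.5)), 0, tolerance = 1e-12)
  expect_identical(td$per_landmark[, 1L], rep(0, 150))

  # px column is the mm column over the in-plane spacing (TWIST 1.3 mm)
  expect_equal(td$per_landmark_px, td$per_landmark / 1.3)
  expect_equal(td$per_landmark_px[1L, 2L], 0.5 / 1.3, tolerance = 1e-12)
  expect_true(all(td$per_landmark >= 0))

  # tidy output contract
  df <- as.data.frame(td)
  expect_named(df, c("landmark_id", "roi_label", "frame", "time_s",
                     "disp_mm", "disp_px"))
  expect_equal(nrow(df), 150 * 3)

  expect_error(displacement_trace(lm, list(tr, tr), grid), "identity")
})

test_that("aggregates are invariant to landmark order", {
  grid <- twist_grid()
  lm <- tube_landmarks()
  idt <- identity_transform(grid, 8 * 1.3)
  tr <- identity_transform(grid, 8 * 1.3)
  set.seed(15)
  tr$coef_x[] <- rnorm(length(tr$coef_x), 0, 0.3)
  t1 <- displacement_trace(lm, list(idt, tr), grid)
  lm2 <- lm
  perm <- sample(nrow(lm$points))
  lm2$points <- lm$points[perm, ]
  t2 <- displacement_trace(lm2, list(idt, tr), grid)
  expect_equal(colMeans(t2$per_landmark), colMeans(t1$per_landmark))
  expect_equal(t2$per_landmark[, 2L], t1$per_landmark[perm, 2L])
})
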