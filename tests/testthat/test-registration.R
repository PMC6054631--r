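test_that("mutual information matches the brute-force histogram oracle", {
  grid <- grid_spec(c(64, 64), 1)
  for (sd_ in 1:5) {
    set.seed(sd_)
    f <- matrix(runif(64 * 64), 64)
    m <- 0.5 * f + matrix(runif(64 * 64, 0, 0.5), 64)
    set.seed(100 + sd_)
    pts <- cbind(runif(3000, -31, 31), runif(3000, -31, 31))
    got <- mutual_information(f, m, grid, bins = 32, sample_points = pts)
    expect_equal(attr(got, "mi"), oracle_mi(f, m, grid, pts, 32),
                 tolerance = 1e-10)
    expect_equal(as.numeric(got), -attr(got, "mi"))
  }
})

test_that("self-MI equals the marginal entropy and relabeling is invariant", {
  grid <- twist_grid()
  f <- tube_frame()
  res <- mutual_information(f, f, grid, bins = 32)
  expect_equal(attr(res, "mi"), attr(res, "h_fixed"), tolerance = 1e-10)

  # strictly monotone per-bin relabeling leaves MI unchanged
  set.seed(5)
  f2 <- matrix(sample(0:31, 64 * 64, replace = TRUE), 64)
  m2 <- matrix(sample(0:31, 64 * 64, replace = TRUE), 64)
  g2 <- grid_spec(c(64, 64), 1)
  ax <- g2$origin[1] + 0:63
  pts <- cbind(rep(ax, each = 64), rep(ax, times = 64))
  # integer-valued images: a monotone remapping that keeps every label in
  # its own histogram bin leaves MI unchanged (affine at 32 bins; the
  # nonlinear square map needs finer bins so no two labels share a bin)
  a <- mutual_information(f2, m2, g2, bins = 32, sample_points = pts)
  b <- mutual_information(f2 * 2 + 7, m2, g2, bins = 32, sample_points = pts)
  expect_equal(attr(a, "mi"), attr(b, "mi"), tolerance = 1e-10)
  a2 <- mutual_information(f2, m2, g2, bins = 1024, sample_points = pts)
  b2 <- mutual_information((f2 + 1)^2, m2, g2, bins = 1024,
                           sample_points = pts)
  expect_equal(attr(a2, "mi"), attr(b2, "mi"), tolerance = 1e-10)

  # degenerate intensity range is defined as zero
  g8 <- grid_spec(c(8, 8), 1)
  expect_identical(as.numeric(mutual_information(matrix(3, 8, 8),
                                                 matrix(0:63 / 63, 8), g8)),
                   0)
})

test_that("independent noise images share almost no information", {
  grid <- grid_spec(c(64, 64), 1)
  set.seed(21)
  f <- matrix(runif(64 * 64), 64)
  m <- matrix(runif(64 * 64), 64)
  pts <- cbind(runif(40000, -31, 31), runif(40000, -31, 31))
  res <- mutual_information(f, m, grid, bins = 32, sample_points = pts)
  expect_lte(attr(res, "mi"), 0.05)
})

test_that("Parzen MI gradient matches finite differences", {
  grid <- twist_grid(48)
  set.seed(6)
  f <- gaussian_blur(matrix(runif(48 * 48), 48), 1)
  m <- gaussian_blur(matrix(runif(48 * 48), 48), 1)
  tr <- identity_transform(grid, 8 * 1.3)
  set.seed(7)
  tr$coef_x[] <- rnorm(length(tr$coef_x), 0, 0.1)
  tr$coef_y[] <- rnorm(length(tr$coef_y), 0, 0.1)
  pts <- phantomflow:::eval_points(grid)
  res <- phantomflow:::cpp_mi_parzen_grad(f, m, grid$origin, grid$spacing,
                                          pts, 32L, tr$coef_x, tr$coef_y,
                                          tr$grid_origin, tr$grid_spacing)
  h <- 1e-5
  set.seed(8)
  for (i in sample(length(tr$coef_x), 5)) {
    tp <- tr; tp$coef_x[i] <- tp$coef_x[i] + h
    tm <- tr; tm$coef_x[i] <- tm$coef_x[i] - h
    fd <- (phantomflow:::cpp_mi_parzen(f, m, grid$origin, grid$spacing, pts,
                                       32L, tp$coef_x, tp$coef_y,
                                       tp$grid_origin, tp$grid_spacing) -
           phantomflow:::cpp_mi_parzen(f, m, grid$origin, grid$spacing, pts,
                                       32L, tm$coef_x, tm$coef_y,
                                       tm$grid_origin, tm$grid_spacing)) / (2 * h)
    expect_equal(res$grad_x[i], fd, tolerance = 1e-5)
  }
})

test_that("registration never scores below the identity transform", {
  grid <- twist_grid()
  seqn <- render_sequence(phantom_geometry("one_sided_aneurysm",
                                           inner_diameter = 4),
                          grid, bolus_profile(), imaging_model("twist_mri"),
                          n_frames = 20, seed = 2)
  for (fr in c(5, 16, 20)) {
    reg <- register_pair(seqn$frames[, , 1L], seqn$frames[, , fr], grid,
                         registration_config(seed = 9), seed_offset = fr)
    md <- attr(reg, "metadata")
    expect_gte(md$mi_final, md$mi_identity)
    expect_true(md$converged)
  }
})

test_that("self-registration stays at the identity, pyramid or not", {
  grid <- twist_grid()
  f <- tube_frame()
  pts <- phantomflow:::landmark_coords(tube_landmarks())
  for (levels in c(3L, 1L)) {
    reg <- register_pair(f, f, grid,
                         registration_config(seed = 10,
                                             pyramid_levels = levels))
    moved <- bspline_displace(reg, pts)
    expect_lt(max(abs(moved - pts)) / 1.3, 0.05)
  }
})

test_that("sub-pixel translations are recovered", {
  grid <- twist_grid()
  f <- tube_frame()
  idt <- identity_transform(grid, 8 * 1.3)
  tr <- identity_transform(grid, 8 * 1.3)
  tr$coef_y[] <- 0.5 * 1.3
  seqw <- apply_known_deformation(two_frame_sequence(f, grid), list(idt, tr))
  reg <- register_pair(f, seqw$frames[, , 2L], grid,
                       registration_config(seed = 11))
  pts <- phantomflow:::landmark_coords(tube_landmarks())
  rec <- bspline_displace(reg, pts) - pts
  expect_lt(abs(mean(sqrt(rowSums(rec^2))) / 1.3 - 0.5), 0.1)
})

test_that("register_sequence returns one transform per frame, identity first", {
  grid <- twist_grid(64)
  s <- render_sequence(phantom_geometry("straight_tube", inner_diameter = 4),
                       grid, bolus_profile(peak = 30, gate_depth = 0),
                       imaging_model("twist_mri", noise_sigma = 3.6),
                       n_frames = 3, seed = 13)
  trs <- register_sequence(s, registration_config(seed = 14))
  expect_length(trs, 3L)
  expect_true(phantomflow:::is_identity(trs[[1L]]))
  expect_length(attr(trs, "metadata"), 3L)
})
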