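test_that("cubic B-spline basis satisfies partition of unity", {
  grid <- twist_grid()
  tr <- identity_transform(grid, 8 * 1.3)
  set.seed(1)
  pts <- cbind(runif(1000, -55, 55), runif(1000, -55, 55))

  # identity: zero coefficients map points to themselves exactly
  expect_identical(bspline_displace(tr, pts), pts)

  # uniform coefficients translate exactly (sum of basis weights = 1)
  tr$coef_x[] <- 0.3; tr$coef_y[] <- -0.4
  moved <- bspline_displace(tr, pts)
  expect_lt(max(abs(moved - cbind(pts[, 1L] + 0.3, pts[, 2L] - 0.4))), 1e-12)
})

test_that("support-window evaluation equals the dense-basis oracle", {
  grid <- grid_spec(c(32, 32), 1)
  tr <- identity_transform(grid, 6)
  # one-hot coefficient
  tr$coef_x[5, 4] <- 1.7
  tr$coef_y[3, 6] <- -0.9
  set.seed(2)
  pts <- cbind(runif(50, -14, 14), runif(50, -14, 14))
  expect_equal(bspline_displace(tr, pts), dense_bspline_displace(tr, pts),
               tolerance = 1e-12)

  # general random coefficients
  set.seed(3)
  tr$coef_x[] <- rnorm(length(tr$coef_x), 0, 0.5)
  tr$coef_y[] <- rnorm(length(tr$coef_y), 0, 0.5)
  expect_equal(bspline_displace(tr, pts), dense_bspline_displace(tr, pts),
               tolerance = 1e-12)
})

test_that("points outside the support raise an indexed error", {
  tr <- identity_transform(grid_spec(c(32, 32), 1), 6)
  expect_error(bspline_displace(tr, rbind(c(0, 0), c(500, 0))), "point 2")
})

test_that("transforms serialize to JSON and back", {
  tr <- identity_transform(grid_spec(c(32, 32), 1), 6)
  set.seed(4)
  tr$coef_x[] <- rnorm(length(tr$coef_x))
  path <- withr::local_tempfile(fileext = ".json")
  write_transforms(list(tr, tr), path, metadata = list(note = "check"))
  back <- read_transforms(path)
  expect_length(back$transforms, 2L)
  expect_equal(back$transforms[[1L]]$coef_x, tr$coef_x)
  expect_equal(back$transforms[[1L]]$grid_origin, tr$grid_origin)
  expect_equal(back$metadata$note, "check")
})
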