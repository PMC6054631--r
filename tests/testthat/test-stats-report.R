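# build a displacement_trace directly from a matrix of mm displacements
make_trace <- function(m, spacing = 1.3, meta = list()) {
  structure(list(per_landmark = m, per_landmark_px = m / spacing,
                 frame_times = (seq_len(ncol(m)) - 1) * 0.5,
                 roi_label = rep("fixture", nrow(m)), spacing = spacing,
                 meta = meta),
            class = "displacement_trace")
}

test_that("analysis windows validate and derive from the bolus profile", {
  expect_error(analysis_windows(integer(), 5:8), "non-empty")
  expect_error(analysis_windows(2:5, 4:8), "disjoint")
  expect_error(analysis_windows(1:4, 5:8), "reference frame")

  p <- bolus_profile()
  times <- (0:59) * 0.5
  w <- derive_windows(p, times)
  expect_length(intersect(w$bolus_frames, w$after_frames), 0)
  g <- phantomflow:::gamma_variate(times - p$t_arrival, p$alpha, p$beta)
  expect_true(all(g[w$bolus_frames] >= 0.25))
  expect_true(all(g[w$after_frames] < 0.25))
  expect_true(all(times[w$after_frames] >=
                    p$t_arrival + p$alpha * p$beta + 3 * p$beta))
})

test_that("ROI intensity traces are plain means", {
  g <- grid_spec(c(8, 8), 1)
  fr <- array(0, c(8, 8, 3))
  fr[, , 1] <- 2; fr[, , 2] <- 5; fr[, , 3] <- -1
  s <- image_sequence(fr, g, 0:2)
  roi <- roi_box(g, 2:5, 3:6)
  expect_equal(roi_intensity_trace(s, roi), c(2, 5, -1))

  # single-pixel ROI equals that pixel's series
  one <- roi_box(g, 4, 4)
  fr[4, 4, ] <- c(7, 8, 9)
  s2 <- image_sequence(fr, g, 0:2)
  expect_equal(roi_intensity_trace(s2, one), c(7, 8, 9))

  expect_error(roi_intensity_trace(s, roi_box(grid_spec(c(4, 4), 1), 1:2, 1:2)),
               "shape")
})

test_that("paired window comparison matches the closed-form t", {
  # identical windows: t = 0, p = 1
  m <- matrix(rep(c(0, 1, 2, 1, 2), each = 5), nrow = 5)
  tr <- make_trace(m)
  w <- analysis_windows(2:3, 4:5)
  nul <- window_compare(tr, w)
  expect_identical(nul$statistic, 0)
  expect_identical(nul$p, 1)

  # textbook oracle: t = mean(d) / (sd(d) / sqrt(n))
  b <- c(2, 1, 3, 2, 2); a <- c(1, 0, 1, 1, 1)
  m2 <- cbind(0, b, a)
  tr2 <- make_trace(m2)
  res <- window_compare(tr2, analysis_windows(2, 3))
  d <- b - a
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-10)
  expect_equal(res$dof, 4)

  # zero-variance differences are guarded, not an error
  tr3 <- make_trace(cbind(0, a + 1, a))
  res3 <- window_compare(tr3, analysis_windows(2, 3))
  expect_identical(res3$statistic, Inf)
  expect_identical(res3$p, 0)

  # landmark_mean dof contract: n landmarks - 1
  set.seed(16)
  big <- make_trace(cbind(0, matrix(runif(150 * 4), 150)))
  r150 <- window_compare(big, analysis_windows(2:3, 4:5))
  expect_equal(r150$dof, 149)
  expect_equal(r150$n_units, 150)

  # landmark_frame pools and truncates to the common window length
  rlf <- window_compare(big, analysis_windows(2:3, 4:5),
                        unit = "landmark_frame")
  expect_equal(rlf$n_units, 300)
  runeq <- window_compare(big, analysis_windows(2:4, 5),
                          unit = "landmark_frame")
  expect_equal(runeq$n_units, 150)
  expect_match(runeq$note, "truncated")
})

test_that("two-sample comparison matches the Welch oracle", {
  set.seed(17)
  A <- make_trace(cbind(0, matrix(rnorm(60, 1.0, 0.2), 20)))
  B <- make_trace(cbind(0, matrix(rnorm(60, 0.6, 0.3), 20)))
  res <- compare_structures(A, B, window = 2:4)
  x <- rowMeans(A$per_landmark[, 2:4]); y <- rowMeans(B$per_landmark[, 2:4])
  sx <- var(x) / 20; sy <- var(y) / 20
  t_oracle <- (mean(x) - mean(y)) / sqrt(sx + sy)
  dof_oracle <- (sx + sy)^2 / (sx^2 / 19 + sy^2 / 19)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$dof, dof_oracle, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), dof_oracle), tolerance = 1e-10)

  # antisymmetry and the self-comparison null
  swap <- compare_structures(B, A, window = 2:4)
  expect_equal(swap$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(swap$p, res$p, tolerance = 1e-12)
  self <- compare_structures(A, A, window = 2:4)
  expect_equal(self$statistic, 0)

  # pooled variant matches t.test's var.equal oracle
  pooled <- compare_structures(A, B, window = 2:4, kind = "two_sample_pooled")
  sp <- sqrt(((19) * var(x) + (19) * var(y)) / 38)
  t_pool <- (mean(x) - mean(y)) / (sp * sqrt(2 / 20))
  expect_equal(pooled$statistic, t_pool, tolerance = 1e-10)
  expect_equal(pooled$dof, 38)
})

test_that("intensity-deformation correlation behaves at the extremes", {
  set.seed(18)
  intens <- cumsum(rnorm(40))
  disp <- c(0, abs(diff(intens))) * 0.37
  expect_equal(correlate_intensity_deformation(intens, disp), 1,
               tolerance = 1e-12)

  # independent noise: |r| small across seeded replicates (null check)
  rs <- sapply(1:40, function(s) {
    set.seed(1000 + s)
    correlate_intensity_deformation(rnorm(50), abs(rnorm(50)))
  })
  expect_lt(quantile(abs(rs), 0.95), 0.35)
  expect_lt(median(abs(rs)), 0.2)

  # joint shift leaves r unchanged; zero variance is flagged
  expect_equal(correlate_intensity_deformation(intens[1:30], disp[1:30]),
               correlate_intensity_deformation(intens[1:30] + 5,
                                               disp[1:30]),
               tolerance = 1e-12)
  expect_warning(r0 <- correlate_intensity_deformation(rep(1, 10), 1:10),
                 "zero-variance")
  expect_true(is.na(r0))
})

test_that("summary table aggregates per-cell window statistics", {
  w <- analysis_windows(2:3, 4:5)
  z <- make_trace(matrix(0, 4, 5), meta = list(modality = "twist_mri",
                                               size_mm = 4,
                                               structure = "straight_tube"))
  s <- build_summary(list(z), w)
  expect_equal(s$mean_bolus, 0)
  expect_equal(s$std_after, 0)

  one <- make_trace(matrix(c(0, rep(0.7, 4)), 1, 5, byrow = TRUE),
                    meta = list(modality = "cta", size_mm = 2,
                                structure = "helix"))
  # single landmark, constant displacement d: mean d, sd NA -> 0-width cell
  s1 <- build_summary(list(one), w)
  expect_equal(s1$mean_bolus, 0.7)

  # printed 3-landmark fixture, hand-computed
  m <- rbind(c(0, 0.2, 0.4, 0.1, 0.1),
             c(0, 0.6, 0.8, 0.2, 0.4),
             c(0, 0.3, 0.5, 0.0, 0.2))
  tr <- make_trace(m, meta = list(modality = "ra3d", size_mm = 3,
                                  structure = "bifurcation"))
  s3 <- build_summary(list(tr), w)
  bm <- rowMeans(m[, 2:3]); am <- rowMeans(m[, 4:5])
  expect_equal(s3$mean_bolus, mean(bm), tolerance = 1e-12)
  expect_equal(s3$std_bolus, sd(bm), tolerance = 1e-12)
  expect_equal(s3$mean_after, mean(am), tolerance = 1e-12)
  expect_equal(s3$std_after, sd(am), tolerance = 1e-12)
  expect_equal(s3$modality, "ra3d")
})
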