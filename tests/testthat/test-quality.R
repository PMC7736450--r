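test_that("quality ratio reproduces the printed worked examples", {
  expect_equal(round(quality_ratio(1, 3), 2), 0.48)
  expect_equal(round(quality_ratio(50, 100), 2), 0.30)
  expect_equal(quality_ratio(c(7, 42, 180), c(7, 42, 180)),
               c(0, 0, 0))
  expect_equal(quality_ratio(100, 50), -log10(2))
})

test_that("quality ratio is antisymmetric and floored", {
  d1 <- runif(50, 0, 250); d2 <- runif(50, 0, 250)
  expect_equal(quality_ratio(d1, d2), -quality_ratio(d2, d1))
  expect_true(all(is.finite(quality_ratio(c(0, 0), c(0, 100)))))
  expect_equal(quality_ratio(0, 1, floor_gy = 0.01), log10(1 / 0.01))
  expect_error(quality_ratio(-1, 5), "non-negative")
})

test_that("weight function hits its breakpoints exactly and is continuous", {
  ws <- weight_spec()
  expect_equal(weight_single(c(10, 40, 120, 200), ws), c(0, 1, 1, 0))
  expect_equal(weight_single(c(5, 25, 80, 160, 250), ws),
               c(0, 0.5, 1, 0.5, 0))
  # continuity: no jump larger than the local slope allows
  d <- seq(0, 260, by = 0.01)
  w <- weight_single(d, ws)
  expect_true(all(abs(diff(w)) <= 0.01 / 30 + 1e-12))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("combined weights take the max and honour the straddle override", {
  expect_equal(combine_weights(80, 80), 1)
  expect_equal(combine_weights(5, 5), 0)
  expect_equal(combine_weights(30, 130), 1)   # straddle: < 40 vs > 120
  expect_equal(combine_weights(5, 250), 1)    # both single weights are 0
  expect_equal(combine_weights(25, 80), 1)    # plain max
  expect_equal(combine_weights(40, 120), 1)   # boundary: no override needed
  # strictly-at-threshold pairs do NOT trigger the override
  expect_equal(combine_weights(40, 121), 1)   # W(40) = 1 anyway
  expect_equal(combine_weights(39, 120), 1)   # W(120) = 1 anyway
  d1 <- runif(200, 0, 260); d2 <- runif(200, 0, 260)
  expect_equal(combine_weights(d1, d2), combine_weights(d2, d1))
})

test_that("quality maps evaluate Q and W over the VOI only", {
  g <- geom_iso(6)
  pred <- uniform_dose(50, g)
  post <- dose_grid(2 * pred$values, g)
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- TRUE
  voi <- voi_mask(m, g, "roi")
  qm <- quality_map(pred, post, voi)
  expect_equal(unique(qm$q[m]), log10(2))
  expect_equal(unique(qm$w[m]), 1)
  expect_true(all(is.na(qm$q[!m])))

  ident <- quality_map(pred, pred, voi)
  expect_equal(unique(ident$q[m]), 0)

  low <- quality_map(uniform_dose(5, g), uniform_dose(5, g), voi)
  expect_equal(unique(low$w[m]), 0)
})

test_that("quality_map rejects mismatched geometries with diagnostics", {
  g1 <- geom_iso(6); g2 <- geom_iso(6, spacing = 2)
  expect_error(quality_map(uniform_dose(50, g1), uniform_dose(50, g2),
                           full_mask(g1)),
               "geometries differ")
  expect_error(quality_map(uniform_dose(50, g1), uniform_dose(50, g1),
                           full_mask(g2)),
               "geometries differ")
})

test_that("QVH curve handles point distributions and zero weights", {
  g <- geom_iso(6)
  voi <- full_mask(g)
  qm <- quality_map(uniform_dose(80, g), uniform_dose(80, g), voi)
  curve <- compute_qvh(qm)
  expect_equal(curve$weighted_volume_fraction[1], 1)
  expect_true(all(curve$weighted_volume_fraction[-1] == 0))

  # half the weighted volume at Q = +0.2, half at -0.2
  vals <- array(80, c(6, 6, 6))
  vals[1:3, , ] <- 80 * 10^0.2
  vals[4:6, , ] <- 80 * 10^-0.2
  qm2 <- quality_map(uniform_dose(80, g), dose_grid(vals, g), voi)
  c2 <- compute_qvh(qm2, bin_width = 0.01)
  f <- c2$weighted_volume_fraction
  e <- c2$q_bin_edges
  expect_true(all(f[e < 0.2 - 1e-9] == 1))
  expect_true(all(f[e > 0.2 + 1e-9] == 0))
  # signed histogram symmetric about zero
  expect_equal(sum(c2$signed_density[c2$signed_breaks[-1] <= 0]), 0.5)

  # weight-zero voxels contribute nothing
  qm3 <- quality_map(uniform_dose(5, g), uniform_dose(2, g), voi)
  expect_warning(c3 <- compute_qvh(qm3), "undefined")
  expect_true(c3$undefined)
})

test_that("quality factor matches hand evaluations", {
  g <- geom_iso(6)
  voi <- full_mask(g)
  ident <- quality_factor(quality_map(uniform_dose(90, g),
                                      uniform_dose(90, g), voi))
  expect_equal(ident$qf, 0)
  expect_equal(ident$category, "good")

  # post = pred / 2 with pred in the full-weight band -> QF = log10 2
  set.seed(1)
  pv <- array(runif(216, 80, 120), c(6, 6, 6))
  halved <- quality_factor(quality_map(dose_grid(pv, g),
                                       dose_grid(pv / 2, g), voi))
  expect_equal(halved$qf, log10(2), tolerance = 1e-12)
  expect_equal(halved$category, "poor")

  # mixed map: half volume Q = 0.4 W = 1, half Q = 0.1 W = 0.5
  pred <- array(0, c(6, 6, 6)); post <- array(0, c(6, 6, 6))
  pred[1:3, , ] <- 80;  post[1:3, , ] <- 80 * 10^0.4    # W(80) = 1
  pred[4:6, , ] <- 160; post[4:6, , ] <- 160 * 10^0.1   # W = max(0.5, 0)
  mixed <- quality_factor(quality_map(dose_grid(pred, g),
                                      dose_grid(post, g), voi))
  expect_equal(mixed$qf, (0.4 * 1 + 0.1 * 0.5) / 1.5, tolerance = 1e-9)

  # all-zero weights -> undefined QF
  suppressWarnings(
    und <- quality_factor(quality_map(uniform_dose(5, g),
                                      uniform_dose(5, g), voi)))
  expect_true(is.nan(und$qf))
  expect_equal(und$category, "undefined")
})

test_that("adding perfectly concordant full-weight voxels never raises QF", {
  g <- geom_iso(6)
  set.seed(7)
  pv <- array(runif(216, 20, 220), c(6, 6, 6))
  tv <- pv * array(runif(216, 0.5, 2), c(6, 6, 6))
  m <- array(FALSE, c(6, 6, 6)); m[1:3, , ] <- TRUE
  base <- quality_factor(quality_map(dose_grid(pv, g), dose_grid(tv, g),
                                     voi_mask(m, g)))$qf
  # extend the VOI with voxels where both doses are identical and in-band
  pv2 <- pv; tv2 <- tv
  pv2[4:6, , ] <- 80; tv2[4:6, , ] <- 80
  grown <- quality_factor(quality_map(dose_grid(pv2, g), dose_grid(tv2, g),
                                      full_mask(g)))$qf
  expect_lte(grown, base + 1e-12)
})

test_that("QF classification uses the half-open interval convention", {
  expect_equal(classify_qf(c(0.05, 0.24, 0.32)),
               c("good", "acceptable", "poor"))
  expect_equal(classify_qf(0.18), "acceptable")
  expect_equal(classify_qf(0.30), "poor")
  expect_equal(classify_qf(0), "good")
  expect_error(classify_qf(-0.1), "non-negative")
})

test_that("the 0.3 cut-off corresponds to a 50% systematic reduction", {
  expect_equal(1 - 10^(-0.3), 0.5, tolerance = 0.003)
  g <- geom_iso(5)
  set.seed(2)
  pv <- array(runif(125, 80, 120), c(5, 5, 5))
  qf <- quality_factor(quality_map(dose_grid(pv, g),
                                   dose_grid(pv * 0.5, g),
                                   full_mask(g)))$qf
  expect_equal(qf, 0.30103, tolerance = 1e-4)
  expect_equal(classify_qf(qf), "poor")
  # and the systematic reduction that sits exactly on the 0.3 boundary
  expect_equal(1 - 10^(-0.3), 0.4988, tolerance = 1e-4)
})

test_that("Q-map export writes signed Q and weights, NA outside the VOI", {
  g <- geom_iso(6)
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- TRUE
  qm <- quality_map(uniform_dose(60, g), uniform_dose(90, g),
                    voi_mask(m, g, "roi"))
  qp <- tempfile(fileext = ".nii.gz")
  paths <- q_map_export(qm, qp)
  qv <- RNifti::readNifti(paths["q"])
  expect_equal(as.vector(qv[m]), rep(log10(90 / 60), sum(m)),
               tolerance = 1e-6)
  expect_true(all(!is.finite(qv[!m])))
  wv <- RNifti::readNifti(paths["w"])
  expect_equal(as.vector(wv[m]), rep(1, sum(m)), tolerance = 1e-6)
  unlink(paths)
})
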