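test_that("voxelized sphere volumes approach the analytic value", {
  g <- grid_geometry(c(60, 60, 60), c(2, 2, 2), origin = -c(59, 59, 59))
  ph <- generate_phantom(phantom_spec(
    geometry = g, liver_semiaxes_mm = c(55, 55, 55),
    lesions = list(list(centre_mm = c(0, 0, 0), radius_mm = 15,
                        mean_dose_gy = 60)),
    ntl_mean_dose_gy = 30, noise_sigma = 0, seed = 1))
  analytic_ml <- 4 / 3 * pi * 15^3 / 1000
  expect_lt(abs(voi_volume_ml(ph$lesions$lesions[[1]]) - analytic_ml) /
              analytic_ml, 0.05)
})

test_that("the generator is bit-identical for a fixed seed", {
  a <- small_phantom(seed = 123)
  b <- small_phantom(seed = 123)
  expect_identical(a$dose$values, b$dose$values)
  expect_identical(a$liver$values, b$liver$values)
  c_ <- small_phantom(seed = 124)
  expect_false(identical(a$dose$values, c_$dose$values))
})

test_that("region mean doses hit their targets and zero noise is uniform", {
  ph <- small_phantom(noise_sigma = 0.3, lesion_dose = 60, ntl_dose = 30)
  tl <- ph$vois$TL$values; ntl <- ph$vois$NTL$values
  expect_lt(abs(mean(ph$dose$values[tl]) - 60) / 60, 0.02)
  expect_lt(abs(mean(ph$dose$values[ntl]) - 30) / 30, 0.02)
  expect_true(all(ph$dose$values[!ph$liver$values] == 0))

  flat <- small_phantom(noise_sigma = 0, lesion_dose = 60, ntl_dose = 30)
  expect_equal(unique(flat$dose$values[flat$vois$TL$values]), 60)
  idx <- dvh_indices(flat$dose, flat$vois$TL)
  expect_equal(unname(unclass(idx)), rep(60, 5))
})

test_that("lesions escaping the liver are rejected", {
  g <- grid_geometry(c(24, 24, 24), c(4, 4, 4), origin = -c(46, 46, 46))
  expect_error(generate_phantom(phantom_spec(
    geometry = g, liver_semiaxes_mm = c(30, 30, 30),
    lesions = list(list(centre_mm = c(28, 0, 0), radius_mm = 8,
                        mean_dose_gy = 60)),
    ntl_mean_dose_gy = 30, noise_sigma = 0, seed = 1)),
    "escapes")
})

test_that("mismatch modes behave as specified and compose in order", {
  ph <- small_phantom(noise_sigma = 0.1)
  d <- ph$dose
  expect_identical(apply_mismatch(d, mismatch_spec("none"))$values,
                   d$values)
  half <- apply_mismatch(d, mismatch_spec("global_scale", 0.5))
  expect_equal(half$values, d$values * 0.5, tolerance = 1e-12)

  les <- apply_mismatch(d, mismatch_spec("lesion_scale", 2), vois = ph$vois)
  tl <- ph$vois$TL$values
  expect_equal(les$values[tl], 2 * d$values[tl], tolerance = 1e-12)
  expect_equal(les$values[!tl], d$values[!tl], tolerance = 1e-12)

  hot <- apply_mismatch(d, mismatch_spec("hot_spot", 30,
                                         centre_mm = c(0, 0, 0),
                                         sigma_mm = 15))
  expect_true(all(hot$values >= d$values - 1e-12))
  # peak sits at the voxel centre nearest the blob centre
  expect_equal(max(hot$values - d$values), 30, tolerance = 0.05)

  # composition order: scale then hot spot differs from the reverse
  s1 <- apply_mismatch(d, list(mismatch_spec("global_scale", 0.5),
                               mismatch_spec("hot_spot", 30,
                                             centre_mm = c(0, 0, 0))))
  s2 <- apply_mismatch(d, list(mismatch_spec("hot_spot", 30,
                                             centre_mm = c(0, 0, 0)),
                               mismatch_spec("global_scale", 0.5)))
  expect_false(isTRUE(all.equal(s1$values, s2$values)))

  # cold spots clip at zero with a message
  expect_message(
    cold <- apply_mismatch(d, mismatch_spec("cold_spot", 500,
                                            centre_mm = c(0, 0, 0),
                                            sigma_mm = 30)),
    "clipped")
  expect_true(all(cold$values >= 0))
})

test_that("shift and blur act geometrically", {
  ph <- small_phantom(noise_sigma = 0)
  d <- ph$dose
  sh <- apply_mismatch(d, mismatch_spec("shift_mm", 4, axis = 1))
  # one full voxel: interior values equal the index-shifted original
  expect_equal(sh$values[2:32, , ], d$values[1:31, , ], tolerance = 1e-9)
  bl <- apply_mismatch(d, mismatch_spec("blur_mm", 6))
  expect_equal(sum(is.na(bl$values)), 0)
  expect_lt(max(bl$values), max(d$values) + 1e-9)  # blur never creates peaks
  expect_gt(stats::sd(d$values) + 1e-9, stats::sd(bl$values))
})

test_that("equal-and-opposite lesion scalings give a symmetric QVH", {
  # two identical lesions; post scales one up and the other down by the
  # same log-amplitude, all doses in the full-weight band
  g <- grid_geometry(c(40, 40, 24), c(4, 4, 4), origin = -c(78, 78, 46))
  ph <- generate_phantom(phantom_spec(
    geometry = g, liver_semiaxes_mm = c(72, 72, 40),
    lesions = list(list(centre_mm = c(-35, 0, 0), radius_mm = 12,
                        mean_dose_gy = 80),
                   list(centre_mm = c(35, 0, 0), radius_mm = 12,
                        mean_dose_gy = 80)),
    ntl_mean_dose_gy = 80, noise_sigma = 0, seed = 2))
  post_vals <- ph$dose$values
  m1 <- ph$lesions$lesions[[1]]$values
  m2 <- ph$lesions$lesions[[2]]$values
  post_vals[m1] <- post_vals[m1] * 10^0.1
  post_vals[m2] <- post_vals[m2] * 10^-0.1
  qm <- quality_map(ph$dose, dose_grid(post_vals, g), ph$vois$TL)
  curve <- compute_qvh(qm, bin_width = 0.01)
  dens <- curve$signed_density
  expect_equal(dens, rev(dens), tolerance = 1e-12)
})

test_that("generated DVFs are smooth, deterministic and fold-free", {
  g <- grid_geometry(c(20, 20, 20), c(4, 4, 4))
  a <- generate_dvf(g, amplitude_mm = 3, correlation_mm = 15, seed = 9)
  b <- generate_dvf(g, amplitude_mm = 3, correlation_mm = 15, seed = 9)
  expect_identical(a$vectors, b$vectors)
  expect_equal(max(abs(a$vectors)), 3, tolerance = 1e-9)

  zero <- generate_dvf(g, amplitude_mm = 0, correlation_mm = 15, seed = 1)
  jd <- jacobian_determinant(zero)
  expect_true(all(abs(jd$determinant - 1) < 1e-12))

  # amplitude above the folding bound is rejected with the bound reported
  expect_error(generate_dvf(g, amplitude_mm = 10, correlation_mm = 15),
               "folding bound")

  # property sweep: 100 seeds, all fold-free
  for (s in 1:100) {
    dvf <- generate_dvf(g, amplitude_mm = 5, correlation_mm = 15, seed = s)
    expect_true(jacobian_determinant(dvf)$fold_free)
  }
})

test_that("phantom plus scale mismatch recovers QF = |log10 s| end to end", {
  ph <- small_phantom(noise_sigma = 0.05)
  for (s in c(1.25, 1.5, 2)) {
    post <- apply_mismatch(ph$dose, mismatch_spec("global_scale", 1 / s))
    fit <- qvh(ph$dose, post, ph$liver)
    expect_equal(fit$qf$qf, log10(s), tolerance = 1e-6)
    # independent voxel-summation oracle
    m <- ph$liver$values
    expect_equal(fit$qf$qf,
                 qf_oracle(ph$dose$values[m], post$values[m]),
                 tolerance = 1e-12)
  }
})

test_that("identical phantom pair yields QF 0 and category good", {
  ph <- small_phantom()
  fit <- qvh(ph$dose, ph$dose, ph$liver)
  expect_equal(fit$qf$qf, 0)
  expect_equal(fit$qf$category, "good")
})
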