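test_that("the Y-90 energy constant follows from the physical constants and is linear", {
  delta <- y90_delta_constant(2.67, 0.93)
  # independent evaluation of the cumulated-decays x mean-energy product
  expect_equal(delta, 1e9 * (2.67 * 86400 / log(2)) * 0.93 * 1.602e-13)
  expect_equal(delta, 49.6, tolerance = 0.001)
  expect_equal(y90_delta_constant(2.67, 1.86), 2 * delta)
  expect_equal(y90_delta_constant(5.34, 0.93), 2 * delta)
  expect_equal(y90_delta_constant(2.67, 0), 0)
  expect_error(y90_delta_constant(0, 1), "> 0")

  # constants object recomputes and carries delta unless overridden
  expect_equal(physics_constants()$delta_Gy_kg_per_GBq, delta)
  expect_equal(physics_constants(delta_Gy_kg_per_GBq = 50)$delta_Gy_kg_per_GBq,
               50)
})

test_that("calibration splits administered activity over counts, net of lung shunt", {
  counts <- grid_of(array(7, c(10, 10, 10)), unit = "counts")
  act <- calibrate_activity(counts, 27.027027, lsf = 0)
  expect_equal(unname(act$values[1, 1, 1]), 1e-3, tolerance = 1e-9)
  expect_equal(sum(act$values), 1.0, tolerance = 1e-9)

  act10 <- calibrate_activity(counts, 27.027027, lsf = 0.10)
  expect_equal(sum(act10$values), 0.9, tolerance = 1e-8)

  set.seed(4)
  rnd <- grid_of(array(runif(1000), c(10, 10, 10)), unit = "counts")
  a <- calibrate_activity(rnd, 39.25, lsf = 0.05)
  # voxelwise proportionality: activity ratios equal count ratios
  i <- c(17, 311); j <- c(901, 45)
  expect_equal(a$values[i[1]] / a$values[j[1]],
               rnd$values[i[1]] / rnd$values[j[1]], tolerance = 1e-12)

  zero <- grid_of(array(0, c(4, 4, 4)), unit = "counts")
  expect_error(calibrate_activity(zero, 10), "zero")
  expect_error(calibrate_activity(counts, 10, lsf = 1.2), "lsf")
  expect_error(calibrate_activity(counts, 0), "> 0")
})

test_that("LDM dose is delta times activity over voxel mass", {
  cons <- physics_constants()
  # 1 GBq spread uniformly over a region of ~1 kg of tissue
  dm <- c(12, 12, 12)
  vv_cc <- 4.8 * 4.8 * 3.0 / 1000
  n_vox <- prod(dm)
  mass_kg <- n_vox * vv_cc * 1.03 / 1000
  act <- grid_of(array(1 / n_vox, dm), unit = "GBq")
  dose <- ldm_dose(act, cons)
  expect_equal(unname(dose$values[3, 4, 5]),
               cons$delta_Gy_kg_per_GBq / mass_kg, tolerance = 1e-12)
  expect_equal(unname(dose$values[3, 4, 5]) * mass_kg / n_vox * n_vox,
               cons$delta_Gy_kg_per_GBq, tolerance = 1e-9)

  # single voxel of 0.110592 cc holding 1 mGBq: ~435 Gy
  one <- voxel_grid(array(c(1e-3, rep(0, 26)), c(3, 3, 3)),
                    spacing = c(4.8, 4.8, 4.8), unit = "GBq")
  d1 <- ldm_dose(one, cons)
  expect_equal(unname(d1$values[1, 1, 1]), 435.3, tolerance = 0.005)
  expect_equal(sum(ldm_dose(grid_of(array(0, c(4, 4, 4)), unit = "GBq"),
                            cons)$values), 0)
})

test_that("a delta kernel reproduces LDM bit for bit and a point source takes the kernel shape", {
  set.seed(9)
  act <- grid_of(array(runif(8 * 8 * 8), c(8, 8, 8)), unit = "GBq")
  expect_identical(dpk_dose(act, kernel_spec("delta"))$values,
                   ldm_dose(act)$values)

  # point source through a gaussian kernel: profile ratios match the kernel
  dm <- c(21, 21, 21)
  pt <- voxel_grid(array(0, dm), spacing = c(3, 3, 3), unit = "GBq")
  pt$values[11, 11, 11] <- 1e-2
  kern <- kernel_spec("gaussian_dpk", fwhm_mm = 8)
  dd <- dpk_dose(pt, kern)
  k <- taredose:::gaussian_kernel3d(8, c(3, 3, 3))
  ck <- (dim(k) + 1) / 2
  expect_equal(dd$values[12, 11, 11] / dd$values[11, 11, 11],
               k[ck[1] + 1, ck[2], ck[3]] / k[ck[1], ck[2], ck[3]],
               tolerance = 1e-9)
  # and the peak equals delta*A*k0/mass
  cons <- physics_constants()
  mass <- 27 / 1000 * 1.03 / 1000
  expect_equal(unname(dd$values[11, 11, 11]),
               cons$delta_Gy_kg_per_GBq * 1e-2 * k[ck[1], ck[2], ck[3]] / mass,
               tolerance = 1e-9)
})

test_that("an interior uniform slab gets the LDM dose from the convolution engine", {
  dm <- c(32, 32, 32)
  act <- voxel_grid(array(0, dm), spacing = c(4.8, 4.8, 3.0), unit = "GBq")
  act$values[8:25, 8:25, 8:25] <- 1e-4
  d_ldm <- ldm_dose(act)
  d_dpk <- dpk_dose(act, kernel_spec("tabulated_dpk"))
  centre <- d_dpk$values[15:18, 15:18, 15:18] / d_ldm$values[15:18, 15:18, 15:18]
  expect_true(all(abs(centre - 1) < 0.005))
})

test_that("both engines conserve energy and are exactly linear", {
  cons <- physics_constants()
  set.seed(31)
  dm <- c(24, 24, 24)
  act <- voxel_grid(array(0, dm), spacing = c(4.8, 4.8, 3.0), unit = "GBq")
  act$values[9:16, 9:16, 9:16] <- runif(512)   # interior source
  mass <- voxel_volume_cc(act) * 1.03 / 1000
  for (eng in list(ldm_dose(act, cons),
                   dpk_dose(act, kernel_spec("tabulated_dpk"), cons))) {
    rel <- sum(eng$values) * mass /
      (cons$delta_Gy_kg_per_GBq * sum(act$values))
    expect_lt(abs(rel - 1), 0.001)
  }
  act2 <- act; act2$values <- act$values * 3.7
  expect_equal(ldm_dose(act2, cons)$values, 3.7 * ldm_dose(act, cons)$values,
               tolerance = 1e-12)
  expect_equal(dpk_dose(act2, kernel = kernel_spec("tabulated_dpk"))$values,
               3.7 * dpk_dose(act, kernel = kernel_spec("tabulated_dpk"))$values,
               tolerance = 1e-12)
})

test_that("halving the voxel size leaves the structure mean dose nearly unchanged", {
  # smooth phantom: gaussian blob activity, fixed physical structure
  mean_dose_at <- function(sp) {
    n <- round(96 / sp)
    ax <- (seq_len(n) - (n + 1) / 2) * sp
    r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
    act <- voxel_grid(array(exp(-r2 / (2 * 15^2)), c(n, n, n)),
                      spacing = rep(sp, 3), unit = "GBq")
    act$values <- act$values / sum(act$values) * 0.5
    m <- roi_mask(array(r2 <= 20^2, c(n, n, n)), spacing = rep(sp, 3))
    mean(ldm_dose(act)$values[m$values])
  }
  coarse <- mean_dose_at(4.8)
  fine <- mean_dose_at(2.4)
  expect_lt(abs(fine - coarse) / coarse, 0.01)
})

test_that("kernels discretize to unit sum and oversized kernels are refused", {
  for (k in list(kernel_spec("gaussian_dpk", fwhm_mm = 9),
                 kernel_spec("tabulated_dpk"))) {
    kd <- taredose:::discretize_kernel(k, c(4.8, 4.8, 3.0))
    expect_lt(abs(sum(kd) - 1), 1e-6)
    expect_true(all(dim(kd) %% 2 == 1))
  }
  small <- grid_of(array(1, c(3, 3, 3)), spacing = c(1, 1, 1), unit = "GBq")
  expect_error(dpk_dose(small, kernel_spec("tabulated_dpk")),
               "support exceeds")
})
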