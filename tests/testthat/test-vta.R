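lead <- build_lead()

test_that("analytic point-source field matches the closed form", {
  g <- unit_grid(21)
  src <- centre_voxel_world(g)
  pl <- lead_placement(src - c(0, 0, 0.75))       # C0 at a voxel centre
  f <- efield_analytic(stim_config(0, 1), pl, lead, sigma = 0.33, g)
  # I = 1 mA, sigma = 0.33 S/m, r = 1 mm -> 0.241 V/mm
  at <- function(off) f$data[matrix(world_to_voxel(g, matrix(src + off, 1)),
                                    1)]
  expect_equal(at(c(1, 0, 0)), 0.241, tolerance = 1e-3)
  # inverse square decay
  expect_equal(at(c(2, 0, 0)), at(c(1, 0, 0)) / 4, tolerance = 1e-12)
  expect_equal(at(c(0, 4, 0)), at(c(0, 2, 0)) / 4, tolerance = 1e-12)
})

test_that("zero amplitude gives a zero field", {
  g <- unit_grid(11)
  f <- efield_analytic(stim_config(integer(0), 0),
                       lead_placement(c(0, 0, 0)), lead, 0.33, g)
  expect_true(all(f$data == 0))
})

test_that("VTA binarization reproduces the threshold radius", {
  g <- unit_grid(41, vs = 0.5)
  src <- centre_voxel_world(g)
  pl <- lead_placement(src - c(0, 0, 0.75))
  # I = 3 mA in white matter: r* = sqrt(I*1e3/(4 pi sigma e)) = 2.92 mm
  f <- efield_analytic(stim_config(0, 3), pl, lead, sigma = 0.14, g)
  vta <- binarize_vta(f, 0.2)
  w <- which(vta$mask$data, arr.ind = TRUE)
  r_b <- max(sqrt(rowSums(sweep(voxel_to_world(g, w), 2, src)^2)))
  expect_equal(r_b, sqrt(3 * 1e3 * 1e-3 / (4 * pi * 0.14 * 0.2)),
               tolerance = 0.5 * g$voxel_size / 2.92)
  expect_equal(vta$volume_mm3, sum(vta$mask$data) * 0.5^3)
})

test_that("thresholding degenerates and monotonicity hold", {
  g <- unit_grid(15)
  pl <- lead_placement(centre_voxel_world(g) - c(0, 0, 0.75))
  f <- efield_analytic(stim_config(0, 1), pl, lead, 0.33, g)
  empty <- binarize_vta(f, max(f$data) * 1.01)
  expect_equal(empty$volume_mm3, 0)
  expect_error(binarize_vta(f, -0.1), ">= 0")
  vols <- sapply(c(1, 2, 3, 5), function(a) {
    binarize_vta(efield_analytic(stim_config(0, a), pl, lead, 0.33, g))$volume_mm3
  })
  expect_true(all(diff(vols) >= 0))
  # raising the threshold never grows the mask
  v_lo <- binarize_vta(f, 0.1)$volume_mm3
  v_hi <- binarize_vta(f, 0.3)$volume_mm3
  expect_true(v_hi <= v_lo)
})

test_that("vta_metrics computes overlap and distances", {
  sph <- label_volume(rasterize_sphere(unit_grid(30), c(0, 0, 0), 4) * 1, 1)
  m <- vta_metrics(as_vta(sph), sph)
  expect_equal(m$overlap_fraction_of_nucleus, 1)
  expect_equal(m$centroid_distance_mm, 0)
  expect_equal(m$min_distance_mm, 0)

  a <- mask_at(12, matrix(c(3, 3, 3), 1))
  b <- mask_at(12, matrix(c(6, 3, 3), 1))
  m2 <- vta_metrics(as_vta(a), b)
  expect_equal(m2$min_distance_mm, 3.0)
  expect_equal(m2$overlap_mm3, 0)

  sph2 <- label_volume(rasterize_sphere(unit_grid(30), c(2, 0, 0), 4) * 1, 1)
  m3 <- vta_metrics(as_vta(sph), sph2)
  expect_equal(m3$centroid_distance_mm, 2.0, tolerance = 0.25)

  expect_error(vta_metrics(as_vta(sph), mask_at(30, matrix(ncol = 3,
                                                           nrow = 0))),
               "empty")
  flagged <- vta_metrics(as_vta(mask_at(30, matrix(ncol = 3, nrow = 0))),
                         sph)
  expect_equal(flagged$flag, "empty_vta")
  expect_true(is.na(flagged$centroid_distance_mm))
})

test_that("FDM field is linear in amplitude and scales as 1/sigma", {
  tis <- label_volume(array(1L, c(24, 24, 24)), 1)
  src <- centre_voxel_world(tis)
  pl <- lead_placement(src - c(0, 0, 0.75))
  f1 <- efield_fdm(stim_config(0, 1), pl, lead, tis, conductivity_model())
  f2 <- efield_fdm(stim_config(0, 2), pl, lead, tis, conductivity_model())
  expect_equal(f2$data, 2 * f1$data, tolerance = 1e-12)
  # current-controlled source: doubling sigma everywhere leaves the
  # potential shape invariant and halves the field
  fs <- efield_fdm(stim_config(0, 1), pl, lead, tis,
                   conductivity_model(0.66, 0.28, 4.0))
  expect_equal(fs$data, f1$data / 2, tolerance = 1e-6)
})

test_that("FDM agrees with the analytic oracle away from the source", {
  tis <- label_volume(array(1L, c(32, 32, 32)), 1)
  src <- centre_voxel_world(tis)
  pl <- lead_placement(src - c(0, 0, 0.75))
  f <- efield_fdm(stim_config(0, 1), pl, lead, tis, conductivity_model())
  fa <- efield_analytic(stim_config(0, 1), pl, lead, 0.33, tis)
  w <- which(array(TRUE, dim(tis$data)), arr.ind = TRUE)
  r <- sqrt(rowSums(sweep(voxel_to_world(tis, w), 2, src)^2))
  shell <- r >= 3 & r <= 8
  rel <- abs(f$data[shell] - fa$data[shell]) / fa$data[shell]
  expect_lt(max(rel), 0.05)
})

test_that("FDM solver errors are informative", {
  tis <- label_volume(array(1L, c(16, 16, 16)), 1)
  pl <- lead_placement(centre_voxel_world(tis) - c(0, 0, 0.75))
  expect_error(efield_fdm(stim_config(0, 1), pl, lead, tis,
                          conductivity_model(), max_sweeps = 2),
               "did not converge")
  far <- lead_placement(c(100, 100, 100))
  expect_error(efield_fdm(stim_config(0, 1), far, lead, tis,
                          conductivity_model()), "outside grid")
})
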