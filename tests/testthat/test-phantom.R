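test_that("spec validation catches bad geometry and labels", {
  expect_error(phantom_spec(nucleus_radii = c(cm = 0, pf = 2)),
               "geometry error")
  expect_error(phantom_spec(region_labels = c(
    brainstem_cerebellum = 1L, postcentral = 1L, precentral = 3L,
    SMA = 4L, middle_frontal = 5L, superior_frontal = 6L)), "unique")
  expect_error(phantom_spec(grid_shape = c(20L, 20L, 20L)),
               "outside the grid")
})

test_that("head phantom places nuclei at the stereotactic target", {
  spec <- phantom_spec()
  vols <- make_head_phantom(spec)
  cm_r <- label_volume(vols$nuclei$data == 1, spec$voxel_size)
  expect_lt(sqrt(sum((mask_centroid(cm_r) - c(9, -9, 0))^2)),
            spec$voxel_size)
  cm_l <- label_volume(vols$nuclei$data == 2, spec$voxel_size)
  expect_lt(sqrt(sum((mask_centroid(cm_l) - c(-9, -9, 0))^2)),
            spec$voxel_size)
  # co-registered, all six regions present, tissue classes complete
  expect_equal(dim(vols$tissue$data), dim(vols$parcellation$data))
  expect_setequal(unique(as.integer(vols$parcellation$data)),
                  c(0L, spec$region_labels))
  expect_setequal(unique(as.integer(vols$tissue$data)), 0:2)
})

test_that("generators are deterministic under the spec seed", {
  spec <- phantom_spec(seed = 7)
  expect_identical(make_head_phantom(spec)$tissue$data,
                   make_head_phantom(spec)$tissue$data)
  t1 <- make_tractogram(spec, 200)
  t2 <- make_tractogram(spec, 200)
  expect_identical(t1$tractogram$coords, t2$tractogram$coords)
  c1 <- make_cohort(spec, n_patients = 4, tract = t1$tractogram,
                    truth = t1$truth)
  c2 <- make_cohort(spec, n_patients = 4, tract = t2$tractogram,
                    truth = t2$truth)
  expect_identical(c1$cohort$table, c2$cohort$table)
  # named substreams: the tractogram draw does not perturb the cohort draw
  c3 <- make_cohort(phantom_spec(seed = 7), n_patients = 4,
                    tract = make_tractogram(spec, 300)$tractogram,
                    truth = make_tractogram(spec, 300)$truth)
  expect_identical(c1$cohort$table$tip_x, c3$cohort$table$tip_x)
})

test_that("tractogram geometry honours counts, labels and bounds", {
  spec <- phantom_spec(seed = 13)
  tg <- make_tractogram(spec, n_streamlines = 10, bundle_fraction = 0.5)
  expect_equal(n_streamlines(tg$tractogram), 10L)
  expect_equal(sum(tg$truth$labels > 0), 5L)
  expect_length(tg$truth$labels, 10L)
  tg2 <- make_tractogram(spec, n_streamlines = 600, bundle_fraction = 0.1)
  half <- spec$grid_shape * spec$voxel_size / 2
  expect_true(all(abs(tg2$tractogram$coords) <=
                    matrix(half, nrow(tg2$tractogram$coords), 3,
                           byrow = TRUE)))
  # every bundle streamline has a vertex inside the dilated CM mask
  vols <- make_head_phantom(spec)
  cm <- label_volume(array(vols$nuclei$data %in% 1:2,
                           dim(vols$nuclei$data)), spec$voxel_size)
  dil <- dilate_mask(cm, 4 * spec$bundle_spread)
  hits <- vapply(tg2$truth$bundle, function(i) {
    p <- streamline(tg2$tractogram, i)
    any(sample_volume <- dbsconn:::sample_volume(dil, p) > 0)
  }, logical(1))
  expect_true(all(hits))
  # distractors avoid the CM/Pf neighbourhood
  lay <- dbsconn:::phantom_layout(spec)
  for (i in utils::head(which(tg2$truth$labels == 0L), 50)) {
    p <- streamline(tg2$tractogram, i)
    d <- sqrt(rowSums(sweep(p, 2, lay$cm_right$centre)^2))
    expect_gt(min(d), spec$nucleus_radii[["cm"]] + spec$distractor_margin)
  }
  expect_error(make_tractogram(spec, 0), ">= 1")
})

test_that("cohort settings follow the clinical stimulation protocol", {
  spec <- phantom_spec(seed = 17)
  tg <- make_tractogram(spec, 800)
  co <- make_cohort(spec, tract = tg$tractogram, truth = tg$truth)
  tab <- co$cohort$table
  expect_true(all(tab$amplitude_V >= 1 & tab$amplitude_V <= 5))
  expect_true(all(tab$frequency_Hz == 60))
  expect_true(all(tab$pulse_us == 90))
  expect_equal(nrow(tab), 20L)           # two hemispheres per patient
  expect_true(all(abs(co$cohort$improvement) <= 100))
  expect_true(all(co$cohort$improvement[, "baseline"] == 0))
  expect_error(make_cohort(spec, n_patients = 2, tract = tg$tractogram,
                           truth = tg$truth), ">= 3")
})

test_that("noise-free improvements are monotone in planted connectivity", {
  spec <- phantom_spec(seed = 19)
  tg <- make_tractogram(spec, 800)
  co <- make_cohort(spec, noise_sd = 0, tract = tg$tractogram,
                    truth = tg$truth)
  expect_equal(order(co$cohort$outcome, seq_along(co$cohort$outcome)),
               order(co$cohort$connectivity,
                     seq_along(co$cohort$connectivity)))
})

test_that("normative fMRI has the acquisition shape and substreams", {
  spec <- phantom_spec(grid_shape = c(22L, 22L, 22L), voxel_size = 3,
                       seed = 23)
  ser <- make_normative_fmri(spec, n_subjects = 2)
  expect_length(ser, 2L)
  expect_equal(dim(ser[[1]]$data)[4], 124L)
  expect_equal(ser[[1]]$TR, 3)
  # subject substreams: a subset call reproduces the same series
  one <- make_normative_fmri(spec, n_subjects = 2, subjects = 2)
  expect_identical(one[[1]]$data, ser[[2]]$data)
  expect_error(make_normative_fmri(spec, n_timepoints = 10), ">= 20")
})

test_that("seed-network correlation converges to the coupling target", {
  spec <- phantom_spec(grid_shape = c(22L, 22L, 22L), voxel_size = 3,
                       seed = 29)
  err <- sapply(c(124, 1000), function(T) {
    ser <- make_normative_fmri(spec, n_subjects = 4, n_timepoints = T,
                               coupling = 0.5)
    net <- attr(ser, "network"); seedm <- attr(ser, "seed")
    rs <- sapply(ser, function(s)
      mean(seed_map(s, seedm)$data[net$data & !seedm$data], na.rm = TRUE))
    abs(mean(rs) - 0.5)
  })
  expect_lt(err[2], err[1] + 0.02)
  expect_lt(err[2], 0.05)
})
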