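test_that("traversal selection requires a resampled vertex in the mask", {
  g <- label_volume(array(0, c(8, 8, 8)), 1)
  mask <- mask_at(8, world_to_voxel(g, matrix(c(0.5, 0.5, 0.5), 1)))
  through <- seg(c(-3, 0.5, 0.5), c(3, 0.5, 0.5))
  outside <- seg(c(-3, 0.5, 3.5), c(3, 0.5, 3.5))
  # only the endpoints are stored and both lie outside the 1-voxel mask;
  # resampling at half a voxel recovers the traversal
  straddle <- seg(c(-0.7, 0.5, 0.5), c(1.9, 0.5, 0.5))
  tr <- tract_of(through, outside, straddle)
  expect_equal(connected_fibers(tr, mask), c(1L, 3L))
  # selection is invariant to point-order reversal
  tr_rev <- tract_of(through[2:1, ], outside[2:1, ], straddle[2:1, ])
  expect_equal(connected_fibers(tr_rev, mask), c(1L, 3L))
  expect_error(connected_fibers(tr, mask_at(8, matrix(ncol = 3, nrow = 0))),
               "empty")
})

test_that("selection is monotone in the mask", {
  set.seed(43)
  g <- label_volume(array(0, c(16, 16, 16)), 1)
  sl <- lapply(1:40, function(i)
    seg(runif(3, -7, 7), runif(3, -7, 7), k = 12))
  tr <- tractogram(sl)
  small <- label_volume(rasterize_sphere(g, c(0, 0, 0), 2), 1)
  big <- label_volume(rasterize_sphere(g, c(0, 0, 0), 5), 1)
  expect_true(all(connected_fibers(tr, small) %in%
                    connected_fibers(tr, big)))
})

test_that("terminal regions label streamline endpoints", {
  spec <- phantom_spec(seed = 51)
  vols <- make_head_phantom(spec)
  lay <- dbsconn:::phantom_layout(spec)
  sma_ctr <- lay$SMA$centre
  tr <- tract_of(seg(sma_ctr, c(0, 0, 0), k = 5),
                 seg(c(0, 0, 0), c(200, 0, 0), k = 5))
  labs <- terminal_regions(tr, vols$parcellation)
  expect_equal(labs$start_label[1], spec$region_labels[["SMA"]])
  expect_equal(labs$end_label[2], 0L)   # outside the head
})

test_that("regional profiles count far endpoints with ground truth", {
  spec <- phantom_spec(seed = 53)
  vols <- make_head_phantom(spec)
  lay <- dbsconn:::phantom_layout(spec)
  # fibers from the right CM into the brainstem region: far endpoint there
  set.seed(7)
  sl <- lapply(1:25, function(i)
    seg(lay$cm_right$centre + rnorm(3, sd = 0.5),
        lay$brainstem_cerebellum$centre + rnorm(3, sd = 1), k = 30))
  tr <- tractogram(sl)
  vta <- as_vta(label_volume(
    rasterize_sphere(vols$tissue, lay$cm_right$centre, 2.5), 1))
  prof <- regional_profile(tr, vta, vols$parcellation)
  expect_equal(prof$raw_count[prof$region == "brainstem_cerebellum"], 25)
  expect_equal(sum(prof$raw_count), 25)
  # normalization: raw / (total streamlines x region voxel size)
  nvox <- sum(vols$parcellation$data ==
                spec$region_labels[["brainstem_cerebellum"]])
  expect_equal(prof$normalized_count[prof$region == "brainstem_cerebellum"],
               25 / (25 * nvox))
  # duplicating every streamline leaves the normalized count fixed
  tr2 <- tractogram(c(sl, sl))
  prof2 <- regional_profile(tr2, vta, vols$parcellation)
  expect_equal(prof2$normalized_count, prof$normalized_count)
  # empty VTA: all-zero, flagged
  prof0 <- regional_profile(tr, as_vta(mask_at(64, matrix(ncol = 3,
                                                          nrow = 0))),
                            vols$parcellation)
  expect_true(all(prof0$raw_count == 0))
  expect_equal(attr(prof0, "flag"), "empty_vta")
})

test_that("profile-outcome association flags degenerate inputs", {
  spec <- phantom_spec(seed = 59)
  tg <- make_tractogram(spec, n_streamlines = 500)
  co <- make_cohort(spec, n_patients = 5, tract = tg$tractogram,
                    truth = tg$truth)
  vols <- make_head_phantom(spec)
  profs <- lapply(co$cohort$vtas, function(v)
    regional_profile(tg$tractogram, v, vols$parcellation))
  flat <- profile_outcome_association(profs, rep(42, 5))
  expect_true(all(flat$flag == "zero_variance"))
})

test_that("noise-free cohort yields r = 1 against planted connectivity", {
  spec <- phantom_spec(seed = 61)
  tg <- make_tractogram(spec, n_streamlines = 1500)
  # small effect so no patient hits the +/-100% truncation bound
  co <- make_cohort(spec, noise_sd = 0, effect = 2, tract = tg$tractogram,
                    truth = tg$truth)
  expect_equal(co$cohort$outcome, 2 * co$cohort$connectivity,
               ignore_attr = TRUE)
  fit <- pearson_regression(co$cohort$connectivity, co$cohort$outcome)
  expect_equal(fit$r, 1, tolerance = 1e-12)
})

test_that("atlas overlap fractions are point proportions", {
  g <- label_volume(array(0, c(10, 10, 10)), 1)
  atlas <- label_volume(array(0L, c(10, 10, 10)), 1)
  atlas$data[, , 1:5] <- 1L     # lower half (z < 0)
  tr <- tract_of(seg(c(0, 0, -4.5), c(0, 0, -0.5), k = 10),
                 seg(c(0, 0, 0.5), c(0, 0, 4.5), k = 10))
  ov <- bundle_atlas_overlap(tr, 1L, atlas)
  expect_equal(ov$fraction, 1)
  ov2 <- bundle_atlas_overlap(tr, 1:2, atlas)
  expect_equal(ov2$fraction, 0.5)
  ov0 <- bundle_atlas_overlap(tr, integer(0), atlas)
  expect_equal(ov0$fraction, 0)
  expect_equal(attr(ov0, "flag"), "empty_selection")
})

test_that("planted bundle overlaps its own generating corridor", {
  spec <- phantom_spec(seed = 67)
  tg <- make_tractogram(spec, n_streamlines = 300, bundle_fraction = 0.2)
  corridor <- bundle_corridor(spec, tg$tractogram)
  atlas <- label_volume(corridor$data * 1L, spec$voxel_size)
  ov <- bundle_atlas_overlap(tg$tractogram, tg$truth$bundle, atlas)
  expect_gte(ov$fraction[ov$label == 1], 0.95)
})

test_that("planted-region association beats distractor regions", {
  wins <- logical(10)
  planted <- c("brainstem_cerebellum", "precentral", "postcentral", "SMA")
  for (s in seq_along(wins)) {
    spec <- phantom_spec(seed = 900 + s)
    tg <- make_tractogram(spec, n_streamlines = 2000)
    co <- make_cohort(spec, tract = tg$tractogram, truth = tg$truth)
    vols <- make_head_phantom(spec)
    rs <- resample_points(tg$tractogram, spec$voxel_size / 2)
    profs <- lapply(co$cohort$vtas, function(v)
      regional_profile(tg$tractogram, v, vols$parcellation, resampled = rs))
    a <- profile_outcome_association(profs, co$cohort$outcome)
    best_planted <- max(a$r[a$region %in% planted], na.rm = TRUE)
    best_other <- suppressWarnings(
      max(a$r[!a$region %in% planted], na.rm = TRUE))
    wins[s] <- best_planted > best_other
  }
  expect_gte(mean(wins), 0.9)
})
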