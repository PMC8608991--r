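mk_series <- function(ts_fun, nvox_side = 3, T = 124, TR = 3) {
  d <- c(nvox_side, nvox_side, nvox_side, T)
  a <- array(0, d)
  for (t in seq_len(T)) a[, , , t] <- ts_fun(t)
  fmri_series(a, TR = TR, voxel_size = 3)
}

test_that("band-pass keeps in-band and removes out-of-band sinusoids", {
  T <- 124; TR <- 3
  tt <- (seq_len(T) - 1) * TR
  keep <- mk_series(function(t) sin(2 * pi * 0.05 * tt[t]))
  kill <- mk_series(function(t) sin(2 * pi * 0.005 * tt[t]))
  dc <- mk_series(function(t) 7)
  out_keep <- preprocess_series(keep, fwhm = 0)
  out_kill <- preprocess_series(kill, fwhm = 0)
  out_dc <- preprocess_series(dc, fwhm = 0)
  amp <- function(s) sd(s$data[2, 2, 2, 20:105])
  expect_gte(amp(out_keep) / amp(keep), 0.9)
  expect_lte(amp(out_kill) / amp(kill), 0.1)
  expect_lt(max(abs(out_dc$data)), 1e-6)
})

test_that("confound regression residualizes exactly", {
  set.seed(71)
  conf <- rnorm(124)
  s <- mk_series(function(t) conf[t])
  out <- preprocess_series(s, confounds = cbind(conf), fwhm = 0)
  expect_lt(max(abs(out$data)), 1e-9)
  expect_error(preprocess_series(s, confounds = cbind(rnorm(100)),
                                 fwhm = 0), "mismatch")
  expect_error(preprocess_series(s, band = c(0.08, 0.01), fwhm = 0),
               "increasing")
  expect_error(preprocess_series(s, band = c(0.01, 0.2), fwhm = 0),
               "Nyquist")
})

test_that("zero-phase filter has |H|^2 gain and no phase shift", {
  bf <- signal::butter(4, c(0.06, 0.48), type = "pass")
  T <- 2000
  for (w in c(0.15, 0.6, 1.2)) {          # rad/sample, inside the band
    x <- sin(w * seq_len(T))
    y <- dbsconn:::iir_filtfilt_mat(bf$b, bf$a, cbind(x))[, 1]
    # forward-backward filtering: gain |H(w)|^2, zero phase
    H <- sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1))) /
      sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
    keep <- 200:(T - 200)
    fit <- stats::lm(y[keep] ~ sin(w * keep) + cos(w * keep) - 1)
    expect_equal(unname(coef(fit)[1]), Mod(H)^2, tolerance = 1e-4)
    expect_lt(abs(unname(coef(fit)[2])), 1e-4)
  }
  # linearity across columns
  set.seed(73)
  x <- rnorm(300)
  mine <- dbsconn:::iir_filtfilt_mat(bf$b, bf$a, cbind(x, 2 * x))
  expect_equal(mine[, 2], 2 * mine[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("seed maps are Pearson correlations with invariances", {
  T <- 60
  base <- sin(seq_len(T)) + rnorm(T, sd = 0.2)
  a <- array(rnorm(2 * 2 * 2 * T, sd = 0.1), c(2, 2, 2, T))
  a[1, 1, 1, ] <- base
  a[2, 1, 1, ] <- -base
  a[1, 2, 1, ] <- 3 + 5 * base          # positive affine rescaling
  a[2, 2, 2, ] <- 0                     # zero variance
  s <- fmri_series(a, TR = 2, voxel_size = 1)
  seed <- mask_at(2, matrix(c(1, 1, 1), 1))
  r <- seed_map(s, seed)
  expect_equal(r$data[1, 1, 1], 1)
  expect_equal(r$data[2, 1, 1], -1)
  expect_equal(r$data[1, 2, 1], 1, tolerance = 1e-12)
  expect_true(is.na(r$data[2, 2, 2]))
  expect_equal(attr(r, "n_undefined"), 1L)
  expect_error(seed_map(s, mask_at(2, matrix(ncol = 3, nrow = 0))),
               "empty")
})

test_that("Fisher transform is atanh with clamping", {
  g <- label_volume(array(c(0, 0.5, -0.5, 1, -1, 0.9, 0.2, -0.2),
                          c(2, 2, 2)), 1)
  class(g) <- c("r_map", class(g))
  z <- fisher_z(g)
  expect_equal(z$data[1, 1, 1], 0)
  expect_equal(z$data[2, 1, 1], 0.5493, tolerance = 1e-4)
  expect_equal(z$data[1, 2, 1], -z$data[2, 1, 1])
  expect_true(is.finite(z$data[2, 2, 1]))
  expect_equal(attr(z, "n_clamped"), 2L)
})

test_that("group t-map is the voxelwise one-sample t", {
  zs <- lapply(c(0.5, 0.7, 0.6, 0.6), function(v) {
    g <- label_volume(array(v, c(2, 2, 2)), 1)
    class(g) <- c("z_map", class(g))
    g
  })
  tm <- group_tmap(zs)
  expect_equal(tm$data[1, 1, 1], 14.70, tolerance = 1e-2)
  zeros <- lapply(1:4, function(i) label_volume(array(0, c(2, 2, 2)), 1))
  expect_true(all(group_tmap(zeros)$data == 0))
  expect_error(group_tmap(zs[1:2]), ">= 3")
  bad <- label_volume(array(0, c(3, 3, 3)), 1)
  expect_error(group_tmap(c(zs, list(bad))), "same grid")
})

test_that("phantom network voxels carry the planted coupling", {
  spec <- phantom_spec(grid_shape = c(22L, 22L, 22L), voxel_size = 3,
                       seed = 79)
  ser <- make_normative_fmri(spec, n_subjects = 3, coupling = 0.6)
  net <- attr(ser, "network"); seedm <- attr(ser, "seed")
  rs <- sapply(ser, function(s)
    mean(seed_map(s, seedm)$data[net$data & !seedm$data], na.rm = TRUE))
  expect_true(all(abs(rs - 0.6) < 0.2))
  # null coupling: mean network correlation near zero
  ser0 <- make_normative_fmri(spec, n_subjects = 6, coupling = 0)
  r0 <- sapply(ser0, function(s)
    mean(seed_map(s, seedm)$data[net$data & !seedm$data], na.rm = TRUE))
  expect_lt(abs(mean(r0)), 3 * sd(r0) / sqrt(length(r0)) + 0.02)
  expect_error(make_normative_fmri(spec, coupling = 1.2), "coupling")
})
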