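#' 4-D fMRI series container
#' @param data 4-D array (x, y, z, time).
#' @param TR repetition time in seconds.
#' @param voxel_size isotropic voxel edge in mm.
#' @param origin world-mm corner of voxel (1,1,1).
#' @export
fmri_series <- function(data, TR, voxel_size = 1, origin = NULL) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4-D array")
  if (dim(data)[4] < 20L) stop("need >= 20 frames")
  if (is.null(origin)) origin <- -dim(data)[1:3] * voxel_size / 2
  structure(list(data = data, TR = TR, voxel_size = voxel_size,
                 origin = origin), class = "fmri_series")
}

#' @export
print.fmri_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_series> %dx%dx%d voxels @ %.3g mm, %d frames, TR %.3g s\n",
              d[1], d[2], d[3], x$voxel_size, d[4], x$TR))
  invisible(x)
}

# grid geometry of a series as a label_volume template
fmri_grid <- function(fmri) {
  label_volume(array(0, dim(fmri$data)[1:3]), fmri$voxel_size, fmri$origin)
}

# 1-D Gaussian kernel band matrix for separable smoothing; rows renormalized
# so the truncated kernel integrates to 1 at the edges
gauss_band <- function(n, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmax(1L, i - r):pmin(n, i + r)
    K[i, j] <- w[j - i + r + 1L]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

# separable 3-D Gaussian smoothing of every frame
smooth_series <- function(fmri, fwhm_mm) {
  if (fwhm_mm <= 0) return(fmri)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / fmri$voxel_size
  d <- dim(fmri$data)
  K1 <- gauss_band(d[1], sigma)
  K2 <- gauss_band(d[2], sigma)
  K3 <- gauss_band(d[3], sigma)
  A <- fmri$data
  dim(A) <- c(d[1], d[2] * d[3] * d[4])
  A <- K1 %*% A
  dim(A) <- d
  A <- aperm(A, c(2, 1, 3, 4))
  dim(A) <- c(d[2], d[1] * d[3] * d[4])
  A <- K2 %*% A
  dim(A) <- c(d[2], d[1], d[3], d[4])
  A <- aperm(A, c(3, 2, 1, 4))          # axes now (z, x, y, t)
  dim(A) <- c(d[3], d[1] * d[2] * d[4])
  A <- K3 %*% A
  dim(A) <- c(d[3], d[1], d[2], d[4])
  A <- aperm(A, c(2, 3, 1, 4))          # back to (x, y, z, t)
  fmri_series(A, fmri$TR, fmri$voxel_size, fmri$origin)
}

# zero-phase IIR filtering of the columns of X (time down the rows):
# odd-reflection padding, forward pass, reverse pass (filtfilt behaviour)
iir_filtfilt_mat <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  pad <- 3L * (nf - 1L)
  one_pass <- function(X) {
    T <- nrow(X)
    top <- 2 * X[rep(1L, pad), , drop = FALSE] -
      X[(pad + 1L):2L, , drop = FALSE]
    bot <- 2 * X[rep(T, pad), , drop = FALSE] -
      X[(T - 1L):(T - pad), , drop = FALSE]
    Xp <- rbind(top, X, bot)
    Y <- matrix(0, nrow(Xp), ncol(Xp))
    z <- matrix(0, nf - 1L, ncol(Xp))      # direct form II transposed state
    for (t in seq_len(nrow(Xp))) {
      xt <- Xp[t, ]
      yt <- b[1] * xt + z[1, ]
      for (k in seq_len(nf - 2L))
        z[k, ] <- b[k + 1L] * xt + z[k + 1L, ] - a[k + 1L] * yt
      z[nf - 1L, ] <- b[nf] * xt - a[nf] * yt
      Y[t, ] <- yt
    }
    Y[(pad + 1L):(pad + T), , drop = FALSE]
  }
  Y <- one_pass(X)
  Y <- one_pass(Y[nrow(Y):1L, , drop = FALSE])
  Y[nrow(Y):1L, , drop = FALSE]
}

#' Minimal resting-state preprocessing
#'
#' Applies, in order: Gaussian spatial smoothing (6 mm FWHM default),
#' ordinary-least-squares residualization against the confound series plus
#' an intercept, and a zero-phase 4th-order Butterworth band-pass
#' (0.01-0.08 Hz default).
#'
#' @param fmri an \code{fmri_series}.
#' @param confounds numeric matrix (frames x q) of nuisance series, e.g.
#'   mean WM and CSF signals; may be NULL.
#' @param band Hz pair, strictly inside (0, Nyquist).
#' @param fwhm smoothing kernel FWHM in mm (0 disables).
#' @return preprocessed \code{fmri_series}.
#' @export
preprocess_series <- function(fmri, confounds = NULL,
                              band = c(0.01, 0.08), fwhm = 6) {
  fs <- 1 / fmri$TR
  if (length(band) != 2 || band[1] >= band[2])
    stop("band must be an increasing Hz pair")
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie strictly inside (0, Nyquist)")
  out <- smooth_series(fmri, fwhm)
  d <- dim(out$data)
  T <- d[4]
  Y <- matrix(out$data, prod(d[1:3]), T)
  Y <- t(Y)                               # frames x voxels
  if (!is.null(confounds) && nrow(as.matrix(confounds)) != T)
    stop("confound series length mismatch")
  X <- cbind(intercept = rep(1, T), confounds)
  Y <- Y - X %*% qr.coef(qr(X), Y)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  Y <- iir_filtfilt_mat(bf$b, bf$a, Y)
  fmri_series(array(t(Y), d), fmri$TR, fmri$voxel_size, fmri$origin)
}

#' Confound series from tissue labels
#'
#' Mean time series over the white-matter and CSF voxels of a co-registered
#' tissue map, the phantom's stand-in for averaged WM and CSF nuisance
#' signals.
#' @param fmri an \code{fmri_series}.
#' @param tissue \code{label_volume} with 0 = CSF/background, 1 = GM,
#'   2 = WM.
#' @return frames x 2 matrix with columns \code{wm}, \code{csf}.
#' @export
tissue_confounds <- function(fmri, tissue) {
  stopifnot_same_grid(fmri_grid(fmri), tissue)
  d <- dim(fmri$data)
  Y <- matrix(fmri$data, prod(d[1:3]), d[4])
  cbind(wm = colMeans(Y[tissue$data == 2, , drop = FALSE]),
        csf = colMeans(Y[tissue$data == 0, , drop = FALSE]))
}

#' Seed-based correlation map
#'
#' Correlates the mean series over the seed voxels with every voxel's
#' series (Pearson). Voxels with zero variance get NA (flagged via the
#' \code{n_undefined} attribute).
#'
#' @param fmri an \code{fmri_series}.
#' @param seed a \code{vta_mask} or nonempty binary \code{label_volume} on
#'   the series grid.
#' @return \code{label_volume} of r values with class \code{r_map} prepended.
#' @export
seed_map <- function(fmri, seed) {
  vol <- if (inherits(seed, "vta_mask")) seed$mask else seed
  stopifnot_same_grid(fmri_grid(fmri), vol)
  if (sum(vol$data != 0) == 0L) stop("seed is empty")
  d <- dim(fmri$data)
  Y <- t(matrix(fmri$data, prod(d[1:3]), d[4]))   # frames x voxels
  s <- rowMeans(Y[, vol$data != 0, drop = FALSE])
  sv <- apply(Y, 2, sd)
  r <- rep(NA_real_, ncol(Y))
  ok <- sv > 0 & sd(s) > 0
  r[ok] <- as.numeric(cor(s, Y[, ok, drop = FALSE]))
  out <- label_volume(array(r, d[1:3]), fmri$voxel_size, fmri$origin)
  class(out) <- c("r_map", class(out))
  attr(out, "n_undefined") <- sum(!ok)
  out
}

#' Fisher z-transform of a correlation map
#'
#' z = atanh(r); correlations with |r| >= 1 - 1e-7 are clamped to that
#' bound first (count in the \code{n_clamped} attribute).
#' @param rmap an \code{r_map}.
#' @return \code{label_volume} of z values with class \code{z_map}.
#' @export
fisher_z <- function(rmap) {
  r <- rmap$data
  lim <- 1 - 1e-7
  clamped <- sum(abs(r) >= lim, na.rm = TRUE)
  r <- pmin(pmax(r, -lim), lim)
  out <- label_volume(atanh(r), rmap$voxel_size, rmap$origin)
  class(out) <- c("z_map", class(out))
  attr(out, "n_clamped") <- clamped
  out
}

#' Across-subject one-sample t-map
#'
#' Voxelwise t = mean(z) * sqrt(n) / sd(z) over subjects. Voxels with zero
#' SD get t = 0 when the mean is 0 too, otherwise a flagged +/-Inf sentinel.
#'
#' @param zmaps list of >= 3 per-subject \code{z_map}s on a common grid.
#' @return \code{label_volume} of t values with class \code{t_map} and an
#'   \code{n_subjects} attribute.
#' @export
group_tmap <- function(zmaps) {
  n <- length(zmaps)
  if (n < 3) stop("need >= 3 subjects")
  for (z in zmaps[-1]) stopifnot_same_grid(zmaps[[1]], z)
  d <- dim(zmaps[[1]]$data)
  Z <- sapply(zmaps, function(z) as.numeric(z$data))   # voxels x subjects
  mu <- rowMeans(Z)
  sdv <- apply(Z, 1, sd)
  t <- mu * sqrt(n) / sdv
  t[sdv == 0 & mu == 0] <- 0
  t[sdv == 0 & mu != 0] <- Inf * sign(mu[sdv == 0 & mu != 0])
  out <- label_volume(array(t, d), zmaps[[1]]$voxel_size, zmaps[[1]]$origin)
  class(out) <- c("t_map", class(out))
  attr(out, "n_subjects") <- n
  attr(out, "n_degenerate") <- sum(sdv == 0 & mu != 0)
  out
}

#' Mean map value per parcellation region
#' @param map a \code{label_volume} (r/z/t map).
#' @param parcellation integer \code{label_volume} with optional
#'   \code{region_labels} attribute.
#' @return data.frame with \code{region} and \code{mean_value}.
#' @export
summarize_map_by_region <- function(map, parcellation) {
  stopifnot_same_grid(map, parcellation)
  rl <- attr(parcellation, "region_labels")
  if (is.null(rl)) {
    labs <- sort(unique(parcellation$data[parcellation$data != 0]))
    rl <- stats::setNames(as.integer(labs), paste0("region_", labs))
  }
  data.frame(region = names(rl),
             mean_value = vapply(rl, function(l)
               mean(map$data[parcellation$data == l], na.rm = TRUE),
               numeric(1)), row.names = NULL)
}
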