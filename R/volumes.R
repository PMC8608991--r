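#' Labelled 3-D volume on a regular grid
#'
#' A minimal container for integer- or real-valued 3-D grids: a data array
#' plus an isotropic voxel size and the world coordinate of the grid corner.
#' World coordinates are RAS millimetres; voxel \code{(i,j,k)} (1-based) owns
#' the half-open cube \code{[origin + (i-1)*vs, origin + i*vs)}, so its centre
#' sits at \code{origin + (i-0.5)*vs}.
#'
#' @param data numeric or integer 3-D array.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param origin world-mm coordinate of the corner of voxel (1,1,1); defaults
#'   to centring the grid on the world origin.
#' @return an object of class \code{label_volume}.
#' @export
label_volume <- function(data, voxel_size = 1, origin = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a positive scalar (mm)")
  if (is.null(origin)) origin <- -dim(data) * voxel_size / 2
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels @ %.3g mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size,
              paste(sprintf("%.1f", x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$data)

#' Voxel-centre world coordinates of given 1-based voxel indices
#' @param vol a \code{label_volume}.
#' @param idx n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind(idx)
  sweep((idx - 0.5) * vol$voxel_size, 2, vol$origin, "+")
}

#' 1-based voxel indices containing given world points
#'
#' Points outside the grid map to indices outside \code{1..dim}; callers test
#' with \code{in_grid}.
#' @param vol a \code{label_volume}.
#' @param pts n x 3 matrix of world mm coordinates.
#' @return n x 3 integer matrix.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind(pts)
  idx <- floor(sweep(pts, 2, vol$origin, "-") / vol$voxel_size) + 1
  storage.mode(idx) <- "integer"
  idx
}

#' @rdname world_to_voxel
#' @param idx n x 3 matrix of 1-based voxel indices.
#' @return logical vector: index lies inside the grid.
#' @export
in_grid <- function(vol, idx) {
  d <- dim(vol$data)
  idx <- rbind(idx)
  idx[, 1] >= 1L & idx[, 1] <= d[1] &
    idx[, 2] >= 1L & idx[, 2] <= d[2] &
    idx[, 3] >= 1L & idx[, 3] <= d[3]
}

# linear (column-major) index for an n x 3 voxel index matrix; NA outside grid
linear_index <- function(vol, idx) {
  d <- dim(vol$data)
  idx <- rbind(idx)
  ok <- in_grid(vol, idx)
  li <- rep(NA_integer_, nrow(idx))
  li[ok] <- idx[ok, 1] + (idx[ok, 2] - 1L) * d[1] +
    (idx[ok, 3] - 1L) * d[1] * d[2]
  li
}

# values at world points; `outside` returned for points off the grid
sample_volume <- function(vol, pts, outside = 0) {
  li <- linear_index(vol, world_to_voxel(vol, pts))
  out <- rep(outside, length(li))
  out[!is.na(li)] <- vol$data[li[!is.na(li)]]
  out
}

# world coordinates of all voxel centres, as three arrays (memoised per call)
coordinate_grids <- function(vol) {
  d <- dim(vol$data)
  cx <- vol$origin[1] + (seq_len(d[1]) - 0.5) * vol$voxel_size
  cy <- vol$origin[2] + (seq_len(d[2]) - 0.5) * vol$voxel_size
  cz <- vol$origin[3] + (seq_len(d[3]) - 0.5) * vol$voxel_size
  list(x = cx, y = cy, z = cz)
}

# squared distance of every voxel centre from a world point, as a 3-D array
dist2_from_point <- function(vol, centre) {
  g <- coordinate_grids(vol)
  d <- dim(vol$data)
  dx2 <- (g$x - centre[1])^2
  dy2 <- (g$y - centre[2])^2
  dz2 <- (g$z - centre[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Rasterize a sphere into a logical mask
#' @param vol template \code{label_volume} (grid geometry is taken from it).
#' @param centre world mm centre.
#' @param radius mm; voxels whose centres lie within \code{radius} are set.
#' @return logical 3-D array.
#' @export
rasterize_sphere <- function(vol, centre, radius) {
  dist2_from_point(vol, centre) <= radius^2
}

#' Centroid of a binary mask in world mm
#' @param vol \code{label_volume} with logical/0-1 data.
#' @export
mask_centroid <- function(vol) {
  w <- which(vol$data != 0, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("mask is empty")
  colMeans(voxel_to_world(vol, w))
}

#' Minimal voxel-centre distance between two binary masks (0 if overlapping)
#' @param a,b \code{label_volume}s on the same grid.
#' @export
mask_min_distance <- function(a, b) {
  if (any(a$data != 0 & b$data != 0)) return(0)
  pa <- voxel_to_world(a, which(a$data != 0, arr.ind = TRUE))
  pb <- voxel_to_world(b, which(b$data != 0, arr.ind = TRUE))
  if (nrow(pa) == 0L || nrow(pb) == 0L) stop("mask is empty")
  # iterate over the smaller mask to bound memory
  if (nrow(pa) > nrow(pb)) { tmp <- pa; pa <- pb; pb <- tmp }
  best <- Inf
  for (i in seq_len(nrow(pa))) {
    d2 <- (pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2 +
      (pb[, 3] - pa[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Dilate a binary mask by a metric radius
#' @param vol binary \code{label_volume}.
#' @param radius_mm dilation radius in mm (voxel centres within this distance
#'   of any mask voxel centre are added).
#' @return \code{label_volume} with logical data.
#' @export
dilate_mask <- function(vol, radius_mm) {
  if (radius_mm < 0) stop("dilation radius must be nonnegative")
  r <- ceiling(radius_mm / vol$voxel_size)
  d <- dim(vol$data)
  src <- vol$data != 0
  out <- array(FALSE, d)
  offs <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  offs <- offs[offs$i^2 + offs$j^2 + offs$k^2 <=
                 (radius_mm / vol$voxel_size)^2, , drop = FALSE]
  for (n in seq_len(nrow(offs))) {
    si <- pmax(1L, 1L - offs$i[n]):pmin(d[1], d[1] - offs$i[n])
    sj <- pmax(1L, 1L - offs$j[n]):pmin(d[2], d[2] - offs$j[n])
    sk <- pmax(1L, 1L - offs$k[n]):pmin(d[3], d[3] - offs$k[n])
    out[si + offs$i[n], sj + offs$j[n], sk + offs$k[n]] <-
      out[si + offs$i[n], sj + offs$j[n], sk + offs$k[n]] | src[si, sj, sk]
  }
  label_volume(out, vol$voxel_size, vol$origin)
}

#' Write a volume as NIfTI-1
#'
#' The affine maps 0-based voxel indices to RAS mm so that voxel centres land
#' on the container's centre convention.
#' @param vol a \code{label_volume}.
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume <- function(vol, path) {
  vs <- vol$voxel_size
  aff <- diag(c(vs, vs, vs, 1))
  aff[1:3, 4] <- vol$origin + 0.5 * vs
  img <- RNifti::asNifti(vol$data * 1)
  img <- RNifti::`pixdim<-`(img, rep(vs, 3))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by \code{write_volume}
#' @param path NIfTI file path.
#' @return a \code{label_volume}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vs <- aff[1, 1]
  origin <- aff[1:3, 4] - 0.5 * vs
  label_volume(array(as.numeric(img), dim = dim(img)), vs, origin)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
}
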