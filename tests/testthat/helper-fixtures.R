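# shared in-code fixtures

# small homogeneous grid for analytic field tests
unit_grid <- function(n = 21, vs = 1) {
  label_volume(array(0, c(n, n, n)), vs)
}

# a voxel-centre world coordinate of a grid (so point sources sit on centres)
centre_voxel_world <- function(grid) {
  voxel_to_world(grid, matrix(ceiling(dim(grid$data) / 2), 1))[1, ]
}

# hand-built tractogram from a list of matrices
tract_of <- function(...) tractogram(list(...))

# straight-line streamline between two points with k vertices
seg <- function(a, b, k = 2) {
  t <- seq(0, 1, length.out = k)
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
        a[3] + t * (b[3] - a[3]))
}

# binary mask volume with given voxel indices set
mask_at <- function(n, idx, vs = 1) {
  a <- array(FALSE, c(n, n, n))
  a[idx] <- TRUE
  label_volume(a, vs)
}

as_vta <- function(vol, threshold = 0.2) {
  structure(list(mask = vol, threshold_used = threshold,
                 volume_mm3 = sum(vol$data != 0) * vol$voxel_size^3),
            class = "vta_mask")
}

# brute-force pooled two-sample t (explicit loops; oracle for fiber_tscores)
brute_t <- function(conn, y, min_per_group = 2) {
  g1 <- y[conn == 1]; g2 <- y[conn == 0]
  if (length(g1) < min_per_group || length(g2) < min_per_group)
    return(NA_real_)
  m1 <- sum(g1) / length(g1); m2 <- sum(g2) / length(g2)
  v1 <- sum((g1 - m1)^2) / (length(g1) - 1)
  v2 <- sum((g2 - m2)^2) / (length(g2) - 1)
  sp2 <- ((length(g1) - 1) * v1 + (length(g2) - 1) * v2) /
    (length(g1) + length(g2) - 2)
  if (sp2 <= 0) return(NA_real_)
  (m1 - m2) / (sqrt(sp2) * sqrt(1 / length(g1) + 1 / length(g2)))
}
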