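#' Write a tractogram as a TrackVis .trk file
#'
#' Minimal TRK version-2 writer. Points are written in world RAS millimetres
#' (the \code{vox_to_ras} header matrix carries the generating grid's affine;
#' \code{voxel_order} is "RAS"). Per-streamline values (e.g. bundle labels or
#' discriminative t-scores) are stored as TRK "properties".
#'
#' @param x a \code{tractogram}.
#' @param path output file path.
#' @param properties named list of per-streamline numeric vectors (at most
#'   10; names at most 19 characters). The tractogram's \code{labels}, if
#'   present, are written automatically as property \code{"bundle"}.
#' @param grid optional \code{label_volume} supplying dim/voxel size for the
#'   header (cosmetic; points remain world mm).
#' @export
write_trk <- function(x, path, properties = list(), grid = NULL) {
  if (!is.null(x$labels) && is.null(properties$bundle))
    properties$bundle <- as.numeric(x$labels)
  np <- length(properties)
  if (np > 10L) stop("at most 10 properties")
  n <- n_streamlines(x)
  for (p in properties) if (length(p) != n)
    stop("each property needs one value per streamline")

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(as.raw(0L), con)
  dims <- if (is.null(grid)) c(0L, 0L, 0L) else dim(grid$data)
  vs <- if (is.null(grid)) c(1, 1, 1) else rep(grid$voxel_size, 3)
  org <- if (is.null(grid)) c(0, 0, 0) else grid$origin
  writeBin(as.integer(dims), con, size = 2)
  writeBin(as.numeric(vs), con, size = 4)
  writeBin(as.numeric(org), con, size = 4)
  writeBin(0L, con, size = 2)                       # n_scalars
  writeBin(raw(10 * 20), con)                       # scalar names
  writeBin(as.integer(np), con, size = 2)           # n_properties
  pname <- raw(10 * 20)
  nm <- names(properties)
  for (i in seq_len(np)) {
    bytes <- utf8ToInt(substr(nm[i], 1, 19))
    pname[(i - 1) * 20 + seq_along(bytes)] <- as.raw(bytes)
  }
  writeBin(pname, con)
  aff <- diag(c(vs[1], vs[2], vs[3], 1))
  aff[1:3, 4] <- org + 0.5 * vs
  writeBin(as.numeric(t(aff)), con, size = 4)       # vox_to_ras, row-major
  writeBin(raw(444), con)                           # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                             # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)
  writeBin(raw(2), con)                             # pad1
  writeBin(raw(6), con)                             # invert/swap flags
  writeBin(as.integer(n), con, size = 4)            # n_count
  writeBin(2L, con, size = 4)                       # version
  writeBin(1000L, con, size = 4)                    # hdr_size

  prop_mat <- if (np > 0) do.call(cbind, properties) else NULL
  for (i in seq_len(n)) {
    p <- streamline(x, i)
    writeBin(nrow(p), con, size = 4)
    writeBin(as.numeric(t(p)), con, size = 4)
    if (np > 0) writeBin(as.numeric(prop_mat[i, ]), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis .trk file
#'
#' Counterpart of \code{\link{write_trk}}; points are interpreted as world
#' RAS mm. A \code{"bundle"} property, if present, is restored as the
#' tractogram's \code{labels}.
#' @param path .trk file path.
#' @return a \code{tractogram}; other properties are attached as the
#'   \code{properties} attribute (named list of per-streamline vectors).
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE)
  if (!identical(magic, "TRACK")) stop("not a TRK file")
  readBin(con, "raw", 1)
  readBin(con, "integer", 3, size = 2)              # dim
  readBin(con, "numeric", 3, size = 4)              # voxel_size
  readBin(con, "numeric", 3, size = 4)              # origin
  n_scalars <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2)
  pname_raw <- readBin(con, "raw", 200)
  pnames <- character(n_props)
  for (i in seq_len(n_props)) {
    bytes <- pname_raw[(i - 1) * 20 + 1:20]
    bytes <- bytes[cumsum(bytes == as.raw(0)) == 0]
    pnames[i] <- rawToChar(bytes)
  }
  readBin(con, "numeric", 16, size = 4)             # vox_to_ras
  readBin(con, "raw", 444)
  readBin(con, "raw", 8)                            # voxel_order + pad2
  readBin(con, "numeric", 6, size = 4)
  readBin(con, "raw", 8)                            # pad1 + flags
  n_count <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)              # version
  hdr <- readBin(con, "integer", 1, size = 4)
  if (hdr != 1000L) stop("unexpected TRK header size")

  sl <- vector("list", max(n_count, 0L))
  props <- matrix(numeric(0), 0, n_props)
  plist <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    m <- readBin(con, "integer", 1, size = 4)
    if (length(m) == 0L) break
    i <- i + 1L
    pts <- readBin(con, "numeric", m * (3 + n_scalars), size = 4)
    pts <- matrix(pts, ncol = 3 + n_scalars, byrow = TRUE)
    sl[[i]] <- pts[, 1:3, drop = FALSE]
    plist[[i]] <- if (n_props > 0)
      readBin(con, "numeric", n_props, size = 4) else numeric(0)
    if (n_count > 0L && i >= n_count) break
  }
  sl <- sl[seq_len(i)]
  labels <- NULL
  properties <- list()
  if (n_props > 0) {
    pm <- do.call(rbind, plist[seq_len(i)])
    for (q in seq_len(n_props)) properties[[pnames[q]]] <- pm[, q]
    if ("bundle" %in% pnames) {
      labels <- as.integer(round(properties$bundle))
      properties$bundle <- NULL
    }
  }
  out <- tractogram(sl, labels = labels)
  attr(out, "properties") <- properties
  out
}
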