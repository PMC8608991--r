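#' Whole-brain tractogram container
#'
#' Streamlines are ordered 3-D polylines in world RAS millimetres. They are
#' stored packed: one \code{coords} matrix for all points plus an
#' \code{offsets} vector (1-based start index per streamline, with a final
#' sentinel of \code{nrow(coords) + 1}), which keeps per-point operations
#' vectorizable at the 200,000-streamline scale.
#'
#' @param streamlines list of n_i x 3 numeric matrices (n_i >= 2), or a
#'   packed list with \code{coords} and \code{offsets}.
#' @param labels optional integer per-streamline bundle label
#'   (0 = distractor, k > 0 = planted bundle id).
#' @return object of class \code{tractogram}.
#' @export
tractogram <- function(streamlines, labels = NULL) {
  if (is.list(streamlines) && !is.null(streamlines$coords)) {
    coords <- streamlines$coords
    offsets <- as.integer(streamlines$offsets)
  } else {
    npts <- vapply(streamlines, nrow, integer(1))
    if (any(npts < 2L)) stop("each streamline needs >= 2 points")
    coords <- do.call(rbind, streamlines)
    offsets <- as.integer(c(1L, 1L + cumsum(npts)))
  }
  if (!all(is.finite(coords))) stop("streamline points must be finite")
  n <- length(offsets) - 1L
  if (any(diff(offsets) < 2L)) stop("each streamline needs >= 2 points")
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have one entry per streamline")
  structure(list(coords = coords, offsets = offsets, labels = labels),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("<tractogram> %d streamlines, %d points%s\n",
              n_streamlines(x), nrow(x$coords),
              if (!is.null(x$labels))
                sprintf(", %d bundle-labelled", sum(x$labels > 0)) else ""))
  invisible(x)
}

#' @rdname tractogram
#' @param x a \code{tractogram}.
#' @export
n_streamlines <- function(x) length(x$offsets) - 1L

#' Extract one streamline as an n x 3 matrix
#' @param x a \code{tractogram}.
#' @param i streamline index.
#' @export
streamline <- function(x, i) {
  x$coords[x$offsets[i]:(x$offsets[i + 1L] - 1L), , drop = FALSE]
}

# per-point streamline id vector (length nrow(coords))
point_ids <- function(x) {
  rep.int(seq_len(n_streamlines(x)), diff(x$offsets))
}

#' Resample streamlines to a maximum step length
#'
#' Linear (arc-length) resampling so that consecutive vertices are at most
#' \code{step} mm apart; endpoints are preserved.
#' @param x a \code{tractogram}.
#' @param step maximum inter-vertex spacing in mm (> 0).
#' @return packed list with \code{coords} (m x 3) and \code{ids}
#'   (streamline index per resampled point).
#' @export
resample_points <- function(x, step) {
  if (step <= 0) stop("step must be > 0")
  n <- n_streamlines(x)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- streamline(x, i)
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2))
    L <- sum(seg)
    if (L == 0) { out[[i]] <- p[1, , drop = FALSE]; next }
    s <- c(0, cumsum(seg))
    m <- max(1L, ceiling(L / step))
    tt <- seq(0, L, length.out = m + 1L)
    out[[i]] <- cbind(approx(s, p[, 1], tt)$y,
                      approx(s, p[, 2], tt)$y,
                      approx(s, p[, 3], tt)$y)
  }
  npts <- vapply(out, nrow, integer(1))
  list(coords = do.call(rbind, out), ids = rep.int(seq_len(n), npts))
}
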