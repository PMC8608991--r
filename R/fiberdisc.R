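#' Streamline-by-patient binary connectivity matrix
#'
#' Entry (i, j) is 1 iff streamline i traverses patient j's (unioned
#' bilateral) VTA. Columns from empty VTAs are all-zero and flagged.
#'
#' @param tract a \code{tractogram}.
#' @param vtas list of per-patient \code{vta_mask}s (>= 1).
#' @param step resample step in mm (default half the voxel size).
#' @return binary matrix (streamlines x patients); attribute
#'   \code{empty_columns} lists flagged patients.
#' @export
connectivity_matrix <- function(tract, vtas, step = NULL) {
  if (length(vtas) < 1L) stop("need >= 1 patient VTA")
  n <- n_streamlines(tract)
  if (is.null(step)) {
    vol1 <- if (inherits(vtas[[1]], "vta_mask")) vtas[[1]]$mask else vtas[[1]]
    step <- vol1$voxel_size / 2
  }
  rs <- resample_points(tract, step)
  M <- matrix(0L, n, length(vtas))
  empty <- integer(0)
  for (j in seq_along(vtas)) {
    vol <- if (inherits(vtas[[j]], "vta_mask")) vtas[[j]]$mask else vtas[[j]]
    if (sum(vol$data != 0) == 0L) { empty <- c(empty, j); next }
    sel <- connected_fibers(tract, vol, resampled = rs)
    M[sel, j] <- 1L
  }
  structure(M, empty_columns = empty)
}

#' Discriminative t-score per streamline
#'
#' For each streamline, a two-sided two-sample t statistic comparing the
#' improvement values of patients whose VTAs the streamline traverses
#' ("connected") against the rest: positive t marks fibers predominantly
#' connected to better responders. Pooled-variance (Student) t by default;
#' Welch is available as an option. Scores are undefined (NA, excluded from
#' ranking) when either group is smaller than \code{min_per_group} or the
#' pooled variance is zero.
#'
#' @param M binary connectivity matrix (streamlines x patients).
#' @param outcomes improvement percentages, one per patient.
#' @param min_per_group minimum group size for a defined score.
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @return object of class \code{score_vector}: data.frame with \code{t},
#'   \code{n_connected}, \code{n_unconnected}.
#' @export
fiber_tscores <- function(M, outcomes, min_per_group = 2, welch = FALSE) {
  if (ncol(M) != length(outcomes))
    stop("outcomes length must equal patient count")
  y <- as.numeric(outcomes)
  n1 <- rowSums(M)
  n2 <- ncol(M) - n1
  s1 <- as.numeric(M %*% y)
  q1 <- as.numeric(M %*% y^2)
  s2 <- sum(y) - s1
  q2 <- sum(y^2) - q1
  m1 <- s1 / n1
  m2 <- s2 / n2
  v1 <- (q1 - s1^2 / n1) / (n1 - 1)
  v2 <- (q2 - s2^2 / n2) / (n2 - 1)
  v1 <- pmax(v1, 0)   # guard tiny negative values from cancellation
  v2 <- pmax(v2, 0)
  v1[n1 < 2] <- 0     # undersized groups are NA-ed below; keep sp2 finite
  v2[n2 < 2] <- 0
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2) * sqrt(1 / n1 + 1 / n2)
  }
  t <- (m1 - m2) / se
  bad <- n1 < min_per_group | n2 < min_per_group | !is.finite(t)
  t[bad] <- NA_real_
  structure(data.frame(t = t, n_connected = n1, n_unconnected = n2),
            class = c("score_vector", "data.frame"),
            min_per_group = min_per_group)
}

#' Retain the top fraction of discriminative fibers
#'
#' Ranks defined scores by signed t, descending (positive = connected to
#' responders), and returns the top \code{floor(fraction * n_defined)}
#' streamline indices; ties break towards the lower index. Undefined scores
#' never enter the pool.
#'
#' @param scores a \code{score_vector} (or numeric vector of t with NA for
#'   undefined).
#' @param fraction proportion to keep, in (0, 1]; default 0.10 (the "top
#'   10 percent" retention rule).
#' @param absolute rank by |t| instead of signed t.
#' @return integer streamline indices; attribute \code{flag} =
#'   \code{"no_defined_scores"} for an empty pool.
#' @export
top_fraction <- function(scores, fraction = 0.10, absolute = FALSE) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  t <- if (is.data.frame(scores)) scores$t else as.numeric(scores)
  defined <- which(!is.na(t))
  if (length(defined) == 0L)
    return(structure(integer(0), flag = "no_defined_scores"))
  key <- if (absolute) abs(t[defined]) else t[defined]
  k <- floor(fraction * length(defined))
  ord <- defined[order(-key, defined)]
  ord[seq_len(k)]
}

#' Precision and recall of a selection against the planted bundle
#'
#' @param selected streamline indices.
#' @param truth ground truth from \code{\link{make_tractogram}} (uses
#'   \code{truth$bundle}).
#' @return list with \code{precision} (NA + flag when the selection is
#'   empty) and \code{recall}.
#' @export
recovery_metrics <- function(selected, truth) {
  bundle <- truth$bundle
  hit <- sum(selected %in% bundle)
  list(precision = if (length(selected)) hit / length(selected) else
    NA_real_,
    recall = if (length(bundle)) hit / length(bundle) else NA_real_,
    flag = if (length(selected)) NA_character_ else "empty_selection")
}

#' Discriminative fibertract analysis
#'
#' The full procedure as one estimator: build the streamline-by-patient
#' connectivity matrix, score every streamline by the two-sample t contrast
#' of outcomes between connected and unconnected patients, and retain the
#' top fraction by signed t.
#'
#' @inheritParams connectivity_matrix
#' @inheritParams fiber_tscores
#' @inheritParams top_fraction
#' @return object of class \code{discfib} with elements \code{scores}
#'   (a \code{score_vector}), \code{selected} (indices), \code{matrix},
#'   \code{fraction}, \code{outcomes}.
#' @export
discriminative_fibertracts <- function(tract, vtas, outcomes,
                                       fraction = 0.10, min_per_group = 2,
                                       step = NULL, welch = FALSE,
                                       absolute = FALSE) {
  M <- connectivity_matrix(tract, vtas, step = step)
  sc <- fiber_tscores(M, outcomes, min_per_group = min_per_group,
                      welch = welch)
  sel <- top_fraction(sc, fraction = fraction, absolute = absolute)
  structure(list(scores = sc, selected = sel, matrix = M,
                 fraction = fraction, outcomes = outcomes,
                 tract = tract), class = "discfib")
}

#' @export
print.discfib <- function(x, ...) {
  nd <- sum(!is.na(x$scores$t))
  cat(sprintf(
    "<discfib> %d streamlines, %d with defined t, %d retained (top %.0f%%)\n",
    nrow(x$scores), nd, length(x$selected), 100 * x$fraction))
  invisible(x)
}

#' @export
summary.discfib <- function(object, ...) {
  t <- object$scores$t
  cat("Discriminative fibertract analysis\n")
  cat(sprintf("  streamlines: %d (defined scores: %d)\n", length(t),
              sum(!is.na(t))))
  cat(sprintf("  patients: %d; retention fraction: %.2f\n",
              ncol(object$matrix), object$fraction))
  if (any(!is.na(t)))
    cat(sprintf("  t range: [%.2f, %.2f]; retained: %d (min retained t %.2f)\n",
                min(t, na.rm = TRUE), max(t, na.rm = TRUE),
                length(object$selected),
                if (length(object$selected))
                  min(t[object$selected]) else NA_real_))
  invisible(object)
}

#' @export
coef.discfib <- function(object, ...) object$scores$t

#' @export
plot.discfib <- function(x, ...) {
  t <- x$scores$t
  graphics::hist(t[!is.na(t)], breaks = 30, col = "grey80",
                 main = "Discriminative fiber t-scores",
                 xlab = "t (positive = connected to responders)", ...)
  if (length(x$selected))
    graphics::abline(v = min(t[x$selected]), col = "red", lwd = 2)
  invisible(x)
}
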