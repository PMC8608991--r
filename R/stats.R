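#' One-way repeated-measures ANOVA across follow-up timepoints
#'
#' Within-subject decomposition of a complete patients x timepoints table:
#' SS_total = SS_subject + SS_time + SS_error, F = MS_time / MS_error with
#' (t-1, (t-1)(n-1)) degrees of freedom. Sphericity is assumed (no
#' Greenhouse-Geisser correction).
#'
#' @param Y numeric matrix or data.frame, patients in rows, timepoints in
#'   columns; complete (no NA).
#' @return list with \code{F}, \code{df_time}, \code{df_error}, \code{p},
#'   the sums of squares, and \code{flag} (\code{"zero_error_variance"}
#'   with F = NA when SS_error is 0).
#' @export
rm_anova <- function(Y) {
  Y <- as.matrix(Y)
  if (any(is.na(Y))) stop("table must be complete for rm-ANOVA")
  n <- nrow(Y); t <- ncol(Y)
  if (n < 2 || t < 2) stop("need >= 2 patients and >= 2 timepoints")
  grand <- mean(Y)
  ss_subj <- t * sum((rowMeans(Y) - grand)^2)
  ss_time <- n * sum((colMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_time
  df_time <- t - 1
  df_err <- (t - 1) * (n - 1)
  if (ss_err <= 1e-12 * max(ss_tot, 1)) {
    return(list(F = NA_real_, df_time = df_time, df_error = df_err,
                p = NA_real_, ss_time = ss_time, ss_subject = ss_subj,
                ss_error = ss_err, flag = "zero_error_variance"))
  }
  F <- (ss_time / df_time) / (ss_err / df_err)
  list(F = F, df_time = df_time, df_error = df_err,
       p = pf(F, df_time, df_err, lower.tail = FALSE),
       ss_time = ss_time, ss_subject = ss_subj, ss_error = ss_err,
       flag = NA_character_)
}

#' Tukey-Kramer pairwise post hoc comparisons of timepoint means
#'
#' Studentized-range comparisons using the rm-ANOVA error mean square and
#' its degrees of freedom: q = |mean_i - mean_j| / sqrt(MS_error / n),
#' adjusted p from the studentized range distribution with t means.
#'
#' @inheritParams rm_anova
#' @return data.frame with one row per ordered pair (i < j):
#'   \code{tp_a}, \code{tp_b}, \code{mean_diff} (b - a), \code{q},
#'   \code{p_adj}.
#' @export
tukey_kramer <- function(Y) {
  Y <- as.matrix(Y)
  a <- rm_anova(Y)
  if (!is.na(a$flag)) stop("post hocs undefined: zero error variance")
  n <- nrow(Y); t <- ncol(Y)
  ms_err <- a$ss_error / a$df_error
  mns <- colMeans(Y)
  nm <- colnames(Y)
  if (is.null(nm)) nm <- paste0("t", seq_len(t))
  pairs <- utils::combn(t, 2)
  res <- apply(pairs, 2, function(pr) {
    d <- mns[pr[2]] - mns[pr[1]]
    q <- abs(d) / sqrt(ms_err / n)
    data.frame(tp_a = nm[pr[1]], tp_b = nm[pr[2]], mean_diff = d, q = q,
               p_adj = ptukey(q, nmeans = t, df = a$df_error,
                              lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pearson linear regression
#'
#' Pearson r with its t-based two-sided p (n - 2 df) and the least-squares
#' slope and intercept.
#'
#' @param x predictor (nonzero variance, n >= 3).
#' @param y response (improvement percentages).
#' @return list with \code{r}, \code{p}, \code{slope}, \code{intercept},
#'   \code{n}.
#' @export
pearson_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (var(x) == 0) stop("x has zero variance")
  r <- cor(x, y)
  if (var(y) == 0) {
    # flat response: r undefined in the usual sense; report slope 0
    return(list(r = NA_real_, p = NA_real_, slope = 0,
                intercept = mean(y), n = n))
  }
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tt), n - 2)
  slope <- r * sd(y) / sd(x)
  list(r = r, p = p, slope = slope, intercept = mean(y) - slope * mean(x),
       n = n)
}
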