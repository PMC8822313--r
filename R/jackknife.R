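#' Leave-one-participant-out subsample curves
#'
#' The jackknife procedure for latency parameters replaces each
#' participant's noisy curve by the average of the other `N - 1`
#' participants' curves: subsample `i` is the bin-wise mean of all curves
#' except participant `i`. The mean of the subsample curves is identical to
#' the mean of the individual curves, but their variance is deflated by
#' `(N - 1)^2` — the reason the downstream F statistics must be corrected
#' (see [corrected_anova()]).
#'
#' @param curves Numeric matrix, participants in rows, bins in columns
#'   (`NA` allowed and propagated: a bin is `NA` in subsample `i` whenever
#'   any retained participant is `NA` there).
#' @return Matrix of the same shape: row `i` is the leave-`i`-out mean
#'   curve.
#' @examples
#' loo_subsamples(matrix(c(0.1, 0.2, 0.3), ncol = 1))  # 0.25, 0.20, 0.15
#' @export
loo_subsamples <- function(curves) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 2L) stop("need at least 2 participant curves to jackknife")
  na <- is.na(curves)
  x <- curves
  x[na] <- 0
  tot <- matrix(colSums(x), nrow = n, ncol = ncol(curves), byrow = TRUE)
  out <- (tot - x) / (n - 1)
  # subsample i is NA in a bin iff some *retained* curve is NA there
  na_cnt <- matrix(colSums(na), nrow = n, ncol = ncol(curves), byrow = TRUE)
  out[na_cnt - na > 0] <- NA
  dimnames(out) <- dimnames(curves)
  out
}

#' Extract a latency parameter from a curve within a region of interest
#'
#' Because each leave-one-out subsample curve is smooth relative to a single
#' participant's curve, simple landmark extraction is reliable: the minimum
#' (e.g. the bottom of a hazard dip), the maximum, or the first crossing of
#' a threshold inside a pre-registered region of interest.
#'
#' @param curve Numeric vector over bins (`NA` allowed).
#' @param roi Integer vector `c(t_lo, t_hi)`, inclusive bin range.
#' @param kind `"min"`, `"max"` or `"threshold"`.
#' @param theta Threshold value (required for `kind = "threshold"`).
#' @param direction For thresholds: `"up"` finds the first bin with
#'   `curve >= theta`, `"down"` the first with `curve <= theta`.
#' @param scheme Optional [binning_scheme()]; when given, `time` is the bin
#'   midpoint in ms, otherwise the bin index.
#' @return List with `bin` (index), `time`, `amplitude`. Ties in extrema
#'   and threshold crossings resolve to the earliest bin. `NA` amplitude
#'   with `bin = NA` when a threshold is never crossed.
#' @export
extract_parameter <- function(curve, roi, kind = c("min", "max", "threshold"),
                              theta = NULL, direction = c("up", "down"),
                              scheme = NULL) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  K <- length(curve)
  if (length(roi) != 2L || roi[1L] < 1L || roi[2L] > K || roi[1L] > roi[2L])
    stop("roi must be c(t_lo, t_hi) with 1 <= t_lo <= t_hi <= ", K)
  idx <- seq.int(roi[1L], roi[2L])
  seg <- curve[idx]
  if (all(is.na(seg))) stop("curve is entirely NA inside the roi")
  pick <- switch(kind,
    min = idx[which.min(seg)],     # which.min skips NA, earliest tie wins
    max = idx[which.max(seg)],
    threshold = {
      if (is.null(theta)) stop("kind = 'threshold' needs theta")
      hit <- if (direction == "up") !is.na(seg) & seg >= theta
             else !is.na(seg) & seg <= theta
      if (!any(hit)) NA_integer_ else idx[which(hit)[1L]]
    })
  if (is.na(pick))
    return(list(bin = NA_integer_, time = NA_real_, amplitude = NA_real_))
  tm <- if (is.null(scheme)) pick else bin_midpoints(scheme)[pick]
  list(bin = pick, time = tm, amplitude = curve[pick])
}

#' ANOVA on jackknife subsample values with the (N-1)^2 F-correction
#'
#' Runs a standard one-way ANOVA on parameter values extracted from
#' leave-one-out subsamples — repeated measures by default (conditions
#' crossed with subsamples, condition effect tested over the
#' condition-by-subsample residual), or independent groups — and then
#' divides the F statistic by `(N - 1)^2`, recomputing the p value from the
#' F distribution at unchanged degrees of freedom. The correction undoes
#' the variance deflation of subsample averaging: for any statistic that is
#' linear in the participant curves, the corrected F equals the F from the
#' same ANOVA on the individual participants' values exactly.
#'
#' @param params Numeric matrix of extracted parameter values, subsamples
#'   in rows, conditions in columns (complete: one value per cell).
#' @param design `"within"` (repeated measures, default) or `"between"`
#'   (each column an independent group of `N` subsamples).
#' @return Data frame with `F_uncorrected`, `F`, `df1`, `df2`, `p`, `N`.
#' @examples
#' prm <- cbind(a = c(1.1, 1.3, 1.2), b = c(1.4, 1.6, 1.4))
#' corrected_anova(prm)
#' @export
corrected_anova <- function(params, design = c("within", "between")) {
  design <- match.arg(design)
  params <- as.matrix(params)
  n <- nrow(params); k <- ncol(params)
  if (k < 2L) stop("need at least 2 conditions")
  if (n < 2L) stop("need at least 2 subsamples per condition")
  if (anyNA(params))
    stop("incomplete parameter table: every subsample x condition cell ",
         "must have a value")
  long <- data.frame(
    value = as.vector(params),
    condition = factor(rep(colnames2(params), each = n)),
    subsample = factor(rep(seq_len(n), times = k)))
  if (design == "within") {
    aov_fit <- stats::aov(value ~ condition + Error(subsample / condition),
                          data = long)
    tab <- summary(aov_fit)[["Error: subsample:condition"]][[1L]]
    rownames(tab) <- trimws(rownames(tab))
    Fu <- tab["condition", "F value"]
    df1 <- tab["condition", "Df"]
    df2 <- tab["Residuals", "Df"]
  } else {
    aov_fit <- stats::aov(value ~ condition, data = long)
    tab <- summary(aov_fit)[[1L]]
    rownames(tab) <- trimws(rownames(tab))
    Fu <- tab["condition", "F value"]
    df1 <- tab["condition", "Df"]
    df2 <- tab["Residuals", "Df"]
  }
  # An effect sum of squares at rounding-noise level (identical condition
  # means) must report F = 0, not a ratio of float residuals.
  ss_scale <- sum(long$value^2) + 1e-300
  if (tab["condition", "Sum Sq"] <= 1e-12 * ss_scale) Fu <- 0
  Fc <- Fu / (n - 1)^2
  data.frame(F_uncorrected = Fu, F = Fc, df1 = df1, df2 = df2,
             p = stats::pf(Fc, df1, df2, lower.tail = FALSE), N = n)
}

#' @keywords internal
colnames2 <- function(m) {
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(m)))
  cn
}

#' End-to-end jackknife test of a latency parameter
#'
#' Convenience wrapper: builds leave-one-out subsample curves per condition,
#' extracts the requested parameter inside the region of interest from each
#' subsample curve, and runs the corrected ANOVA on the chosen landmark
#' coordinate.
#'
#' @param condition_curves Named list of participant-by-bin matrices, one
#'   per condition, identical row order (participants) and bin count.
#' @param roi,kind,theta,direction,scheme Passed to [extract_parameter()].
#' @param on `"time"` or `"amplitude"`: which coordinate enters the ANOVA.
#' @param design Passed to [corrected_anova()].
#' @return List with `params` (subsample-by-condition matrix) and `anova`.
#' @export
jackknife_test <- function(condition_curves, roi, kind = "min",
                           theta = NULL, direction = "up", scheme = NULL,
                           on = c("time", "amplitude"),
                           design = "within") {
  on <- match.arg(on)
  if (length(condition_curves) < 2L) stop("need at least 2 conditions")
  dims <- vapply(condition_curves, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all condition matrices must share participants and bins")
  params <- vapply(condition_curves, function(m) {
    sub <- loo_subsamples(m)
    apply(sub, 1L, function(cv)
      extract_parameter(cv, roi, kind, theta, direction, scheme)[[on]])
  }, numeric(dims[1L, 1L]))
  list(params = params, anova = corrected_anova(params, design = design))
}
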