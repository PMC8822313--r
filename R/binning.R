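#' Binning scheme for discrete-time analysis
#'
#' A binning scheme partitions the observation window `(0, censor_time]` into
#' `K` contiguous half-open bins `(edges[t-1], edges[t]]`, `t = 1..K`. The
#' last edge is the censoring time: trials without a response by then are
#' right-censored in bin `K`. Bin membership is right-closed, so a response
#' time exactly on an edge belongs to the earlier bin (rt = 400 with 40-ms
#' bins falls in bin 10).
#'
#' @param edges Numeric vector of strictly increasing bin edges, starting at
#'   0; the last edge is the censoring time in milliseconds.
#' @return An object of class `"binning_scheme"` with elements `edges`,
#'   `n_bins`, `censor_time`.
#' @seealso [uniform_bins()] for the common equal-width case.
#' @examples
#' uniform_bins(40, 600)              # Fifteen 40-ms bins up to 600 ms
#' binning_scheme(c(0, 100, 300, 600)) # unequal widths are allowed
#' @export
binning_scheme <- function(edges) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L)
    stop("a binning scheme needs at least two edges (0 and the censoring time)")
  if (anyNA(edges)) stop("bin edges must not contain NA")
  if (edges[1L] != 0) stop("the first bin edge must be 0")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  structure(
    list(edges = edges,
         n_bins = length(edges) - 1L,
         censor_time = edges[length(edges)]),
    class = "binning_scheme")
}

#' @rdname binning_scheme
#' @param width Bin width in milliseconds.
#' @param censor_time Fixed censoring time (response deadline) in
#'   milliseconds; must be a multiple of `width`.
#' @export
uniform_bins <- function(width, censor_time) {
  if (width <= 0) stop("bin width must be positive")
  k <- censor_time / width
  if (abs(k - round(k)) > 1e-8)
    stop("censoring time must be a whole number of bin widths")
  binning_scheme(seq(0, censor_time, by = width))
}

#' @export
print.binning_scheme <- function(x, ...) {
  w <- diff(x$edges)
  cat(sprintf("Binning scheme: %d bins on (0, %g] ms", x$n_bins, x$censor_time))
  if (length(unique(w)) == 1L) cat(sprintf(", width %g ms", w[1L]))
  cat("\n")
  invisible(x)
}

#' @rdname binning_scheme
#' @param x A `binning_scheme`.
#' @export
n_bins <- function(x) {
  stopifnot(inherits(x, "binning_scheme"))
  x$n_bins
}

#' Bin midpoints and interval labels
#'
#' @param scheme A [binning_scheme()].
#' @return `bin_midpoints()`: numeric vector of bin-center times (ms);
#'   `bin_labels()`: interval strings in the `"(a,b]"` notation.
#' @export
bin_midpoints <- function(scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  (scheme$edges[-1L] + scheme$edges[-length(scheme$edges)]) / 2
}

#' @rdname bin_midpoints
#' @export
bin_labels <- function(scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  e <- scheme$edges
  sprintf("(%g,%g]", e[-length(e)], e[-1L])
}

#' Map response times to bin indices
#'
#' Assigns each response time to its half-open bin `(edges[t-1], edges[t]]`.
#' `NA` encodes a right-censored trial (no response by the deadline) and maps
#' to `NA`, understood as censored at bin `K`. Times at or below 0, or above
#' the censoring time, are rejected: late responses must be converted to
#' censored explicitly at ingestion (see [read_trials()]), never silently
#' re-binned.
#'
#' @param rt Numeric vector of response times in milliseconds; `NA` =
#'   censored.
#' @param scheme A [binning_scheme()].
#' @return Integer vector of bin indices in `1..K`; `NA` for censored trials.
#' @examples
#' s <- uniform_bins(40, 600)
#' assign_bin(c(365, 400, NA), s)  # 10, 10 (right-closed edge), NA
#' @export
assign_bin <- function(rt, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  rt <- as.numeric(rt)
  obs <- !is.na(rt)
  if (any(rt[obs] <= 0))
    stop("response times must be positive (got rt <= 0)")
  if (any(rt[obs] > scheme$censor_time))
    stop("response times exceed the censoring time ", scheme$censor_time,
         " ms; convert late responses to censored (NA) before binning")
  out <- rep(NA_integer_, length(rt))
  # left.open intervals (edges[t-1], edges[t]] match the right-closed scheme
  out[obs] <- findInterval(rt[obs], scheme$edges, left.open = TRUE)
  out
}

#' @keywords internal
same_scheme <- function(a, b) {
  isTRUE(all.equal(a$edges, b$edges))
}
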