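#' Tabulate trials into per-bin counts and risk sets
#'
#' First stage of life-table construction: count, for each bin, the emitted
#' responses `E` (split into correct and error), the right-censored trials
#' `rc`, and the risk set `RS` — the number of trials still response-free at
#' the start of the bin. Trials censored at the deadline (rt = `NA`) sit in
#' the risk set of every bin and are counted as `rc` in bin `K`; trials with
#' an explicit earlier censor time (e.g. equipment errors) may censor in
#' interior bins via the `censor_bin` column.
#'
#' All trials must belong to one participant-by-condition stratum; use
#' [life_table_by()] to split a full data set.
#'
#' @param trials Data frame with columns `rt` (milliseconds, `NA` =
#'   censored) and `correct` (0/1, `NA` exactly when `rt` is `NA`).
#'   An optional integer column `censor_bin` gives an earlier censoring bin
#'   for trials with `rt = NA`.
#' @param scheme A [binning_scheme()].
#' @return Data frame with one row per bin: `t`, `E`, `rc`, `RS`,
#'   `n_correct`, `n_error`.
#' @export
tabulate_trials <- function(trials, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  trials <- validate_trials(trials, scheme)
  if (nrow(trials) == 0L) stop("no trials to tabulate")
  K <- scheme$n_bins
  bin <- assign_bin(trials$rt, scheme)
  cens <- is.na(bin)
  cbin <- rep(NA_integer_, nrow(trials))
  if (!is.null(trials$censor_bin)) {
    cbin <- as.integer(trials$censor_bin)
    if (any(!is.na(cbin) & !cens))
      stop("censor_bin may only be set on censored trials (rt = NA)")
    if (any(!is.na(cbin) & (cbin < 1L | cbin > K)))
      stop("censor_bin out of range 1..K")
  }
  cbin[cens & is.na(cbin)] <- K
  E  <- tabulate(bin[!cens], nbins = K)
  rc <- tabulate(cbin[cens], nbins = K)
  n_correct <- tabulate(bin[!cens & trials$correct == 1], nbins = K)
  RS <- nrow(trials) - cumsum(c(0L, (E + rc)[-K]))
  data.frame(t = seq_len(K), E = E, rc = rc, RS = RS,
             n_correct = n_correct, n_error = E - n_correct)
}

#' @keywords internal
validate_trials <- function(trials, scheme = NULL) {
  if (!is.data.frame(trials)) stop("trials must be a data frame")
  if (!all(c("rt", "correct") %in% names(trials)))
    stop("trials must have columns 'rt' and 'correct'")
  cens <- is.na(trials$rt)
  if (any(is.na(trials$correct) != cens))
    stop("'correct' must be missing exactly when 'rt' is censored (NA)")
  ok <- is.na(trials$correct) | trials$correct %in% c(0, 1)
  if (!all(ok)) stop("'correct' must be 0 or 1")
  if (any(trials$rt[!cens] <= 0)) stop("response times must be positive")
  if (!is.null(scheme) && any(trials$rt[!cens] > scheme$censor_time))
    stop("response times exceed the censoring time; ",
         "convert late responses to censored first (see read_trials)")
  trials
}

#' Life table for one participant-by-condition stratum
#'
#' Builds the life table and estimates the four descriptive functions of
#' discrete-time event history analysis with their standard errors:
#' \describe{
#'   \item{hazard}{\eqn{h(t) = P(T = t \mid T \ge t)}, estimated as
#'     `E(t)/RS(t)`: the conditional probability that the response occurs in
#'     bin `t` given it has not occurred before.}
#'   \item{survivor}{\eqn{S(t) = P(T > t) = \prod_{i \le t} (1 - h(i))}.}
#'   \item{probability mass}{\eqn{P(t) = P(T = t) = h(t)\,S(t-1)}.}
#'   \item{conditional accuracy}{\eqn{ca(t) = P(\mathrm{correct} \mid T = t)},
#'     estimated as `n_correct(t)/E(t)` — the micro-level speed-accuracy
#'     trade-off. `NA` when no response was emitted in the bin.}
#' }
#' Standard errors for `h`, `P` and `ca` use the binomial formula
#' \eqn{\sqrt{p(1-p)/N}} with `N` equal to `RS(t)`, `RS(1)` and `E(t)`
#' respectively. `se_S` uses Greenwood's formula
#' \eqn{S(t)\sqrt{\sum_{i\le t} E(i) / (RS(i)(RS(i)-E(i)))}}.
#'
#' Right-censored trials stay in the risk set of every bin they survive,
#' so the estimates use all trials without the sampling bias that discarding
#' censored observations would introduce. Bins whose risk set is exhausted
#' (`RS = 0`) have `NA` estimates, and `S` propagates `NA` from there on.
#'
#' @param trials Data frame of one stratum's trials; see [tabulate_trials()].
#' @param scheme A [binning_scheme()].
#' @param counts Alternatively, precomputed per-bin counts (a data frame with
#'   columns `E`, `rc`, `n_correct`, `n_error`), e.g. a published life
#'   table's count columns. Supply either `trials` or `counts`.
#' @return A data frame of class `"life_table"` with one row per bin and
#'   columns `bin` (interval label), `t`, `rc`, `E`, `RS`, `h`, `se_h`, `S`,
#'   `se_S`, `P`, `se_P`, `n_correct`, `n_error`, `ca`, `se_ca`, carrying the
#'   scheme as attribute `"scheme"`. Values are kept at full precision;
#'   see [format_life_table()] for display rounding.
#' @examples
#' s <- uniform_bins(40, 600)
#' trials <- data.frame(rt = c(50, 55, 130, NA), correct = c(1, 0, 1, NA))
#' lt <- life_table(trials, s)
#' lt$h          # 0, 0.5, 0, 0.333..., then 0 with rc in bin 15
#' cdf(lt)       # F(t) = 1 - S(t)
#' @export
life_table <- function(trials = NULL, scheme, counts = NULL) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (is.null(counts)) {
    if (is.null(trials)) stop("supply either trials or counts")
    counts <- tabulate_trials(trials, scheme)
  } else {
    counts <- as.data.frame(counts)
    need <- c("E", "rc", "n_correct", "n_error")
    if (!all(need %in% names(counts)))
      stop("counts must have columns ", paste(need, collapse = ", "))
    K <- scheme$n_bins
    if (nrow(counts) != K) stop("counts must have one row per bin")
    if (any(counts$n_correct + counts$n_error != counts$E))
      stop("n_correct + n_error must equal E in every bin")
    if (any(counts[need] < 0)) stop("counts must be non-negative")
    counts$t <- seq_len(K)
    counts$RS <- sum(counts$E + counts$rc) -
      cumsum(c(0L, (counts$E + counts$rc)[-K]))
  }
  estimate_lifetable(counts, scheme)
}

#' @keywords internal
estimate_lifetable <- function(counts, scheme) {
  K <- scheme$n_bins
  E <- counts$E; RS <- counts$RS; rc <- counts$rc
  h <- ifelse(RS > 0, E / RS, NA_real_)
  S <- cumprod(1 - h)                   # NA propagates once RS hits 0
  S_prev <- c(1, S[-K])
  P <- h * S_prev
  se_h <- ifelse(RS > 0, sqrt(h * (1 - h) / RS), NA_real_)
  se_P <- ifelse(RS > 0, sqrt(P * (1 - P) / RS[1L]), NA_real_)
  ca <- ifelse(E > 0, counts$n_correct / E, NA_real_)
  se_ca <- ifelse(E > 0, sqrt(ca * (1 - ca) / E), NA_real_)
  # Greenwood variance term is 0 in bins with E = 0; undefined once RS = E
  gterm <- ifelse(RS > 0 & RS > E, E / (RS * (RS - E)),
                  ifelse(RS > 0 & E == RS, NA_real_, NA_real_))
  gterm[RS > 0 & E == 0] <- 0
  se_S <- S * sqrt(cumsum(gterm))
  out <- data.frame(
    bin = bin_labels(scheme), t = counts$t, rc = rc, E = E, RS = RS,
    h = h, se_h = se_h, S = S, se_S = se_S, P = P, se_P = se_P,
    n_correct = counts$n_correct, n_error = counts$n_error,
    ca = ca, se_ca = se_ca)
  structure(out, scheme = scheme, class = c("life_table", "data.frame"))
}

#' Cumulative distribution accessor
#'
#' `F(t) = P(T <= t) = 1 - S(t)` for a fitted life table.
#'
#' @param lt A [life_table()].
#' @return Numeric vector of length `K`.
#' @export
cdf <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  1 - lt$S
}

#' @export
print.life_table <- function(x, digits = 3, ...) {
  cat(sprintf("Discrete-time life table: %d bins, %d trials (%d censored)\n",
              nrow(x), x$RS[1L], sum(x$rc)))
  print.data.frame(format_life_table(x, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Round a life table for display or export
#'
#' Estimates are held at full precision internally; this formatting layer
#' rounds probabilities and standard errors for reporting (3 decimals by
#' default; conditional accuracy to 2, matching common reporting practice).
#'
#' @param lt A [life_table()].
#' @param digits Decimal places for probabilities and standard errors.
#' @param ca_digits Decimal places for `ca`.
#' @return A plain data frame with rounded columns.
#' @export
format_life_table <- function(lt, digits = 3, ca_digits = 2) {
  stopifnot(inherits(lt, "life_table"))
  out <- as.data.frame(lt)
  for (col in c("h", "se_h", "S", "se_S", "P", "se_P", "se_ca"))
    out[[col]] <- round(out[[col]], digits)
  out$ca <- round(out$ca, ca_digits)
  out
}

#' Life tables for every participant-by-condition stratum
#'
#' Splits a trial data set by the given stratification columns and builds one
#' life table per stratum. Per-participant stratification is the default
#' analysis unit for small-N designs; pooling across participants must be an
#' explicit choice (drop `"participant"` from `by`).
#'
#' @param trials Data frame with `rt`, `correct` and the `by` columns.
#' @param scheme A [binning_scheme()].
#' @param by Character vector of stratification column names.
#' @return Named list of [life_table()] objects; names are the
#'   dot-separated stratum labels.
#' @export
life_table_by <- function(trials, scheme, by = "participant") {
  if (!all(by %in% names(trials)))
    stop("missing stratification columns: ",
         paste(setdiff(by, names(trials)), collapse = ", "))
  idx <- interaction(trials[by], drop = TRUE, sep = ".")
  lapply(split(trials, idx), life_table, scheme = scheme)
}

#' Per-bin difference between two estimated curves
#'
#' Compares two life tables bin by bin on the hazard or conditional-accuracy
#' scale — the recommended alternative to averaging quantiles, since it keeps
#' effects aligned to the experiment's time axis. The difference is
#' `a(t) - b(t)` with standard error `sqrt(se_a^2 + se_b^2)`; `NA` wherever
#' either input is `NA`.
#'
#' @param a,b [life_table()] objects on the same binning scheme.
#' @param which `"h"` or `"ca"`.
#' @return Data frame with columns `t`, `diff`, `se_diff`.
#' @export
diff_curves <- function(a, b, which = c("h", "ca")) {
  which <- match.arg(which)
  stopifnot(inherits(a, "life_table"), inherits(b, "life_table"))
  if (!same_scheme(attr(a, "scheme"), attr(b, "scheme")))
    stop("life tables use different binning schemes")
  se_col <- paste0("se_", which)
  data.frame(t = a$t,
             diff = a[[which]] - b[[which]],
             se_diff = sqrt(a[[se_col]]^2 + b[[se_col]]^2))
}
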