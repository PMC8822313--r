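#' Discrete hazard + conditional-accuracy profile
#'
#' A discrete profile specifies a population of response times directly by
#' its per-bin hazard probabilities `h(t)` and, optionally, the per-bin
#' probability that an emitted response is correct, `ca(t)`. The hazard
#' sequence completely determines the waiting-time distribution; once a bin
#' reaches `h = 1` every trial has responded and later values are unused.
#'
#' @param h Numeric vector of `K` hazard probabilities in `[0, 1]`.
#' @param ca Numeric vector of `K` conditional accuracies in `[0, 1]`, or
#'   `NA` for bins that can never emit a response (`h = 0`); default all 1.
#' @param scheme A [binning_scheme()] with `K` bins.
#' @return Object of class `"discrete_profile"` with elements `h`, `ca`,
#'   `scheme` plus the implied `S`, `P` and censored fraction.
#' @export
discrete_profile <- function(h, ca = NULL, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  K <- scheme$n_bins
  if (length(h) != K) stop("h must have one value per bin")
  if (anyNA(h) || any(h < 0 | h > 1)) stop("h values must lie in [0, 1]")
  if (is.null(ca)) ca <- rep(1, K)
  if (length(ca) != K) stop("ca must have one value per bin")
  if (any(!is.na(ca) & (ca < 0 | ca > 1)))
    stop("ca values must lie in [0, 1] or be NA")
  if (any(is.na(ca) & h > 0))
    stop("ca is NA in a bin with positive hazard")
  S <- cumprod(1 - h)
  structure(list(h = h, ca = ca, scheme = scheme,
                 S = S, P = h * c(1, S[-K]), censored_fraction = S[K]),
            class = "discrete_profile")
}

#' Sample trials from a discrete hazard profile
#'
#' Simulates the generative story of discrete-time hazard directly: each
#' trial walks bins `1..K`; given survival to bin `t` the response occurs
#' there with probability `h(t)`, and an occurring response is correct with
#' probability `ca(t)`. Trials without a response by bin `K` are censored.
#' Response times are drawn uniformly inside the event bin, so the sample
#' is a valid trial table in milliseconds for any downstream analysis.
#'
#' @param profile A [discrete_profile()].
#' @param n Number of trials.
#' @param seed Optional integer seed; the same seed reproduces the sample.
#' @return Data frame with columns `rt` (ms, `NA` = censored) and
#'   `correct` (0/1, `NA` when censored).
#' @export
sample_discrete <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "discrete_profile"))
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  K <- profile$scheme$n_bins
  edges <- profile$scheme$edges
  # event bin via inverse-cdf on the implied mass function (equivalent to,
  # and much faster than, the per-bin Bernoulli walk)
  pmf <- c(profile$P, profile$censored_fraction)
  bin <- sample.int(K + 1L, n, replace = TRUE, prob = pmf)
  cens <- bin == K + 1L
  rt <- rep(NA_real_, n)
  rt[!cens] <- stats::runif(sum(!cens),
                            min = edges[bin[!cens]],
                            max = edges[bin[!cens] + 1L])
  correct <- rep(NA_integer_, n)
  correct[!cens] <- stats::rbinom(sum(!cens), 1L, profile$ca[bin[!cens]])
  data.frame(rt = rt, correct = correct)
}

#' Parametric continuous waiting-time families
#'
#' Wraps the four classic waiting-time families — exponential, Weibull,
#' gamma and log-normal — with their density, survivor and hazard-rate
#' functions \eqn{\lambda(t) = f(t) / S(t)}. Their hazard shapes span the
#' qualitatively different regimes a response-time model can produce: flat
#' (exponential), monotonically increasing (Weibull with shape > 1), rising
#' to an asymptote (gamma with shape > 1), and peaked with a slow decay
#' (log-normal).
#'
#' @param family `"exponential"`, `"weibull"`, `"gamma"` or `"lognormal"`.
#' @param ... Family parameters: `rate` (exponential); `shape`, `scale`
#'   (Weibull); `shape`, `rate` (gamma); `meanlog`, `sdlog` (log-normal).
#' @return Object of class `"parametric_family"` with functions `f`, `S`,
#'   `F`, `Q` (quantile) and `r` (sampler).
#' @examples
#' fam <- parametric_family("weibull", shape = 2, scale = 400)
#' hazard_curve(fam, c(100, 200, 400))
#' @export
parametric_family <- function(family = c("exponential", "weibull",
                                         "gamma", "lognormal"), ...) {
  family <- match.arg(family)
  p <- list(...)
  need <- function(nm) {
    if (!all(nm %in% names(p)))
      stop(family, " family needs parameters: ", paste(nm, collapse = ", "))
    if (any(vapply(p[nm], function(v) !is.numeric(v) || v <= 0, TRUE)))
      stop(family, " parameters must be positive")
  }
  fns <- switch(family,
    exponential = {
      need("rate")
      list(f = function(t) stats::dexp(t, p$rate),
           S = function(t) stats::pexp(t, p$rate, lower.tail = FALSE),
           F = function(t) stats::pexp(t, p$rate),
           Q = function(q) stats::qexp(q, p$rate),
           r = function(n) stats::rexp(n, p$rate))
    },
    weibull = {
      need(c("shape", "scale"))
      list(f = function(t) stats::dweibull(t, p$shape, p$scale),
           S = function(t) stats::pweibull(t, p$shape, p$scale,
                                           lower.tail = FALSE),
           F = function(t) stats::pweibull(t, p$shape, p$scale),
           Q = function(q) stats::qweibull(q, p$shape, p$scale),
           r = function(n) stats::rweibull(n, p$shape, p$scale))
    },
    gamma = {
      need(c("shape", "rate"))
      list(f = function(t) stats::dgamma(t, p$shape, p$rate),
           S = function(t) stats::pgamma(t, p$shape, p$rate,
                                         lower.tail = FALSE),
           F = function(t) stats::pgamma(t, p$shape, p$rate),
           Q = function(q) stats::qgamma(q, p$shape, p$rate),
           r = function(n) stats::rgamma(n, p$shape, p$rate))
    },
    lognormal = {
      if (!all(c("meanlog", "sdlog") %in% names(p)))
        stop("lognormal family needs parameters: meanlog, sdlog")
      if (p$sdlog <= 0) stop("sdlog must be positive")
      list(f = function(t) stats::dlnorm(t, p$meanlog, p$sdlog),
           S = function(t) stats::plnorm(t, p$meanlog, p$sdlog,
                                         lower.tail = FALSE),
           F = function(t) stats::plnorm(t, p$meanlog, p$sdlog),
           Q = function(q) stats::qlnorm(q, p$meanlog, p$sdlog),
           r = function(n) stats::rlnorm(n, p$meanlog, p$sdlog))
    })
  structure(c(list(family = family, parameters = p), fns),
            class = "parametric_family")
}

#' Continuous-time hazard rate of a parametric family
#'
#' \eqn{\lambda(t) = f(t)/S(t)}, evaluated with the survivor function on
#' the `lower.tail = FALSE` path so the ratio stays accurate deep in the
#' right tail where `F(t)` is numerically 1.
#'
#' @param fam A [parametric_family()].
#' @param t Positive time grid (ms).
#' @return Numeric vector of hazard rates (events per ms).
#' @export
hazard_curve <- function(fam, t) {
  stopifnot(inherits(fam, "parametric_family"))
  if (any(t <= 0)) stop("t must be positive")
  fam$f(t) / fam$S(t)
}

#' Sample right-censored trials from a parametric family
#'
#' Draws i.i.d. response times from the family and censors every draw
#' beyond the fixed response deadline — the singly-Type-I censoring design
#' recommended for response-time experiments. All responses are coded
#' correct (continuous families model latency only); recode `correct`
#' downstream if an accuracy process is needed.
#'
#' @param fam A [parametric_family()].
#' @param n Number of trials.
#' @param deadline Censoring time in ms (`Inf` for no censoring).
#' @param seed Optional integer seed.
#' @return Data frame with columns `rt`, `correct` as in
#'   [sample_discrete()].
#' @export
sample_continuous <- function(fam, n, deadline, seed = NULL) {
  stopifnot(inherits(fam, "parametric_family"))
  if (n < 1) stop("n must be at least 1")
  if (deadline <= 0) stop("deadline must be positive")
  if (!is.null(seed)) set.seed(seed)
  x <- fam$r(n)
  cens <- x > deadline
  data.frame(rt = ifelse(cens, NA_real_, x),
             correct = ifelse(cens, NA_integer_, 1L))
}

#' True discrete hazard implied by a continuous family and a binning scheme
#'
#' Treating the binned data as interval-censored, the population discrete
#' hazard of bin `t = (a, b]` is
#' \deqn{h(t) = \frac{S(a) - S(b)}{S(a)},}
#' the conditional probability of an event inside the bin given survival to
#' its start. This is the exact target that life-table estimates from
#' binned samples of the family converge to.
#'
#' @param fam A [parametric_family()].
#' @param scheme A [binning_scheme()].
#' @return Numeric vector of `K` discrete hazard probabilities (`NA` from
#'   the first bin whose start the family cannot survive to).
#' @examples
#' # exponential: constant discrete hazard 1 - exp(-rate * width)
#' discretize_true_hazard(parametric_family("exponential", rate = 1/200),
#'                        uniform_bins(40, 600))
#' @export
discretize_true_hazard <- function(fam, scheme) {
  stopifnot(inherits(fam, "parametric_family"),
            inherits(scheme, "binning_scheme"))
  e <- scheme$edges
  S_lo <- fam$S(e[-length(e)])
  S_hi <- fam$S(e[-1L])
  ifelse(S_lo > 0, (S_lo - S_hi) / S_lo, NA_real_)
}

#' Sample trials from a discrete-time hazard regression model
#'
#' Generates trials whose per-bin hazard follows the linked linear model
#' \deqn{g[h_i(t)] = \alpha_0 + \alpha_1 (t-c) + \dots + \alpha_d (t-c)^d +
#'   x_i^\top \beta + (t-c)\, x_i^\top \gamma,}
#' i.e. a polynomial baseline plus covariate shifts and optional
#' covariate-by-time interactions on the link scale. Each trial walks the
#' bins with its own hazard sequence; trials surviving bin `K` are censored.
#' This is the generative counterpart of [fit_hazard_model()], used for
#' parameter-recovery validation.
#'
#' @param alpha Numeric vector `(alpha_0, ..., alpha_d)` of baseline
#'   polynomial coefficients in centered time.
#' @param beta Named numeric vector of covariate coefficients (names =
#'   columns of `X`); empty for a pure baseline.
#' @param gamma Named numeric vector of covariate-by-time interaction
#'   coefficients; default none.
#' @param X Data frame of trial-level covariates, one row per trial.
#' @param scheme A [binning_scheme()].
#' @param center Time centering constant `c` (default 1).
#' @param link `"cloglog"` or `"logit"`.
#' @param seed Optional integer seed.
#' @return Data frame with `rt`, `correct` (all responses coded correct)
#'   and the covariate columns.
#' @export
sample_hazard_model <- function(alpha, beta = numeric(), gamma = numeric(),
                                X, scheme, center = 1,
                                link = c("cloglog", "logit"), seed = NULL) {
  link <- match.arg(link)
  stopifnot(inherits(scheme, "binning_scheme"))
  if (length(beta) && !all(names(beta) %in% names(X)))
    stop("beta names must match columns of X")
  if (length(gamma) && !all(names(gamma) %in% names(X)))
    stop("gamma names must match columns of X")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  K <- scheme$n_bins
  tc <- seq_len(K) - center
  base <- vapply(tc, function(z)
    sum(alpha * z^(seq_along(alpha) - 1L)), numeric(1))
  shift <- rep(0, n)
  for (nm in names(beta)) shift <- shift + beta[[nm]] * X[[nm]]
  slope <- rep(0, n)
  for (nm in names(gamma)) slope <- slope + gamma[[nm]] * X[[nm]]
  inv <- link_fun(link)$inv
  # n x K hazard matrix, then one geometric-style walk per trial
  eta <- outer(shift, base, `+`) + outer(slope, tc)
  h <- pmin(pmax(inv(eta), 0), 1)
  u <- matrix(stats::runif(n * K), n, K)
  hit <- u < h
  first <- apply(hit, 1L, function(r) if (any(r)) which(r)[1L] else NA_integer_)
  cens <- is.na(first)
  rt <- rep(NA_real_, n)
  rt[!cens] <- stats::runif(sum(!cens),
                            min = scheme$edges[first[!cens]],
                            max = scheme$edges[first[!cens] + 1L])
  out <- data.frame(rt = rt,
                    correct = ifelse(cens, NA_integer_, 1L))
  cbind(out, X)
}
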