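#' Complementary log-log and logit links
#'
#' The discrete-time hazard model links the per-bin event probability to a
#' linear predictor. The complementary log-log link,
#' `cloglog(p) = ln(-ln(1 - p))`, is preferred for response times because
#' events can occur at any instant within a bin; its exponentiated
#' coefficients are hazard ratios. The logit link is the familiar logistic
#' alternative.
#'
#' @param p Probability strictly inside (0, 1).
#' @param x Real number (linear-predictor scale).
#' @return `cloglog()`/`logit()`: the linked value; `inv_cloglog()`/
#'   `inv_logit()`: the probability.
#' @examples
#' cloglog(1 - exp(-1))   # 0
#' inv_cloglog(cloglog(0.3))
#' @export
cloglog <- function(p) {
  check_prob(p)
  log(-log1p(-p))
}

#' @rdname cloglog
#' @export
inv_cloglog <- function(x) -expm1(-exp(x))

#' @rdname cloglog
#' @export
logit <- function(p) {
  check_prob(p)
  log(p / (1 - p))
}

#' @rdname cloglog
#' @export
inv_logit <- function(x) stats::plogis(x)

#' @keywords internal
check_prob <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p >= 1))
    stop("probabilities must lie strictly inside (0, 1)")
  invisible(p)
}

#' @keywords internal
link_fun <- function(link) {
  switch(link,
         cloglog = list(fun = cloglog, inv = inv_cloglog),
         logit = list(fun = logit, inv = inv_logit),
         stop("unknown link: ", link))
}

#' Expand trials into person-trial-bin format
#'
#' Hazard regression works on the long "person-trial-bin" layout: one row
#' per trial per bin the trial is at risk in. A trial whose response falls
#' in bin `t` contributes `t` rows with the event indicator 1 only in the
#' last; a trial censored at bin `c` contributes `c` rows, all 0. With this
#' layout the discrete-time hazard model is an ordinary binomial GLM of the
#' event indicator.
#'
#' @param trials Data frame with `rt` and `correct` (see [life_table()]);
#'   any columns named in `covariates` are carried onto every row of their
#'   trial.
#' @param scheme A [binning_scheme()].
#' @param covariates Character vector of trial-level covariate columns to
#'   carry along.
#' @return Data frame with columns `trial`, `t`, `event`, plus covariates
#'   (and `participant` if present in `trials`).
#' @examples
#' s <- uniform_bins(40, 600)
#' expand_person_trial_bin(data.frame(rt = 95, correct = 1), s)  # 3 rows
#' @export
expand_person_trial_bin <- function(trials, scheme, covariates = NULL) {
  stopifnot(inherits(scheme, "binning_scheme"))
  trials <- validate_trials(trials, scheme)
  if (!is.null(covariates) && !all(covariates %in% names(trials)))
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(trials)), collapse = ", "))
  K <- scheme$n_bins
  bin <- assign_bin(trials$rt, scheme)
  n_rows <- ifelse(is.na(bin), K, bin)          # censored trials risk all K
  trial_id <- rep(seq_len(nrow(trials)), n_rows)
  t_idx <- sequence(n_rows)
  event <- as.integer(!is.na(bin[trial_id]) & t_idx == n_rows[trial_id])
  out <- data.frame(trial = trial_id, t = t_idx, event = event)
  if ("participant" %in% names(trials))
    out <- cbind(participant = trials$participant[trial_id], out)
  for (cv in covariates) out[[cv]] <- trials[[cv]][trial_id]
  out
}

#' Specify a discrete-time hazard model
#'
#' The model for the per-bin hazard is
#' \deqn{g[h(t)] = \alpha_0 + \alpha_1 (t-c) + \dots + \alpha_d (t-c)^d +
#'   \sum_i \beta_i x_i + \sum_j \gamma_j x_j (t-c)}
#' with `g` the chosen link. The alpha polynomial in centered time describes
#' the baseline hazard shape (all covariates zero); each beta shifts the
#' whole baseline vertically on the link scale; a covariate-by-time
#' interaction lets that shift grow linearly with `t - c`. A saturated
#' `time_basis = "dummy"` uses one indicator per bin instead of the
#' polynomial, in which case the fitted baseline reproduces the life-table
#' hazard estimates exactly.
#'
#' @param link `"cloglog"` (default, preferred for interval-recorded event
#'   times) or `"logit"`.
#' @param time_basis `"polynomial"` or `"dummy"`.
#' @param degree Polynomial degree (0 = intercept-only baseline).
#' @param center Centering constant `c` for `TIME`; default 1, so the
#'   intercept is the bin-1 baseline.
#' @param covariates Character vector of covariate names.
#' @param time_interactions Subset of `covariates` that interact with
#'   centered time.
#' @return Object of class `"hazard_model_spec"`.
#' @export
hazard_model_spec <- function(link = c("cloglog", "logit"),
                              time_basis = c("polynomial", "dummy"),
                              degree = 3, center = 1,
                              covariates = character(),
                              time_interactions = character()) {
  link <- match.arg(link)
  time_basis <- match.arg(time_basis)
  if (degree < 0) stop("degree must be >= 0")
  if (!all(time_interactions %in% covariates))
    stop("time_interactions must name covariates")
  structure(list(link = link, time_basis = time_basis,
                 degree = as.integer(degree), center = center,
                 covariates = covariates,
                 time_interactions = time_interactions),
            class = "hazard_model_spec")
}

#' @keywords internal
model_formula <- function(spec) {
  rhs <- if (spec$time_basis == "dummy") {
    "0 + factor(t)"
  } else if (spec$degree == 0) {
    "1"
  } else {
    paste(sprintf("I((t - %g)^%d)", spec$center, seq_len(spec$degree)),
          collapse = " + ")
  }
  for (cv in spec$covariates) rhs <- paste(rhs, "+", cv)
  for (cv in spec$time_interactions)
    rhs <- paste0(rhs, " + I(", cv, " * (t - ", spec$center, "))")
  stats::as.formula(paste("event ~", rhs))
}

#' Fit a discrete-time hazard regression model
#'
#' Maximum-likelihood fit of the binomial GLM for the event indicator on
#' person-trial-bin data, under the spec's link and terms. Estimation is
#' single-level ML: when the data pool several participants the rows are
#' treated as independent, which understates uncertainty under strong
#' between-participant clustering — a warning is raised in that case.
#'
#' @param data Person-trial-bin data frame from
#'   [expand_person_trial_bin()].
#' @param spec A [hazard_model_spec()].
#' @return Object of class `"hazard_fit"`: coefficients, standard errors,
#'   log-likelihood, the spec, and the underlying `glm` object.
#' @examples
#' s <- uniform_bins(100, 500)
#' trials <- data.frame(rt = c(150, 250, 250, 450, NA), correct = c(1, 1, 0, 1, NA))
#' ptb <- expand_person_trial_bin(trials, s)
#' fit <- fit_hazard_model(ptb, hazard_model_spec(degree = 0))
#' coef(fit)[["(Intercept)"]] == cloglog(4 / nrow(ptb))
#' @export
fit_hazard_model <- function(data, spec = hazard_model_spec()) {
  stopifnot(inherits(spec, "hazard_model_spec"))
  if (!all(c("t", "event") %in% names(data)))
    stop("data must be in person-trial-bin format (columns t, event)")
  if (sum(data$event) < 1) stop("no events in the data")
  missing_cv <- setdiff(spec$covariates, names(data))
  if (length(missing_cv))
    stop("covariates not found in data: ", paste(missing_cv, collapse = ", "))
  if ("participant" %in% names(data) &&
      length(unique(data$participant)) > 1L)
    warning("pooling ", length(unique(data$participant)),
            " participants in one single-level fit; clustered standard ",
            "errors are not accounted for")
  fml <- model_formula(spec)
  fit <- stats::glm(fml, family = stats::binomial(link = spec$link),
                    data = data,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged)
    stop("hazard model did not converge (possible complete separation)")
  if (fit$rank < length(stats::coef(fit)) || anyNA(stats::coef(fit)))
    stop("design matrix is rank deficient; drop or recode collinear terms")
  fh <- stats::fitted(fit)
  if (any(fh < 1e-12) || any(fh > 1 - 1e-12))
    stop("fitted hazards on the boundary of (0,1): complete separation")
  sm <- summary(fit)
  structure(list(coefficients = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 logLik = as.numeric(stats::logLik(fit)),
                 spec = spec,
                 n_bins = max(data$t),
                 glm = fit),
            class = "hazard_fit")
}

#' @export
coef.hazard_fit <- function(object, ...) object$coefficients

#' @export
logLik.hazard_fit <- function(object, ...) stats::logLik(object$glm)

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("Discrete-time hazard model (%s link)\n", x$spec$link))
  print(data.frame(estimate = x$coefficients, se = x$se))
  cat(sprintf("log-likelihood: %.3f\n", x$logLik))
  invisible(x)
}

#' Hazard ratios from a fitted hazard model
#'
#' Exponentiates the covariate coefficients of a cloglog-link fit into
#' hazard ratios, with Wald intervals formed on the link scale and then
#' exponentiated. Under the logit link the exponentiated coefficients are
#' odds ratios of the per-bin event probability; the column name keeps the
#' hazard-ratio reading of the cloglog link.
#'
#' @param fit A [fit_hazard_model()] result.
#' @param level Confidence level (default 0.95).
#' @param terms Coefficient names to report; default all covariate terms
#'   (alpha/time terms excluded).
#' @return Data frame with `term`, `estimate`, `se`, `hr`, `lower`, `upper`.
#' @export
hazard_ratios <- function(fit, level = 0.95, terms = NULL) {
  stopifnot(inherits(fit, "hazard_fit"))
  if (is.null(terms)) {
    time_terms <- grepl("^\\(Intercept\\)$|^I\\(\\(t|^factor\\(t\\)",
                        names(fit$coefficients))
    terms <- names(fit$coefficients)[!time_terms]
  }
  b <- fit$coefficients[terms]
  se <- fit$se[terms]
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = terms, estimate = unname(b), se = unname(se),
             hr = exp(unname(b)),
             lower = exp(unname(b - z * se)),
             upper = exp(unname(b + z * se)),
             row.names = NULL)
}

#' Predicted hazard curve for a covariate profile
#'
#' Evaluates the fitted model's hazard over the bins `1..K` at the given
#' covariate values (all-zero profile = the baseline hazard), honouring
#' covariate-by-time interactions bin by bin.
#'
#' @param fit A [fit_hazard_model()] result.
#' @param profile Named list/vector of covariate values; every covariate in
#'   the spec must be supplied. Empty for the baseline.
#' @param K Number of bins to predict (default: bins seen when fitting).
#' @return Numeric vector `h(1..K)`.
#' @export
predict_hazard <- function(fit, profile = list(), K = NULL) {
  stopifnot(inherits(fit, "hazard_fit"))
  spec <- fit$spec
  if (is.null(K)) K <- fit$n_bins
  missing_cv <- setdiff(spec$covariates, names(profile))
  if (length(missing_cv))
    stop("profile is missing covariates: ",
         paste(missing_cv, collapse = ", "))
  nd <- data.frame(t = seq_len(K))
  for (cv in spec$covariates) nd[[cv]] <- profile[[cv]]
  eta <- stats::predict(fit$glm, newdata = nd, type = "link")
  unname(link_fun(spec$link)$inv(eta))
}

#' @rdname predict_hazard
#' @export
baseline_hazard <- function(fit, K = NULL) {
  profile <- as.list(stats::setNames(rep(0, length(fit$spec$covariates)),
                                     fit$spec$covariates))
  predict_hazard(fit, profile, K = K)
}
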