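test_that("link functions satisfy their identities", {
  expect_equal(cloglog(1 - exp(-1)), 0)
  expect_equal(logit(0.5), 0)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(inv_cloglog(cloglog(p)), p)
  expect_equal(inv_logit(logit(p)), p)
  expect_true(all(diff(cloglog(p)) > 0))   # strictly increasing
  expect_true(all(diff(logit(p)) > 0))
  for (bad in list(0, 1, -0.1, 1.1, NA))
    expect_error(cloglog(bad), "strictly inside")
})

test_that("person-trial-bin expansion gives one row per bin at risk", {
  s <- uniform_bins(40, 600)
  # event in bin 3: exactly 3 rows, event only in the last
  one <- expand_person_trial_bin(data.frame(rt = 95, correct = 1), s)
  expect_equal(one$t, 1:3)
  expect_equal(one$event, c(0, 0, 1))
  # censored trial: K rows, all zero
  cens <- expand_person_trial_bin(
    data.frame(rt = NA_real_, correct = NA_integer_), s)
  expect_equal(nrow(cens), 15)
  expect_equal(sum(cens$event), 0)
})

test_that("expansion row total matches the closed-form count on the published table", {
  s <- table1_scheme()
  cnt <- table1_counts()
  trials <- trials_from_counts(cnt, s)
  ptb <- expand_person_trial_bin(trials, s)
  # sum over trials of min(event bin, K): brute-force from the counts
  expect_equal(nrow(ptb), sum(cnt$E * cnt$t) + sum(cnt$rc) * 15)
  expect_equal(nrow(ptb), 220 * 15 - sum(cnt$E * (15 - cnt$t)))
  expect_equal(nrow(ptb), 2421)
  expect_equal(sum(ptb$event), sum(cnt$E))
  # events per bin recoverable from the long table
  expect_equal(as.vector(table(factor(ptb$t[ptb$event == 1], levels = 1:15))),
               cnt$E)
})

test_that("covariates are carried onto every row and missing ones refused", {
  s <- binning_scheme(c(0, 100, 200, 300))
  trials <- data.frame(rt = c(150, NA), correct = c(1, NA), x1 = c(1, 0))
  ptb <- expand_person_trial_bin(trials, s, covariates = "x1")
  expect_equal(ptb$x1, c(1, 1, 0, 0, 0))
  expect_error(expand_person_trial_bin(trials, s, covariates = "x9"),
               "missing covariate")
})

test_that("intercept-only fits return the pooled event proportion under any link", {
  s <- uniform_bins(40, 600)
  trials <- trials_from_counts(table1_counts(), s)
  ptb <- expand_person_trial_bin(trials, s)
  p_hat <- sum(ptb$event) / nrow(ptb)
  links <- list(cloglog = cloglog, logit = logit)
  for (link in names(links)) {
    fit <- fit_hazard_model(ptb, hazard_model_spec(link = link, degree = 0))
    expect_equal(unname(coef(fit)[1]), links[[link]](p_hat),
                 tolerance = 1e-8)
    expect_equal(unique(round(stats::fitted(fit$glm), 10)),
                 round(p_hat, 10))
  }
})

test_that("saturated time-dummy fits reproduce life-table hazards exactly", {
  s <- binning_scheme(seq(0, 600, by = 100))
  set.seed(7)
  prof <- discrete_profile(c(0.1, 0.25, 0.4, 0.35, 0.5, 0.3),
                           scheme = s)
  trials <- sample_discrete(prof, 400, seed = 11)
  lt <- life_table(trials, s)
  ptb <- expand_person_trial_bin(trials, s)
  for (link in c("cloglog", "logit")) {
    fit <- fit_hazard_model(
      ptb, hazard_model_spec(link = link, time_basis = "dummy"))
    expect_equal(baseline_hazard(fit), lt$h, tolerance = 1e-7)
  }
})

test_that("hazard ratios exponentiate coefficients with Wald intervals", {
  fit <- structure(
    list(coefficients = c(`(Intercept)` = -2, x1 = 0, x2 = log(2),
                          x3 = 0.7),
         se = c(`(Intercept)` = 0.1, x1 = 0.2, x2 = 0.15, x3 = 0.1),
         spec = hazard_model_spec(covariates = c("x1", "x2", "x3"))),
    class = "hazard_fit")
  hr <- hazard_ratios(fit)
  expect_equal(hr$term, c("x1", "x2", "x3"))
  expect_equal(hr$hr, c(1, 2, exp(0.7)))
  expect_equal(hr$lower[3], exp(0.7 - qnorm(0.975) * 0.1))
  expect_equal(hr$upper[3], exp(0.7 + qnorm(0.975) * 0.1))
})

test_that("a covariate shifts the whole baseline on the link scale", {
  s <- binning_scheme(seq(0, 500, by = 100))
  set.seed(3)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5)
  trials <- sample_hazard_model(
    alpha = c(-2, 0.3), beta = c(x1 = 0.6),
    X = data.frame(x1 = x1), scheme = s)
  ptb <- expand_person_trial_bin(trials, s, covariates = "x1")
  fit <- fit_hazard_model(
    ptb, hazard_model_spec(degree = 1, covariates = "x1"))
  h0 <- predict_hazard(fit, list(x1 = 0))
  h1 <- predict_hazard(fit, list(x1 = 1))
  shift <- cloglog(h1) - cloglog(h0)
  expect_equal(shift, rep(shift[1], 5), tolerance = 1e-8)
  expect_error(predict_hazard(fit, list()), "missing covariates")
})

test_that("simulated cloglog data are recovered within 3 reported SEs", {
  s <- binning_scheme(seq(0, 600, by = 40))
  set.seed(20)
  n <- 5000
  X <- data.frame(x1 = rbinom(n, 1, 0.5))
  trials <- sample_hazard_model(alpha = -2, beta = c(x1 = 0.7),
                                X = X, scheme = s)
  ptb <- expand_person_trial_bin(trials, s, covariates = "x1")
  fit <- fit_hazard_model(ptb, hazard_model_spec(degree = 0,
                                                 covariates = "x1"))
  expect_lt(abs(coef(fit)[["(Intercept)"]] - (-2)) / fit$se[1], 3)
  expect_lt(abs(coef(fit)[["x1"]] - 0.7) / fit$se[2], 3)
})

test_that("degenerate fits raise diagnostics instead of silent output", {
  s <- binning_scheme(c(0, 100, 200, 300))
  trials <- data.frame(rt = c(NA, NA), correct = c(NA, NA))
  ptb <- expand_person_trial_bin(trials, s)
  expect_error(fit_hazard_model(ptb, hazard_model_spec(degree = 0)),
               "no events")
  # perfectly separating covariate
  tr2 <- data.frame(rt = c(rep(50, 20), rep(NA, 20)),
                    correct = c(rep(1, 20), rep(NA, 20)),
                    x1 = c(rep(1, 20), rep(0, 20)))
  ptb2 <- expand_person_trial_bin(tr2, s, covariates = "x1")
  expect_error(fit_hazard_model(ptb2, hazard_model_spec(degree = 0,
                                                        covariates = "x1")),
               "separation|converge|boundary")
  # duplicated covariate column -> rank deficiency
  tr3 <- data.frame(rt = c(50, 150, NA, 250), correct = c(1, 0, NA, 1),
                    x1 = c(1, 0, 1, 0))
  tr3$x2 <- tr3$x1
  ptb3 <- expand_person_trial_bin(tr3, s, covariates = c("x1", "x2"))
  expect_error(fit_hazard_model(ptb3,
                                hazard_model_spec(degree = 0,
                                                  covariates = c("x1", "x2"))),
               "rank deficient")
})

test_that("pooling several participants in one fit warns about clustering", {
  s <- binning_scheme(c(0, 100, 200, 300))
  trials <- data.frame(participant = c("P1", "P1", "P2", "P2"),
                       rt = c(50, 150, 250, NA),
                       correct = c(1, 1, 0, NA))
  ptb <- expand_person_trial_bin(trials, s)
  expect_warning(fit_hazard_model(ptb, hazard_model_spec(degree = 0)),
                 "pooling")
})
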