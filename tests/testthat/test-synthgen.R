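test_that("discrete profiles validate hazards and accuracy gating", {
  s <- uniform_bins(100, 500)
  expect_error(discrete_profile(c(0.1, 0.2), scheme = s), "one value per bin")
  expect_error(discrete_profile(rep(1.2, 5), scheme = s), "\\[0, 1\\]")
  expect_error(discrete_profile(rep(0.2, 5), ca = c(NA, 1, 1, 1, 1),
                                scheme = s), "positive hazard")
  # ca may be NA where the hazard is zero
  p <- discrete_profile(c(0, 0.2, 0.2, 0.2, 0.2), ca = c(NA, 1, 1, 1, 1),
                        scheme = s)
  expect_equal(p$S, cumprod(1 - p$h))
  expect_equal(sum(p$P) + p$censored_fraction, 1)
})

test_that("degenerate hazard profiles sample as promised", {
  s <- uniform_bins(100, 500)
  # h = 1 in bin 1: every trial responds there
  all_first <- sample_discrete(
    discrete_profile(c(1, 0, 0, 0, 0), ca = c(1, NA, NA, NA, NA), scheme = s),
    50, seed = 1)
  expect_true(all(!is.na(all_first$rt) & all_first$rt <= 100))
  # h = 0 everywhere: every trial censored
  none <- sample_discrete(
    discrete_profile(rep(0, 5), ca = rep(NA, 5), scheme = s), 50, seed = 2)
  expect_true(all(is.na(none$rt)))
  expect_true(all(is.na(none$correct)))
  # same seed, same sample; different seed, different sample
  p <- discrete_profile(rep(0.3, 5), scheme = s)
  expect_identical(sample_discrete(p, 100, seed = 9),
                   sample_discrete(p, 100, seed = 9))
  expect_false(identical(sample_discrete(p, 100, seed = 9),
                         sample_discrete(p, 100, seed = 10)))
})

test_that("life-table estimates recover known discrete profiles within binomial error", {
  s <- uniform_bins(50, 500)
  shapes <- list(
    flat = rep(0.2, 10),
    increasing = seq(0.05, 0.5, length.out = 10),
    peaked = c(0.05, 0.1, 0.3, 0.5, 0.6, 0.5, 0.3, 0.2, 0.1, 0.1),
    late = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.55, 0.5, 0.4))
  ca_true <- c(0.6, 0.7, 0.8, 0.9, 0.95, 1, 1, 1, 0.9, 0.8)
  for (nm in names(shapes)) {
    prof <- discrete_profile(shapes[[nm]], ca = ca_true, scheme = s)
    lt <- life_table(sample_discrete(prof, 10000, seed = 101), s)
    se <- sqrt(prof$h * (1 - prof$h) / lt$RS)
    expect_true(all(abs(lt$h - prof$h) <= pmax(3 * se, 1e-12)),
                label = paste("hazard recovery:", nm))
    ok <- lt$E > 30
    se_ca <- sqrt(ca_true * (1 - ca_true) / lt$E)
    expect_true(all((abs(lt$ca - ca_true) <= 3 * pmax(se_ca, 1e-12))[ok]),
                label = paste("ca recovery:", nm))
  }
})

test_that("parametric hazard rates have their characteristic shapes", {
  tg <- seq(50, 2000, by = 50)
  # exponential: flat at the rate
  lam <- hazard_curve(parametric_family("exponential", rate = 1/300), tg)
  expect_equal(lam, rep(1/300, length(tg)))
  # Weibull shape 1 reduces to the exponential
  lam_w <- hazard_curve(parametric_family("weibull", shape = 1, scale = 300),
                        tg)
  expect_equal(lam_w, lam)
  # Weibull shape > 1 keeps increasing
  expect_true(all(diff(hazard_curve(
    parametric_family("weibull", shape = 2, scale = 400), tg)) > 0))
  # log-normal: rises to a peak, then decreases
  lam_ln <- hazard_curve(
    parametric_family("lognormal", meanlog = log(400), sdlog = 0.5),
    seq(20, 5000, by = 20))
  pk <- which.max(lam_ln)
  expect_gt(pk, 1)
  expect_lt(pk, length(lam_ln))
  expect_true(all(diff(lam_ln[1:pk]) > 0))
  expect_true(all(diff(lam_ln[pk:length(lam_ln)]) < 0))
  expect_error(hazard_curve(parametric_family("exponential", rate = 1), 0),
               "positive")
  expect_error(parametric_family("gamma", shape = 2), "needs parameters")
  expect_error(parametric_family("exponential", rate = -1), "positive")
})

test_that("deadline censoring matches the family's survivor function", {
  fam <- parametric_family("exponential", rate = 1/250)
  smp <- sample_continuous(fam, 10000, deadline = 600, seed = 21)
  p_cens <- mean(is.na(smp$rt))
  truth <- exp(-600 / 250)
  expect_lt(abs(p_cens - truth), 3 * sqrt(truth * (1 - truth) / 10000))
  expect_true(all(smp$rt[!is.na(smp$rt)] <= 600))
  # same seed reproduces; infinite deadline censors nothing
  expect_identical(smp, sample_continuous(fam, 10000, deadline = 600,
                                          seed = 21))
  expect_false(anyNA(sample_continuous(fam, 1000, deadline = Inf,
                                       seed = 22)$rt))
})

test_that("interval-censored discretization has its closed forms and limits", {
  s <- uniform_bins(40, 600)
  r <- 1/200
  h <- discretize_true_hazard(parametric_family("exponential", rate = r), s)
  expect_equal(h, rep(1 - exp(-r * 40), 15))
  # shrinking bins: h(t)/width converges to the continuous rate at midpoints
  fam <- parametric_family("weibull", shape = 2, scale = 400)
  for (w in c(10, 1, 0.1)) {
    sw <- uniform_bins(w, 400)
    hd <- discretize_true_hazard(fam, sw)
    lam <- hazard_curve(fam, bin_midpoints(sw))
    expect_lt(max(abs(hd / w - lam) / lam), w / 100)
  }
  # exhausted support: NA from the first bin whose start cannot be survived
  s2 <- binning_scheme(c(0, 100, 200, 400, 600))
  fam2 <- parametric_family("weibull", shape = 30, scale = 100)
  h2 <- discretize_true_hazard(fam2, s2)
  expect_false(anyNA(h2[1:2]))
  expect_true(all(is.na(h2[3:4])))
})

test_that("sampled continuous trials recover the discretized truth end to end", {
  s <- uniform_bins(40, 600)
  fam <- parametric_family("lognormal", meanlog = log(350), sdlog = 0.35)
  h_true <- discretize_true_hazard(fam, s)
  lt <- life_table(sample_continuous(fam, 20000, deadline = 600, seed = 31), s)
  se <- sqrt(h_true * (1 - h_true) / lt$RS)
  # the 3-SE band is a normal approximation: compare only bins whose
  # expected event count supports it, and bound the far-tail bins by their
  # Poisson 99.9% quantile instead
  big <- h_true * lt$RS >= 5
  expect_true(all((abs(lt$h - h_true) <= 3 * se)[big]))
  expect_true(all((lt$E <= stats::qpois(0.999, h_true * lt$RS))[!big]))
})

test_that("crossing hazards can coexist with strictly ordered survivor curves", {
  pair <- crossing_hazard_pair()
  s <- uniform_bins(50, 500)
  pa <- discrete_profile(pair$h_a, scheme = s)
  pb <- discrete_profile(pair$h_b, scheme = s)
  d <- pair$h_a - pair$h_b
  expect_true(any(d > 0) && any(d < 0))            # hazards cross
  expect_true(all(pa$S < pb$S))                     # survivors never do
})

test_that("regression-model sampling matches its specified hazards", {
  s <- uniform_bins(40, 600)
  X <- data.frame(x1 = rep(c(0, 1), each = 4000))
  trials <- sample_hazard_model(alpha = c(-2.2, 0.15), beta = c(x1 = 0.5),
                                X = X, scheme = s, seed = 41)
  for (v in c(0, 1)) {
    h_true <- inv_cloglog(-2.2 + 0.15 * (1:15 - 1) + 0.5 * v)
    lt <- life_table(trials[trials$x1 == v, c("rt", "correct")], s)
    se <- sqrt(h_true * (1 - h_true) / lt$RS)
    expect_true(all(abs(lt$h - h_true) <= 3 * se))
  }
  expect_error(sample_hazard_model(alpha = -2, beta = c(zz = 1),
                                   X = X, scheme = s), "columns of X")
})
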