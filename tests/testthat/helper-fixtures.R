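# Shared fixtures: the published single-participant life-table counts
# (220 trials, 15 x 40 ms bins, 4 trials censored at the 600 ms deadline),
# reconstruction of trials from counts, and random generators used by the
# property suites.

table1_counts <- function() {
  data.frame(
    t = 1:15,
    E = c(0, 0, 0, 0, 0, 0, 7, 13, 26, 40, 48, 37, 32, 9, 4),
    rc = c(rep(0, 14), 4),
    n_correct = c(0, 0, 0, 0, 0, 0, 2, 10, 24, 40, 47, 37, 32, 9, 4),
    n_error = c(0, 0, 0, 0, 0, 0, 5, 3, 2, 0, 1, 0, 0, 0, 0))
}

table1_scheme <- function() uniform_bins(40, 600)

# Expand per-bin counts back into a trial table (response times placed at
# bin midpoints; censored trials get rt = NA).
trials_from_counts <- function(counts, scheme) {
  mid <- bin_midpoints(scheme)
  rt <- c(rep(mid, counts$n_correct), rep(mid, counts$n_error),
          rep(NA_real_, sum(counts$rc)))
  correct <- c(rep(1L, sum(counts$n_correct)), rep(0L, sum(counts$n_error)),
               rep(NA_integer_, sum(counts$rc)))
  data.frame(rt = rt, correct = correct)
}

# Independent brute-force oracle for the life-table estimators: walks the
# trial list bin by bin, never touching the package's counting code.
brute_force_lifetable <- function(trials, scheme) {
  K <- n_bins(scheme)
  edges <- scheme$edges
  bins <- vapply(trials$rt, function(rt) {
    if (is.na(rt)) return(NA_integer_)
    which(rt > edges[-length(edges)] & rt <= edges[-1L])[1L]
  }, integer(1))
  h <- S <- P <- ca <- numeric(K)
  s_prev <- 1
  for (t in seq_len(K)) {
    at_risk <- sum(is.na(bins) | bins >= t)
    ev <- sum(!is.na(bins) & bins == t)
    h[t] <- ev / at_risk
    S[t] <- s_prev * (1 - h[t])
    P[t] <- h[t] * s_prev
    ca[t] <- if (ev > 0)
      mean(trials$correct[!is.na(bins) & bins == t]) else NA_real_
    s_prev <- S[t]
  }
  list(h = h, S = S, P = P, ca = ca)
}

# Random per-bin count table with a prescribed hazard sequence: integer
# events chosen so the realized E/RS tracks the target hazards closely.
counts_from_hazard <- function(h, n0 = 10000L) {
  K <- length(h)
  E <- integer(K); RS <- integer(K)
  at_risk <- n0
  for (t in seq_len(K)) {
    RS[t] <- at_risk
    E[t] <- as.integer(round(h[t] * at_risk))
    at_risk <- at_risk - E[t]
  }
  data.frame(t = seq_len(K), E = E, rc = c(rep(0L, K - 1L), at_risk),
             n_correct = E, n_error = 0L)
}

# A pair of discrete hazard profiles whose hazard curves cross while the
# survivor curves keep a strict ordering: profile A front-loads its hazard
# (early fast responses) and then falls below profile B, but B's later
# advantage never repays A's accumulated head start.
crossing_hazard_pair <- function() {
  list(h_a = c(0.08, 0.20, 0.50, 0.50, 0.20, 0.10, 0.10, 0.10, 0.10, 0.10),
       h_b = c(0.05, 0.10, 0.10, 0.15, 0.35, 0.45, 0.30, 0.20, 0.15, 0.12))
}
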