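#' Code a per-bin conditional-accuracy comparison between two conditions
#'
#' For each time bin, compares the conditional accuracy of two prime
#' conditions (A = congruent, B = incongruent in the priming application)
#' and assigns a state code describing the evidence in that bin:
#'
#' * both conditions have responses: `"P"` (ca_A = 1 and ca_B = 0),
#'   `"N"` (ca_A = 0 and ca_B = 1), `"p"` (ca_A - ca_B >= `diff_threshold`),
#'   `"n"` (ca_A - ca_B <= -`diff_threshold`), `"all"` (both strictly above
#'   `all_threshold`), else `"?"`;
#' * responses only in A: `"cc"` (ca_A = 1), `"ic"` (ca_A = 0), else `"?"`;
#' * responses only in B: `"ci"` (ca_B = 1), `"ii"` (ca_B = 0), else `"?"`;
#' * no responses in either: `"x"`.
#'
#' The rules are applied in the order exact-extreme (`P`/`N`), threshold
#' (`p`/`n`), `all`, so a bin with ca_A = 1 and ca_B = 0 is always `"P"`
#' even though it also clears the threshold rule: the most specific label
#' wins. The function is total — every input receives exactly one code.
#'
#' @param ca_a,ca_b Conditional accuracies in `[0, 1]`, or `NA` when no
#'   response was observed in that condition's bin. Vectorised.
#' @param diff_threshold Minimum ca difference for the `p`/`n` codes
#'   (default 0.2).
#' @param all_threshold Strict lower bound for the `all` code (default 0.8).
#' @return Character vector of codes.
#' @examples
#' code_ca_bin(1, 0)        # "P"
#' code_ca_bin(0.95, 0.9)   # "all"
#' code_ca_bin(NA, NA)      # "x"
#' @export
code_ca_bin <- function(ca_a, ca_b, diff_threshold = 0.2,
                        all_threshold = 0.8) {
  if (diff_threshold <= 0 || diff_threshold >= 1 ||
      all_threshold <= 0 || all_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  n <- max(length(ca_a), length(ca_b))
  ca_a <- rep_len(ca_a, n); ca_b <- rep_len(ca_b, n)
  bad <- !is.na(ca_a) & (ca_a < 0 | ca_a > 1) |
         !is.na(ca_b) & (ca_b < 0 | ca_b > 1)
  if (any(bad)) stop("conditional accuracies must lie in [0, 1] or be NA")
  has_a <- !is.na(ca_a); has_b <- !is.na(ca_b)
  out <- rep("?", n)
  both <- has_a & has_b
  d <- ca_a - ca_b
  eps <- 1e-9   # absorb float noise in differences of count ratios
  out[both & ca_a > all_threshold & ca_b > all_threshold] <- "all"
  out[both & d >= diff_threshold - eps] <- "p"
  out[both & d <= -diff_threshold + eps] <- "n"
  out[both & ca_a == 1 & ca_b == 0] <- "P"
  out[both & ca_a == 0 & ca_b == 1] <- "N"
  only_a <- has_a & !has_b
  out[only_a & ca_a == 1] <- "cc"
  out[only_a & ca_a == 0] <- "ic"
  only_b <- !has_a & has_b
  out[only_b & ca_b == 1] <- "ci"
  out[only_b & ca_b == 0] <- "ii"
  out[!has_a & !has_b] <- "x"
  out
}

#' Default mapping from transition codes to evidence classes
#'
#' `P`, `p` (and the single-condition codes `cc`, `ii`) count as evidence
#' for a positive congruency effect; `N`, `n` (and `ic`, `ci`) for a
#' negative one; `all` marks bins where both conditions are essentially
#' always correct (no evidence for either); `x` and `?` are uninformative.
#' The single-condition assignments follow the sign of the implied effect
#' (responses occurring only in the congruent condition and being correct —
#' `cc` — point the same way as `P`); pass a modified map to reclassify.
#'
#' @return Named character vector: code -> class in
#'   `{"PCE-evidence", "NCE-evidence", "no-evidence", "other"}`.
#' @export
default_code_classes <- function() {
  c(P = "PCE-evidence", p = "PCE-evidence", cc = "PCE-evidence",
    ii = "PCE-evidence",
    N = "NCE-evidence", n = "NCE-evidence", ic = "NCE-evidence",
    ci = "NCE-evidence",
    all = "no-evidence", x = "other", `?` = "other")
}

#' Transition-code matrix across participants and bins
#'
#' Applies [code_ca_bin()] participant by participant to paired
#' conditional-accuracy series, producing the participants-by-bins state
#' matrix used in ca(t)-state transition plots, plus the evidence-class
#' matrix.
#'
#' @param ca_a,ca_b Numeric matrices (participants x bins) of conditional
#'   accuracies, `NA` where a participant emitted no response in a bin.
#'   Row names label participants.
#' @param diff_threshold,all_threshold Passed to [code_ca_bin()].
#' @param classes Code-to-class map; see [default_code_classes()].
#' @return List of class `"ca_code_matrix"`: `codes` and `classes`
#'   (character matrices), plus the thresholds used.
#' @export
code_matrix <- function(ca_a, ca_b, diff_threshold = 0.2,
                        all_threshold = 0.8,
                        classes = default_code_classes()) {
  ca_a <- as.matrix(ca_a); ca_b <- as.matrix(ca_b)
  if (!all(dim(ca_a) == dim(ca_b)))
    stop("ca matrices must have identical dimensions ",
         "(same participants and binning scheme)")
  codes <- matrix(code_ca_bin(as.vector(ca_a), as.vector(ca_b),
                              diff_threshold, all_threshold),
                  nrow = nrow(ca_a), dimnames = dimnames(ca_a))
  cls <- matrix(unname(classes[codes]), nrow = nrow(codes),
                dimnames = dimnames(codes))
  structure(list(codes = codes, classes = cls,
                 diff_threshold = diff_threshold,
                 all_threshold = all_threshold),
            class = "ca_code_matrix")
}

#' @export
print.ca_code_matrix <- function(x, ...) {
  cat(sprintf("ca(t)-state transition codes: %d participants x %d bins\n",
              nrow(x$codes), ncol(x$codes)))
  print(x$codes, quote = FALSE)
  invisible(x)
}

#' Long-format export of a transition-code matrix
#'
#' @param x A [code_matrix()] result.
#' @return Data frame with columns `participant`, `bin`, `code`,
#'   `color_class`.
#' @export
code_matrix_long <- function(x) {
  stopifnot(inherits(x, "ca_code_matrix"))
  p <- rownames(x$codes)
  if (is.null(p)) p <- as.character(seq_len(nrow(x$codes)))
  data.frame(participant = rep(p, times = ncol(x$codes)),
             bin = rep(seq_len(ncol(x$codes)), each = nrow(x$codes)),
             code = as.vector(x$codes),
             color_class = as.vector(x$classes))
}
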