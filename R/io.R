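#' Read trial-level data from delimited text
#'
#' Reads one row per trial: a participant identifier, any number of factor
#' columns, the response time in milliseconds (empty = no response =
#' right-censored at the deadline), and response correctness (0/1, empty
#' exactly when no response). Responses recorded after the deadline are
#' converted to censored — under a fixed response deadline a later response
#' carries only the information that `RT > deadline` — and the conversion
#' count is reported via a warning.
#'
#' @param path CSV file path.
#' @param censor_time Fixed censoring time (ms).
#' @param rt_col,correct_col,participant_col Column names (defaults
#'   `"rt_ms"`, `"correct"`, `"participant"`).
#' @param factor_cols Condition factor columns to retain; default: every
#'   other column.
#' @param fail_fast If `TRUE` (default) any invalid row aborts with
#'   per-row diagnostics; if `FALSE` invalid rows are dropped with a
#'   warning.
#' @return Data frame with columns `participant`, the factor columns,
#'   `rt` (`NA` = censored) and `correct`.
#' @export
read_trials <- function(path, censor_time,
                        rt_col = "rt_ms", correct_col = "correct",
                        participant_col = "participant",
                        factor_cols = NULL, fail_fast = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(participant_col, rt_col, correct_col)
  if (!all(need %in% names(raw)))
    stop("missing required columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  if (is.null(factor_cols))
    factor_cols <- setdiff(names(raw), need)
  rt <- suppressWarnings(as.numeric(raw[[rt_col]]))
  unparseable <- !is.na(raw[[rt_col]]) & raw[[rt_col]] != "" & is.na(rt)
  correct <- suppressWarnings(as.integer(raw[[correct_col]]))
  bad_correct <- !is.na(correct) & !correct %in% c(0L, 1L)
  # correctness present on a censored trial (or vice versa) is inconsistent
  mismatch <- xor(is.na(rt), is.na(correct)) & !unparseable
  nonpos <- !is.na(rt) & rt <= 0
  bad <- unparseable | bad_correct | mismatch | nonpos
  if (any(bad)) {
    msg <- sprintf(
      "%d invalid row(s): %s",
      sum(bad),
      paste(utils::head(which(bad), 10L), collapse = ", "))
    if (fail_fast) stop(msg, " (row numbers exclude the header)")
    warning(msg, "; dropped")
    keep <- !bad
    raw <- raw[keep, , drop = FALSE]; rt <- rt[keep]; correct <- correct[keep]
  }
  late <- !is.na(rt) & rt > censor_time
  if (any(late)) {
    warning(sum(late), " response(s) after the ", censor_time,
            " ms deadline converted to censored")
    rt[late] <- NA_real_
    correct[late] <- NA_integer_
  }
  out <- data.frame(participant = raw[[participant_col]],
                    stringsAsFactors = FALSE)
  for (fc in factor_cols) out[[fc]] <- raw[[fc]]
  out$rt <- rt
  out$correct <- correct
  out
}

#' Write and re-read life tables as CSV
#'
#' `write_life_table()` exports the standard life-table column set
#' (`bin, t, rc, E, RS, h, se_h, S, se_S, P, se_P, n_correct, n_error, ca,
#' se_ca`). By default values are written at full precision so that
#' `read_life_table()` round-trips exactly; pass `digits` to apply the
#' display rounding of [format_life_table()] instead.
#'
#' @param lt A [life_table()].
#' @param path Output CSV path.
#' @param digits `NULL` (full precision) or decimal places for display
#'   export.
#' @param ca_digits Decimal places for `ca` when `digits` is given.
#' @return `write_life_table()`: the path, invisibly;
#'   `read_life_table()`: a data frame with the life-table columns.
#' @export
write_life_table <- function(lt, path, digits = NULL, ca_digits = 2) {
  stopifnot(inherits(lt, "life_table"))
  out <- if (is.null(digits)) as.data.frame(lt)
         else format_life_table(lt, digits = digits, ca_digits = ca_digits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run a named analysis end to end and write its artifacts
#'
#' Thin orchestration layer over the package's functions, used by the
#' command-line wrapper: reads the input, runs one of the five analyses,
#' writes CSV artifacts plus a JSON manifest (the echoed configuration,
#' package version, seed and row counts) so a run is reproducible from its
#' output directory alone.
#'
#' Commands:
#' \describe{
#'   \item{lifetable}{one life-table CSV per stratum.}
#'   \item{model}{person-trial-bin expansion + hazard regression;
#'     writes the long table, coefficients and hazard ratios.}
#'   \item{transitions}{ca(t) state codes comparing two condition levels.}
#'   \item{jackknife}{leave-one-out ANOVA on a hazard-curve landmark.}
#'   \item{simulate}{synthetic trials from a discrete profile.}
#' }
#'
#' @param command One of `"lifetable"`, `"model"`, `"transitions"`,
#'   `"jackknife"`, `"simulate"`.
#' @param config Named list; see Details in the package vignette. Common
#'   fields: `input`, `bin_width` (or `edges`), `censor_time`, `by`,
#'   `out_dir`, `seed`; model fields: `link`, `time_degree`, `covariates`;
#'   jackknife fields: `roi`, `kind`, `on`; transitions: `factor`,
#'   `level_a`, `level_b`; simulate: `h`, `ca`, `n`.
#' @return Invisibly, a list of the objects computed, with the manifest.
#' @export
run_command <- function(command = c("lifetable", "model", "transitions",
                                    "jackknife", "simulate"),
                        config) {
  command <- match.arg(command)
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- if (!is.null(cfg$edges)) binning_scheme(cfg$edges)
            else uniform_bins(cfg$bin_width, cfg$censor_time)
  by <- if (is.null(cfg$by)) "participant" else cfg$by
  result <- switch(command,
    lifetable = {
      trials <- read_trials(cfg$input, scheme$censor_time)
      lts <- life_table_by(trials, scheme, by = by)
      for (nm in names(lts))
        write_life_table(lts[[nm]],
                         file.path(cfg$out_dir,
                                   paste0("lifetable_", nm, ".csv")),
                         digits = cfg$digits)
      lts
    },
    model = {
      trials <- read_trials(cfg$input, scheme$censor_time)
      ptb <- expand_person_trial_bin(trials, scheme,
                                     covariates = cfg$covariates)
      spec <- hazard_model_spec(
        link = if (is.null(cfg$link)) "cloglog" else cfg$link,
        degree = if (is.null(cfg$time_degree)) 3 else cfg$time_degree,
        center = if (is.null(cfg$time_center)) 1 else cfg$time_center,
        covariates = if (is.null(cfg$covariates)) character()
                     else cfg$covariates,
        time_interactions = if (is.null(cfg$time_interactions)) character()
                            else cfg$time_interactions)
      fit <- fit_hazard_model(ptb, spec)
      utils::write.csv(ptb, file.path(cfg$out_dir, "person_trial_bin.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(
        data.frame(term = names(fit$coefficients),
                   estimate = unname(fit$coefficients),
                   se = unname(fit$se)),
        file.path(cfg$out_dir, "coefficients.csv"), row.names = FALSE)
      hr <- hazard_ratios(fit)
      if (nrow(hr))
        utils::write.csv(hr, file.path(cfg$out_dir, "hazard_ratios.csv"),
                         row.names = FALSE)
      list(fit = fit, ptb_rows = nrow(ptb))
    },
    transitions = {
      trials <- read_trials(cfg$input, scheme$censor_time)
      if (is.null(cfg$factor) || is.null(cfg$level_a) ||
          is.null(cfg$level_b))
        stop("transitions needs config$factor, $level_a, $level_b")
      ca_mat <- function(level) {
        sub <- trials[trials[[cfg$factor]] == level, , drop = FALSE]
        lts <- life_table_by(sub, scheme, by = "participant")
        do.call(rbind, lapply(lts, function(x) x$ca))
      }
      cm <- code_matrix(ca_mat(cfg$level_a), ca_mat(cfg$level_b))
      utils::write.csv(as.data.frame(cm$codes),
                       file.path(cfg$out_dir, "transition_codes.csv"))
      utils::write.csv(code_matrix_long(cm),
                       file.path(cfg$out_dir, "transition_codes_long.csv"),
                       row.names = FALSE)
      cm
    },
    jackknife = {
      trials <- read_trials(cfg$input, scheme$censor_time)
      if (is.null(cfg$factor) || is.null(cfg$roi))
        stop("jackknife needs config$factor and $roi")
      levels <- unique(trials[[cfg$factor]])
      curves <- lapply(levels, function(lv) {
        sub <- trials[trials[[cfg$factor]] == lv, , drop = FALSE]
        lts <- life_table_by(sub, scheme, by = "participant")
        do.call(rbind, lapply(lts, function(x) x$h))
      })
      names(curves) <- levels
      jt <- jackknife_test(curves, roi = cfg$roi,
                           kind = if (is.null(cfg$kind)) "min" else cfg$kind,
                           theta = cfg$theta,
                           scheme = scheme,
                           on = if (is.null(cfg$on)) "time" else cfg$on)
      prm <- as.data.frame(jt$params)
      prm$subsample <- seq_len(nrow(prm))
      utils::write.csv(prm, file.path(cfg$out_dir, "jackknife_params.csv"),
                       row.names = FALSE)
      utils::write.csv(jt$anova, file.path(cfg$out_dir, "jackknife_anova.csv"),
                       row.names = FALSE)
      jt
    },
    simulate = {
      if (is.null(cfg$h) || is.null(cfg$n))
        stop("simulate needs config$h and $n")
      prof <- discrete_profile(cfg$h, cfg$ca, scheme)
      trials <- sample_discrete(prof, cfg$n, seed = cfg$seed)
      trials <- data.frame(participant = "sim", condition = "sim",
                           rt_ms = trials$rt, correct = trials$correct)
      utils::write.csv(trials, file.path(cfg$out_dir, "trials.csv"),
                       row.names = FALSE, quote = FALSE, na = "")
      trials
    })
  manifest <- list(
    command = command,
    config = cfg[!vapply(cfg, is.function, TRUE)],
    package_version = as.character(utils::packageVersion("dteha")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    n_rows = if (is.data.frame(result)) nrow(result) else NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(result = result, manifest = manifest))
}
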