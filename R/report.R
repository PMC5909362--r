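# Batch workflows: calibrate from measurement CSVs, compute per-exam dose
# reports, and augment them with reference AGD for comparison.  Per-exam
# failures never abort a batch; they are collected into the report so an
# audit run degrades gracefully.

#' Calibrate all combinations found in measurement CSVs
#'
#' Runs [fit_kerma_line()] and [fit_attenuation()] per anode-filter
#' combination present in the inputs, extracts the yield at the reference
#' kVp from the kerma set, averages per-kVp attenuation coefficients into
#' the combination average, and assembles [tube_calibration()] objects.
#'
#' @param kerma_csv Path to the kerma measurement CSV
#'   (`combination, kvp, mas, kerma_mgy, replicate`).
#' @param attenuation_csv Path to the attenuation CSV
#'   (`combination, kvp, depth_cm, intensity_mgy, replicate`).
#' @param reference_kvp Reference tube voltage for yields (default 28).
#' @param out Optional path: write the calibration set as JSON.
#' @return List with `calibrations` (named list of [tube_calibration()])
#'   and `failures` (named list of error messages for combinations that
#'   could not be fitted).
#' @export
calibrate_from_csv <- function(kerma_csv, attenuation_csv,
                               reference_kvp = 28, out = NULL) {
  kdf <- read_kerma_csv(kerma_csv)
  adf <- read_attenuation_csv(attenuation_csv)
  if (nrow(kdf) == 0 || nrow(adf) == 0)
    stop("empty measurement CSV", call. = FALSE)
  combos <- union(unique(kdf$combination), unique(adf$combination))
  calibrations <- list()
  failures <- list()
  for (combo in combos) {
    res <- tryCatch({
      kc <- kdf[kdf$combination == combo, ]
      ac <- adf[adf$combination == combo, ]
      if (nrow(kc) == 0) stop("no kerma measurements")
      if (nrow(ac) == 0) stop("no attenuation measurements")
      line <- fit_kerma_line(kc)
      yld_pts <- kc[kc$kvp == reference_kvp, ]
      if (nrow(yld_pts) == 0)
        stop(sprintf("no kerma measurements at the reference %g kVp",
                     reference_kvp))
      yld <- tube_yield(yld_pts)
      per_kvp <- lapply(split(ac, ac$kvp), fit_attenuation)
      mu_tab <- data.frame(
        kvp = as.numeric(names(per_kvp)),
        mu_en = vapply(per_kvp, function(f) f$estimates[["mu_en"]], 0),
        sigma = vapply(per_kvp, function(f) f$sigmas[["mu_en"]], 0))
      mu_avg <- average_mu_en(mu_tab$mu_en, mu_tab$sigma)
      tube_calibration(combo,
                       alpha = line$estimates[["alpha"]],
                       beta = line$estimates[["beta"]],
                       alpha_sigma = line$sigmas[["alpha"]],
                       beta_sigma = line$sigmas[["beta"]],
                       Y0 = yld$Y, Y0_sigma = yld$sigma,
                       mu_en = mu_avg$mu_en, mu_en_sigma = mu_avg$sigma,
                       reference_kvp = reference_kvp,
                       mu_en_by_kvp = mu_tab,
                       kvp_validity = range(kc$kvp))
    }, error = function(e) e)
    if (inherits(res, "error"))
      failures[[combo]] <- conditionMessage(res)
    else calibrations[[combo_key(combo)]] <- res
  }
  if (!is.null(out) && length(calibrations))
    write_calibrations(calibrations, out)
  list(calibrations = calibrations, failures = failures)
}

#' Compute a dose report for a batch of exams
#'
#' One row per exam with incident air kerma and 2ABD (each with 1-sigma).
#' Per-exam errors (unknown combination, missing yield, bad geometry) are
#' collected in the `error` column; the batch always completes.
#'
#' @param exams List of [exam_record()]s (e.g. from [read_exam_csv()]).
#' @param calibrations Named list of [tube_calibration()]s keyed by
#'   combination (e.g. [default_calibrations()]).
#' @param registry Named list of [device_profile()]s.
#' @param mu_en_mode `"average"` or `"per_kvp"`.
#' @param round_mgy Presentation rounding step in mGy (`0.1` matches the
#'   convention of clinical dose tables) or `NA` for full precision; only
#'   the `*_rounded` columns are affected.
#' @return Data.frame of class `dose_report`; full-precision values always
#'   retained.
#' @export
compute_doses <- function(exams, calibrations, registry,
                          mu_en_mode = c("average", "per_kvp"),
                          round_mgy = 0.1) {
  mu_en_mode <- match.arg(mu_en_mode)
  rows <- lapply(exams, function(ex) {
    base <- data.frame(exam_id = ex$exam_id,
                       combination = format(ex$combination),
                       kvp = ex$kvp, mas = ex$mas, d_cm = ex$thickness_cm,
                       hvl_mmal = ex$hvl_mmal,
                       k_ai = NA_real_, k_ai_sigma = NA_real_,
                       two_abd = NA_real_, two_abd_sigma = NA_real_,
                       two_abd_sigma_rel = NA_real_,
                       error = NA_character_)
    res <- tryCatch({
      cal <- calibrations[[combo_key(ex$combination)]]
      if (is.null(cal))
        stop(sprintf("no calibration for combination %s",
                     format(ex$combination)))
      dev <- registry_device(registry, ex$device_id)
      dose <- average_breast_dose(cal, dev, ex, mu_en_mode = mu_en_mode)
      base$k_ai <- dose$k_ai$k_ai
      base$k_ai_sigma <- dose$k_ai$sigma
      base$two_abd <- dose$two_abd
      base$two_abd_sigma <- dose$sigma
      base$two_abd_sigma_rel <- dose$sigma_rel
      base
    }, error = function(e) { base$error <- conditionMessage(e); base })
    res
  })
  report <- do.call(rbind, rows)
  if (!is.na(round_mgy)) {
    report$two_abd_rounded <- round(report$two_abd / round_mgy) * round_mgy
    report$two_abd_sigma_rounded <-
      round(report$two_abd_sigma / round_mgy) * round_mgy
  }
  class(report) <- c("dose_report", "data.frame")
  report
}

#' Add reference AGD columns to a dose report
#'
#' Evaluates Dance (`k_ai * g * c * s`) and Wu (`k_ai * DgN`) AGD for each
#' row by bilinear interpolation of the supplied coefficient grids at the
#' exam's (HVL, thickness), attaches the conventional 20% sigmas, and an
#' overlap flag: `|2ABD - AGD| <= sigma(2ABD) + sigma(AGD)` (agreement
#' within combined uncertainties, symmetric in its arguments).  Rows with
#' no HVL or with out-of-grid lookups get a per-row error and stay
#' uncomputed.
#'
#' @param report A `dose_report` from [compute_doses()].
#' @param exams The exam list the report was computed from (provides age /
#'   glandularity for the `c` stratum).
#' @param g_table,c_tables,dgn_tables [coefficient_table()]s: `c_tables`
#'   is a named list keyed by stratum (`"40-49"`, `"50-64"`, ...);
#'   `dgn_tables` may be a single table or a list keyed by combination.
#' @param s_factors Named vector of Dance `s` factors by combination.
#' @param clamp Clamp out-of-grid (HVL, d) queries to the table edge.
#' @return The report with columns `agd_dance`, `agd_dance_sigma`,
#'   `agd_wu`, `agd_wu_sigma`, `overlap_dance`, `overlap_wu`,
#'   `compare_error`.
#' @export
compare_doses <- function(report, exams, g_table, c_tables, s_factors,
                          dgn_tables, clamp = FALSE) {
  stopifnot(nrow(report) == length(exams))
  report$agd_dance <- NA_real_; report$agd_dance_sigma <- NA_real_
  report$agd_wu <- NA_real_; report$agd_wu_sigma <- NA_real_
  report$overlap_dance <- NA; report$overlap_wu <- NA
  report$compare_error <- NA_character_
  for (i in seq_len(nrow(report))) {
    ex <- exams[[i]]
    res <- tryCatch({
      if (!is.na(report$error[i])) stop(report$error[i])
      if (is.na(ex$hvl_mmal)) stop("no HVL recorded for this exam")
      g <- interpolate_coefficient(g_table, ex$hvl_mmal, ex$thickness_cm,
                                   clamp = clamp)
      stratum <- select_c_stratum(ex$age_years, ex$glandularity_pct)
      ct <- c_tables[[stratum]]
      if (is.null(ct)) stop(sprintf("no c table for stratum %s", stratum))
      cf <- interpolate_coefficient(ct, ex$hvl_mmal, ex$thickness_cm,
                                    clamp = clamp)
      s <- s_factors[[combo_key(ex$combination)]]
      if (is.null(s) || is.na(s))
        stop(sprintf("no s factor for %s", format(ex$combination)))
      dt <- if (inherits(dgn_tables, "coefficient_table")) dgn_tables
            else dgn_tables[[combo_key(ex$combination)]]
      if (is.null(dt)) stop(sprintf("no DgN table for %s",
                                    format(ex$combination)))
      dgn <- interpolate_coefficient(dt, ex$hvl_mmal, ex$thickness_cm,
                                     clamp = clamp)
      dance <- dance_agd(report$k_ai[i], g, cf, s)
      wu <- wu_agd(report$k_ai[i], dgn)
      list(dance = dance, wu = wu)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      report$compare_error[i] <- conditionMessage(res)
    } else {
      report$agd_dance[i] <- res$dance$value
      report$agd_dance_sigma[i] <- res$dance$sigma
      report$agd_wu[i] <- res$wu$value
      report$agd_wu_sigma[i] <- res$wu$sigma
      report$overlap_dance[i] <- dose_overlap(report$two_abd[i],
                                              report$two_abd_sigma[i],
                                              res$dance$value,
                                              res$dance$sigma)
      report$overlap_wu[i] <- dose_overlap(report$two_abd[i],
                                           report$two_abd_sigma[i],
                                           res$wu$value, res$wu$sigma)
    }
  }
  report
}

#' Agreement of two dose values within combined uncertainties
#'
#' @param a,b Dose values (mGy).
#' @param sigma_a,sigma_b Their 1-sigma uncertainties.
#' @return `TRUE` when `|a - b| <= sigma_a + sigma_b`.
#' @export
dose_overlap <- function(a, sigma_a, b, sigma_b) {
  abs(a - b) <= sigma_a + sigma_b
}

#' Write a dose report
#'
#' CSV for reading, JSON for machines (always full precision).
#'
#' @param report A `dose_report`.
#' @param path Output path; format by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_dose_report <- function(report, path) {
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  else
    utils::write.csv(report, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
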