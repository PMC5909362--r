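# Estimation of the calibration constants from measurement series:
#   - kerma line: OLS of kerma/mAs against kVp (zero-thickness measurements
#     on the reference tube, so yield ratio and inverse-square are both 1)
#   - attenuation: I(x) = I0 exp(-mu_en x) through solid water, nonlinear
#     least squares in intensity space, initialized from the log-linear
#     closed form (log-space OLS also available as a fast diagnostic)
#   - tube yield: replicate mean of kerma/mAs at the reference kVp

#' @rdname fit_kerma_line
#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf("%s fit (%d points, R^2 = %.5f)\n", x$model, x$n_points,
              x$r_squared))
  for (nm in names(x$estimates))
    cat(sprintf("  %-6s %.6g +/- %.3g\n", nm, x$estimates[[nm]], x$sigmas[[nm]]))
  invisible(x)
}

.new_fit <- function(model, estimates, sigmas, r_squared, n_points,
                     residuals, extra = list()) {
  stopifnot(all(sigmas >= 0), n_points >= length(estimates))
  structure(c(list(model = model, estimates = estimates, sigmas = sigmas,
                   r_squared = max(0, min(1, r_squared)), n_points = n_points,
                   residuals = residuals), extra),
            class = "dose_fit")
}

# internal: average replicate rows sharing the same design cells
.average_replicates <- function(df, cells, value) {
  agg <- stats::aggregate(df[[value]], by = df[cells], FUN = mean)
  names(agg)[ncol(agg)] <- value
  agg
}

#' Fit the incident-air-kerma line
#'
#' Ordinary least squares of `kerma / mAs` against `kVp` on zero-thickness
#' measurements of the reference tube, giving the slope `alpha`
#' (mGy/mAs/kVp) and intercept `beta` (mGy/mAs) of the kerma model.
#'
#' @param points A data.frame with columns `kvp`, `mas`, `kerma_mgy` and
#'   optionally `replicate`.
#' @param averaging `"replicates_first"` (default: replicate measurements at
#'   the same `(kvp, mas)` cell are averaged before fitting, matching how
#'   repeated meter readings are treated) or `"pooled"` (every point enters
#'   the regression).
#' @return A `dose_fit` with `estimates` (`alpha`, `beta`), 1-sigma standard
#'   errors, the alpha-beta covariance (`cov_alpha_beta`), and `r_squared`.
#' @export
fit_kerma_line <- function(points, averaging = c("replicates_first", "pooled")) {
  averaging <- match.arg(averaging)
  points <- as.data.frame(points)
  req <- c("kvp", "mas", "kerma_mgy")
  miss <- setdiff(req, names(points))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(points$kerma_mgy <= 0)) stop("kerma must be > 0", call. = FALSE)
  if (any(points$mas <= 0)) stop("mas must be > 0", call. = FALSE)
  if (averaging == "replicates_first")
    points <- .average_replicates(points, c("kvp", "mas"), "kerma_mgy")
  if (length(unique(points$kvp)) < 2L)
    stop("need at least 2 distinct kVp values to fit a line", call. = FALSE)
  y <- points$kerma_mgy / points$mas
  fit <- stats::lm(y ~ kvp, data = data.frame(kvp = points$kvp, y = y))
  # noiseless validation data triggers the "essentially perfect fit"
  # warning in summary.lm; a perfect fit is a legitimate input here
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  vc <- suppressWarnings(stats::vcov(fit))
  r2 <- if (stats::var(y) == 0) 1 else sm$r.squared
  # perfect (noiseless) fits: lm reports NaN standard errors when the
  # residual variance underflows; report 0
  se <- co[, "Std. Error"]
  se[!is.finite(se)] <- 0
  .new_fit("kerma line",
           estimates = c(alpha = unname(co["kvp", "Estimate"]),
                         beta = unname(co["(Intercept)", "Estimate"])),
           sigmas = c(alpha = unname(se["kvp"]),
                      beta = unname(se["(Intercept)"])),
           r_squared = r2, n_points = nrow(points),
           residuals = stats::residuals(fit),
           extra = list(cov_alpha_beta = vc["kvp", "(Intercept)"],
                        design = points))
}

# closed-form log-linear solution, also the nonlinear start
.loglinear_attenuation <- function(depth, intensity) {
  fit <- stats::lm(log(intensity) ~ depth)
  co <- stats::coef(fit)
  list(i0 = exp(unname(co[1])), mu = -unname(co[2]), lm = fit)
}

#' Fit an exponential attenuation series
#'
#' Estimates the incident intensity `I0` and the effective energy absorption
#' coefficient `mu_en` from `I(x) = I0 exp(-mu_en x)`.  The default fits by
#' nonlinear least squares in intensity space (Levenberg-Marquardt,
#' initialized from the log-linear closed form); `method = "loglinear"`
#' returns the log-space OLS solution directly.  `r_squared` is always
#' computed in intensity space.
#'
#' @param points A data.frame with columns `depth_cm`, `intensity_mgy` and
#'   optionally `replicate`.
#' @param method `"nonlinear"` (default) or `"loglinear"`.
#' @param averaging As in [fit_kerma_line()].
#' @return A `dose_fit` with `estimates` (`i0`, `mu_en`) and their sigmas.
#' @export
fit_attenuation <- function(points, method = c("nonlinear", "loglinear"),
                            averaging = c("replicates_first", "pooled")) {
  method <- match.arg(method)
  averaging <- match.arg(averaging)
  points <- as.data.frame(points)
  miss <- setdiff(c("depth_cm", "intensity_mgy"), names(points))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(points$depth_cm < 0)) stop("depth_cm must be >= 0", call. = FALSE)
  if (any(points$intensity_mgy <= 0))
    stop("intensity must be > 0 (cannot take logs)", call. = FALSE)
  if (averaging == "replicates_first")
    points <- .average_replicates(points, "depth_cm", "intensity_mgy")
  if (length(unique(points$depth_cm)) < 2L)
    stop("need at least 2 distinct depths to fit the exponential", call. = FALSE)
  x <- points$depth_cm; I <- points$intensity_mgy
  start <- .loglinear_attenuation(x, I)
  if (method == "loglinear") {
    sm <- suppressWarnings(summary(start$lm))
    se <- sm$coefficients[, "Std. Error"]
    se[!is.finite(se)] <- 0
    fitted_I <- start$i0 * exp(-start$mu * x)
    r2 <- 1 - sum((I - fitted_I)^2) / max(sum((I - mean(I))^2), .Machine$double.eps)
    return(.new_fit("attenuation (log-linear)",
                    estimates = c(i0 = start$i0, mu_en = start$mu),
                    # delta method for I0 = exp(intercept)
                    sigmas = c(i0 = start$i0 * unname(se[1]),
                               mu_en = unname(se[2])),
                    r_squared = r2, n_points = nrow(points),
                    residuals = I - fitted_I,
                    extra = list(design = points)))
  }
  fit <- minpack.lm::nlsLM(I ~ i0 * exp(-mu * x),
                           data = data.frame(x = x, I = I),
                           start = list(i0 = start$i0, mu = start$mu),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- suppressWarnings(summary(fit))$coefficients
  se <- co[, "Std. Error"]
  se[!is.finite(se)] <- 0
  fitted_I <- stats::fitted(fit)
  r2 <- 1 - sum((I - fitted_I)^2) / max(sum((I - mean(I))^2), .Machine$double.eps)
  .new_fit("attenuation (nonlinear)",
           estimates = c(i0 = unname(co["i0", "Estimate"]),
                         mu_en = unname(co["mu", "Estimate"])),
           sigmas = c(i0 = unname(se["i0"]), mu_en = unname(se["mu"])),
           r_squared = r2, n_points = nrow(points),
           residuals = I - fitted_I,
           extra = list(design = points))
}

#' Average the per-kVp energy absorption coefficients
#'
#' The per-combination coefficient is the unweighted arithmetic mean of the
#' per-kVp values (the kVp dependence is weak over the calibrated range).
#' Its sigma is the larger of the sample standard deviation of the values
#' and the mean of the per-kVp sigmas, so neither the spread across kVp nor
#' the individual fit errors is understated.
#'
#' @param mu_en Numeric vector of per-kVp coefficients (1/cm).
#' @param sigma Optional vector of their 1-sigma errors (recycled).
#' @return List with `mu_en` (mean) and `sigma`.
#' @examples
#' average_mu_en(c(1.04, 0.95, 0.89, 0.84, 0.81))  # Mo-Mo: 0.906 -> 0.91
#' @export
average_mu_en <- function(mu_en, sigma = 0) {
  if (length(mu_en) == 0L) stop("empty mu_en set", call. = FALSE)
  sigma <- rep_len(sigma, length(mu_en))
  spread <- if (length(mu_en) > 1L) stats::sd(mu_en) else 0
  list(mu_en = mean(mu_en), sigma = max(spread, mean(sigma)))
}

#' Tube yield from replicate measurements at the reference kVp
#'
#' @param points Data.frame with columns `kvp`, `mas`, `kerma_mgy`: repeated
#'   zero-thickness measurements, all at the same (reference) kVp.
#' @return List with `Y` (mean kerma/mAs, mGy/mAs), `sigma` (sample standard
#'   deviation; 0 with a warning when only one measurement), `kvp`, `n`.
#' @export
tube_yield <- function(points) {
  points <- as.data.frame(points)
  miss <- setdiff(c("kvp", "mas", "kerma_mgy"), names(points))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(points) == 0L) stop("no yield measurements", call. = FALSE)
  if (length(unique(points$kvp)) != 1L)
    stop("yield measurements mix kVp values; all must share the reference kVp",
         call. = FALSE)
  y <- points$kerma_mgy / points$mas
  s <- if (length(y) > 1L) stats::sd(y) else {
    warning("single yield measurement: sigma reported as 0", call. = FALSE)
    0
  }
  list(Y = mean(y), sigma = s, kvp = points$kvp[1], n = length(y))
}

#' Consistency of a calibration's line and measured yield
#'
#' The kerma line evaluated at the reference kVp and the measured yield `Y0`
#' estimate the same physical quantity by different routes; their relative
#' difference `(alpha*ref_kvp + beta)/Y0 - 1` is a self-check on the
#' calibration set.
#'
#' @param cal A [tube_calibration()].
#' @return Signed relative difference.
#' @export
calibration_self_check <- function(cal) {
  (cal$alpha * cal$reference_kvp + cal$beta) / cal$Y0 - 1
}

# ---- measurement CSV interfaces -------------------------------------------

#' Read calibration measurement CSVs
#'
#' `read_kerma_csv()` expects columns `combination, kvp, mas, kerma_mgy,
#' replicate`; `read_attenuation_csv()` expects `combination, kvp, depth_cm,
#' intensity_mgy, replicate` (UTF-8, dot decimal, header required).
#'
#' @param path CSV file path.
#' @return A data.frame with the validated columns.
#' @export
read_kerma_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("combination", "kvp", "mas", "kerma_mgy"), names(df))
  if (length(miss))
    stop("kerma CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_kerma_csv
#' @export
read_attenuation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("combination", "kvp", "depth_cm", "intensity_mgy"),
                  names(df))
  if (length(miss))
    stop("attenuation CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Export a fit report as JSON
#'
#' @param fit A `dose_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(model = fit$model,
                            estimates = as.list(fit$estimates),
                            sigmas = as.list(fit$sigmas),
                            r_squared = fit$r_squared,
                            n_points = fit$n_points,
                            residuals = fit$residuals),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
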