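# Core record types: tube calibration, device profile, exam record.
# All quantities repo-wide are cm, mGy, kVp, mAs, cm^-1 and mm Al (HVL);
# DICOM thickness (mm) is converted at ingest.

#' Tube calibration constants for one anode-filter combination
#'
#' Holds the fitted physics constants behind the incident-air-kerma line
#' (`k/mAs = alpha * kVp + beta`), the measured reference tube yield `Y0`
#' (kerma per mAs at the reference kVp, zero thickness), and the effective
#' energy absorption coefficient `mu_en` of water-equivalent soft tissue for
#' that spectrum, each with a 1-sigma uncertainty.
#'
#' @param combination An [anode_filter()] object or combination string.
#' @param alpha Kerma line slope (mGy / mAs / kVp), `> 0`.
#' @param beta Kerma line intercept (mGy / mAs).
#' @param Y0 Reference tube yield (mGy / mAs at `reference_kvp`, d = 0), `> 0`.
#' @param mu_en Average energy absorption coefficient (1/cm), `> 0`.
#' @param alpha_sigma,beta_sigma,Y0_sigma,mu_en_sigma 1-sigma uncertainties
#'   (all `>= 0`).
#' @param reference_kvp Tube voltage at which yields are defined (default 28).
#' @param mu_en_by_kvp Optional per-kVp table: a data.frame with columns
#'   `kvp`, `mu_en` and optionally `sigma`, for `mu_en_mode = "per_kvp"`.
#' @param kvp_validity Closed interval of calibrated tube voltages
#'   (default `c(22, 34)`); use outside it is allowed with a warning.
#' @return An object of class `tube_calibration`.
#' @seealso [default_calibrations()] for the bundled constants.
#' @export
tube_calibration <- function(combination, alpha, beta, Y0, mu_en,
                             alpha_sigma = 0, beta_sigma = 0,
                             Y0_sigma = 0, mu_en_sigma = 0,
                             reference_kvp = 28,
                             mu_en_by_kvp = NULL,
                             kvp_validity = c(22, 34)) {
  if (!inherits(combination, "anode_filter"))
    combination <- parse_combination(combination)
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(Y0),
            is.numeric(mu_en), length(kvp_validity) == 2L)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (Y0 <= 0) stop("Y0 must be > 0", call. = FALSE)
  if (mu_en <= 0) stop("mu_en must be > 0", call. = FALSE)
  if (alpha * reference_kvp + beta <= 0)
    stop("kerma line is non-positive at the reference kVp", call. = FALSE)
  sig <- c(alpha_sigma, beta_sigma, Y0_sigma, mu_en_sigma)
  if (any(sig < 0)) stop("sigmas must be >= 0", call. = FALSE)
  if (!is.null(mu_en_by_kvp)) {
    mu_en_by_kvp <- as.data.frame(mu_en_by_kvp)
    if (!all(c("kvp", "mu_en") %in% names(mu_en_by_kvp)))
      stop("mu_en_by_kvp needs columns 'kvp' and 'mu_en'", call. = FALSE)
    if (is.null(mu_en_by_kvp$sigma)) mu_en_by_kvp$sigma <- 0
    mu_en_by_kvp <- mu_en_by_kvp[order(mu_en_by_kvp$kvp), , drop = FALSE]
  }
  structure(list(combination = combination,
                 alpha = alpha, alpha_sigma = alpha_sigma,
                 beta = beta, beta_sigma = beta_sigma,
                 Y0 = Y0, Y0_sigma = Y0_sigma,
                 mu_en = mu_en, mu_en_sigma = mu_en_sigma,
                 reference_kvp = reference_kvp,
                 mu_en_by_kvp = mu_en_by_kvp,
                 kvp_validity = sort(as.numeric(kvp_validity))),
            class = "tube_calibration")
}

#' @export
print.tube_calibration <- function(x, ...) {
  cat(sprintf("Tube calibration %s\n", format(x$combination)))
  cat(sprintf("  alpha  %.5g +/- %.2g mGy/mAs/kVp\n", x$alpha, x$alpha_sigma))
  cat(sprintf("  beta   %.5g +/- %.2g mGy/mAs\n", x$beta, x$beta_sigma))
  cat(sprintf("  Y0     %.4g +/- %.2g mGy/mAs at %g kVp\n",
              x$Y0, x$Y0_sigma, x$reference_kvp))
  cat(sprintf("  mu_en  %.3g +/- %.2g 1/cm%s\n", x$mu_en, x$mu_en_sigma,
              if (!is.null(x$mu_en_by_kvp)) sprintf(" (per-kVp table, %d entries)",
                                                    nrow(x$mu_en_by_kvp)) else ""))
  cat(sprintf("  calibrated kVp range [%g, %g]\n",
              x$kvp_validity[1], x$kvp_validity[2]))
  invisible(x)
}

#' Device profile: geometry and tube output of one mammography unit
#'
#' @param device_id Free-text identifier matched against exam records.
#' @param fid_cm Focus-to-image distance (cm), `> 0`.
#' @param yields Named list (by canonical combination string) of tube yields:
#'   each entry either a single number `Y` (mGy/mAs at the reference kVp) or
#'   a list/vector with elements `Y` and `sigma`.
#' @return An object of class `device_profile`.
#' @export
device_profile <- function(device_id, fid_cm, yields) {
  stopifnot(is.character(device_id), length(device_id) == 1L)
  if (!is.numeric(fid_cm) || fid_cm <= 0) stop("FID must be > 0", call. = FALSE)
  out <- list()
  for (nm in names(yields)) {
    y <- yields[[nm]]
    if (is.numeric(y) && is.null(names(y))) y <- list(Y = y[1], sigma = 0)
    y <- as.list(y)
    if (is.null(y$sigma)) y$sigma <- 0
    if (!is.numeric(y$Y) || y$Y <= 0)
      stop(sprintf("yield for %s must be > 0", nm), call. = FALSE)
    if (y$sigma < 0) stop("yield sigma must be >= 0", call. = FALSE)
    out[[combo_key(nm)]] <- list(Y = as.numeric(y$Y), sigma = as.numeric(y$sigma))
  }
  structure(list(device_id = device_id, fid_cm = as.numeric(fid_cm),
                 yields = out),
            class = "device_profile")
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("Device '%s': FID %g cm; yields for %s\n", x$device_id,
              x$fid_cm, paste(names(x$yields), collapse = ", ")))
  invisible(x)
}

# internal: yield lookup with a structured error
device_yield <- function(device, combination) {
  key <- combo_key(combination)
  y <- device$yields[[key]]
  if (is.null(y))
    stop(sprintf("device '%s' has no yield for combination %s",
                 device$device_id, key), call. = FALSE)
  y
}

#' One mammographic exposure's acquisition parameters
#'
#' @param exam_id Free-text identifier.
#' @param combination [anode_filter()] or combination string.
#' @param kvp Tube voltage (kVp), `> 0`.
#' @param mas Tube current-time product (mAs), `> 0`.
#' @param thickness_cm Compressed breast thickness (cm), `>= 0`.
#' @param device_id Identifier resolved against a device registry.
#' @param thickness_sigma_cm 1-sigma thickness uncertainty; the 0.5 cm
#'   default is the tolerance quoted in device technical manuals.
#' @param age_years,glandularity_pct,hvl_mmal Optional patient age, breast
#'   glandularity (%) and measured half value layer (mm Al).
#' @return An object of class `exam_record`.
#' @export
exam_record <- function(exam_id, combination, kvp, mas, thickness_cm,
                        device_id, thickness_sigma_cm = 0.5,
                        age_years = NA_real_, glandularity_pct = NA_real_,
                        hvl_mmal = NA_real_) {
  if (!inherits(combination, "anode_filter"))
    combination <- parse_combination(combination)
  if (!is.numeric(kvp) || is.na(kvp) || kvp <= 0) stop("kvp must be > 0", call. = FALSE)
  if (!is.numeric(mas) || is.na(mas) || mas <= 0) stop("mas must be > 0", call. = FALSE)
  if (!is.numeric(thickness_cm) || is.na(thickness_cm) || thickness_cm < 0)
    stop("thickness_cm must be >= 0", call. = FALSE)
  if (thickness_sigma_cm < 0) stop("thickness sigma must be >= 0", call. = FALSE)
  if (!is.na(hvl_mmal) && hvl_mmal <= 0) stop("hvl_mmal must be > 0", call. = FALSE)
  structure(list(exam_id = as.character(exam_id), combination = combination,
                 kvp = as.numeric(kvp), mas = as.numeric(mas),
                 thickness_cm = as.numeric(thickness_cm),
                 thickness_sigma_cm = as.numeric(thickness_sigma_cm),
                 device_id = as.character(device_id),
                 age_years = as.numeric(age_years),
                 glandularity_pct = as.numeric(glandularity_pct),
                 hvl_mmal = as.numeric(hvl_mmal)),
            class = "exam_record")
}

#' @export
print.exam_record <- function(x, ...) {
  cat(sprintf("Exam %s: %s, %g kVp, %g mAs, d = %g +/- %g cm (device '%s')\n",
              x$exam_id, format(x$combination), x$kvp, x$mas,
              x$thickness_cm, x$thickness_sigma_cm, x$device_id))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

.cal_to_list <- function(cal) {
  out <- list(combination = format(cal$combination),
              alpha = cal$alpha, alpha_sigma = cal$alpha_sigma,
              beta = cal$beta, beta_sigma = cal$beta_sigma,
              Y0 = cal$Y0, Y0_sigma = cal$Y0_sigma,
              reference_kvp = cal$reference_kvp,
              mu_en = cal$mu_en, mu_en_sigma = cal$mu_en_sigma,
              kvp_validity = cal$kvp_validity)
  if (!is.null(cal$mu_en_by_kvp))
    out$mu_en_by_kvp <- list(kvp = cal$mu_en_by_kvp$kvp,
                             mu_en = cal$mu_en_by_kvp$mu_en,
                             sigma = cal$mu_en_by_kvp$sigma)
  out
}

.cal_from_list <- function(x) {
  mt <- NULL
  if (!is.null(x$mu_en_by_kvp))
    mt <- data.frame(kvp = as.numeric(x$mu_en_by_kvp$kvp),
                     mu_en = as.numeric(x$mu_en_by_kvp$mu_en),
                     sigma = as.numeric(x$mu_en_by_kvp$sigma %||% 0))
  tube_calibration(x$combination, alpha = x$alpha, beta = x$beta,
                   Y0 = x$Y0, mu_en = x$mu_en,
                   alpha_sigma = x$alpha_sigma %||% 0,
                   beta_sigma = x$beta_sigma %||% 0,
                   Y0_sigma = x$Y0_sigma %||% 0,
                   mu_en_sigma = x$mu_en_sigma %||% 0,
                   reference_kvp = x$reference_kvp %||% 28,
                   mu_en_by_kvp = mt,
                   kvp_validity = as.numeric(x$kvp_validity %||% c(22, 34)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write tube calibrations as JSON
#'
#' A calibration set is a JSON object keyed by canonical combination string.
#'
#' @param path File path.
#' @return `read_calibrations()` returns a named list of
#'   [tube_calibration()] objects.
#' @export
read_calibrations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  for (nm in names(raw)) {
    x <- raw[[nm]]
    if (is.null(x$combination)) x$combination <- nm
    out[[combo_key(nm)]] <- .cal_from_list(x)
  }
  out
}

#' @param calibrations Named list of [tube_calibration()] objects.
#' @rdname read_calibrations
#' @export
write_calibrations <- function(calibrations, path) {
  if (inherits(calibrations, "tube_calibration"))
    calibrations <- list(calibrations)
  out <- list()
  for (cal in calibrations) out[[format(cal$combination)]] <- .cal_to_list(cal)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bundled tube calibrations for the five reference combinations
#'
#' Calibration constants of the two reference tubes (GE Senographe DS for
#' Mo-Mo / Mo-Rh / Rh-Rh, Hologic Selenia Dimensions for W-Rh / W-Ag):
#' fitted kerma-line slope/intercept, measured yield at 28 kVp and the
#' per-spectrum energy absorption coefficients (average and per-kVp).
#'
#' @return Named list of [tube_calibration()] objects, keyed by combination.
#' @export
default_calibrations <- function() {
  read_calibrations(system.file("extdata", "tube_calibrations.json",
                                package = "mammodose", mustWork = TRUE))
}

#' Read a device registry (JSON or YAML)
#'
#' The registry maps `device_id` to `{FID_cm, yields: {combo: {Y, sigma}}}`.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return Named list of [device_profile()] objects.
#' @export
read_device_registry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (nm in names(raw)) {
    x <- raw[[nm]]
    out[[nm]] <- device_profile(nm, fid_cm = x$FID_cm, yields = x$yields)
  }
  out
}

#' Bundled example device registry
#'
#' Contains the GE Senographe DS reference unit (FID 63.5 cm) whose yields
#' coincide with the reference yields `Y0`, usable for audits where the
#' clinical tube is the calibration tube.
#'
#' @return Named list of [device_profile()] objects.
#' @export
default_registry <- function() {
  read_device_registry(system.file("extdata", "device_registry.json",
                                   package = "mammodose", mustWork = TRUE))
}

# internal: registry lookup with structured error
registry_device <- function(registry, device_id) {
  dev <- registry[[device_id]]
  if (is.null(dev))
    stop(sprintf("device '%s' not found in registry", device_id), call. = FALSE)
  dev
}
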