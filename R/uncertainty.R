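# First-order (delta-method) uncertainty propagation through the dose
# model.  2ABD is a product of terms in (alpha, beta, Y0, Ytb, kVp, mAs,
# FID, d, mu_en); writing D = (Ytb/Y0) L(kVp) mAs S(FID,d)^2 f(mu d) with
# L = alpha kVp + beta, S = FID/(FID - d), f = (1 - e^-u)/u, the partials
# all reduce to D times a logarithmic sensitivity:
#   dD/dYtb   =  D / Ytb             dD/dY0 = -D / Y0
#   dD/dalpha =  D kVp / L           dD/dbeta = D / L
#   dD/dkVp   =  D alpha / L
#   dD/dFID   = -2 D d / (FID (FID - d))
#   dD/dd     =  D [ 2/(FID - d) + mu f'(u)/f(u) ]
#   dD/dmu    =  D d f'(u)/f(u)
# Sigmas combine in quadrature, with an optional alpha-beta covariance
# cross-term supplied by the kerma-line fit.

#' Uncertainty budget for the dose model
#'
#' 1-sigma uncertainties for each input of the 2ABD model.  `kvp`, `fid`
#' and `mas` default to 0 (set-point values taken as exact); thickness
#' defaults to the 0.5 cm tolerance quoted in device manuals.
#'
#' @param alpha,beta,Y0,Ytb,mu_en Sigmas of the calibration constants and
#'   tube yield (same units as the quantities).
#' @param kvp,d,fid Sigmas of the acquisition parameters (kVp, cm, cm).
#' @param cov_alpha_beta Optional covariance of the fitted (alpha, beta);
#'   included as a cross-term when non-`NULL`.
#' @return An object of class `uncertainty_budget`.
#' @export
uncertainty_budget <- function(alpha = 0, beta = 0, Y0 = 0, Ytb = 0,
                               kvp = 0, d = 0.5, fid = 0, mu_en = 0,
                               cov_alpha_beta = NULL) {
  s <- c(alpha = alpha, beta = beta, Y0 = Y0, Ytb = Ytb, kvp = kvp,
         d = d, fid = fid, mu_en = mu_en)
  if (any(s < 0)) stop("all budget sigmas must be >= 0", call. = FALSE)
  if (!is.null(cov_alpha_beta)) {
    if (alpha > 0 && beta > 0 &&
        abs(cov_alpha_beta) > alpha * beta * (1 + 1e-12))
      stop("alpha-beta covariance implies |correlation| > 1", call. = FALSE)
  }
  structure(list(sigma = s, cov_alpha_beta = cov_alpha_beta),
            class = "uncertainty_budget")
}

#' Default budget assembled from calibration, device and exam sigmas
#'
#' Takes the fit sigmas from the calibration, the yield sigma from the
#' device registry entry, the exam's thickness sigma (0.5 cm unless
#' overridden), and treats kVp and FID as exact.
#'
#' @inheritParams incident_air_kerma
#' @param mu_sigma Optional override for the mu_en sigma (used when a
#'   per-kVp value was interpolated).
#' @return An [uncertainty_budget()].
#' @export
default_budget <- function(cal, device, exam, mu_sigma = NULL) {
  yld <- device_yield(device, exam$combination)
  uncertainty_budget(alpha = cal$alpha_sigma, beta = cal$beta_sigma,
                     Y0 = cal$Y0_sigma, Ytb = yld$sigma,
                     kvp = 0, d = exam$thickness_sigma_cm, fid = 0,
                     mu_en = mu_sigma %||% cal$mu_en_sigma)
}

# internal: 2ABD and its analytic partials w.r.t. the eight inputs
.dose_partials <- function(cal, device, exam, mu_en_mode = "average") {
  yld <- device_yield(device, exam$combination)
  mu <- resolve_mu_en(cal, exam, mu_en_mode)$mu_en
  fid <- device$fid_cm
  d <- exam$thickness_cm
  L <- cal$alpha * exam$kvp + cal$beta
  if (L <= 0) stop("kerma line term non-positive", call. = FALSE)
  u <- mu * d
  f <- attenuation_integral_factor(mu, d)
  D <- (yld$Y / cal$Y0) * L * exam$mas * inverse_square_factor(fid, d) * f
  g <- .attenuation_logderiv(u)  # d ln f / d u at u = mu*d
  partials <- c(alpha = D * exam$kvp / L,
                beta = D / L,
                Y0 = -D / cal$Y0,
                Ytb = D / yld$Y,
                kvp = D * cal$alpha / L,
                d = D * (2 / (fid - d) + mu * g),
                fid = -2 * D * d / (fid * (fid - d)),
                mu_en = D * d * g)
  list(value = D, partials = partials)
}

#' Propagate input uncertainties to 2ABD
#'
#' First-order propagation with analytic partial derivatives, summed in
#' quadrature over the eight model inputs (plus the alpha-beta covariance
#' cross-term when the budget carries one).
#'
#' @inheritParams incident_air_kerma
#' @param budget An [uncertainty_budget()]; defaults to [default_budget()].
#' @param mu_en_mode As in [average_breast_dose()].
#' @return List with `sigma_abs` (mGy), `sigma_rel`, `value` (the 2ABD the
#'   partials were taken at), and `contributions` (per-input absolute
#'   1-sigma terms).
#' @export
propagate_2abd <- function(cal, device, exam, budget = NULL,
                           mu_en_mode = c("average", "per_kvp")) {
  mu_en_mode <- match.arg(mu_en_mode)
  if (is.null(budget)) budget <- default_budget(cal, device, exam)
  dp <- .dose_partials(cal, device, exam, mu_en_mode)
  terms <- dp$partials * budget$sigma[names(dp$partials)]
  var <- sum(terms^2)
  if (!is.null(budget$cov_alpha_beta))
    var <- var + 2 * dp$partials["alpha"] * dp$partials["beta"] *
      budget$cov_alpha_beta
  var <- max(var, 0)
  list(sigma_abs = sqrt(var), sigma_rel = sqrt(var) / dp$value,
       value = dp$value, contributions = abs(terms))
}

#' Finite-difference check of the analytic propagation
#'
#' Rebuilds every partial derivative by central finite differences
#' (relative step `1e-5` per input) and returns the worst relative
#' disagreement with the analytic partials (among inputs with non-zero
#' sensitivity), together with the sigma recomputed from the numeric
#' partials.
#'
#' @inheritParams propagate_2abd
#' @param step Relative finite-difference step.
#' @return List with `max_discrepancy`, `sigma_numeric`, `sigma_analytic`.
#' @export
finite_difference_check <- function(cal, device, exam, budget = NULL,
                                    mu_en_mode = c("average", "per_kvp"),
                                    step = 1e-5) {
  mu_en_mode <- match.arg(mu_en_mode)
  if (is.null(budget)) budget <- default_budget(cal, device, exam)
  base <- list(alpha = cal$alpha, beta = cal$beta, Y0 = cal$Y0,
               Ytb = device_yield(device, exam$combination)$Y,
               kvp = exam$kvp, d = exam$thickness_cm, fid = device$fid_cm,
               mu_en = resolve_mu_en(cal, exam, mu_en_mode)$mu_en)
  eval_dose <- function(p) {
    L <- p$alpha * p$kvp + p$beta
    (p$Ytb / p$Y0) * L * exam$mas * inverse_square_factor(p$fid, p$d) *
      attenuation_integral_factor(p$mu_en, p$d)
  }
  analytic <- .dose_partials(cal, device, exam, mu_en_mode)$partials
  numeric <- analytic
  for (nm in names(base)) {
    h <- step * max(abs(base[[nm]]), step)
    up <- base; up[[nm]] <- base[[nm]] + h
    dn <- base; dn[[nm]] <- base[[nm]] - h
    numeric[nm] <- (eval_dose(up) - eval_dose(dn)) / (2 * h)
  }
  rel <- abs(numeric - analytic) /
    pmax(abs(analytic), .Machine$double.eps^0.5)
  sig <- function(p) sqrt(sum((p * budget$sigma[names(p)])^2))
  list(max_discrepancy = max(rel), sigma_numeric = sig(numeric),
       sigma_analytic = sig(analytic))
}

#' Read an uncertainty budget from JSON
#'
#' JSON keys match the [uncertainty_budget()] arguments; absent keys take
#' the defaults.  The bundled defaults file
#' (`system.file("extdata", "uncertainty_defaults.json", package =
#' "mammodose")`) carries the acquisition-parameter sigmas (thickness
#' 0.5 cm, kVp and FID exact); calibration and yield sigmas live with the
#' calibration set and registry.
#'
#' @param path JSON path.
#' @return An [uncertainty_budget()].
#' @export
read_budget_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(raw),
                    c("alpha", "beta", "Y0", "Ytb", "kvp", "d", "fid",
                      "mu_en", "cov_alpha_beta"))
  do.call(uncertainty_budget, lapply(raw[keep], as.numeric))
}

#' Fixed 20% AGD uncertainty
#'
#' Table-based AGD estimates carry a conventional overall 20% relative
#' error; this returns the corresponding 1-sigma.
#'
#' @param agd_value AGD (mGy), `>= 0`.
#' @return `0.20 * agd_value`.
#' @export
agd_sigma <- function(agd_value) {
  if (any(agd_value < 0)) stop("AGD must be >= 0", call. = FALSE)
  0.20 * agd_value
}
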