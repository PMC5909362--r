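# Closed-form dosimetry.
#
# Incident air kerma at the upper breast surface:
#   k_ai = (Y_tb / Y_0) (alpha kVp + beta) mAs (FID / (FID - d))^2
# and the average absorbed breast dose, the depth average of the
# exponentially attenuated kerma over the compressed thickness d:
#   2ABD = k_ai (1 - exp(-mu_en d)) / (mu_en d)

#' Depth-averaged attenuation factor
#'
#' The dimensionless factor `(1 - exp(-mu*d)) / (mu*d)` that turns incident
#' air kerma into a depth average of the exponentially attenuated beam over
#' thickness `d`.  Continuous at `mu*d -> 0` (series branch below 1e-6),
#' strictly decreasing in `mu*d`, and always in `(0, 1]`.
#'
#' @param mu_en Energy absorption coefficient (1/cm), `>= 0`.
#' @param d Thickness (cm), `>= 0`.
#' @return The attenuation factor, vectorized over its arguments.
#' @examples
#' attenuation_integral_factor(0.68, 5)   # 0.284302
#' attenuation_integral_factor(0, 3)      # 1: zero-attenuation limit
#' @export
attenuation_integral_factor <- function(mu_en, d) {
  if (any(mu_en < 0)) stop("mu_en must be >= 0", call. = FALSE)
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  u <- mu_en * d
  out <- numeric(length(u))
  small <- u < 1e-6
  # 3-term series avoids cancellation in (1 - exp(-u))/u for tiny u
  out[small] <- 1 - u[small] / 2 + u[small]^2 / 6
  out[!small] <- (1 - exp(-u[!small])) / u[!small]
  out
}

# d ln f / d u for f(u) = (1 - e^-u)/u; used by the uncertainty propagation
.attenuation_logderiv <- function(u) {
  out <- numeric(length(u))
  small <- u < 1e-6
  out[small] <- -0.5 + u[small] / 12
  us <- u[!small]
  out[!small] <- (exp(-us) * (1 + us) - 1) / (us * (1 - exp(-us)))
  out
}

#' Inverse-square distance correction
#'
#' `(FID / (FID - d))^2`: scales tube output measured at the image plane to
#' the upper breast surface, a distance `d` closer to the focus.
#'
#' @param fid Focus-to-image distance (cm), `> 0`.
#' @param d Breast thickness (cm), `0 <= d < fid`.
#' @return The correction factor (`>= 1`), vectorized.
#' @examples
#' inverse_square_factor(63.5, 5)  # (63.5/58.5)^2 = 1.178245
#' @export
inverse_square_factor <- function(fid, d) {
  if (any(fid <= 0)) stop("FID must be > 0", call. = FALSE)
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  if (any(d >= fid))
    stop("breast thicker than focus distance (d >= FID)", call. = FALSE)
  (fid / (fid - d))^2
}

# internal: mu_en for an exam under the requested mode
resolve_mu_en <- function(cal, exam, mu_en_mode = c("average", "per_kvp")) {
  mu_en_mode <- match.arg(mu_en_mode)
  if (mu_en_mode == "average")
    return(list(mu_en = cal$mu_en, sigma = cal$mu_en_sigma))
  tab <- cal$mu_en_by_kvp
  if (is.null(tab))
    stop(sprintf("per-kVp mu_en requested but calibration %s has no per-kVp table",
                 format(cal$combination)), call. = FALSE)
  # linear in kVp, clamped at the table ends
  k <- min(max(exam$kvp, min(tab$kvp)), max(tab$kvp))
  list(mu_en = stats::approx(tab$kvp, tab$mu_en, xout = k, rule = 2)$y,
       sigma = stats::approx(tab$kvp, tab$sigma, xout = k, rule = 2)$y)
}

#' Incident air kerma from acquisition parameters
#'
#' Evaluates the calibrated kerma model: yield ratio `Y_tb / Y_0` (both
#' defined at the same reference kVp), the kerma line `(alpha*kVp + beta)`
#' times `mAs`, and the inverse-square correction to the breast entrance
#' surface.  A kVp outside the calibrated range raises a warning (not an
#' error): extrapolation of the linear model is the caller's choice.
#'
#' @param cal A [tube_calibration()] for the exam's combination.
#' @param device A [device_profile()] holding FID and the tube yield.
#' @param exam An [exam_record()].
#' @return An object of class `kerma_result`: `k_ai` (mGy), `sigma`
#'   (first-order 1-sigma from the calibration/yield uncertainties), and
#'   `components` (yield ratio, line term x mAs, inverse-square factor whose
#'   product is `k_ai`).
#' @export
incident_air_kerma <- function(cal, device, exam) {
  if (!isTRUE(cal$combination == exam$combination))
    stop(sprintf("calibration is for %s but exam %s uses %s",
                 format(cal$combination), exam$exam_id,
                 format(exam$combination)), call. = FALSE)
  yld <- device_yield(device, exam$combination)
  if (exam$thickness_cm >= device$fid_cm)
    stop("breast thicker than focus distance (d >= FID)", call. = FALSE)
  line <- cal$alpha * exam$kvp + cal$beta
  if (line <= 0)
    stop(sprintf("kerma line term alpha*kVp+beta = %.4g is non-positive at %g kVp (line root at %.3g kVp)",
                 line, exam$kvp, -cal$beta / cal$alpha), call. = FALSE)
  if (exam$kvp < cal$kvp_validity[1] || exam$kvp > cal$kvp_validity[2])
    warning(sprintf("exam %s: kVp %g outside calibrated range [%g, %g]; extrapolating the kerma line",
                    exam$exam_id, exam$kvp, cal$kvp_validity[1],
                    cal$kvp_validity[2]), call. = FALSE)
  components <- c(yield_ratio = yld$Y / cal$Y0,
                  line_mas = line * exam$mas,
                  inverse_square = inverse_square_factor(device$fid_cm,
                                                         exam$thickness_cm))
  k_ai <- prod(components)
  # first-order sigma from the multiplicative factors that carry calibration
  # uncertainty (Ytb, Y0, alpha, beta); geometry taken as exact here
  rel2 <- (yld$sigma / yld$Y)^2 + (cal$Y0_sigma / cal$Y0)^2 +
    (cal$alpha_sigma * exam$kvp / line)^2 + (cal$beta_sigma / line)^2
  structure(list(k_ai = k_ai, sigma = k_ai * sqrt(rel2),
                 components = components),
            class = "kerma_result")
}

#' @export
print.kerma_result <- function(x, ...) {
  cat(sprintf("k_a,i = %.4g +/- %.2g mGy  (yield ratio %.4g x line*mAs %.4g x inv-square %.4g)\n",
              x$k_ai, x$sigma, x$components[1], x$components[2], x$components[3]))
  invisible(x)
}

#' Average absorbed breast dose (2ABD)
#'
#' The proposed mammography dose index: incident air kerma attenuated
#' exponentially through the compressed breast and averaged over its
#' thickness.  With `mu_en_mode = "average"` (default) the per-combination
#' average coefficient is used; `"per_kvp"` interpolates the calibration's
#' per-kVp table linearly in kVp (clamped at the table ends).
#'
#' @inheritParams incident_air_kerma
#' @param mu_en_mode `"average"` or `"per_kvp"`.
#' @param budget An [uncertainty_budget()]; defaults to the calibration /
#'   device / exam sigmas via [default_budget()].
#' @return An object of class `dose_result`: `two_abd` (mGy), `sigma`,
#'   `sigma_rel`, the underlying `kerma_result`, and the `mu_en` used.
#' @examples
#' cal <- default_calibrations()[["Mo-Mo"]]
#' dev <- default_registry()[["senographe-ds"]]
#' ex <- exam_record("p1", "Mo-Mo", kvp = 25, mas = 32, thickness_cm = 2,
#'                   device_id = "senographe-ds")
#' average_breast_dose(cal, dev, ex)
#' @export
average_breast_dose <- function(cal, device, exam,
                                mu_en_mode = c("average", "per_kvp"),
                                budget = NULL) {
  mu_en_mode <- match.arg(mu_en_mode)
  kr <- incident_air_kerma(cal, device, exam)
  mu <- resolve_mu_en(cal, exam, mu_en_mode)
  d <- exam$thickness_cm
  two_abd <- if (d == 0) kr$k_ai else
    kr$k_ai * attenuation_integral_factor(mu$mu_en, d)
  if (is.null(budget)) budget <- default_budget(cal, device, exam, mu_sigma = mu$sigma)
  pr <- propagate_2abd(cal, device, exam, budget, mu_en_mode = mu_en_mode)
  structure(list(two_abd = two_abd, sigma = pr$sigma_abs,
                 sigma_rel = pr$sigma_rel, k_ai = kr,
                 mu_en = mu$mu_en, mu_en_mode = mu_en_mode,
                 agd_dance = NULL, agd_wu = NULL),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("2ABD = %.4g +/- %.2g mGy (%.1f%%), k_a,i = %.4g mGy, mu_en = %.3g 1/cm [%s]\n",
              x$two_abd, x$sigma, 100 * x$sigma_rel, x$k_ai$k_ai, x$mu_en,
              x$mu_en_mode))
  if (!is.null(x$agd_dance))
    cat(sprintf("AGD (Dance) = %.4g +/- %.2g mGy\n",
                x$agd_dance$value, x$agd_dance$sigma))
  if (!is.null(x$agd_wu))
    cat(sprintf("AGD (Wu)    = %.4g +/- %.2g mGy\n",
                x$agd_wu$value, x$agd_wu$sigma))
  invisible(x)
}
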