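# Synthetic measurement generators.  They emulate the calibration bench
# designs: kerma readings over kVp 22-34 / mAs 10-100 with five replicates
# per setting, transmission series through 0-5.5 cm of solid water, and
# clinical exposure cohorts spanning the parameter ranges seen in audits
# (kVp 25-30, mAs 18-114, d 2-7 cm, the five calibrated combinations).
# Default measurement noise is 1% multiplicative Gaussian, the
# repeatability scale of solid-state dosemeters; every generator is fully
# determined by its seed.

.apply_noise <- function(x, noise, sigma, positive = TRUE) {
  noise <- match.arg(noise, c("none", "gaussian_relative", "gaussian_absolute"))
  if (noise == "none" || sigma == 0) return(x)
  out <- if (noise == "gaussian_relative")
    x * (1 + stats::rnorm(length(x), 0, sigma))
  else x + stats::rnorm(length(x), 0, sigma)
  if (positive) {
    bad <- which(out <= 0)
    for (i in bad) {  # resample the rare non-positive draws
      repeat {
        v <- if (noise == "gaussian_relative")
          x[i] * (1 + stats::rnorm(1, 0, sigma))
        else x[i] + stats::rnorm(1, 0, sigma)
        if (v > 0) break
      }
      out[i] <- v
    }
  }
  out
}

#' Generate a kerma calibration measurement set
#'
#' Zero-thickness kerma readings from the linear tube-output model
#' `kerma = (alpha*kVp + beta) * mAs`, optionally noised.
#'
#' @param alpha,beta Generating truth (mGy/mAs/kVp, mGy/mAs).
#' @param kvp_grid,mas_grid Design grids; every (kVp, mAs) cell is measured.
#' @param replicates Measurements per cell (default 5).
#' @param noise `"none"`, `"gaussian_relative"` or `"gaussian_absolute"`.
#' @param sigma Noise scale (relative fraction or mGy).
#' @param seed Integer seed; fully determines the output.
#' @return Data.frame with columns `kvp, mas, kerma_mgy, replicate`.
#' @export
generate_kerma_calibration <- function(alpha, beta,
                                       kvp_grid = seq(22, 34, by = 1),
                                       mas_grid = c(10, 20, 40, 63, 100),
                                       replicates = 5,
                                       noise = "gaussian_relative",
                                       sigma = 0.01, seed = 1) {
  line <- alpha * kvp_grid + beta
  if (any(line <= 0))
    stop(sprintf("kerma line non-positive at kVp %s (line root at %.3g kVp)",
                 paste(kvp_grid[line <= 0], collapse = ", "), -beta / alpha),
         call. = FALSE)
  design <- expand.grid(replicate = seq_len(replicates), mas = mas_grid,
                        kvp = kvp_grid)[, c("kvp", "mas", "replicate")]
  truth <- (alpha * design$kvp + beta) * design$mas
  set.seed(seed)
  design$kerma_mgy <- .apply_noise(truth, noise, sigma)
  design
}

#' Generate an exponential attenuation series
#'
#' Transmission readings from `I(x) = I0 * exp(-mu_en * x)`.
#'
#' @param i0 Incident intensity (mGy), `> 0`.
#' @param mu_en Generating absorption coefficient (1/cm), `> 0`.
#' @param depths Solid-water depths (cm), default 12 levels over 0-5.5 cm.
#' @param replicates Measurements per depth.
#' @inheritParams generate_kerma_calibration
#' @return Data.frame with columns `depth_cm, intensity_mgy, replicate`.
#' @export
generate_attenuation_series <- function(i0, mu_en,
                                        depths = seq(0, 5.5, length.out = 12),
                                        replicates = 1,
                                        noise = "gaussian_relative",
                                        sigma = 0.01, seed = 1) {
  if (i0 <= 0) stop("i0 must be > 0", call. = FALSE)
  if (mu_en < 0) stop("mu_en must be >= 0", call. = FALSE)
  if (any(depths < 0)) stop("depths must be >= 0", call. = FALSE)
  design <- expand.grid(replicate = seq_len(replicates),
                        depth_cm = depths)[, c("depth_cm", "replicate")]
  truth <- i0 * exp(-mu_en * design$depth_cm)
  set.seed(seed)
  design$intensity_mgy <- .apply_noise(truth, noise, sigma)
  design
}

#' Generate a synthetic exam cohort
#'
#' Samples `n` plausible screening exposures across the calibrated
#' combinations: kVp 25-30, mAs 18-114, compressed thickness 2-7 cm
#' (thicker breasts paired with harder spectra, loosely following clinical
#' technique selection).  Optionally writes one header-only DICOM file per
#' exam.
#'
#' @param n Cohort size, `>= 1`.
#' @param registry Named list of [device_profile()]s; devices are drawn
#'   from it and combinations from each device's yield table.
#' @param seed Integer seed.
#' @param dicom_dir Optional directory: write `exam_<id>.dcm` fixtures.
#' @return List of [exam_record()]s; when `dicom_dir` is given, the file
#'   paths are attached as attribute `dicom_files`.
#' @export
generate_exam_cohort <- function(n, registry, seed = 1, dicom_dir = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(registry) == 0) stop("registry is empty", call. = FALSE)
  set.seed(seed)
  exams <- vector("list", n)
  for (i in seq_len(n)) {
    dev_id <- sample(names(registry), 1)
    dev <- registry[[dev_id]]
    combo <- sample(names(dev$yields), 1)
    exams[[i]] <- exam_record(
      exam_id = sprintf("syn-%03d", i),
      combination = combo,
      kvp = sample(25:30, 1),
      mas = round(stats::runif(1, 18, 114)),
      thickness_cm = round(stats::runif(1, 2, 7), 1),
      device_id = dev_id,
      age_years = sample(40:64, 1),
      glandularity_pct = round(stats::runif(1, 10, 100)))
  }
  if (!is.null(dicom_dir)) {
    if (!dir.exists(dicom_dir)) dir.create(dicom_dir, recursive = TRUE)
    files <- vapply(exams, function(e) {
      p <- file.path(dicom_dir, paste0("exam_", e$exam_id, ".dcm"))
      write_exam_dicom(e, p, fid_cm = registry[[e$device_id]]$fid_cm)
      p
    }, character(1))
    attr(exams, "dicom_files") <- files
  }
  exams
}
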