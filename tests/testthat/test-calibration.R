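# Estimation of alpha/beta, mu_en, I0 and tube yields.

test_that("noiseless kerma line is recovered to 6+ significant digits", {
  pts <- generate_kerma_calibration(0.00997, -0.186, noise = "none")
  fit <- fit_kerma_line(pts)
  expect_equal(fit$estimates[["alpha"]], 0.00997, tolerance = 1e-9)
  expect_equal(fit$estimates[["beta"]], -0.186, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("two-point kerma line equals the closed-form slope/intercept", {
  y1 <- 0.04; y2 <- 0.13
  pts <- data.frame(kvp = c(22, 34), mas = 1, kerma_mgy = c(y1, y2))
  fit <- fit_kerma_line(pts)
  expect_equal(fit$estimates[["alpha"]], (y2 - y1) / 12, tolerance = 1e-12)
  expect_equal(fit$estimates[["beta"]], y1 - 22 * (y2 - y1) / 12,
               tolerance = 1e-12)
})

test_that("kerma-line residuals are orthogonal to the design (OLS)", {
  pts <- generate_kerma_calibration(0.00997, -0.186, sigma = 0.02, seed = 11)
  fit <- fit_kerma_line(pts)
  kvp <- fit$design$kvp
  expect_lt(abs(sum(fit$residuals)), 1e-8)
  expect_lt(abs(sum(fit$residuals * kvp)), 1e-8)
})

test_that("kerma-line fit needs two distinct kVp values", {
  pts <- data.frame(kvp = 28, mas = c(10, 20), kerma_mgy = c(0.93, 1.86))
  expect_error(fit_kerma_line(pts), "distinct kVp")
})

test_that("replicate averaging happens before the fit when requested", {
  # replicate counts unbalanced across cells: pooled and averaged fits differ
  pts <- rbind(
    data.frame(kvp = 24, mas = 10, kerma_mgy = c(0.53, 0.55, 0.57, 0.59),
               replicate = 1:4),
    data.frame(kvp = 30, mas = 10, kerma_mgy = 1.13, replicate = 1),
    data.frame(kvp = 34, mas = 10, kerma_mgy = 1.55, replicate = 1))
  f_avg <- fit_kerma_line(pts, averaging = "replicates_first")
  f_pool <- fit_kerma_line(pts, averaging = "pooled")
  expect_equal(f_avg$n_points, 3)
  expect_equal(f_pool$n_points, 6)
  expect_false(isTRUE(all.equal(f_avg$sigmas[["alpha"]],
                                f_pool$sigmas[["alpha"]])))
})

test_that("noiseless exponential is recovered exactly by both methods", {
  pts <- generate_attenuation_series(2.08, 0.76, depths = 0:5, noise = "none")
  for (m in c("nonlinear", "loglinear")) {
    fit <- fit_attenuation(pts, method = m)
    expect_equal(fit$estimates[["i0"]], 2.08, tolerance = 1e-7)
    expect_equal(fit$estimates[["mu_en"]], 0.76, tolerance = 1e-7)
  }
})

test_that("two-point attenuation series gives the log-ratio closed form", {
  i0 <- 1.45; mu <- 0.9
  pts <- data.frame(depth_cm = c(0, 1), intensity_mgy = c(i0, i0 * exp(-mu)))
  fit <- fit_attenuation(pts)
  expect_equal(fit$estimates[["mu_en"]],
               log(pts$intensity_mgy[1] / pts$intensity_mgy[2]),
               tolerance = 1e-9)
})

test_that("attenuation fit guards its inputs", {
  expect_error(fit_attenuation(data.frame(depth_cm = c(2, 2, 2),
                                          intensity_mgy = c(1, 1.1, 0.9))),
               "distinct depths")
  expect_error(fit_attenuation(data.frame(depth_cm = 0:2,
                                          intensity_mgy = c(1, -0.5, 0.2))),
               "> 0")
})

test_that("loglinear and nonlinear fits agree within 0.5% under 1% noise", {
  # the two estimators weight the low-intensity deep points differently, so
  # individual draws scatter against each other; as estimators (over 50
  # seeds) they agree far inside 0.5%
  fits <- vapply(1:50, function(seed) {
    pts <- generate_attenuation_series(2.08, 0.68, sigma = 0.01, seed = seed)
    c(fit_attenuation(pts, "nonlinear")$estimates[["mu_en"]],
      fit_attenuation(pts, "loglinear")$estimates[["mu_en"]])
  }, c(nl = 0, ll = 0))
  expect_lt(abs(mean(fits["nl", ]) - mean(fits["ll", ])) /
              mean(fits["nl", ]), 0.005)
})

test_that("estimator bias shrinks as replication grows", {
  truth <- 0.68
  mean_mu <- function(noise_sigma, reps) {
    mean(vapply(1:40, function(s) {
      pts <- generate_attenuation_series(2.08, truth, replicates = reps,
                                         sigma = noise_sigma, seed = s)
      fit_attenuation(pts)$estimates[["mu_en"]]
    }, 0))
  }
  for (sig in c(0.005, 0.01, 0.02)) {
    err1 <- abs(mean_mu(sig, 1) - truth)
    err4 <- abs(mean_mu(sig, 4) - truth)
    expect_lt(err4, max(err1, 0.004))
  }
})

test_that("per-combination mu_en averages round to the reference constants", {
  # per-kVp columns -> combination averages (2-decimal rounding)
  expect_equal(round(average_mu_en(c(1.04, 0.95, 0.89, 0.84, 0.81))$mu_en, 2),
               0.91)
  expect_equal(round(average_mu_en(c(0.58, 0.55, 0.52, 0.50, 0.48))$mu_en, 2),
               0.53)
  one <- average_mu_en(0.70, 0.02)
  expect_equal(one$mu_en, 0.70)
  expect_equal(one$sigma, 0.02)
  expect_error(average_mu_en(numeric(0)), "empty")
})

test_that("tube yield is the replicate mean of kerma/mAs", {
  five <- data.frame(kvp = 28, mas = 1, kerma_mgy = rep(0.0938, 5))
  y <- tube_yield(five)
  expect_equal(y$Y, 0.0938)
  expect_equal(y$sigma, 0)
  three <- data.frame(kvp = 28, mas = 1,
                      kerma_mgy = c(0.093, 0.094, 0.095))
  y3 <- tube_yield(three)
  expect_equal(y3$Y, 0.094)
  expect_equal(y3$sigma, 0.001, tolerance = 1e-9)
  expect_error(tube_yield(three[0, ]), "no yield")
  expect_error(tube_yield(data.frame(kvp = c(28, 30), mas = 1,
                                     kerma_mgy = c(0.09, 0.10))),
               "mix kVp")
  expect_warning(tube_yield(three[1, ]), "single")
})
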