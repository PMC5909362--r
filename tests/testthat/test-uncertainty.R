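# Delta-method propagation and its finite-difference / Monte-Carlo oracles.

test_that("zero budget propagates to zero sigma", {
  cal <- ref_cals[["Mo-Mo"]]; dev <- make_device("Mo-Mo")
  ex <- make_exam("Mo-Mo", 28, 20, 4, "test-device")
  zero <- uncertainty_budget(d = 0)
  pr <- propagate_2abd(cal, dev, ex, zero)
  expect_identical(pr$sigma_abs, 0)
  fd <- finite_difference_check(cal, dev, ex, zero)
  expect_identical(fd$sigma_numeric, 0)
})

test_that("a lone yield sigma gives exactly its relative error", {
  cal <- ref_cals[["Mo-Mo"]]
  dev <- make_device("Mo-Mo", Y = 0.0944, sigma = 0.002)
  ex <- make_exam("Mo-Mo", 28, 20, 4, "test-device")
  budget <- uncertainty_budget(Ytb = 0.002, d = 0)
  pr <- propagate_2abd(cal, dev, ex, budget)
  expect_equal(pr$sigma_rel, 0.002 / 0.0944, tolerance = 1e-12)
})

test_that("analytic partials match central finite differences", {
  set.seed(5)
  for (i in 1:100) {
    combo <- sample(names(ref_cals), 1)
    cal <- ref_cals[[combo]]
    dev <- make_device(combo, fid = runif(1, 55, 70),
                       Y = cal$Y0 * runif(1, 0.8, 1.2), sigma = 0.001)
    ex <- make_exam(combo, kvp = round(runif(1, 24, 32)),
                    mas = runif(1, 10, 110), d = runif(1, 0.5, 7.5),
                    device_id = "test-device")
    fd <- suppressWarnings(finite_difference_check(cal, dev, ex))
    expect_lt(fd$max_discrepancy, 1e-4)
  }
})

test_that("large thickness sigma stays in the first-order regime", {
  cal <- ref_cals[["Rh-Rh"]]; dev <- make_device("Rh-Rh")
  ex <- make_exam("Rh-Rh", 29, 60, 6, "test-device")
  budget <- uncertainty_budget(d = 2)
  fd <- finite_difference_check(cal, dev, ex, budget)
  expect_lt(fd$max_discrepancy, 1e-3)
  expect_equal(fd$sigma_numeric, fd$sigma_analytic, tolerance = 1e-6)
})

test_that("enlarging any single sigma never decreases sigma(2ABD)", {
  cal <- ref_cals[["Mo-Rh"]]; dev <- make_device("Mo-Rh")
  ex <- make_exam("Mo-Rh", 27, 50, 4, "test-device")
  base_args <- list(alpha = 1e-5, beta = 1e-3, Y0 = 5e-4, Ytb = 5e-4,
                    kvp = 0.2, d = 0.5, fid = 0.1, mu_en = 0.02)
  base <- propagate_2abd(cal, dev, ex,
                         do.call(uncertainty_budget, base_args))$sigma_abs
  for (nm in names(base_args)) {
    args <- base_args; args[[nm]] <- args[[nm]] * 3
    bumped <- propagate_2abd(cal, dev, ex,
                             do.call(uncertainty_budget, args))$sigma_abs
    expect_gte(bumped, base)
  }
})

test_that("sigma scales linearly with the dose (multiplicative structure)", {
  cal <- ref_cals[["Mo-Mo"]]; dev <- make_device("Mo-Mo")
  ex1 <- make_exam("Mo-Mo", 28, 20, 4, "test-device")
  ex2 <- make_exam("Mo-Mo", 28, 60, 4, "test-device")  # 3x the mAs
  p1 <- propagate_2abd(cal, dev, ex1)
  p2 <- propagate_2abd(cal, dev, ex2)
  expect_equal(p2$sigma_abs, 3 * p1$sigma_abs, tolerance = 1e-9)
  expect_equal(p2$sigma_rel, p1$sigma_rel, tolerance = 1e-12)
})

test_that("alpha-beta covariance enters as a cross-term", {
  cal <- ref_cals[["Mo-Mo"]]; dev <- make_device("Mo-Mo")
  ex <- make_exam("Mo-Mo", 28, 20, 4, "test-device")
  no_cov <- uncertainty_budget(alpha = 5e-5, beta = 1e-3, d = 0)
  # anticorrelated slope/intercept (the usual case for a fitted line
  # with positive abscissae) shrinks the combined sigma
  with_cov <- uncertainty_budget(alpha = 5e-5, beta = 1e-3, d = 0,
                                 cov_alpha_beta = -0.9 * 5e-5 * 1e-3)
  s0 <- propagate_2abd(cal, dev, ex, no_cov)$sigma_abs
  s1 <- propagate_2abd(cal, dev, ex, with_cov)$sigma_abs
  expect_lt(s1, s0)
  expect_error(uncertainty_budget(alpha = 1e-5, beta = 1e-3,
                                  cov_alpha_beta = 1), "correlation")
})

test_that("delta-method sigma agrees with Monte Carlo on a smooth case", {
  cal <- ref_cals[["Rh-Rh"]]; dev <- make_device("Rh-Rh")
  ex <- make_exam("Rh-Rh", 28, 48, 5, "test-device")
  budget <- uncertainty_budget(alpha = cal$alpha_sigma, beta = cal$beta_sigma,
                               Y0 = cal$Y0_sigma, Ytb = cal$Y0_sigma,
                               d = 0.3, mu_en = cal$mu_en_sigma)
  pr <- propagate_2abd(cal, dev, ex, budget)
  set.seed(99)
  n <- 20000
  draws <- vapply(seq_len(n), function(i) {
    a <- rnorm(1, cal$alpha, budget$sigma["alpha"])
    b <- rnorm(1, cal$beta, budget$sigma["beta"])
    y0 <- rnorm(1, cal$Y0, budget$sigma["Y0"])
    ytb <- rnorm(1, cal$Y0, budget$sigma["Ytb"])
    d <- rnorm(1, ex$thickness_cm, budget$sigma["d"])
    mu <- rnorm(1, cal$mu_en, budget$sigma["mu_en"])
    (ytb / y0) * (a * ex$kvp + b) * ex$mas *
      inverse_square_factor(dev$fid_cm, d) *
      attenuation_integral_factor(mu, d)
  }, 0)
  expect_equal(sd(draws), pr$sigma_abs, tolerance = 0.03)
})

test_that("the 20% AGD rule is linear and guarded", {
  expect_equal(agd_sigma(1.0), 0.2)
  expect_equal(agd_sigma(0), 0)
  expect_equal(agd_sigma(1.5), 0.3)
  expect_error(agd_sigma(-1), ">= 0")
})

test_that("budget JSON round-trips through the bundled defaults", {
  path <- system.file("extdata", "uncertainty_defaults.json",
                      package = "mammodose")
  b <- read_budget_json(path)
  expect_equal(unname(b$sigma["d"]), 0.5)
  expect_equal(unname(b$sigma["kvp"]), 0)
  expect_equal(unname(b$sigma["fid"]), 0)
})
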