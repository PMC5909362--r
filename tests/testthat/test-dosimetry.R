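# Closed-form kerma and dose evaluation.

test_that("attenuation factor matches direct evaluation and limits", {
  expect_identical(attenuation_integral_factor(0, 3), 1)
  expect_equal(attenuation_integral_factor(0.68, 5),
               (1 - exp(-3.4)) / 3.4, tolerance = 1e-12)
  expect_equal(attenuation_integral_factor(0.68, 5), 0.284302,
               tolerance = 1e-6)
  expect_equal(attenuation_integral_factor(0.91, 2), 0.460425,
               tolerance = 1e-6)
  expect_error(attenuation_integral_factor(-0.1, 3), ">= 0")
  expect_error(attenuation_integral_factor(0.5, -1), ">= 0")
})

test_that("attenuation factor equals quadrature of the defining integral", {
  # oracle: composite Simpson integration of int_0^d exp(-mu x) dx / d,
  # 1e4 panels (accurate well below the 1e-8 band being asserted)
  quad_factor <- function(mu, d) {
    x <- seq(0, d, length.out = 10001)
    y <- exp(-mu * x)
    h <- x[2] - x[1]
    n <- length(x)
    (h / 3) * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, by = 2)]) +
                 2 * sum(y[seq(3, n - 2, by = 2)])) / d
  }
  for (mu in seq(0.1, 1.2, by = 0.25)) {
    for (d in c(0.5, 2, 4.5, 8)) {
      expect_equal(attenuation_integral_factor(mu, d), quad_factor(mu, d),
                   tolerance = 1e-8)
    }
  }
})

test_that("series and exact branches agree at the switch threshold", {
  u <- 1e-6  # switch point; evaluate both branch formulas at the same u
  series <- 1 - u / 2 + u^2 / 6
  exact <- (1 - exp(-u)) / u
  expect_equal(series, exact, tolerance = 1e-10)
  # the function itself is continuous through the switch
  expect_equal(attenuation_integral_factor(u * (1 - 1e-6), 1),
               attenuation_integral_factor(u * (1 + 1e-6), 1),
               tolerance = 1e-10)
  # strictly decreasing in mu*d
  us <- seq(0.01, 6, by = 0.05)
  expect_true(all(diff(attenuation_integral_factor(us, 1)) < 0))
  expect_true(all(attenuation_integral_factor(us, 1) > 0 &
                    attenuation_integral_factor(us, 1) <= 1))
})

test_that("inverse-square factor is exact and guards its domain", {
  expect_identical(inverse_square_factor(63.5, 0), 1)
  expect_equal(inverse_square_factor(63.5, 5), (63.5 / 58.5)^2,
               tolerance = 1e-12)
  expect_equal(inverse_square_factor(63.5, 5), 1.178245, tolerance = 1e-6)
  expect_error(inverse_square_factor(64, 64), "thicker than focus")
  # strictly increasing in d
  ds <- seq(0, 8, by = 0.5)
  expect_true(all(diff(inverse_square_factor(63.5, ds)) > 0))
})

test_that("incident air kerma reduces to the line value when all factors are 1", {
  cal <- ref_cals[["Mo-Mo"]]
  dev <- make_device("Mo-Mo", Y = cal$Y0)
  ex <- make_exam("Mo-Mo", kvp = 28, mas = 1, d = 0, device_id = "test-device")
  kr <- incident_air_kerma(cal, dev, ex)
  expect_equal(kr$k_ai, cal$alpha * 28 + cal$beta, tolerance = 1e-12)
  expect_equal(unname(kr$components), c(1, cal$alpha * 28 + cal$beta, 1),
               tolerance = 1e-12)
})

test_that("kerma components multiply back to k_ai", {
  for (combo in names(ref_cals)) {
    cal <- ref_cals[[combo]]
    dev <- make_device(combo)
    ex <- make_exam(combo, kvp = 29, mas = 55, d = 5.5,
                    device_id = "test-device")
    kr <- incident_air_kerma(cal, dev, ex)
    expect_equal(prod(kr$components), kr$k_ai, tolerance = 1e-12)
  }
})

test_that("kerma errors and warnings name the offending condition", {
  cal <- ref_cals[["Mo-Mo"]]
  dev <- make_device("Mo-Rh")  # yield for the wrong combination
  ex <- make_exam("Mo-Mo", device_id = "test-device")
  expect_error(incident_air_kerma(cal, dev, ex), "no yield")
  dev2 <- make_device("Mo-Mo")
  ex_low <- make_exam("Mo-Mo", kvp = 18, device_id = "test-device")
  expect_error(incident_air_kerma(cal, dev2, ex_low),
               "alpha\\*kVp\\+beta")
  ex_out <- make_exam("Mo-Mo", kvp = 36, device_id = "test-device")
  expect_warning(incident_air_kerma(cal, dev2, ex_out),
                 "outside calibrated range")
})

test_that("2ABD never exceeds k_ai, with equality exactly at d = 0", {
  cal <- ref_cals[["Rh-Rh"]]
  dev <- make_device("Rh-Rh")
  for (d in c(0, 0.5, 2, 5, 8)) {
    ex <- make_exam("Rh-Rh", kvp = 29, mas = 40, d = d,
                    device_id = "test-device")
    dose <- average_breast_dose(cal, dev, ex)
    if (d == 0) expect_identical(dose$two_abd, dose$k_ai$k_ai)
    else expect_lt(dose$two_abd, dose$k_ai$k_ai)
    expect_gt(dose$two_abd, 0)
  }
})

test_that("2ABD decreases in mu_en, k_ai increases in d", {
  dev <- make_device("Rh-Rh")
  ex <- make_exam("Rh-Rh", kvp = 29, mas = 40, d = 5, device_id = "test-device")
  doses <- sapply(seq(0.4, 1.2, by = 0.1), function(mu) {
    cal <- ref_cals[["Rh-Rh"]]; cal$mu_en <- mu
    average_breast_dose(cal, dev, ex)$two_abd
  })
  expect_true(all(diff(doses) < 0))
  ks <- sapply(seq(0, 7, by = 0.5), function(d) {
    ex$thickness_cm <- d
    incident_air_kerma(ref_cals[["Rh-Rh"]], dev, ex)$k_ai
  })
  expect_true(all(diff(ks) > 0))
})

test_that("per-kVp mu_en mode interpolates and clamps the table", {
  cal <- ref_cals[["Mo-Mo"]]  # per-kVp table at 22..30 kVp
  dev <- make_device("Mo-Mo")
  ex25 <- make_exam("Mo-Mo", kvp = 25, mas = 30, d = 3, device_id = "test-device")
  d_avg <- average_breast_dose(cal, dev, ex25, mu_en_mode = "average")
  d_kvp <- average_breast_dose(cal, dev, ex25, mu_en_mode = "per_kvp")
  expect_equal(d_kvp$mu_en, (0.95 + 0.89) / 2)  # midpoint of 24 and 26 kVp
  expect_false(isTRUE(all.equal(d_avg$two_abd, d_kvp$two_abd)))
  ex33 <- make_exam("Mo-Mo", kvp = 33, mas = 30, d = 3, device_id = "test-device")
  expect_equal(average_breast_dose(cal, dev, ex33,
                                   mu_en_mode = "per_kvp")$mu_en, 0.81)
  cal_no_tab <- cal; cal_no_tab$mu_en_by_kvp <- NULL
  expect_error(average_breast_dose(cal_no_tab, dev, ex25,
                                   mu_en_mode = "per_kvp"),
               "no per-kVp table")
})
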