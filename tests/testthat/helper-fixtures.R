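# Shared fixtures: the bundled reference calibrations/registry and small
# builders used across test files.

ref_cals <- default_calibrations()
ref_registry <- default_registry()
ref_device <- ref_registry[["senographe-ds"]]

make_exam <- function(combination = "Mo-Mo", kvp = 28, mas = 20,
                      d = 4, device_id = "senographe-ds", ...) {
  exam_record(paste0("t-", combination, "-", kvp), combination, kvp, mas,
              thickness_cm = d, device_id = device_id, ...)
}

# a one-off device with chosen FID / yield for a single combination
make_device <- function(combination = "Mo-Mo", fid = 63.5, Y = NULL,
                        sigma = 0, id = "test-device") {
  Y <- Y %||% ref_cals[[combination]]$Y0
  yields <- list(); yields[[combination]] <- list(Y = Y, sigma = sigma)
  device_profile(id, fid, yields)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exam rows of the bundled 20-exposure audit cohort
cohort_exams <- function() {
  read_exam_csv(system.file("extdata", "example_exams.csv",
                            package = "mammodose"))
}

# identity coefficient table (all ones) covering the cohort's (HVL, d)
identity_table <- function(name = "wu_dgn") {
  coefficient_table(name, hvl_grid = c(0.2, 0.8), thickness_grid = c(1, 8),
                    values = matrix(1, 2, 2))
}
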